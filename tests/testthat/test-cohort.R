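# Synthetic cohort generator: orientation sampling, head tilt, hierarchy
# construction and signal generation.

small_config <- function(...) {
  cohort_config(n_subjects = 1, n_tracts = 2, n_segments_per_tract = 3,
                n_voxels_per_segment = 4, seed = 71, ...)
}

test_that("uniform orientation sampling has the sin(theta) polar density", {
  v <- sample_orientations(1e5, "uniform_sphere", seed = 72)
  expect_equal(unname(sqrt(rowSums(v^2))), rep(1, nrow(v)), tolerance = 1e-12)
  theta <- acos(pmin(1, abs(v[, 3]))) * 180 / pi
  bins <- seq(0, 90, by = 1)
  obs <- table(cut(theta, bins))
  p <- diff(-cos(bins * pi / 180))   # folded density ~ sin(theta)
  chi <- suppressWarnings(chisq.test(as.vector(obs), p = p / sum(p)))
  expect_gt(chi$p.value, 0.001)
})

test_that("histogram orientation sampling respects the bins", {
  h <- data.frame(lower = 89, upper = 90, prob = 1)
  v <- sample_orientations(500, "custom_histogram", seed = 73, histogram = h)
  theta <- acos(pmin(1, abs(v[, 3]))) * 180 / pi
  expect_true(all(theta >= 89 & theta <= 90))
  expect_error(sample_orientations(5, "custom_histogram",
                                   histogram = data.frame()), "non-empty")
})

test_that("orientation sampling is reproducible under a fixed seed", {
  expect_identical(sample_orientations(50, seed = 74),
                   sample_orientations(50, seed = 74))
})

test_that("head tilt is a proper rotation of the anatomy", {
  v <- sample_orientations(20, seed = 75)
  expect_equal(apply_head_tilt(v, 0), v, tolerance = 1e-12)
  # orientation parallel to the axis is unchanged
  ax <- matrix(c(1, 0, 0), 1)
  expect_equal(apply_head_tilt(ax, 18), ax, tolerance = 1e-12)
  # composition: two 9-degree tilts equal one 18-degree tilt
  expect_equal(apply_head_tilt(apply_head_tilt(v, 9), 9),
               apply_head_tilt(v, 18), tolerance = 1e-12)
  # norms preserved
  expect_equal(rowSums(apply_head_tilt(v, 18)^2), rep(1, 20),
               tolerance = 1e-12)
})

test_that("cohort bookkeeping matches the configured hierarchy", {
  cfg <- small_config()
  ch <- build_cohort(cfg)
  expect_equal(nrow(ch), 1 * 2 * 3 * 4 * 2)   # x 2 head orientations
  expect_setequal(unique(ch$head), c("default", "tilted"))
  expect_true(all(ch$is_sfp))
  expect_equal(sqrt(ch$nx^2 + ch$ny^2 + ch$nz^2), rep(1, nrow(ch)),
               tolerance = 1e-10)
  # theta column consistent with the stored orientation
  expect_equal(ch$theta, acos(pmin(1, abs(ch$nz))) * 180 / pi,
               tolerance = 1e-10)

  # zero jitter: identical tissue in every voxel
  ch0 <- build_cohort(cohort_config(n_subjects = 1, n_tracts = 1,
                                    n_segments_per_tract = 1,
                                    n_voxels_per_segment = 5,
                                    tissue_jitter = 0, seed = 76))
  expect_equal(length(unique(ch0$f)), 1L)
  expect_equal(length(unique(ch0$d_ea_perp)), 1L)

  # jittered parameters stay within their invariants
  chj <- build_cohort(cohort_config(n_subjects = 2, n_tracts = 3,
                                    n_segments_per_tract = 2,
                                    n_voxels_per_segment = 10,
                                    tissue_jitter = 0.3, seed = 77))
  expect_true(all(chj$f >= 0 & chj$f <= 1))
  expect_true(all(chj$d_ea_par >= chj$d_ea_perp))
  expect_true(all(chj$d_ia_par >= chj$d_ia_perp))
})

test_that("within-segment orientations scatter tightly around the tract", {
  ch <- build_cohort(cohort_config(n_subjects = 2, n_tracts = 5,
                                   n_segments_per_tract = 10,
                                   n_voxels_per_segment = 8, seed = 78))
  d <- ch[ch$head == "default", ]
  seg_angles <- d |>
    dplyr::summarise(
      mx = mean(.data$nx), my = mean(.data$ny), mz = mean(.data$nz),
      ang = {
        m <- c(mean(.data$nx), mean(.data$ny), mean(.data$nz))
        m <- m / sqrt(sum(m^2))
        mean(acos(pmin(1, abs(cbind(.data$nx, .data$ny, .data$nz) %*% m))) *
               180 / pi)
      },
      .by = c("subject", "tract", "segment"))
  expect_lt(mean(seg_angles$ang), 10)
})

test_that("cohort and signal tables are reproducible given the seed", {
  cfg <- small_config()
  sch <- default_scheme(n_dirs = 8, te = 54)
  c1 <- build_cohort(cfg); c2 <- build_cohort(cfg)
  expect_identical(c1, c2)
  s1 <- generate_cohort_signals(c1, sch)
  s2 <- generate_cohort_signals(c2, sch)
  expect_identical(s1, s2)
})

test_that("noiseless signals equal the forward-model closed form", {
  cfg <- cohort_config(n_subjects = 1, n_tracts = 1,
                       n_segments_per_tract = 1, n_voxels_per_segment = 1,
                       tissue_jitter = 0, seed = 79)
  ch <- build_cohort(cfg)
  sch <- default_scheme(n_dirs = 8, te = 54)
  sig <- generate_cohort_signals(ch, sch, snr = Inf)
  row <- ch[ch$head == "default", ]
  ts <- tissue_params(f = row$f, d_ia_par = row$d_ia_par,
                      d_ia_perp = row$d_ia_perp, d_ea_par = row$d_ea_par,
                      d_ea_perp = row$d_ea_perp,
                      relax_intra = relaxation_model("constant",
                                                     row$r2_ia_iso),
                      relax_extra = relaxation_model("sin4", row$r2_ea_iso,
                                                     row$r2_ea_aniso),
                      n = c(row$nx, row$ny, row$nz))
  expect_equal(sig$signal[sig$head == "default"],
               signal_no_dispersion(sch, ts), tolerance = 1e-12)
})

test_that("a fibre on the tilt axis gives identical signals in both heads", {
  # one voxel, no scatter, oriented exactly along the L-R axis
  cfg <- cohort_config(n_subjects = 1, n_tracts = 1,
                       n_segments_per_tract = 1, n_voxels_per_segment = 1,
                       tissue_jitter = 0, segment_scatter_sd = 0,
                       voxel_scatter_sd = 0, seed = 80,
                       theta_sampling = "custom_histogram",
                       theta_histogram = data.frame(lower = 90, upper = 90,
                                                    prob = 1))
  ch <- build_cohort(cfg)
  # force the orientation exactly onto the tilt (x) axis in both heads:
  # a fibre along the rotation axis is unchanged by the tilt
  ch[, c("nx", "ny", "nz")] <- rbind(c(1, 0, 0), c(1, 0, 0))
  ch$theta <- c(90, 90)
  sch <- default_scheme(n_dirs = 8, te = 54)
  sig <- generate_cohort_signals(ch, sch, snr = Inf)
  expect_equal(sig$signal[sig$head == "default"],
               sig$signal[sig$head == "tilted"], tolerance = 1e-12)
})

test_that("tilting a theta = 0 fibre lowers the b0 signal at TE 54", {
  # extra-axonal R2 rises with sin^4(theta), so the relaxation-weighted
  # b = 0 signal must drop when the fibre moves from 0 to 18 degrees
  sch <- acquisition_scheme(b = 0, g = rbind(c(0, 0, 0)), te = 54)
  s0 <- signal_no_dispersion(sch, study_tissue(f = 0.4, n = c(0, 0, 1)))
  n18 <- apply_head_tilt(matrix(c(0, 0, 1), 1), 18, c(1, 0, 0))[1, ]
  s18 <- signal_no_dispersion(sch, study_tissue(f = 0.4, n = n18))
  expect_lt(s18, s0)
})

test_that("pooling both head orientations broadens the theta coverage", {
  ch <- build_cohort(cohort_config(n_subjects = 2, n_tracts = 5,
                                   n_segments_per_tract = 10,
                                   n_voxels_per_segment = 8, seed = 81))
  bins <- function(x) length(unique(floor(x)))
  b_default <- bins(ch$theta[ch$head == "default"])
  b_tilted <- bins(ch$theta[ch$head == "tilted"])
  b_pooled <- bins(ch$theta)
  expect_gt(b_pooled, b_default)
  expect_gt(b_pooled, b_tilted)
  expect_gte(diff(range(ch$theta)),
             diff(range(ch$theta[ch$head == "default"])))
})

test_that("config validation guards the cohort parameters", {
  expect_error(cohort_config(n_subjects = 1, seed = 1, tilt_angle = 95),
               "tilt_angle")
  expect_error(cohort_config(n_subjects = 0, seed = 1), ">= 1")
  expect_error(cohort_config(n_subjects = 1), "seed")
})
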