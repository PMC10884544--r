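# Simulation-grid, pooled and tractometry pipelines.

# Broad theta coverage (many tracts) for pooled-spline checks.
pooled_cohort <- function(seed = 91, ...) {
  cohort_config(n_subjects = 1, n_tracts = 25, n_segments_per_tract = 2,
                n_voxels_per_segment = 4, tissue_jitter = 0,
                seed = seed, ...)
}

# Deeper tracts (6 segments) for tractometry exclusion checks.
tract_cohort <- function(seed = 91, tilt = 18, ...) {
  cohort_config(n_subjects = 1, n_tracts = 12, n_segments_per_tract = 6,
                n_voxels_per_segment = 5, tissue_jitter = 0,
                tilt_angle = tilt, seed = seed, ...)
}

test_that("analytic grid reproduces the orientation-dependence signs", {
  g <- run_simulation_grid(f_values = 0.4, te_values = c(54, 130),
                           conditions = "analytic")
  pick <- function(m, te) g$b_hat[g$measure == m & g$te == te]
  expect_gt(pick("ad", 54), 0)
  expect_gt(pick("fa", 54), 0)
  expect_lt(pick("rd", 54), 0)
  # |B| grows with echo time
  expect_gt(abs(pick("rd", 130)), abs(pick("rd", 54)))
  expect_gt(abs(pick("ad", 130)), abs(pick("ad", 54)))
  # one row per condition x measure x TE x f cell, B reported everywhere
  expect_equal(nrow(g), 1 * 4 * 2 * 1)
  expect_true(all(is.finite(g$b_hat)))
})

test_that("removing relaxation anisotropy nullifies the analytic grid", {
  iso_tissue <- tissue_params(
    relax_extra = relaxation_model("constant", 17.4))
  g <- run_simulation_grid(f_values = c(0.3, 0.7), te_values = c(54, 100),
                           conditions = "analytic", tissue = iso_tissue)
  expect_equal(g$b_hat, rep(0, nrow(g)), tolerance = 1e-10)
  expect_true(all(g$selected == "isotropic"))
})

test_that("noisy null grid selects the isotropic representation", {
  iso_tissue <- tissue_params(
    relax_extra = relaxation_model("constant", 17.4))
  g <- run_simulation_grid(f_values = c(0.3, 0.7), te_values = 54,
                           conditions = "noisy", tissue = iso_tissue,
                           n_repeats = 200, seed = 92)
  expect_true(all(g$selected == "isotropic"))
})

test_that("a noisy grid cell recovers the analytic anisotropy", {
  set.seed(93)
  ga <- run_simulation_grid(f_values = 0.4, te_values = 54,
                            conditions = "analytic")
  gn <- run_simulation_grid(f_values = 0.4, te_values = 54,
                            conditions = "noisy", n_repeats = 400,
                            seed = 93)
  for (m in c("ad", "rd")) {
    a <- ga$b_hat[ga$measure == m]
    n <- gn$b_hat[gn$measure == m]
    expect_equal(sign(a), sign(n))
    expect_lt(abs(a - n), 0.5 * abs(a) + 0.01)
  }
})

test_that("dispersed condition produces a complete, finite grid cell", {
  gd <- run_simulation_grid(f_values = 0.4, te_values = 54,
                            conditions = "dispersed", n_repeats = 60,
                            n_nodes = 256, kappa = 16, seed = 94,
                            scheme = default_scheme(n_dirs = 12, te = 54))
  expect_equal(nrow(gd), 4L)   # one row per measure
  expect_true(all(is.finite(gd$b_hat)))
  expect_true(all(gd$condition == "dispersed"))
  expect_true(all(gd$selected %in% c("isotropic", "anisotropic")))
})

test_that("grid runs are bit-reproducible from the seed", {
  a <- run_simulation_grid(f_values = 0.4, te_values = 54,
                           conditions = "noisy", n_repeats = 50, seed = 95)
  b <- run_simulation_grid(f_values = 0.4, te_values = 54,
                           conditions = "noisy", n_repeats = 50, seed = 95)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("end-to-end noiseless cohort recovers analytic AD and RD", {
  cfg <- cohort_config(n_subjects = 1, n_tracts = 3,
                       n_segments_per_tract = 2, n_voxels_per_segment = 2,
                       tissue_jitter = 0, seed = 96)
  ch <- build_cohort(cfg)
  ts <- attr(ch, "config")$tissue

  # low-b scheme: the tensor is a b -> 0 representation, so the chain must
  # reproduce the analytic ADC once higher-order b-terms are negligible
  sch_lo <- default_scheme(n_dirs = 15, b = c(0, 2, 4), te = 54)
  fits_lo <- fit_cohort_dt(generate_cohort_signals(ch, sch_lo, snr = Inf),
                           sch_lo)
  an <- purrr::map_dfr(fits_lo$theta_true,
                       function(th) analytic_dt_measures(54, th, ts))
  expect_lt(max(abs(fits_lo$ad - an$ad)), 1e-4)
  expect_lt(max(abs(fits_lo$rd - an$rd)), 1e-4)
  expect_lt(max(abs(fits_lo$theta - fits_lo$theta_true)), 0.1)

  # at the study shells the bi-exponential signal leaves a small, bounded
  # cumulant-truncation bias in the fitted diffusivities
  sch_hi <- default_scheme(n_dirs = 15, te = 54)
  fits_hi <- fit_cohort_dt(generate_cohort_signals(ch, sch_hi, snr = Inf),
                           sch_hi)
  expect_lt(max(abs(fits_hi$ad - an$ad)), 0.03)
  expect_lt(max(abs(fits_hi$rd - an$rd)), 0.03)
  expect_lt(max(abs(fits_hi$theta - fits_hi$theta_true)), 0.5)
})

test_that("pooled analysis finds the expected signs on noiseless data", {
  cfg <- pooled_cohort()
  sch <- default_scheme(n_dirs = 30, te = 54)
  sig <- generate_cohort_signals(build_cohort(cfg), sch, snr = Inf)
  pa <- run_pooled_analysis(sig, sch)
  s <- pa$summary
  expect_lt(s$b_hat[s$measure == "rd"], 0)
  expect_gt(s$b_hat[s$measure == "ad"], 0)
  expect_gt(s$b_hat[s$measure == "fa"], 0)
  # spline magnitude and sin4 B agree in sign; comparable in size
  for (m in c("ad", "rd", "fa")) {
    row <- s[s$measure == m, ]
    expect_equal(sign(row$magnitude), sign(row$b_hat))
    expect_lt(abs(row$magnitude - row$b_hat), 0.5 * abs(row$b_hat) + 1e-3)
  }
  expect_true(all(s$variance_contribution >= 0))
})

test_that("pooled analysis of a null cohort shows no anisotropy", {
  # dense direction set: residual orientation dependence of the tensor-fit
  # truncation bias shrinks with direction sampling
  iso <- tissue_params(relax_extra = relaxation_model("constant", 17.4))
  cfg <- pooled_cohort(seed = 97, tissue = iso)
  sch <- default_scheme(n_dirs = 60, te = 54)
  sig <- generate_cohort_signals(build_cohort(cfg), sch, snr = Inf)
  pa <- run_pooled_analysis(sig, sch)
  expect_true(all(abs(pa$summary$magnitude) < 1e-3 * pa$summary$a_hat))
})

test_that("tractometry applies the exclusion rules", {
  cfg <- tract_cohort(seed = 98)
  sch <- default_scheme(n_dirs = 15, te = 54)
  sig <- generate_cohort_signals(build_cohort(cfg), sch, snr = Inf)
  fits <- fit_cohort_dt(sig, sch)
  tr <- run_tractometry(fits)
  # 6 segments per tract, 10% trim each end -> segments 2..5 survive
  expect_setequal(unique(tr$segments$segment), 2:5)

  # voxel-count rule: 3 voxels excluded, 4 retained
  f3 <- fits[fits$voxel <= 3, ]
  f4 <- fits[fits$voxel <= 4, ]
  tr3 <- tryCatch(run_tractometry(f3), error = function(e) NULL)
  expect_null(tr3)   # every segment has exactly 3 voxels -> all excluded
  tr4 <- run_tractometry(f4)
  expect_gt(nrow(tr4$segments), 0)
})

test_that("tractometry without tilt is flagged degenerate", {
  cfg <- tract_cohort(seed = 99, tilt = 0)
  sch <- default_scheme(n_dirs = 15, te = 54)
  sig <- generate_cohort_signals(build_cohort(cfg), sch, snr = Inf)
  tr <- run_tractometry(sig, sch)
  expect_true(all(tr$summary$degenerate))
  expect_true(all(is.na(tr$summary$b_hat)))
})

test_that("tractometry and pooled analysis agree in sign when noiseless", {
  cfg <- tract_cohort(seed = 100)
  # 30 directions: the MD anisotropy is small, so the direction-set
  # component of the fit bias must be well below it
  sch <- default_scheme(n_dirs = 30, te = 54)
  sig <- generate_cohort_signals(build_cohort(cfg), sch, snr = Inf)
  fits <- fit_cohort_dt(sig, sch)
  pa <- run_pooled_analysis(fits)
  tr <- run_tractometry(fits)
  for (m in c("md", "ad", "rd", "fa")) {
    expect_equal(sign(tr$summary$b_hat[tr$summary$measure == m]),
                 sign(pa$summary$b_hat[pa$summary$measure == m]),
                 info = m)
  }
  # the studied pattern: positive for AD and FA, negative for RD
  expect_gt(tr$summary$b_hat[tr$summary$measure == "ad"], 0)
  expect_gt(tr$summary$b_hat[tr$summary$measure == "fa"], 0)
  expect_lt(tr$summary$b_hat[tr$summary$measure == "rd"], 0)
})

test_that("autoplot methods return ggplot objects", {
  g <- run_simulation_grid(f_values = c(0.3, 0.7), te_values = c(54, 100),
                           conditions = "analytic")
  expect_s3_class(autoplot(g), "ggplot")

  cfg <- tract_cohort(seed = 101)
  sch <- default_scheme(n_dirs = 15, te = 54)
  sig <- generate_cohort_signals(build_cohort(cfg), sch, snr = Inf)
  fits <- fit_cohort_dt(sig, sch)
  pa <- run_pooled_analysis(fits)
  expect_s3_class(autoplot(pa$splines[[1]]), "ggplot")
  tr <- run_tractometry(fits)
  expect_s3_class(autoplot(tr), "ggplot")
})
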