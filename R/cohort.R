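# Synthetic cohort generator: single-fibre-population voxels organised into
# subjects, tracts and segments, imaged in a default and an 18-degree tilted
# head orientation. Gradient directions and B0 stay fixed in the scanner
# frame; only the anatomy (fibre orientations) rotates.

#' Cohort configuration
#'
#' @param n_subjects,n_tracts,n_segments_per_tract,n_voxels_per_segment
#'   Hierarchy sizes (all >= 1). Defaults give 2 x 5 x 10 x 8 = 800 voxels
#'   per head orientation.
#' @param tilt_angle Head tilt in degrees about `tilt_axis` (default 18;
#'   must satisfy 0 <= tilt < 90).
#' @param tilt_axis Rotation axis, default the left-right scanner x axis.
#' @param theta_sampling `"uniform_sphere"` (isotropic tract directions) or
#'   `"custom_histogram"` (theta drawn from `theta_histogram`).
#' @param theta_histogram For `custom_histogram`: a data frame with columns
#'   `lower`, `upper` (degrees) and `prob`.
#' @param tissue Baseline [tissue_params()] shared by all voxels before
#'   jitter.
#' @param tissue_jitter Coefficient of variation of the multiplicative
#'   truncated-Gaussian per-parameter jitter (default 0.05).
#' @param segment_scatter_sd,voxel_scatter_sd Angular standard deviation
#'   (degrees) of the Watson-like scatter of segment directions about the
#'   tract direction and of voxel orientations about the segment direction
#'   (default 5 each).
#' @param snr Rician SNR on the b = 0, TE = 0 signal (default 100).
#' @param seed Mandatory RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 2, n_tracts = 5,
                          n_segments_per_tract = 10,
                          n_voxels_per_segment = 8,
                          tilt_angle = 18, tilt_axis = c(1, 0, 0),
                          theta_sampling = c("uniform_sphere",
                                             "custom_histogram"),
                          theta_histogram = NULL,
                          tissue = tissue_params(),
                          tissue_jitter = 0.05,
                          segment_scatter_sd = 5, voxel_scatter_sd = 5,
                          snr = 100, seed) {
  if (missing(seed)) abort("`seed` is mandatory in cohort_config().")
  theta_sampling <- match.arg(theta_sampling)
  counts <- c(n_subjects, n_tracts, n_segments_per_tract,
              n_voxels_per_segment)
  if (any(counts < 1)) abort("All cohort counts must be >= 1.")
  if (tilt_angle < 0 || tilt_angle >= 90) {
    abort("`tilt_angle` must satisfy 0 <= tilt_angle < 90.")
  }
  if (tissue_jitter < 0) abort("`tissue_jitter` must be >= 0.")
  assert_unit(tilt_axis, "tilt_axis")
  stopifnot(inherits(tissue, "tissue_params"))
  structure(list(n_subjects = n_subjects, n_tracts = n_tracts,
                 n_segments_per_tract = n_segments_per_tract,
                 n_voxels_per_segment = n_voxels_per_segment,
                 tilt_angle = tilt_angle, tilt_axis = tilt_axis,
                 theta_sampling = theta_sampling,
                 theta_histogram = theta_histogram,
                 tissue = tissue, tissue_jitter = tissue_jitter,
                 segment_scatter_sd = segment_scatter_sd,
                 voxel_scatter_sd = voxel_scatter_sd,
                 snr = snr, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Sample fibre orientations
#'
#' `uniform_sphere` draws directions isotropically (after folding to the
#' upper hemisphere the polar angle density is proportional to sin(theta)).
#' `custom_histogram` draws theta from a user histogram (`lower`, `upper` in
#' degrees, `prob`) and the azimuth uniformly.
#'
#' @param n Number of orientations.
#' @param mode `"uniform_sphere"` or `"custom_histogram"`.
#' @param seed Optional seed (set before drawing when given).
#' @param histogram Data frame for `custom_histogram` mode.
#' @return An n x 3 matrix of unit vectors.
#' @export
sample_orientations <- function(n, mode = c("uniform_sphere",
                                            "custom_histogram"),
                                seed = NULL, histogram = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "uniform_sphere") {
    z <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    unname(cbind(r * cos(phi), r * sin(phi), z))
  } else {
    if (is.null(histogram) || nrow(histogram) == 0) {
      abort("`custom_histogram` mode needs a non-empty `histogram`.")
    }
    if (!all(c("lower", "upper", "prob") %in% names(histogram))) {
      abort("`histogram` must have columns lower, upper, prob.")
    }
    bin <- sample.int(nrow(histogram), n, replace = TRUE,
                      prob = histogram$prob)
    theta <- runif(n, histogram$lower[bin], histogram$upper[bin]) * DEG
    phi <- runif(n, 0, 2 * pi)
    cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  }
}

# Watson-distributed axes about mu, concentration kappa, via numeric inverse
# CDF of the density ~ exp(kappa t^2) on t in [0, 1].
rwatson_axis <- function(n, mu, kappa) {
  assert_unit(mu, "mu")
  tg <- seq(0, 1, length.out = 4096)
  dens <- exp(kappa * (tg^2 - 1))
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  inv <- approxfun(cdf, tg, rule = 2, ties = "ordered")
  t <- inv(runif(n))
  phi <- runif(n, 0, 2 * pi)
  st <- sqrt(pmax(0, 1 - t^2))
  fr <- complete_frame(mu)
  outer(t, mu) + (st * cos(phi)) %o% fr[, "u"] + (st * sin(phi)) %o% fr[, "v"]
}

# Watson concentration giving roughly the requested angular sd (degrees);
# small-dispersion approximation E[theta^2] ~ 1/kappa.
scatter_kappa <- function(sd_deg) 1 / (sd_deg * DEG)^2

#' Tilt fibre orientations with the head
#'
#' Rotates anatomy (fibre orientations) by `angle` about `axis` while B0 and
#' the gradient directions stay fixed in the scanner frame.
#'
#' @param orientations An n x 3 matrix of unit vectors.
#' @param angle Rotation angle in degrees.
#' @param axis Unit rotation axis (default left-right scanner x).
#' @return The rotated n x 3 matrix.
#' @export
apply_head_tilt <- function(orientations, angle, axis = c(1, 0, 0)) {
  R <- rotation_about_axis(axis, angle)
  orientations %*% t(R)
}

# Multiplicative truncated-Gaussian jitter clamped to [lo, hi].
jitter_param <- function(x, cv, n, lo = 0, hi = Inf) {
  if (cv == 0) return(rep(x, n))
  pmin(hi, pmax(lo, x * (1 + rnorm(n, 0, cv))))
}

#' Generate the synthetic cohort table
#'
#' Builds the subject / tract / segment / voxel hierarchy in both head
#' orientations. Tract directions are drawn per subject according to
#' `theta_sampling`; segment directions scatter about the tract direction and
#' voxel orientations about the segment direction (Watson-like scatter with
#' the configured angular sd), emulating along-tract fanning. Per-voxel
#' tissue parameters jitter multiplicatively about the baseline. All voxels
#' are single-fibre-population by construction.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per voxel x head orientation: identifier
#'   columns `subject`, `tract`, `segment`, `voxel`, `head` ("default" or
#'   "tilted"), orientation columns `nx`, `ny`, `nz` (scanner frame, for that
#'   head position), `theta` (degrees to B0 = scanner +z), tissue columns
#'   `f`, `d_ia_par`, `d_ia_perp`, `d_ea_par`, `d_ea_perp`, `r2_ia_iso`,
#'   `r2_ia_aniso`, `r2_ea_iso`, `r2_ea_aniso`, `kappa`, and `is_sfp`.
#' @export
#' @examples
#' cohort <- build_cohort(cohort_config(n_subjects = 1, n_tracts = 1,
#'   n_segments_per_tract = 1, n_voxels_per_segment = 3, seed = 7))
build_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  ts <- config$tissue
  n_vox_total <- config$n_subjects * config$n_tracts *
    config$n_segments_per_tract * config$n_voxels_per_segment

  ids <- tidyr::expand_grid(
    subject = seq_len(config$n_subjects),
    tract = seq_len(config$n_tracts),
    segment = seq_len(config$n_segments_per_tract),
    voxel = seq_len(config$n_voxels_per_segment))

  tract_dirs <- sample_orientations(
    config$n_subjects * config$n_tracts, config$theta_sampling,
    histogram = config$theta_histogram)
  tract_key <- tidyr::expand_grid(subject = seq_len(config$n_subjects),
                                  tract = seq_len(config$n_tracts))

  k_seg <- scatter_kappa(max(config$segment_scatter_sd, 1e-3))
  k_vox <- scatter_kappa(max(config$voxel_scatter_sd, 1e-3))

  seg_rows <- tidyr::expand_grid(
    subject = seq_len(config$n_subjects),
    tract = seq_len(config$n_tracts),
    segment = seq_len(config$n_segments_per_tract))
  seg_dirs <- matrix(NA_real_, nrow(seg_rows), 3)
  for (i in seq_len(nrow(seg_rows))) {
    j <- which(tract_key$subject == seg_rows$subject[i] &
                 tract_key$tract == seg_rows$tract[i])
    mu <- tract_dirs[j, ]
    seg_dirs[i, ] <- if (config$segment_scatter_sd > 0) {
      rwatson_axis(1, mu, k_seg)
    } else mu
  }

  vox_dirs <- matrix(NA_real_, nrow(ids), 3)
  seg_index <- match(paste(ids$subject, ids$tract, ids$segment),
                     paste(seg_rows$subject, seg_rows$tract,
                           seg_rows$segment))
  for (s in unique(seg_index)) {
    rows <- which(seg_index == s)
    mu <- seg_dirs[s, ]
    vox_dirs[rows, ] <- if (config$voxel_scatter_sd > 0) {
      rwatson_axis(length(rows), mu, k_vox)
    } else matrix(mu, length(rows), 3, byrow = TRUE)
  }

  cv <- config$tissue_jitter
  tissue_tbl <- tibble::tibble(
    f = jitter_param(ts$f, cv, n_vox_total, 0, 1),
    d_ia_par = jitter_param(ts$d_ia_par, cv, n_vox_total),
    d_ia_perp = jitter_param(ts$d_ia_perp, cv, n_vox_total),
    d_ea_par = jitter_param(ts$d_ea_par, cv, n_vox_total),
    d_ea_perp = jitter_param(ts$d_ea_perp, cv, n_vox_total),
    r2_ia_iso = jitter_param(ts$relax_intra$r2_iso, cv, n_vox_total),
    r2_ia_aniso = jitter_param(ts$relax_intra$r2_aniso, cv, n_vox_total),
    r2_ea_iso = jitter_param(ts$relax_extra$r2_iso, cv, n_vox_total),
    r2_ea_aniso = jitter_param(ts$relax_extra$r2_aniso, cv, n_vox_total))
  # jitter cannot re-order axial vs radial diffusivities
  tissue_tbl$d_ia_perp <- pmin(tissue_tbl$d_ia_perp, tissue_tbl$d_ia_par)
  tissue_tbl$d_ea_perp <- pmin(tissue_tbl$d_ea_perp, tissue_tbl$d_ea_par)

  base <- dplyr::bind_cols(ids, tissue_tbl)
  base$relax_ia_kind <- ts$relax_intra$kind
  base$relax_ea_kind <- ts$relax_extra$kind
  base$kappa <- ts$kappa
  base$is_sfp <- TRUE

  tilted <- apply_head_tilt(vox_dirs, config$tilt_angle, config$tilt_axis)
  b0 <- c(0, 0, 1)
  theta_of <- function(m) acos(pmin(1, abs(m[, 3]))) / DEG

  out <- dplyr::bind_rows(
    dplyr::mutate(base, head = "default",
                  nx = vox_dirs[, 1], ny = vox_dirs[, 2], nz = vox_dirs[, 3],
                  theta = theta_of(vox_dirs)),
    dplyr::mutate(base, head = "tilted",
                  nx = tilted[, 1], ny = tilted[, 2], nz = tilted[, 3],
                  theta = theta_of(tilted)))
  attr(out, "config") <- config
  dplyr::relocate(out, "subject", "tract", "segment", "voxel", "head")
}

#' Simulate acquisition signals for a cohort
#'
#' For each voxel and head orientation, evaluates the forward model (with
#' Watson dispersion when the voxel's `kappa` is finite) for every scheme
#' measurement, then adds Rician noise at the configured SNR. With
#' `snr = Inf` the noiseless signals are returned.
#'
#' @param cohort Output of [build_cohort()].
#' @param scheme An [acquisition_scheme()].
#' @param snr SNR on the b = 0, TE = 0 signal; defaults to the cohort
#'   config's value. Use `Inf` for noiseless signals.
#' @param seed Seed for the noise stream; defaults to the cohort seed + 1.
#' @return A long tibble: identifiers, `head`, `measurement` (scheme row),
#'   `b`, `te`, `theta`, and `signal`.
#' @export
generate_cohort_signals <- function(cohort, scheme, snr = NULL, seed = NULL) {
  config <- attr(cohort, "config")
  snr <- snr %||% (if (!is.null(config)) config$snr else 100)
  seed <- seed %||% (if (!is.null(config)) config$seed + 1L else 1L)
  b0 <- scheme_b0_dir(scheme)
  n_meas <- nrow(scheme)
  sig <- matrix(NA_real_, nrow(cohort), n_meas)
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    ts <- tissue_params(
      f = row$f, d_ia_par = row$d_ia_par, d_ia_perp = row$d_ia_perp,
      d_ea_par = row$d_ea_par, d_ea_perp = row$d_ea_perp,
      relax_intra = relaxation_model(row$relax_ia_kind,
                                     row$r2_ia_iso, row$r2_ia_aniso),
      relax_extra = relaxation_model(row$relax_ea_kind,
                                     row$r2_ea_iso, row$r2_ea_aniso),
      n = c(row$nx, row$ny, row$nz), kappa = row$kappa)
    sig[i, ] <- if (is.finite(row$kappa)) {
      signal_with_dispersion(scheme, ts, b0)
    } else {
      signal_no_dispersion(scheme, ts, b0)
    }
  }
  if (is.finite(snr)) {
    set.seed(seed)
    sigma <- 1 / snr      # signals normalised to S(0, 0) = 1
    sig <- matrix(add_rician(as.vector(sig), sigma),
                  nrow(cohort), n_meas)
  }
  keys <- dplyr::select(cohort, "subject", "tract", "segment", "voxel",
                        "head", "theta")
  out <- tidyr::expand_grid(keys, measurement = seq_len(n_meas))
  out$b <- scheme$b[out$measurement]
  out$te <- scheme$te[out$measurement]
  out$signal <- as.vector(t(sig))
  out
}
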