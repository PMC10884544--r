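# The three experiment pipelines: the simulation grid (analytic / noisy /
# dispersed conditions over f and TE), the pooled single-fibre analysis, and
# the tractometry comparison between head orientations.

MEASURES <- c("md", "ad", "rd", "fa")

# Fit a cohort-style long signal table: one IWLLS tensor per
# voxel x head x TE. Returns a tibble of per-voxel measures.
#' Fit diffusion tensors for every voxel of a signal table
#'
#' Partitions the signal table by voxel, head orientation and echo time and
#' fits each subset with [fit_dt_iwlls()] (measurements are fitted per TE, as
#' the estimation scheme requires). The fibre angle theta is recomputed from
#' the fitted principal eigenvector.
#'
#' @param signals Long table from [generate_cohort_signals()].
#' @param scheme The [acquisition_scheme()] the signals were generated with.
#' @return A tibble with one row per voxel x head x TE: identifiers, `te`,
#'   `md`, `ad`, `rd`, `fa`, `theta` (degrees, from the fitted tensor),
#'   `theta_true` (the generating orientation's angle), `converged`,
#'   `negative_eigenvalues`.
#' @export
fit_cohort_dt <- function(signals, scheme) {
  b0 <- scheme_b0_dir(scheme)
  tes <- sort(unique(scheme$te))
  sub_schemes <- lapply(tes, function(t) scheme[scheme$te == t, ])
  sub_rows <- lapply(tes, function(t) which(scheme$te == t))
  names(sub_schemes) <- names(sub_rows) <- as.character(tes)

  signals |>
    dplyr::arrange(.data$subject, .data$tract, .data$segment, .data$voxel,
                   .data$head, .data$measurement) |>
    tidyr::nest(data = c("measurement", "b", "te", "signal")) |>
    dplyr::mutate(fit = purrr::map(.data$data, function(d) {
      purrr::map_dfr(as.character(tes), function(tn) {
        idx <- match(sub_rows[[tn]], d$measurement)
        fit <- fit_dt_iwlls(sub_schemes[[tn]], d$signal[idx], b0_dir = b0)
        tibble::tibble(te = fit$te, md = fit$md, ad = fit$ad, rd = fit$rd,
                       fa = fit$fa, theta = fit$theta,
                       converged = fit$converged,
                       negative_eigenvalues = fit$negative_eigenvalues)
      })
    })) |>
    dplyr::select(-"data") |>
    dplyr::rename(theta_true = "theta") |>
    tidyr::unnest("fit")
}

#' Run the simulation grid
#'
#' For every cell of the f x TE grid and each requested condition, generates
#' the four tensor measures as a function of the fibre angle theta and fits
#' the sin^4(theta) representation with AIC model selection:
#' \describe{
#'   \item{analytic}{noiseless analytic measures on the theta grid;}
#'   \item{noisy}{signals simulated per theta with Rician noise at `snr`,
#'     tensors fitted by IWLLS, theta taken from the fitted eigenvector;}
#'   \item{dispersed}{as noisy, with Watson fibre dispersion of concentration
#'     `kappa` inside the signal generation.}
#' }
#' The anisotropy magnitude B is reported for every cell even when the
#' isotropic representation is selected (the selection is carried
#' separately).
#'
#' @param f_values Intra-axonal signal fractions (default the studied grid
#'   `c(0.1, 0.3, 0.5, 0.7, 0.9)`).
#' @param te_values Echo times in ms (default `c(54, 75, 100, 130)`).
#' @param conditions Subset of `c("analytic", "noisy", "dispersed")`.
#' @param tissue Baseline [tissue_params()]; its `f` is overridden per cell.
#' @param theta_grid Fibre angles in degrees (default 0..90 in 1-degree
#'   steps).
#' @param scheme Acquisition scheme for the noisy conditions (default
#'   [default_scheme()] restricted to `te_values`).
#' @param n_repeats Simulated voxels per cell in the noisy conditions; their
#'   angles cycle through `theta_grid` and the representation is fitted to
#'   all repeats pooled (default 1000).
#' @param snr Rician SNR (default 100).
#' @param kappa Watson concentration for the dispersed condition
#'   (default 16).
#' @param n_nodes Quadrature nodes for the dispersed condition.
#' @param seed RNG seed (mandatory for the noisy conditions).
#' @return A `sim_grid` tibble: one row per condition x measure x TE x f with
#'   columns `a_hat`, `b_hat`, `b_ci_low`, `b_ci_high`, `aic_iso`,
#'   `aic_aniso`, `delta_aic_iso`, `selected`. Seed and parameters are
#'   attached as attributes.
#' @export
#' @examples
#' g <- run_simulation_grid(f_values = 0.4, te_values = 54,
#'                          conditions = "analytic")
#' g[, c("measure", "b_hat", "selected")]
run_simulation_grid <- function(f_values = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                te_values = c(54, 75, 100, 130),
                                conditions = c("analytic", "noisy",
                                               "dispersed"),
                                tissue = tissue_params(),
                                theta_grid = 0:90,
                                scheme = NULL,
                                n_repeats = 1000,
                                snr = 100, kappa = 16, n_nodes = 1024,
                                seed = 1L) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (is.null(scheme)) scheme <- default_scheme(te = te_values)
  b0 <- scheme_b0_dir(scheme)
  set.seed(seed)

  fit_cell <- function(df, condition, f, te) {
    purrr::map_dfr(MEASURES, function(m) {
      fit <- fit_sin4(tibble::tibble(theta = df$theta, v = df[[m]]),
                      theta, v)
      dplyr::bind_cols(
        tibble::tibble(condition = condition, measure = m, te = te, f = f),
        glance(fit)[c("a_hat", "b_hat", "b_ci_low", "b_ci_high",
                      "aic_iso", "aic_aniso", "delta_aic_iso", "selected")])
    })
  }

  cells <- tidyr::expand_grid(f = f_values, te = te_values)
  out <- list()

  if ("analytic" %in% conditions) {
    out$analytic <- purrr::pmap_dfr(cells, function(f, te) {
      ts <- modify_tissue(tissue, f = f)
      fit_cell(analytic_dt_measures(te, theta_grid, ts), "analytic", f, te)
    })
  }

  for (cond in intersect(c("noisy", "dispersed"), conditions)) {
    disp <- cond == "dispersed"
    out[[cond]] <- purrr::pmap_dfr(cells, function(f, te) {
      ts <- modify_tissue(tissue, f = f,
                          kappa = if (disp) kappa else Inf)
      sub <- scheme[scheme$te == te, ]
      thetas <- rep_len(theta_grid, n_repeats)
      meas <- purrr::map_dfr(thetas, function(th) {
        tsv <- modify_tissue(ts, n = c(sin(th * DEG), 0, cos(th * DEG)))
        s <- if (disp) {
          signal_with_dispersion(sub, tsv, b0, n_nodes = n_nodes)
        } else {
          signal_no_dispersion(sub, tsv, b0)
        }
        fit <- fit_dt_iwlls(sub, add_rician(s, 1 / snr), b0_dir = b0)
        tibble::tibble(theta = fit$theta, md = fit$md, ad = fit$ad,
                       rd = fit$rd, fa = fit$fa)
      })
      fit_cell(meas, cond, f, te)
    })
  }

  res <- dplyr::bind_rows(out)
  res <- structure(res, class = c("sim_grid", class(res)))
  attr(res, "seed") <- seed
  attr(res, "params") <- list(tissue = tissue, snr = snr, kappa = kappa,
                              n_repeats = n_repeats,
                              theta_grid = theta_grid)
  res
}

# Return a tissue_params with selected fields replaced.
modify_tissue <- function(tissue, ...) {
  upd <- list(...)
  args <- list(f = tissue$f,
               d_ia_par = tissue$d_ia_par, d_ia_perp = tissue$d_ia_perp,
               d_ea_par = tissue$d_ea_par, d_ea_perp = tissue$d_ea_perp,
               relax_intra = tissue$relax_intra,
               relax_extra = tissue$relax_extra,
               n = tissue$n, kappa = tissue$kappa)
  args[names(upd)] <- upd
  do.call(tissue_params, args)
}

#' Pooled single-fibre analysis across subjects and head orientations
#'
#' Pools every single-fibre voxel from all subjects and both head
#' orientations and, per measure and TE: (i) fits the sin^4(theta)
#' representation to the unbinned voxel values, (ii) averages in 1-degree
#' angle bins and fits a count-weighted smoothing spline, reporting the
#' signed spline magnitude and the contribution of orientational anisotropy
#' to the variance across voxels.
#'
#' @param signals Long signal table from [generate_cohort_signals()], or a
#'   pre-fitted voxel table from [fit_cohort_dt()].
#' @param scheme The acquisition scheme (needed when `signals` is raw).
#' @param bin_width Angle bin width in degrees (default 1).
#' @param min_bins Minimum populated bins required for the spline
#'   (default 10).
#' @return A list of class `pooled_analysis`: `voxels` (per-voxel measures),
#'   `summary` (per measure x TE: sin^4 fit columns plus `magnitude`,
#'   `variance_contribution`, `spline_spar`, `n_bins`), and `splines`
#'   (named list of `spline_aniso` objects, "measure_te").
#' @export
run_pooled_analysis <- function(signals, scheme = NULL, bin_width = 1,
                                min_bins = 10) {
  voxels <- if ("signal" %in% names(signals)) {
    if (is.null(scheme)) abort("`scheme` is required with raw signals.")
    fit_cohort_dt(signals, scheme)
  } else signals

  cells <- tidyr::expand_grid(measure = MEASURES,
                              te = sort(unique(voxels$te)))
  splines <- list()
  summary <- purrr::pmap_dfr(cells, function(measure, te) {
    d <- voxels[voxels$te == te, ]
    vals <- d[[measure]]
    s4 <- fit_sin4(tibble::tibble(theta = d$theta, v = vals), theta, v)
    binned <- bin_average(tibble::tibble(theta = d$theta, v = vals),
                          theta, v, width = bin_width)
    if (nrow(binned) < min_bins) {
      abort(sprintf(
        "Only %d populated angle bins for %s at TE = %g ms (need >= %d).",
        nrow(binned), measure, te, min_bins))
    }
    sp <- spline_anisotropy(binned)
    splines[[paste(measure, te, sep = "_")]] <<- sp
    vc <- variance_contribution(vals, predict_spline_aniso(sp, d$theta))
    dplyr::bind_cols(
      tibble::tibble(measure = measure, te = te),
      glance(s4)[c("a_hat", "b_hat", "b_ci_low", "b_ci_high",
                   "aic_iso", "aic_aniso", "delta_aic_iso", "selected")],
      tibble::tibble(magnitude = sp$magnitude, variance_contribution = vc,
                     spline_spar = sp$spar, n_bins = nrow(binned)))
  })
  structure(list(voxels = voxels, summary = summary, splines = splines),
            class = "pooled_analysis")
}

#' @export
print.pooled_analysis <- function(x, ...) {
  cat(sprintf("<pooled_analysis> %d voxel fits, %d measure x TE cells\n",
              nrow(x$voxels), nrow(x$summary)))
  print(x$summary)
  invisible(x)
}

#' Tractometry comparison between head orientations
#'
#' Averages each measure and sin^4(theta) over the single-fibre voxels of
#' every tract segment, separately per head orientation, then regresses the
#' segment-wise change between default and tilted positions,
#' `delta_measure = B * delta_sin4`, through the origin (the isotropic
#' representation predicts no change, so the null model is `delta = 0`).
#' The outermost segments of every tract and segments with too few voxels
#' are excluded first.
#'
#' @param signals Long signal table or pre-fitted voxel table (see
#'   [run_pooled_analysis()]).
#' @param scheme The acquisition scheme (needed when `signals` is raw).
#' @param trim_frac Fraction of segments removed from *each* end of every
#'   tract (default 0.1, i.e. 20% of segments in total; set 0.2 for the
#'   stricter reading).
#' @param min_voxels Segments with this many voxels or fewer are excluded
#'   (default 3).
#' @return A list of class `tractometry_result`: `segments` (per segment x
#'   measure x TE deltas), `summary` (per measure x TE: `b_hat`, `b_se`,
#'   `aic_iso`, `aic_aniso`, `star` for an AIC advantage > 2, `std_change`,
#'   `n_segments`, `degenerate`).
#' @export
run_tractometry <- function(signals, scheme = NULL, trim_frac = 0.1,
                            min_voxels = 3) {
  voxels <- if ("signal" %in% names(signals)) {
    if (is.null(scheme)) abort("`scheme` is required with raw signals.")
    fit_cohort_dt(signals, scheme)
  } else signals
  if (!all(c("default", "tilted") %in% unique(voxels$head))) {
    abort("Tractometry needs both head orientations in the data.")
  }

  seg <- voxels |>
    dplyr::mutate(sin4 = sin(.data$theta * DEG)^4) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c(MEASURES, "sin4")), mean),
                     n_vox = dplyr::n(),
                     .by = c("subject", "tract", "segment", "head", "te"))

  # exclusion rules: outermost trim_frac of segments per tract end, and
  # segments with min_voxels or fewer voxels in either head position
  n_seg_per_tract <- seg |>
    dplyr::summarise(n_seg = max(.data$segment),
                     .by = c("subject", "tract"))
  seg <- seg |>
    dplyr::left_join(n_seg_per_tract, by = c("subject", "tract")) |>
    dplyr::filter(.data$segment > ceiling(trim_frac * .data$n_seg),
                  .data$segment <= .data$n_seg -
                    ceiling(trim_frac * .data$n_seg))

  wide <- seg |>
    tidyr::pivot_wider(id_cols = c("subject", "tract", "segment", "te"),
                       names_from = "head",
                       values_from = dplyr::all_of(c(MEASURES, "sin4",
                                                     "n_vox"))) |>
    dplyr::filter(!is.na(.data$n_vox_default), !is.na(.data$n_vox_tilted),
                  .data$n_vox_default > min_voxels,
                  .data$n_vox_tilted > min_voxels)
  if (nrow(wide) == 0) abort("No tract segments survive the exclusions.")

  segments <- wide |>
    dplyr::mutate(d_sin4 = .data$sin4_default - .data$sin4_tilted,
                  d_md = .data$md_default - .data$md_tilted,
                  d_ad = .data$ad_default - .data$ad_tilted,
                  d_rd = .data$rd_default - .data$rd_tilted,
                  d_fa = .data$fa_default - .data$fa_tilted) |>
    dplyr::select("subject", "tract", "segment", "te", "d_sin4",
                  dplyr::all_of(paste0("d_", MEASURES)))

  cells <- tidyr::expand_grid(measure = MEASURES,
                              te = sort(unique(segments$te)))
  summary <- purrr::pmap_dfr(cells, function(measure, te) {
    d <- segments[segments$te == te, ]
    x <- d$d_sin4
    y <- d[[paste0("d_", measure)]]
    n <- length(y)
    if (max(abs(x)) < 1e-12) {
      return(tibble::tibble(measure = measure, te = te, b_hat = NA_real_,
                            b_se = NA_real_, aic_iso = NA_real_,
                            aic_aniso = NA_real_, star = FALSE,
                            std_change = NA_real_, n_segments = n,
                            degenerate = TRUE))
    }
    fit <- lm(y ~ 0 + x)
    rss1 <- sum(fit$residuals^2)
    rss0 <- sum(y^2)                     # null model: delta = 0
    aic1 <- aic_ls(rss1, n, 1)
    aic0 <- aic_ls(rss0, n, 0)
    tibble::tibble(
      measure = measure, te = te,
      b_hat = unname(coef(fit)), b_se = sqrt(diag(stats::vcov(fit))),
      aic_iso = aic0, aic_aniso = aic1,
      star = (aic0 - aic1) > 2,
      std_change = variance_contribution(y, unname(coef(fit)) * x),
      n_segments = n, degenerate = FALSE)
  })
  structure(list(segments = segments, summary = summary),
            class = "tractometry_result")
}

#' @export
print.tractometry_result <- function(x, ...) {
  cat(sprintf("<tractometry_result> %d segment rows\n", nrow(x$segments)))
  print(x$summary)
  invisible(x)
}
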