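# Run configuration: a flat YAML-dialect key-value file validated into a
# fully defaulted list. Every pipeline artifact is derivable from the echoed
# effective configuration plus the seed.

config_defaults <- function() {
  list(
    seed = NULL,                       # mandatory, no default
    out_dir = ".",
    scheme = list(bval = NULL, bvec = NULL, te = NULL,
                  n_dirs = 30, b = c(0, 750, 1500),
                  te_values = c(54, 75, 100, 130)),
    tissue = list(f = 0.6, d_ia_par = 2.6, d_ia_perp = 0,
                  d_ea_par = 2.0, d_ea_perp = 0.4,
                  r2_ia_iso = 12, r2_ia_aniso = 0, relax_ia_kind = "constant",
                  r2_ea_iso = 17.4, r2_ea_aniso = 2.4,
                  relax_ea_kind = "sin4", kappa = Inf),
    grid = list(f = c(0.1, 0.3, 0.5, 0.7, 0.9),
                te = c(54, 75, 100, 130),
                conditions = c("analytic", "noisy", "dispersed"),
                n_repeats = 1000),
    cohort = list(n_subjects = 2, n_tracts = 5, n_segments_per_tract = 10,
                  n_voxels_per_segment = 8, tilt_angle = 18,
                  tissue_jitter = 0.05, segment_scatter_sd = 5,
                  voxel_scatter_sd = 5),
    noise = list(snr = 100),
    analysis = list(bin_width = 1, trim_frac = 0.1, min_voxels = 3)
  )
}

#' Validate a run configuration
#'
#' Reads a YAML-dialect key-value file (or an already-parsed list), fills in
#' all documented defaults, checks units/ranges and rejects unknown keys.
#' `seed` is mandatory. Re-validating an echoed effective configuration is
#' idempotent.
#'
#' @param config Path to a YAML file, a YAML string, or a named list.
#' @return The effective configuration (class `run_config`), printable as
#'   YAML via [format_config()].
#' @export
#' @examples
#' cfg <- validate_config(list(seed = 42))
#' identical(validate_config(unclass(cfg)), cfg)
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (file.exists(config)) {
      yaml::read_yaml(config)
    } else {
      yaml::yaml.load(config)
    }
  }
  if (!is.list(config)) abort("`config` must be a file path or a named list.")
  defaults <- config_defaults()

  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  merged <- defaults
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      sub_unknown <- setdiff(names(config[[k]]), names(defaults[[k]]))
      if (length(sub_unknown)) {
        abort(sprintf("Unknown key(s) under `%s`: %s", k,
                      paste(sub_unknown, collapse = ", ")))
      }
      merged[[k]][names(config[[k]])] <- config[[k]]
    } else {
      merged[[k]] <- config[[k]]
    }
  }

  if (is.null(merged$seed)) abort("`seed` is mandatory in the configuration.")
  merged$seed <- as.integer(merged$seed)

  tt <- merged$tissue
  if (tt$f < 0 || tt$f > 1) {
    abort("`tissue.f` must lie in [0, 1] (dimensionless fraction).")
  }
  for (k in c("d_ia_par", "d_ia_perp", "d_ea_par", "d_ea_perp")) {
    if (tt[[k]] < 0) abort(sprintf("`tissue.%s` must be >= 0 (um^2/ms).", k))
  }
  for (k in c("r2_ia_iso", "r2_ea_iso")) {
    if (tt[[k]] < 0) abort(sprintf("`tissue.%s` must be >= 0 (1/s).", k))
  }
  if (any(merged$grid$f < 0 | merged$grid$f > 1)) {
    abort("`grid.f` values must lie in [0, 1].")
  }
  if (any(merged$grid$te < 0)) abort("`grid.te` values must be >= 0 (ms).")
  if (merged$noise$snr <= 0) abort("`noise.snr` must be > 0.")
  if (merged$analysis$trim_frac < 0 || merged$analysis$trim_frac >= 0.5) {
    abort("`analysis.trim_frac` must lie in [0, 0.5).")
  }
  for (p in c("bval", "bvec", "te")) {
    path <- merged$scheme[[p]]
    if (!is.null(path) && !file.exists(path)) {
      abort(sprintf("`scheme.%s` path does not resolve: %s", p, path))
    }
  }
  structure(merged, class = "run_config")
}

#' @rdname validate_config
#' @param x A `run_config`.
#' @export
format_config <- function(x) {
  stopifnot(inherits(x, "run_config"))
  yaml::as.yaml(unclass(x))
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(format_config(x))
  invisible(x)
}

#' Build package objects from a validated configuration
#'
#' Convenience constructors mapping a [validate_config()] result onto the
#' package's domain objects.
#'
#' @param config A `run_config`.
#' @return `config_tissue()` a [tissue_params()]; `config_scheme()` an
#'   [acquisition_scheme()] (read from the configured files when paths are
#'   given, else the default scheme); `config_cohort()` a [cohort_config()].
#' @export
config_tissue <- function(config) {
  tt <- config$tissue
  tissue_params(
    f = tt$f, d_ia_par = tt$d_ia_par, d_ia_perp = tt$d_ia_perp,
    d_ea_par = tt$d_ea_par, d_ea_perp = tt$d_ea_perp,
    relax_intra = relaxation_model(tt$relax_ia_kind, tt$r2_ia_iso,
                                   tt$r2_ia_aniso),
    relax_extra = relaxation_model(tt$relax_ea_kind, tt$r2_ea_iso,
                                   tt$r2_ea_aniso),
    kappa = tt$kappa)
}

#' @rdname config_tissue
#' @export
config_scheme <- function(config) {
  sc <- config$scheme
  if (!is.null(sc$bval)) {
    read_scheme(sc$bval, sc$bvec, sc$te)
  } else {
    default_scheme(n_dirs = sc$n_dirs, b = sc$b, te = sc$te_values)
  }
}

#' @rdname config_tissue
#' @export
config_cohort <- function(config) {
  ch <- config$cohort
  cohort_config(
    n_subjects = ch$n_subjects, n_tracts = ch$n_tracts,
    n_segments_per_tract = ch$n_segments_per_tract,
    n_voxels_per_segment = ch$n_voxels_per_segment,
    tilt_angle = ch$tilt_angle,
    tissue = config_tissue(config),
    tissue_jitter = ch$tissue_jitter,
    segment_scatter_sd = ch$segment_scatter_sd,
    voxel_scatter_sd = ch$voxel_scatter_sd,
    snr = config$noise$snr, seed = config$seed)
}
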