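#' Compartmental transverse-relaxation model
#'
#' Describes how a compartment's R2 (1/T2) depends on the fibre angle theta to
#' the main field B0. Three kinds are supported:
#' \describe{
#'   \item{constant}{`R2(theta) = r2_iso`.}
#'   \item{sin4}{`R2(theta) = r2_iso + r2_aniso * sin^4(theta)`, the form
#'     observed for the extra-axonal compartment of white matter.}
#'   \item{dipolar}{`R2(theta) = r2_iso + r2_aniso * (3 cos^2(theta) - 1)^2`,
#'     the residual dipolar-coupling ("magic angle") form, vanishing
#'     anisotropy at theta = acos(1/sqrt(3)) ~ 54.7 degrees.}
#' }
#'
#' @param kind One of `"constant"`, `"sin4"`, `"dipolar"`.
#' @param r2_iso Isotropic rate in 1/s (must be >= 0).
#' @param r2_aniso Anisotropic amplitude in 1/s (forced to 0 for
#'   `kind = "constant"`).
#' @return An object of class `relaxation_model`.
#' @export
#' @examples
#' relaxation_model("sin4", r2_iso = 17.4, r2_aniso = 2.4)
relaxation_model <- function(kind = c("constant", "sin4", "dipolar"),
                             r2_iso, r2_aniso = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(r2_iso), length(r2_iso) == 1L,
            is.numeric(r2_aniso), length(r2_aniso) == 1L)
  if (r2_iso < 0) abort("`r2_iso` must be >= 0.")
  if (kind == "constant") r2_aniso <- 0
  structure(list(kind = kind, r2_iso = r2_iso, r2_aniso = r2_aniso),
            class = "relaxation_model")
}

#' @export
print.relaxation_model <- function(x, ...) {
  cat(sprintf("<relaxation_model: %s> r2_iso = %g 1/s, r2_aniso = %g 1/s\n",
              x$kind, x$r2_iso, x$r2_aniso))
  invisible(x)
}

#' Evaluate a relaxation model at a fibre angle
#'
#' @param model A [relaxation_model()].
#' @param theta Fibre angle(s) to B0 in degrees, each in \[0, 90\]. Callers
#'   must fold angles first (see [fold_angle()]).
#' @return Rate(s) in 1/s, vectorised over `theta`.
#' @export
#' @examples
#' m <- relaxation_model("sin4", 17.4, 2.4)
#' relaxation_rate(m, c(0, 90)) # 17.4, 19.8
relaxation_rate <- function(model, theta) {
  stopifnot(inherits(model, "relaxation_model"), is.numeric(theta))
  if (any(theta < 0 | theta > 90)) {
    abort("`theta` must lie in [0, 90] degrees; fold angles first.")
  }
  t <- theta * DEG
  switch(model$kind,
    constant = rep(model$r2_iso, length(theta)),
    sin4     = model$r2_iso + model$r2_aniso * sin(t)^4,
    dipolar  = model$r2_iso + model$r2_aniso * (3 * cos(t)^2 - 1)^2
  )
}

#' Two-compartment white-matter tissue parameters
#'
#' Parameters of the stick + zeppelin model: an intra-axonal "stick"
#' (zero perpendicular diffusivity) with signal fraction `f`, and an
#' extra-axonal axially symmetric "zeppelin". Each compartment carries its own
#' relaxation model; by default the intra-axonal rate is a constant 12 1/s and
#' the extra-axonal rate is `17.4 + 2.4 sin^4(theta)` 1/s.
#'
#' @param f Intra-axonal signal fraction in \[0, 1\].
#' @param d_ia_par,d_ia_perp Intra-axonal parallel/perpendicular diffusivity,
#'   um^2/ms (stick: `d_ia_perp = 0`).
#' @param d_ea_par,d_ea_perp Extra-axonal parallel/perpendicular diffusivity,
#'   um^2/ms.
#' @param relax_intra,relax_extra [relaxation_model()] objects for the two
#'   compartments.
#' @param n Principal fibre orientation, unit 3-vector in the scanner frame.
#' @param kappa Watson concentration of fibre dispersion; `Inf` means a
#'   perfectly coherent fibre population.
#' @return An object of class `tissue_params`.
#' @export
#' @examples
#' tissue_params(f = 0.4)
tissue_params <- function(f = 0.6,
                          d_ia_par = 2.6, d_ia_perp = 0,
                          d_ea_par = 2.0, d_ea_perp = 0.4,
                          relax_intra = relaxation_model("constant", 12),
                          relax_extra = relaxation_model("sin4", 17.4, 2.4),
                          n = c(0, 0, 1),
                          kappa = Inf) {
  stopifnot(is.numeric(f), length(f) == 1L)
  if (f < 0 || f > 1) abort("`f` must lie in [0, 1].")
  ds <- c(d_ia_par = d_ia_par, d_ia_perp = d_ia_perp,
          d_ea_par = d_ea_par, d_ea_perp = d_ea_perp)
  if (any(ds < 0)) abort("Diffusivities must be >= 0.")
  if (d_ia_par < d_ia_perp) abort("`d_ia_par` must be >= `d_ia_perp`.")
  if (d_ea_par < d_ea_perp) abort("`d_ea_par` must be >= `d_ea_perp`.")
  stopifnot(inherits(relax_intra, "relaxation_model"),
            inherits(relax_extra, "relaxation_model"))
  assert_unit(n, "n")
  if (kappa < 0) abort("`kappa` must be >= 0 (Inf for no dispersion).")
  structure(list(f = f,
                 d_ia_par = d_ia_par, d_ia_perp = d_ia_perp,
                 d_ea_par = d_ea_par, d_ea_perp = d_ea_perp,
                 relax_intra = relax_intra, relax_extra = relax_extra,
                 n = n, kappa = kappa),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<tissue_params> f = %g; D_ia = (%g, %g), D_ea = (%g, %g) um^2/ms\n",
    "  intra: %s(%g, %g); extra: %s(%g, %g) 1/s; kappa = %g\n"),
    x$f, x$d_ia_par, x$d_ia_perp, x$d_ea_par, x$d_ea_perp,
    x$relax_intra$kind, x$relax_intra$r2_iso, x$relax_intra$r2_aniso,
    x$relax_extra$kind, x$relax_extra$r2_iso, x$relax_extra$r2_aniso,
    x$kappa))
  invisible(x)
}

#' Convert between orientation dispersion index and Watson concentration
#'
#' Uses the conventional mapping `OD = (2/pi) * atan(1/kappa)`, so OD lies in
#' \[0, 1\] with OD -> 0 as kappa -> Inf.
#'
#' @param od Orientation dispersion index in (0, 1\].
#' @param kappa Watson concentration >= 0.
#' @return The corresponding concentration (or dispersion index).
#' @export
od_to_kappa <- function(od) {
  stopifnot(is.numeric(od), all(od > 0 & od <= 1))
  1 / tan(od * pi / 2)
}

#' @rdname od_to_kappa
#' @export
kappa_to_od <- function(kappa) {
  stopifnot(is.numeric(kappa), all(kappa >= 0))
  (2 / pi) * atan2(1, kappa)
}
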