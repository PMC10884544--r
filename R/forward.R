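# Two-compartment (stick + zeppelin) diffusion-T2 forward model.
#
# Unit conventions used throughout: b in s/mm^2, diffusivities in um^2/ms, so
# the dimensionless diffusion exponent is b * D * 1e-3; TE in ms and R2 in
# 1/s, so the relaxation exponent is R2 * TE * 1e-3.

B_SCALE <- 1e-3
TE_SCALE <- 1e-3

#' Apparent diffusivity of an axially symmetric compartment along a direction
#'
#' For a compartment with parallel/perpendicular diffusivities `d_par`,
#' `d_perp` and symmetry axis `n`, the diffusivity probed along gradient
#' direction `g` is `d_perp + (g . n)^2 (d_par - d_perp)`.
#'
#' @param g Gradient direction, unit 3-vector.
#' @param n Compartment symmetry axis (fibre direction), unit 3-vector.
#' @param d_par,d_perp Parallel and perpendicular diffusivity, um^2/ms.
#' @return Projected diffusivity in um^2/ms, bounded by
#'   `[min(d_par, d_perp), max(d_par, d_perp)]`.
#' @export
#' @examples
#' project_diffusivity(c(1, 0, 0), c(0, 0, 1), 2.0, 0.4) # perpendicular: 0.4
project_diffusivity <- function(g, n, d_par, d_perp) {
  assert_unit(g, "g")
  assert_unit(n, "n")
  d_perp + sum(g * n)^2 * (d_par - d_perp)
}

# Vectorised core: ct2 is (g . n)^2 (any length).
project_diffusivity_ <- function(ct2, d_par, d_perp) {
  d_perp + ct2 * (d_par - d_perp)
}

#' Noiseless two-compartment diffusion-T2 signal (no dispersion)
#'
#' Signal for a coherent single-fibre voxel:
#' `S = f exp(-R2_ia(theta) TE) exp(-b D_ia(g)) +
#'  (1 - f) exp(-R2_ea(theta) TE) exp(-b D_ea(g))`,
#' normalised so that `S(b = 0, TE = 0) = 1`. The fibre angle theta to B0 is
#' computed internally as the folded angle between `tissue$n` and `b0_dir`;
#' each compartment's relaxation model is evaluated at that angle.
#'
#' @param scheme An [acquisition_scheme()] (or any tibble with columns `b`,
#'   `gx`, `gy`, `gz`, `te`).
#' @param tissue A [tissue_params()]; `tissue$kappa` is ignored here (see
#'   [signal_with_dispersion()] for finite concentrations).
#' @param b0_dir Main-field direction; defaults to the scheme's `b0_dir`
#'   attribute (scanner +z).
#' @return Numeric vector of normalised signals, one per scheme row, in
#'   (0, 1\].
#' @export
signal_no_dispersion <- function(scheme, tissue, b0_dir = NULL) {
  stopifnot(inherits(tissue, "tissue_params"))
  b0_dir <- b0_dir %||% scheme_b0_dir(scheme)
  assert_unit(b0_dir, "b0_dir")
  n <- tissue$n
  theta <- fold_angle(n, b0_dir)
  g <- cbind(scheme$gx, scheme$gy, scheme$gz)
  ct2 <- as.vector(g %*% n)^2
  d_ia <- project_diffusivity_(ct2, tissue$d_ia_par, tissue$d_ia_perp)
  d_ea <- project_diffusivity_(ct2, tissue$d_ea_par, tissue$d_ea_perp)
  r2_ia <- relaxation_rate(tissue$relax_intra, theta)
  r2_ea <- relaxation_rate(tissue$relax_extra, theta)
  tissue$f * exp(-r2_ia * scheme$te * TE_SCALE - scheme$b * d_ia * B_SCALE) +
    (1 - tissue$f) *
      exp(-r2_ea * scheme$te * TE_SCALE - scheme$b * d_ea * B_SCALE)
}

#' Analytic apparent diffusion coefficient of the two-compartment model
#'
#' The ADC is the first-order coefficient of the Maclaurin expansion of
#' `ln S` in b: a T2-weighted mixture of the compartment diffusivities,
#' `ADC(TE) = (f D_ia e^{-R2_ia TE} + (1-f) D_ea e^{-R2_ea TE}) /
#'            (f e^{-R2_ia TE} + (1-f) e^{-R2_ea TE})`,
#' with each compartment's diffusivity projected along (`parallel`) or across
#' (`perpendicular`) the fibre. Orientation dependence enters only through the
#' relaxation weighting, so at TE = 0 the ADC is independent of theta.
#'
#' @param te Echo time, ms.
#' @param theta Fibre angle(s) to B0, degrees in \[0, 90\]; vectorised.
#' @param g_mode `"parallel"` (gradient along the fibre) or
#'   `"perpendicular"`.
#' @param tissue A [tissue_params()] (no dispersion assumed).
#' @return ADC(s) in um^2/ms.
#' @export
#' @examples
#' adc_analytic(0, 0, "parallel", tissue_params(f = 0.5)) # (2.6 + 2)/2 = 2.3
adc_analytic <- function(te, theta, g_mode = c("parallel", "perpendicular"),
                         tissue) {
  g_mode <- match.arg(g_mode)
  stopifnot(inherits(tissue, "tissue_params"))
  if (any(theta < 0 | theta > 90)) abort("`theta` must lie in [0, 90].")
  d_ia <- if (g_mode == "parallel") tissue$d_ia_par else tissue$d_ia_perp
  d_ea <- if (g_mode == "parallel") tissue$d_ea_par else tissue$d_ea_perp
  w_ia <- tissue$f *
    exp(-relaxation_rate(tissue$relax_intra, theta) * te * TE_SCALE)
  w_ea <- (1 - tissue$f) *
    exp(-relaxation_rate(tissue$relax_extra, theta) * te * TE_SCALE)
  (w_ia * d_ia + w_ea * d_ea) / (w_ia + w_ea)
}

#' Analytic diffusion tensor measures of the two-compartment model
#'
#' AD is the analytic ADC with the gradient along the fibre, RD across it,
#' MD = (AD + 2 RD)/3, and FA follows from the axisymmetric eigenvalue triple
#' (AD, RD, RD) via the standard formula.
#'
#' @inheritParams adc_analytic
#' @return A tibble with columns `te`, `theta`, `md`, `ad`, `rd`
#'   (um^2/ms) and `fa`, one row per (te, theta) combination.
#' @export
#' @examples
#' analytic_dt_measures(54, c(0, 45, 90), tissue_params(f = 0.4))
analytic_dt_measures <- function(te, theta, tissue) {
  grid <- tidyr::expand_grid(te = te, theta = theta)
  ad <- adc_analytic(grid$te, grid$theta, "parallel", tissue)
  rd <- adc_analytic(grid$te, grid$theta, "perpendicular", tissue)
  fa <- vapply(seq_along(ad),
               function(i) fa_from_eigenvalues(c(ad[i], rd[i], rd[i])),
               numeric(1))
  tibble::tibble(te = grid$te, theta = grid$theta,
                 md = (ad + 2 * rd) / 3, ad = ad, rd = rd, fa = fa)
}

# Deterministic Watson quadrature nodes/weights about mean axis mu.
# Product rule: Gauss-Legendre in t = cos(polar) on [0, 1] (the integrand is
# antipodally symmetric) x periodic trapezoid in azimuth. For large kappa the
# polar interval is split at t0 = sqrt(1 - 20/kappa) with half the nodes on
# each piece, so the near-delta limit is resolved.
watson_quadrature <- function(mu, kappa, n_nodes = 1024) {
  if (n_nodes < 64) abort("`n_nodes` must be at least 64.")
  assert_unit(mu, "mu")
  m_az <- max(8L, round(sqrt(n_nodes)))
  n_pol <- max(8L, ceiling(n_nodes / m_az))
  gauss_legendre <- function(k, a, b) {
    # Golub-Welsch on the Jacobi matrix, rescaled from [-1, 1] to [a, b]
    j <- seq_len(k - 1)
    beta <- j / sqrt(4 * j^2 - 1)
    E <- eigen(diag(0, k) +
                 rbind(cbind(0, diag(beta, k - 1, k - 1)), 0) +
                 rbind(0, cbind(diag(beta, k - 1, k - 1), 0)),
               symmetric = TRUE)
    x <- E$values
    w <- 2 * E$vectors[1, ]^2
    list(x = (a + b) / 2 + (b - a) / 2 * x, w = (b - a) / 2 * w)
  }
  if (is.finite(kappa) && kappa > 30) {
    t0 <- sqrt(1 - 20 / kappa)
    k1 <- floor(n_pol / 2); k2 <- n_pol - k1
    q1 <- gauss_legendre(k1, 0, t0)
    q2 <- gauss_legendre(k2, t0, 1)
    t <- c(q1$x, q2$x); wt <- c(q1$w, q2$w)
  } else {
    q <- gauss_legendre(n_pol, 0, 1)
    t <- q$x; wt <- q$w
  }
  phi <- 2 * pi * (seq_len(m_az) - 1) / m_az
  fr <- complete_frame(mu)
  tt <- rep(t, each = m_az)
  pp <- rep(phi, times = length(t))
  st <- sqrt(pmax(0, 1 - tt^2))
  nodes <- outer(tt, mu) + st * cos(pp) %o% fr[, "u"] +
    st * sin(pp) %o% fr[, "v"]
  kk <- if (is.finite(kappa)) kappa else 0
  # exp(kappa (t^2 - 1)) avoids overflow; normalisation below absorbs scale
  w <- rep(wt, each = m_az) * exp(kk * (tt^2 - 1))
  list(nodes = nodes, weights = w / sum(w))
}

#' Two-compartment signal under Watson fibre dispersion
#'
#' Integrates [signal_no_dispersion()] over sub-fibre orientations n' drawn
#' from a Watson distribution with mean axis `tissue$n` and concentration
#' `tissue$kappa`: each distinctly oriented sub-compartment carries its own
#' orientation (so its own extra-axonal relaxation rate at the folded angle
#' between n' and B0). The integral is evaluated with a deterministic
#' spherical product quadrature (see Details in the package vignette).
#'
#' @inheritParams signal_no_dispersion
#' @param n_nodes Quadrature node budget (>= 64; default 1024).
#' @return Numeric vector of normalised signals, one per scheme row.
#' @export
signal_with_dispersion <- function(scheme, tissue, b0_dir = NULL,
                                   n_nodes = 1024) {
  stopifnot(inherits(tissue, "tissue_params"))
  if (!is.finite(tissue$kappa)) {
    return(signal_no_dispersion(scheme, tissue, b0_dir))
  }
  b0_dir <- b0_dir %||% scheme_b0_dir(scheme)
  assert_unit(b0_dir, "b0_dir")
  q <- watson_quadrature(tissue$n, tissue$kappa, n_nodes)
  thetas <- acos(pmin(1, abs(as.vector(q$nodes %*% b0_dir)))) / DEG
  r2_ia <- relaxation_rate(tissue$relax_intra, thetas)
  r2_ea <- relaxation_rate(tissue$relax_extra, thetas)
  g <- cbind(scheme$gx, scheme$gy, scheme$gz)
  ct2 <- (g %*% t(q$nodes))^2            # n_meas x n_nodes
  d_ia <- project_diffusivity_(ct2, tissue$d_ia_par, tissue$d_ia_perp)
  d_ea <- project_diffusivity_(ct2, tissue$d_ea_par, tissue$d_ea_perp)
  te_s <- scheme$te * TE_SCALE
  bb <- scheme$b * B_SCALE
  s_nodes <- tissue$f *
    exp(outer(te_s, r2_ia, `*`) * -1 - bb * d_ia) +
    (1 - tissue$f) * exp(outer(te_s, r2_ea, `*`) * -1 - bb * d_ea)
  as.vector(s_nodes %*% q$weights)
}
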