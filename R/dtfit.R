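# Diffusion tensor estimation by iterative weighted linear least squares
# (IWLLS): ordinary least squares on log-signals for initialisation, then
# weights equal to the squared model-predicted signals, iterated to
# convergence. Log-linear model: ln S = ln S0 - sum_ij b_ij D_ij.

# 7-column b-matrix design for log-linear tensor fitting; b scaled by 1e-3 so
# tensor elements come out in um^2/ms.
dt_design <- function(b, g) {
  bb <- b * B_SCALE
  cbind(1,
        -bb * g[, 1]^2, -bb * g[, 2]^2, -bb * g[, 3]^2,
        -2 * bb * g[, 1] * g[, 2],
        -2 * bb * g[, 1] * g[, 3],
        -2 * bb * g[, 2] * g[, 3])
}

#' Fit a diffusion tensor by iterative weighted linear least squares
#'
#' Fits `ln S = ln S0 - sum b_ij D_ij` on the measurements of a single echo
#' time. Initialised by ordinary least squares on log-signals; subsequent
#' iterations weight by the squared model-predicted signals, until the maximum
#' relative parameter change drops below `tol` or `max_iter` is reached.
#' Non-positive signals are clipped to a small positive floor
#' (`1e-10 * max(signal)`) before the log; negative tensor eigenvalues are
#' flagged, not repaired.
#'
#' @param scheme An [acquisition_scheme()] subset containing a single echo
#'   time, with at least one b = 0 row and at least 6 non-collinear nonzero-b
#'   directions.
#' @param signals Signal vector, one per scheme row.
#' @param b0_dir Main-field direction for the fibre angle; defaults to the
#'   scheme's attribute.
#' @param tol Convergence tolerance on the relative parameter change
#'   (default 1e-6).
#' @param max_iter Maximum weighted iterations after initialisation
#'   (default 10).
#' @return An object of class `dt_fit`: fields `s0`, `tensor` (3 x 3,
#'   um^2/ms), `eigenvalues` (descending), `e1`, `md`, `ad`, `rd`, `fa`,
#'   `theta` (degrees to B0), `converged`, `n_iter`, `n_clipped`,
#'   `negative_eigenvalues`.
#' @export
#' @examples
#' sch <- default_scheme(te = 54)
#' s <- signal_no_dispersion(sch, tissue_params(f = 0.4))
#' fit <- fit_dt_iwlls(sch, s)
#' tidy(fit)
fit_dt_iwlls <- function(scheme, signals, b0_dir = NULL,
                         tol = 1e-6, max_iter = 10) {
  if (length(unique(scheme$te)) != 1L) {
    abort("`scheme` must contain a single echo time; fit each TE separately.")
  }
  if (length(signals) != nrow(scheme)) {
    abort("`signals` must have one value per scheme row.")
  }
  g <- cbind(scheme$gx, scheme$gy, scheme$gz)
  if (!any(scheme$b == 0)) abort("At least one b = 0 measurement is required.")
  X <- dt_design(scheme$b, g)
  if (qr(X)$rank < 7L) {
    abort(paste("Rank-deficient design: need >= 6 non-collinear gradient",
                "directions plus a b = 0 measurement."))
  }
  floor_val <- 1e-10 * max(signals)
  n_clipped <- sum(signals < floor_val)
  y <- log(pmax(signals, floor_val))

  beta <- qr.solve(X, y)
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    w <- exp(2 * as.vector(X %*% beta))   # squared predicted signals
    fit <- lm.fit(X * sqrt(w), y * sqrt(w))
    beta_new <- fit$coefficients
    n_iter <- it
    # scale by the largest parameter so exactly-zero tensor elements do not
    # mask convergence
    rel <- max(abs(beta_new - beta)) / max(abs(beta), 1e-8)
    beta <- beta_new
    if (rel < tol) { converged <- TRUE; break }
  }

  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  es <- eigen(D, symmetric = TRUE)
  lambda <- es$values                      # descending
  e1 <- es$vectors[, 1]
  e1 <- e1 / vec_norm(e1)
  b0_dir <- b0_dir %||% scheme_b0_dir(scheme)
  structure(list(
    s0 = exp(beta[1]),
    tensor = D,
    eigenvalues = lambda,
    e1 = e1,
    md = mean(lambda),
    ad = lambda[1],
    rd = (lambda[2] + lambda[3]) / 2,
    fa = fa_from_eigenvalues(lambda),
    theta = fibre_angle_to_b0(e1, b0_dir),
    te = scheme$te[1],
    converged = converged,
    n_iter = n_iter,
    n_clipped = n_clipped,
    negative_eigenvalues = any(lambda < 0)
  ), class = "dt_fit")
}

#' @export
print.dt_fit <- function(x, ...) {
  cat(sprintf(
    "<dt_fit> TE = %g ms: MD = %.4f, AD = %.4f, RD = %.4f um^2/ms, FA = %.4f, theta = %.1f deg%s\n",
    x$te, x$md, x$ad, x$rd, x$fa, x$theta,
    if (x$negative_eigenvalues) " [negative eigenvalues]" else ""))
  invisible(x)
}

#' @rdname fit_dt_iwlls
#' @param x A `dt_fit`.
#' @param ... Unused.
#' @export
tidy.dt_fit <- function(x, ...) {
  D <- x$tensor
  tibble::tibble(
    te = x$te, s0 = x$s0,
    dxx = D[1, 1], dyy = D[2, 2], dzz = D[3, 3],
    dxy = D[1, 2], dxz = D[1, 3], dyz = D[2, 3],
    lambda1 = x$eigenvalues[1], lambda2 = x$eigenvalues[2],
    lambda3 = x$eigenvalues[3],
    md = x$md, ad = x$ad, rd = x$rd, fa = x$fa, theta = x$theta,
    converged = x$converged, n_iter = x$n_iter,
    negative_eigenvalues = x$negative_eigenvalues)
}

#' @rdname fit_dt_iwlls
#' @export
glance.dt_fit <- function(x, ...) {
  tibble::tibble(converged = x$converged, n_iter = x$n_iter,
                 n_clipped = x$n_clipped,
                 negative_eigenvalues = x$negative_eigenvalues)
}

#' Fibre angle to the main field
#'
#' `theta = acos(|e1 . b0_dir|)` in degrees, in \[0, 90\] (fibres are axes,
#' so antipodal first eigenvectors give the same angle).
#'
#' @param e1 Principal eigenvector (unit 3-vector).
#' @param b0_dir Main-field direction (unit 3-vector).
#' @return Angle in degrees in \[0, 90\].
#' @export
fibre_angle_to_b0 <- function(e1, b0_dir) {
  fold_angle(e1, b0_dir)
}
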