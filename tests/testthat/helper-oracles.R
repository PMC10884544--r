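# Independent oracles used across the suite. Each deliberately avoids the
# package's own computation path.

# b -> 0 slope of -ln(S) by central finite differences (step 1 s/mm^2
# either side of b = 0) on the closed-form two-compartment signal,
# evaluated directly from the model equation.
fd_adc_oracle <- function(te, theta_deg, g_mode, tissue, db = 1) {
  d_ia <- if (g_mode == "parallel") tissue$d_ia_par else tissue$d_ia_perp
  d_ea <- if (g_mode == "parallel") tissue$d_ea_par else tissue$d_ea_perp
  r2_ia <- relaxation_rate(tissue$relax_intra, theta_deg)
  r2_ea <- relaxation_rate(tissue$relax_extra, theta_deg)
  s_of_b <- function(b) {
    tissue$f * exp(-r2_ia * te * 1e-3 - b * d_ia * 1e-3) +
      (1 - tissue$f) * exp(-r2_ea * te * 1e-3 - b * d_ea * 1e-3)
  }
  -(log(s_of_b(db)) - log(s_of_b(-db))) / (2 * db * 1e-3)
}

# FA from an explicit eigenvalue triple, written out independently of
# fa_from_eigenvalues().
fa_oracle <- function(l1, l2, l3) {
  lb <- (l1 + l2 + l3) / 3
  sqrt(3 / 2) * sqrt((l1 - lb)^2 + (l2 - lb)^2 + (l3 - lb)^2) /
    sqrt(l1^2 + l2^2 + l3^2)
}

# Rejection-sampling Watson axes about mu (concentration kappa): uniform
# sphere proposals accepted with probability exp(kappa (t^2 - 1)).
rwatson_reject <- function(n, mu, kappa) {
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- max(2L * n, 1e5L)
    z <- runif(m, -1, 1)
    phi <- runif(m, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    p <- cbind(r * cos(phi), r * sin(phi), z)
    t <- as.vector(p %*% mu)
    keep <- runif(m) < exp(kappa * (t^2 - 1))
    out <- rbind(out, p[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Monte-Carlo dispersed signal: average the closed-form signal over Watson
# axis samples, evaluating the model equation directly per sample.
mc_dispersed_signal <- function(scheme, tissue, b0_dir, n_samp) {
  axes <- rwatson_reject(n_samp, tissue$n, tissue$kappa)
  thetas <- acos(pmin(1, abs(axes %*% b0_dir))) * 180 / pi
  r2_ia <- relaxation_rate(tissue$relax_intra, thetas)
  r2_ea <- relaxation_rate(tissue$relax_extra, thetas)
  g <- cbind(scheme$gx, scheme$gy, scheme$gz)
  ct2 <- (g %*% t(axes))^2
  d_ia <- tissue$d_ia_perp + ct2 * (tissue$d_ia_par - tissue$d_ia_perp)
  d_ea <- tissue$d_ea_perp + ct2 * (tissue$d_ea_par - tissue$d_ea_perp)
  s <- tissue$f * exp(-outer(scheme$te * 1e-3, as.vector(r2_ia)) -
                        scheme$b * 1e-3 * d_ia) +
    (1 - tissue$f) * exp(-outer(scheme$te * 1e-3, as.vector(r2_ea)) -
                           scheme$b * 1e-3 * d_ea)
  list(mean = rowMeans(s), se = apply(s, 1, sd) / sqrt(n_samp))
}

# Nonlinear least-squares tensor fit oracle (mono-exponential model in the
# signal domain), independent of the log-linear IWLLS path.
nls_tensor_oracle <- function(scheme, signals) {
  g <- cbind(scheme$gx, scheme$gy, scheme$gz)
  bb <- scheme$b * 1e-3
  pred <- function(p) {
    D <- matrix(c(p[2], p[5], p[6],
                  p[5], p[3], p[7],
                  p[6], p[7], p[4]), 3, 3)
    p[1] * exp(-bb * rowSums((g %*% D) * g))
  }
  start <- c(max(signals), 1, 1, 1, 0, 0, 0)
  fit <- minpack.lm::nls.lm(par = start,
                            fn = function(p) signals - pred(p),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  p <- fit$par
  D <- matrix(c(p[2], p[5], p[6],
                p[5], p[3], p[7],
                p[6], p[7], p[4]), 3, 3)
  es <- eigen(D, symmetric = TRUE)
  list(s0 = p[1], eigenvalues = es$values,
       ad = es$values[1], rd = mean(es$values[2:3]))
}

# Mean of a Rician variate by numerical integration of the density
# (exponent combined with the scaled Bessel factor for stability:
# -(x^2 + nu^2)/(2 s^2) + x nu / s^2 = -(x - nu)^2 / (2 s^2)).
rician_mean_oracle <- function(nu, sigma) {
  integrand <- function(x) {
    x * (x / sigma^2) * exp(-(x - nu)^2 / (2 * sigma^2)) *
      besselI(x * nu / sigma^2, 0, expon.scaled = TRUE)
  }
  stats::integrate(integrand, max(0, nu - 12 * sigma), nu + 12 * sigma,
                   rel.tol = 1e-10)$value
}

# Small default tissue helper for tests (the studied parameter set).
study_tissue <- function(f = 0.4, ...) tissue_params(f = f, ...)
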