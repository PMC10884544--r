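#' Build an acquisition scheme table
#'
#' An acquisition scheme is a tibble with one row per measurement and columns
#' `b` (s/mm^2), `gx`, `gy`, `gz` (unit gradient direction in the scanner
#' frame; may be zero for b = 0 rows) and `te` (echo time, ms). Pulse timing
#' (`delta_big`, `delta_small`, both ms) and the main-field direction
#' `b0_dir` are carried as attributes. Gradient directions are defined in
#' scanner coordinates and are never rotated with the head.
#'
#' @param b Numeric vector of b-values, s/mm^2 (>= 0).
#' @param g Matrix (n x 3) of gradient directions, scanner frame. Rows with
#'   b = 0 may be zero; nonzero rows are renormalised when within 1% of unit
#'   norm and rejected otherwise.
#' @param te Echo times in ms (>= 0), one per measurement.
#' @param delta_big Time between diffusion gradients, ms (default 22).
#' @param delta_small Diffusion gradient duration, ms (default 8).
#' @param b0_dir Unit vector of the main field B0 in the scanner frame
#'   (default +z).
#' @return A tibble of class `acq_scheme`.
#' @export
#' @examples
#' acquisition_scheme(b = c(0, 1500), g = rbind(c(0, 0, 0), c(1, 0, 0)),
#'                    te = c(54, 54))
acquisition_scheme <- function(b, g, te,
                               delta_big = 22, delta_small = 8,
                               b0_dir = c(0, 0, 1)) {
  g <- unname(as.matrix(g))
  if (ncol(g) != 3L) abort("`g` must have 3 columns (x, y, z).")
  n <- length(b)
  if (nrow(g) != n || length(te) != n) {
    abort("`b`, `g` and `te` must have one entry per measurement.")
  }
  if (any(b < 0)) abort("b-values must be >= 0 (column `b`).")
  if (any(te < 0)) abort("Echo times must be >= 0 (column `te`).")
  norms <- sqrt(rowSums(g^2))
  nonzero_b <- b > 0
  if (any(nonzero_b & norms == 0)) {
    abort("Zero gradient vectors are only allowed on b = 0 rows (column `g`).")
  }
  check <- norms > 0
  bad <- check & abs(norms - 1) > 0.01
  if (any(bad)) {
    abort(sprintf(
      "Gradient rows %s deviate from unit norm by more than 1%% (column `g`).",
      paste(which(bad), collapse = ", ")))
  }
  g[check, ] <- g[check, , drop = FALSE] / norms[check]
  assert_unit(b0_dir, "b0_dir")
  out <- tibble::tibble(b = as.numeric(b),
                        gx = g[, 1], gy = g[, 2], gz = g[, 3],
                        te = as.numeric(te))
  structure(out,
            class = c("acq_scheme", class(out)),
            delta_big = delta_big, delta_small = delta_small,
            b0_dir = b0_dir)
}

#' @rdname acquisition_scheme
#' @param scheme An `acq_scheme`.
#' @export
scheme_b0_dir <- function(scheme) attr(scheme, "b0_dir") %||% c(0, 0, 1)

#' Quasi-uniform gradient direction set
#'
#' Deterministic point set on the hemisphere: Fibonacci-lattice initialisation
#' followed by a fixed number of electrostatic-repulsion sweeps on antipodally
#' symmetrised charges, as commonly used for diffusion sampling schemes.
#'
#' @param n Number of directions (>= 6).
#' @param sweeps Repulsion refinement sweeps (default 20).
#' @return An n x 3 matrix of unit vectors.
#' @export
gradient_directions <- function(n, sweeps = 20) {
  stopifnot(n >= 6)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n              # hemisphere z in (0, 1)
  r <- sqrt(pmax(0, 1 - z^2))
  p <- cbind(r * cos(phi), r * sin(phi), z)
  for (s in seq_len(sweeps)) {
    force <- matrix(0, n, 3)
    for (j in seq_len(n)) {
      d1 <- sweep(p, 2, p[j, ])        # from other points
      d2 <- sweep(-p, 2, p[j, ])       # from their antipodes
      for (d in list(d1, d2)) {
        r2 <- rowSums(d^2)
        keep <- r2 > 1e-12
        force[j, ] <- force[j, ] - colSums(d[keep, , drop = FALSE] /
                                             r2[keep]^1.5)
      }
    }
    p <- p + 0.001 * force
    p <- p / sqrt(rowSums(p^2))
    p[p[, 3] < 0, ] <- -p[p[, 3] < 0, , drop = FALSE]
  }
  unname(p)
}

#' Default multi-echo-time acquisition scheme
#'
#' Per echo time: one b = 0 measurement plus `n_dirs` directions on each
#' nonzero b shell, with the same direction set reused across shells and TEs
#' (directions fixed in the scanner frame).
#'
#' @param n_dirs Directions per nonzero shell (default 30).
#' @param b Shell b-values in s/mm^2 (default `c(0, 750, 1500)`).
#' @param te Echo times in ms (default `c(54, 75, 100, 130)`).
#' @inheritParams acquisition_scheme
#' @return An `acq_scheme` tibble.
#' @export
default_scheme <- function(n_dirs = 30, b = c(0, 750, 1500),
                           te = c(54, 75, 100, 130),
                           delta_big = 22, delta_small = 8,
                           b0_dir = c(0, 0, 1)) {
  dirs <- gradient_directions(n_dirs)
  b_nz <- b[b > 0]
  one_te <- rbind(c(0, 0, 0, 0),
                  do.call(rbind, lapply(b_nz, function(bb) {
                    cbind(bb, dirs)
                  })))
  all_rows <- do.call(rbind, lapply(te, function(t) cbind(one_te, t)))
  acquisition_scheme(b = all_rows[, 1], g = all_rows[, 2:4],
                     te = all_rows[, 5],
                     delta_big = delta_big, delta_small = delta_small,
                     b0_dir = b0_dir)
}

#' Read an acquisition scheme from FSL-dialect text files
#'
#' `bval` holds whitespace-separated b-values (s/mm^2) on one row; `bvec`
#' holds three whitespace-separated rows of x, y, z gradient components in the
#' scanner frame; the TE sidecar holds one echo time (ms) per measurement,
#' one per line (a single whitespace-separated row is also accepted).
#'
#' @param bval_path,bvec_path,te_path File paths.
#' @inheritParams acquisition_scheme
#' @return An `acq_scheme` tibble.
#' @export
read_scheme <- function(bval_path, bvec_path, te_path,
                        delta_big = 22, delta_small = 8,
                        b0_dir = c(0, 0, 1)) {
  for (p in c(bval_path, bvec_path, te_path)) {
    if (!file.exists(p)) abort(sprintf("File not found: %s", p))
  }
  bval <- scan(bval_path, quiet = TRUE)
  bvec <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvec) != 3L) {
    abort(sprintf("bvec file must have 3 rows (x, y, z); found %d (file %s).",
                  nrow(bvec), bvec_path))
  }
  if (ncol(bvec) != length(bval)) {
    abort(sprintf(
      "bvec column count (%d) does not match bval count (%d).",
      ncol(bvec), length(bval)))
  }
  te <- scan(te_path, quiet = TRUE)
  if (length(te) != length(bval)) {
    abort(sprintf("TE count (%d) does not match bval count (%d).",
                  length(te), length(bval)))
  }
  acquisition_scheme(b = bval, g = t(bvec), te = te,
                     delta_big = delta_big, delta_small = delta_small,
                     b0_dir = b0_dir)
}

#' Write an acquisition scheme to FSL-dialect text files
#'
#' Inverse of [read_scheme()]; round-trips exactly at the printed precision.
#'
#' @param scheme An `acq_scheme`.
#' @inheritParams read_scheme
#' @return Invisibly, the scheme.
#' @export
write_scheme <- function(scheme, bval_path, bvec_path, te_path) {
  stopifnot(inherits(scheme, "acq_scheme"))
  writeLines(paste(format(scheme$b, trim = TRUE, digits = 15),
                   collapse = " "), bval_path)
  g <- rbind(scheme$gx, scheme$gy, scheme$gz)
  writeLines(apply(g, 1, function(r) {
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")
  }), bvec_path)
  writeLines(format(scheme$te, trim = TRUE, digits = 15), te_path)
  invisible(scheme)
}
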