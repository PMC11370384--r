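# Principal diffusion orientation extraction.
#
# The default source is the principal eigenvector of a fitted tensor;
# alternatively the maximum of an even-order real spherical-harmonic
# function (an fODF surrogate) located by dense-grid search with local
# refinement. Peaks are orientations: u and -u are identified.

#' Principal peak per location
#'
#' @param fit a `dti_fit` tibble (uses `e1x/e1y/e1z` and flags
#'   near-isotropic locations), or a matrix of even-order real SH
#'   coefficients (one row per location, see [sh_eval()] for ordering).
#' @param fa_min tensor fits with FA below this are flagged degenerate.
#' @return tibble: `px`, `py`, `pz` unit orientation (sign convention:
#'   non-negative z, then y, then x), `flagged`.
#' @export
principal_peak <- function(fit, fa_min = 0.05) {
  if (inherits(fit, "dti_fit")) {
    p <- cbind(fit$e1x, fit$e1y, fit$e1z)
    flag <- fit$flagged | !is.finite(fit$fa) | fit$fa < fa_min
  } else {
    stopifnot(is.matrix(fit))
    p <- t(apply(fit, 1, sh_peak))
    flag <- apply(fit, 1, function(cf) max(abs(cf[-1])) < 1e-8 * max(1, abs(cf[1])))
  }
  p <- canonical_orientation(p)
  p[flag, ] <- NA_real_
  tibble::tibble(px = p[, 1], py = p[, 2], pz = p[, 3], flagged = flag)
}

canonical_orientation <- function(p) {
  s <- sign(p[, 3])
  zz <- abs(p[, 3]) < 1e-12
  s[zz] <- sign(p[zz, 2])
  zz2 <- zz & abs(p[, 2]) < 1e-12
  s[zz2] <- sign(p[zz2, 1])
  s[s == 0] <- 1
  p * s
}

# real even spherical harmonics (descoteaux-style ordering):
# for l = 0, 2, ..., lmax and m = -l..l:
#   m < 0 -> sqrt(2) Im(Y_l^|m|), m = 0 -> Y_l^0, m > 0 -> sqrt(2) Re(Y_l^m)
#' Evaluate real even-order spherical harmonics
#'
#' @param dirs `n x 3` unit vectors.
#' @param lmax even maximum order.
#' @return `n x n_coef` design matrix, `n_coef = (lmax+1)(lmax+2)/2`.
#' @export
sh_eval <- function(dirs, lmax = 8) {
  theta <- acos(pmin(pmax(dirs[, 3], -1), 1))
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  cols <- list()
  for (l in seq(0, lmax, by = 2)) {
    Plm <- assoc_legendre(cos(theta), l)
    for (m in -l:l) {
      am <- abs(m)
      norm <- sqrt((2 * l + 1) / (4 * pi) *
                     exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      base <- norm * Plm[, am + 1]
      cols[[length(cols) + 1]] <- if (m < 0) {
        sqrt(2) * base * sin(am * phi)
      } else if (m == 0) base else sqrt(2) * base * cos(am * phi)
    }
  }
  do.call(cbind, cols)
}

# associated Legendre P_l^m(x) for m = 0..l (Condon-Shortley included)
assoc_legendre <- function(x, l) {
  out <- matrix(0, length(x), l + 1)
  sx <- sqrt(pmax(1 - x^2, 0))
  for (m in 0:l) {
    pmm <- rep(1, length(x))
    if (m > 0) pmm <- (-1)^m * prod(seq(1, 2 * m - 1, by = 2)) * sx^m
    if (l == m) { out[, m + 1] <- pmm; next }
    pmmp1 <- x * (2 * m + 1) * pmm
    if (l == m + 1) { out[, m + 1] <- pmmp1; next }
    pll <- pmmp1
    for (ll in (m + 2):l) {
      pll <- ((2 * ll - 1) * x * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
      pmm <- pmmp1
      pmmp1 <- pll
    }
    out[, m + 1] <- pll
  }
  out
}

# dense-grid + Nelder-Mead refinement of the SH maximum
sh_peak <- function(coefs, lmax = NULL) {
  n_coef <- length(coefs)
  if (is.null(lmax)) lmax <- (-3 + sqrt(1 + 8 * n_coef)) / 2
  grid <- the$sh_peak_grid
  if (is.null(grid)) {
    gl <- gauss_legendre(24, -1, 1)
    az <- seq(0, 2 * pi, length.out = 49)[-49]
    g <- expand.grid(ct = gl$nodes, phi = az)
    st <- sqrt(1 - g$ct^2)
    grid <- cbind(st * cos(g$phi), st * sin(g$phi), g$ct)
    the$sh_peak_grid <- grid
  }
  vals <- sh_eval(grid, lmax) %*% coefs
  x0 <- grid[which.max(vals), ]
  th0 <- acos(pmin(pmax(x0[3], -1), 1)); ph0 <- atan2(x0[2], x0[1])
  f <- function(p) {
    d <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
    -as.numeric(sh_eval(matrix(d, 1), lmax) %*% coefs)
  }
  o <- optim(c(th0, ph0), f, method = "Nelder-Mead",
             control = list(reltol = 1e-12, maxit = 500))
  c(sin(o$par[1]) * cos(o$par[2]), sin(o$par[1]) * sin(o$par[2]),
    cos(o$par[1]))
}
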