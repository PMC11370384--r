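# Small numerical building blocks shared across the signal models.

#' Gauss-Legendre nodes and weights on an interval
#'
#' Golub-Welsch eigenvalue construction; cached per (n, a, b).
#'
#' @param n number of nodes.
#' @param a,b interval endpoints.
#' @return list with `nodes` and `weights`.
#' @keywords internal
gauss_legendre <- function(n, a = -1, b = 1) {
  key <- paste0("gl_", n, "_", a, "_", b)
  if (!is.null(the[[key]])) return(the[[key]])
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  out <- list(
    nodes = (b - a) / 2 * x[ord] + (a + b) / 2,
    weights = (b - a) / 2 * w[ord]
  )
  the[[key]] <- out
  out
}

#' Error function
#' @param x numeric vector.
#' @keywords internal
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Legendre polynomials P_0..P_lmax evaluated by upward recurrence
#'
#' @param x numeric vector in `[-1, 1]`.
#' @param lmax highest order.
#' @return matrix `length(x)` by `lmax + 1`; column `l + 1` holds `P_l(x)`.
#' @keywords internal
legendre_table <- function(x, lmax) {
  P <- matrix(0, length(x), lmax + 1)
  P[, 1] <- 1
  if (lmax >= 1) P[, 2] <- x
  if (lmax >= 2) {
    for (l in 1:(lmax - 1)) {
      P[, l + 2] <- ((2 * l + 1) * x * P[, l + 1] - l * P[, l]) / (l + 1)
    }
  }
  P
}

#' Spherical mean of the Rician distribution (exact)
#'
#' Mean of `|nu + e1 + i e2|` with independent Gaussian channels of sd
#' `sigma`, via the Laguerre half-order closed form. Used as a test oracle
#' for the noise generator.
#'
#' @param nu noiseless magnitude.
#' @param sigma channel standard deviation.
#' @return expected magnitude.
#' @export
rician_mean <- function(nu, sigma) {
  x <- -nu^2 / (2 * sigma^2)
  # exp-scaled Bessel keeps this finite for large SNR
  L <- (1 - x) * besselI(-x / 2, 0, expon.scaled = TRUE) -
    x * besselI(-x / 2, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * L
}

#' Deterministic child seeds from one master seed
#' @param seed master seed.
#' @param n how many child seeds.
#' @keywords internal
child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.integer(seed) + 104729L * seq_len(n)) %% 2147483647L
}
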