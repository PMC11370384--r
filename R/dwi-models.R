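# Closed-form forward signal models.
#
# Unit conventions: b in ms/um^2, diffusivities in um^2/ms, radii in um,
# pulse timings delta/Delta in ms. All signals are normalized to S(b=0).

#' Tensor model parameters
#'
#' @param D symmetric positive semi-definite 3x3 diffusion tensor
#'   (um^2/ms).
#' @param S0 baseline signal.
#' @return object of class `tensor_params`.
#' @export
tensor_params <- function(D, S0 = 1) {
  D <- as.matrix(D)
  stopifnot(all(dim(D) == c(3, 3)))
  if (max(abs(D - t(D))) > 1e-8) stop("tensor must be symmetric", call. = FALSE)
  if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("tensor must be positive semi-definite", call. = FALSE)
  }
  structure(list(D = (D + t(D)) / 2, S0 = S0), class = "tensor_params")
}

#' Diffusion tensor signal
#'
#' `S = S0 exp(-<B, D>_F)` with the b-matrix `B = b g g^T` per volume.
#'
#' @param params a [tensor_params()].
#' @param protocol a [make_protocol()] table.
#' @return signal per volume.
#' @export
tensor_signal <- function(params, protocol) {
  stopifnot(inherits(params, "tensor_params"))
  G <- cbind(protocol$gx, protocol$gy, protocol$gz)
  D <- params$D
  quad <- G[, 1]^2 * D[1, 1] + G[, 2]^2 * D[2, 2] + G[, 3]^2 * D[3, 3] +
    2 * G[, 1] * G[, 2] * D[1, 2] + 2 * G[, 1] * G[, 3] * D[1, 3] +
    2 * G[, 2] * G[, 3] * D[2, 3]
  params$S0 * exp(-protocol$b * quad)
}

#' FA and MD from tensor eigenvalues
#'
#' MD is the eigenvalue mean; FA the usual normalized eigenvalue
#' dispersion. An all-zero tensor has FA defined as 0.
#'
#' @param ev numeric vector of three eigenvalues (um^2/ms).
#' @return named list with `fa` and `md`.
#' @export
fa_md <- function(ev) {
  stopifnot(length(ev) == 3, all(is.finite(ev)))
  md <- mean(ev)
  ss <- sum(ev^2)
  fa <- if (ss == 0) 0 else sqrt(1.5 * sum((ev - md)^2) / ss)
  list(fa = min(fa, 1), md = md)
}

#' Isotropic Gaussian ("ball") signal
#' @param b b-value (ms/um^2).
#' @param D diffusivity (um^2/ms).
#' @return `exp(-b D)`.
#' @export
ball_signal <- function(b, D) {
  stopifnot(all(b >= 0), all(D >= 0))
  exp(-b * D)
}

#' Spherical mean of the stick (zero-radius cylinder) signal
#'
#' Direction average of `exp(-b D cos^2 psi)`:
#' `sqrt(pi / (4 b D)) * erf(sqrt(b D))`, with limit 1 as `b D -> 0`.
#'
#' @param b b-value(s), ms/um^2.
#' @param D intra-neurite diffusivity, um^2/ms.
#' @return mean signal per b.
#' @export
stick_sphmean <- function(b, D) {
  stopifnot(all(b >= 0), all(D >= 0))
  x <- b * D
  out <- numeric(length(x))
  small <- x < 1e-8
  out[small] <- 1 - x[small] / 3
  xs <- x[!small]
  out[!small] <- sqrt(pi / (4 * xs)) * erf(sqrt(xs))
  out
}

# Roots of j1'(x) = 0 (spherical Bessel derivative), cached.
sphere_bessel_roots <- function(n = 50L) {
  key <- paste0("j1proots_", n)
  if (!is.null(the[[key]])) return(the[[key]])
  j1p <- function(x) (2 / x^2 - 1) * sin(x) / x - 2 * cos(x) / x^2
  roots <- numeric(n)
  lo <- 1.1
  k <- 0L
  while (k < n) {
    hi <- lo + 0.5
    if (j1p(lo) * j1p(hi) < 0) {
      k <- k + 1L
      roots[k] <- uniroot(j1p, c(lo, hi), tol = 1e-13)$root
    }
    lo <- hi
  }
  the[[key]] <- roots
  roots
}

#' Spherical mean of restricted diffusion in a sphere (GPD approximation)
#'
#' Gaussian-phase-distribution attenuation for a pulsed-gradient pair
#' (Murday-Cotts series over the roots of the spherical Bessel derivative).
#' The sphere signal is orientation independent, so the spherical mean
#' equals the directional signal. Gradient strength enters through
#' `b = gamma^2 G^2 delta^2 (Delta - delta/3)`.
#'
#' @param b b-value(s), ms/um^2.
#' @param r_s sphere (soma) radius, um.
#' @param delta,Delta pulse duration and separation, ms.
#' @param D_is intra-sphere diffusivity, um^2/ms (3.0 by convention).
#' @param n_roots series length (default 50; converged well before 20
#'   for radii up to 12 um).
#' @return mean signal per b.
#' @export
sphere_gpd_sphmean <- function(b, r_s, delta, Delta, D_is = 3.0,
                               n_roots = 50L) {
  if (!(Delta > delta && delta > 0)) {
    stop("pulse timings must satisfy Delta > delta > 0", call. = FALSE)
  }
  stopifnot(r_s > 0, D_is > 0, all(b >= 0))
  am <- sphere_bessel_roots(n_roots) / r_s
  a2D <- am^2 * D_is
  term <- 2 * delta - (2 + exp(-a2D * (Delta - delta)) - 2 * exp(-a2D * delta) -
    2 * exp(-a2D * Delta) + exp(-a2D * (Delta + delta))) / a2D
  s <- sum(term / (am^4 * (am^2 * r_s^2 - 2)))
  g2 <- b / (delta^2 * (Delta - delta / 3)) # gamma^2 G^2 per b
  exp(-2 * g2 / D_is * s)
}

#' SANDI parameters
#'
#' Soma And Neurite Density Imaging compartment parameters. `f_ec` is the
#' extracellular signal fraction; `f_in` the intra-neurite fraction of the
#' cellular (non-extracellular) signal; the soma fraction of the cellular
#' signal is `1 - f_in`.
#'
#' @param f_ec extracellular signal fraction in `[0, 1]`.
#' @param f_in intra-neurite fraction of the cellular compartment, `[0, 1]`.
#' @param r_s soma radius, um.
#' @param D_in intra-neurite diffusivity, um^2/ms.
#' @param D_ec extracellular diffusivity, um^2/ms.
#' @param D_is intra-soma diffusivity, fixed at 3.0 um^2/ms by convention.
#' @return object of class `sandi_params`.
#' @export
sandi_params <- function(f_ec, f_in, r_s, D_in = 1.7, D_ec = 1.0,
                         D_is = 3.0) {
  stopifnot(f_ec >= 0, f_ec <= 1, f_in >= 0, f_in <= 1,
            r_s > 0, D_in >= 0, D_ec >= 0, D_is > 0)
  structure(list(f_ec = f_ec, f_in = f_in, r_s = r_s,
                 D_in = D_in, D_ec = D_ec, D_is = D_is),
            class = "sandi_params")
}

#' SANDI spherical-mean signal
#'
#' `S(b) = (1 - f_ec) [ f_in S_in + (1 - f_in) S_is ] + f_ec S_ec`, with
#' the stick spherical mean, the GPD sphere, and the isotropic ball.
#'
#' @param params a [sandi_params()].
#' @param b b-values, ms/um^2.
#' @param delta,Delta pulse timings, ms.
#' @return mean signal per b.
#' @export
sandi_sphmean <- function(params, b, delta = 7, Delta = 24) {
  stopifnot(inherits(params, "sandi_params"))
  s_in <- stick_sphmean(b, params$D_in)
  s_is <- vapply(b, function(bb)
    sphere_gpd_sphmean(bb, params$r_s, delta, Delta, params$D_is), numeric(1))
  s_ec <- ball_signal(b, params$D_ec)
  (1 - params$f_ec) * (params$f_in * s_in + (1 - params$f_in) * s_is) +
    params$f_ec * s_ec
}

#' Derived SANDI signal-fraction maps
#'
#' `fextracellular = f_ec`, `fneurite = (1 - f_ec) f_in`,
#' `fsoma = (1 - f_ec)(1 - f_in)`; the three sum to 1 exactly.
#'
#' @param f_ec,f_in SANDI fractions (vectors allowed).
#' @return tibble with `fneurite`, `fsoma`, `fextracellular`.
#' @export
sandi_derived_fractions <- function(f_ec, f_in) {
  tibble::tibble(
    fneurite = (1 - f_ec) * f_in,
    fsoma = (1 - f_ec) * (1 - f_in),
    fextracellular = f_ec
  )
}
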