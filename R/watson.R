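# Watson-dispersed stick compartment and the NODDI three-compartment model.
#
# The dispersed-stick signal is computed by Legendre-band convolution
# (Funk-Hecke): with the Watson density written as a function of
# t = u . mu, g(t) = exp(kappa t^2) / (2 integral_0^1 exp(kappa s^2) ds),
# and the stick kernel K(t) = exp(-b d t^2),
#   S(n) = sum_l g_l [ integral_-1^1 K(t) P_l(t) dt ] P_l(n . mu),
# where g_l are the Legendre coefficients of g. Both one-dimensional
# integrals use 64-node Gauss-Legendre quadrature; only even orders
# contribute by antipodal symmetry.

WATSON_LMAX <- 40L
WATSON_NODES <- 64L

# sharply concentrated distributions need more bands and finer quadrature
watson_lmax <- function(kappa) if (kappa > 64) 100L else WATSON_LMAX
watson_nodes <- function(kappa) if (kappa > 64) 192L else WATSON_NODES

#' Orientation dispersion index from the Watson concentration
#'
#' `ODI = (2/pi) atan(1/kappa)`, extended by continuity to `ODI(0) = 1`.
#'
#' @param kappa Watson concentration, `>= 0`.
#' @return ODI in `[0, 1]`.
#' @export
odi_from_kappa <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
  ifelse(kappa == 0, 1, (2 / pi) * atan(1 / kappa))
}

#' @rdname odi_from_kappa
#' @param odi orientation dispersion index in `(0, 1]`.
#' @export
kappa_from_odi <- function(odi) {
  stopifnot(all(odi > 0), all(odi <= 1))
  ifelse(odi == 1, 0, 1 / tan(pi * odi / 2))
}

# Legendre coefficients g_l of the normalized Watson profile (even l only;
# returned as a dense vector over l = 0..lmax with odd entries zero).
watson_legendre_coefs <- function(kappa, lmax = watson_lmax(kappa)) {
  nodes <- max(watson_nodes(kappa), if (lmax > 64) 192L else 0L)
  gl <- gauss_legendre(nodes, -1, 1)
  # max-exponent shift keeps large kappa finite; it cancels on normalizing
  ft <- exp(kappa * (gl$nodes^2 - 1))
  ft <- ft / sum(gl$weights * ft) # normalize so integral over [-1,1] is 1
  P <- legendre_table(gl$nodes, lmax)
  l <- 0:lmax
  coefs <- (2 * l + 1) / 2 * as.numeric(crossprod(P, gl$weights * ft))
  coefs[l %% 2 == 1] <- 0
  coefs
}

# integral_-1^1 exp(-bd t^2) P_l(t) dt for l = 0..lmax (odd orders zero).
stick_kernel_legendre <- function(bd, lmax = WATSON_LMAX, nodes = WATSON_NODES) {
  gl <- gauss_legendre(nodes, -1, 1)
  K <- exp(-bd * gl$nodes^2)
  P <- legendre_table(gl$nodes, lmax)
  k <- as.numeric(crossprod(P, gl$weights * K))
  k[(0:lmax) %% 2 == 1] <- 0
  k
}

#' Watson-dispersed stick signal
#'
#' Signal of sticks with orientations Watson-distributed about `mu`,
#' measured along directions at angle `acos(cos_alpha)` from `mu`.
#'
#' @param b b-value (scalar), ms/um^2.
#' @param d_par stick diffusivity, um^2/ms.
#' @param kappa Watson concentration.
#' @param cos_alpha cosine(s) of the angle between `mu` and the gradient
#'   direction.
#' @return signal per direction.
#' @export
watson_stick_signal <- function(b, d_par, kappa, cos_alpha) {
  stopifnot(kappa >= 0, b >= 0, d_par >= 0)
  lmax <- watson_lmax(kappa)
  g <- watson_legendre_coefs(kappa, lmax)
  k <- stick_kernel_legendre(b * d_par, lmax, watson_nodes(kappa))
  P <- legendre_table(cos_alpha, lmax)
  as.numeric(P %*% (g * k))
}

#' Watson mean-squared orientation coherence
#'
#' `tau1 = E[(u . mu)^2]` under the Watson distribution; 1/3 at
#' `kappa = 0`, 1 as `kappa -> Inf`. Sets the eigenvalues of the
#' dispersion-averaged extra-neurite tensor.
#'
#' @param kappa Watson concentration.
#' @return tau1 in `[1/3, 1]`.
#' @export
watson_tau1 <- function(kappa) {
  gl <- gauss_legendre(watson_nodes(kappa), 0, 1)
  ft <- exp(kappa * (gl$nodes^2 - 1))
  sum(gl$weights * gl$nodes^2 * ft) / sum(gl$weights * ft)
}

#' NODDI parameters
#'
#' @param f_iso CSF signal fraction in `[0, 1]`.
#' @param f_in intra-neurite fraction of the tissue signal, `[0, 1]`.
#' @param kappa Watson concentration, `>= 0`.
#' @param mu mean orientation (unit 3-vector; normalized internally).
#' @param d_par parallel diffusivity, fixed at 1.7 um^2/ms by convention.
#' @param d_iso CSF diffusivity, fixed at 3.0 um^2/ms by convention.
#' @return object of class `noddi_params`.
#' @export
noddi_params <- function(f_iso, f_in, kappa, mu = c(0, 0, 1),
                         d_par = 1.7, d_iso = 3.0) {
  stopifnot(f_iso >= 0, f_iso <= 1, f_in >= 0, f_in <= 1, kappa >= 0,
            length(mu) == 3, d_par >= 0, d_iso >= 0)
  nm <- sqrt(sum(mu^2))
  if (nm == 0) stop("mu must be a nonzero vector", call. = FALSE)
  structure(list(f_iso = f_iso, f_in = f_in, kappa = kappa, mu = mu / nm,
                 d_par = d_par, d_iso = d_iso), class = "noddi_params")
}

#' NODDI three-compartment signal
#'
#' `S = (1 - f_iso) [ f_in S_in + (1 - f_in) S_en ] + f_iso S_iso`.
#' `S_in` is the Watson-dispersed stick; `S_en` the dispersion-averaged
#' axially symmetric tensor with tortuosity
#' `d_perp = d_par (1 - f_in)`; `S_iso = exp(-b d_iso)`.
#'
#' @param params a [noddi_params()].
#' @param protocol a [make_protocol()] table.
#' @return signal per volume.
#' @export
noddi_signal <- function(params, protocol) {
  stopifnot(inherits(params, "noddi_params"))
  G <- cbind(protocol$gx, protocol$gy, protocol$gz)
  ca <- as.numeric(G %*% params$mu)
  b <- protocol$b
  s <- numeric(nrow(protocol))
  d_perp <- params$d_par * (1 - params$f_in)
  t1 <- watson_tau1(params$kappa)
  # dispersion-averaged zeppelin eigenvalues
  e_par <- d_perp + (params$d_par - d_perp) * t1
  e_perp <- d_perp + (params$d_par - d_perp) * (1 - t1) / 2
  for (bb in unique(b)) {
    i <- which(b == bb)
    s_in <- watson_stick_signal(bb, params$d_par, params$kappa, ca[i])
    s_en <- exp(-bb * (e_perp + (e_par - e_perp) * ca[i]^2))
    s_iso <- exp(-bb * params$d_iso)
    s[i] <- (1 - params$f_iso) *
      (params$f_in * s_in + (1 - params$f_in) * s_en) +
      params$f_iso * s_iso
  }
  s
}
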