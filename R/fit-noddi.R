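# NODDI estimation by multi-start bounded nonlinear least squares with
# the conventional fixed diffusivities (d_par = 1.7, d_iso = 3.0
# um^2/ms).

# Per-protocol cache: unique b's, volume index map, stick-kernel Legendre
# coefficients (d_par is fixed) and CSF signals.
noddi_proto_cache <- function(protocol, d_par = 1.7, d_iso = 3.0) {
  ub <- unique(protocol$b)
  list(
    b = protocol$b,
    G = cbind(protocol$gx, protocol$gy, protocol$gz),
    ub = ub,
    idx = lapply(ub, function(bb) which(protocol$b == bb)),
    lmax = 100L,
    klg = lapply(ub, function(bb)
      stick_kernel_legendre(bb * d_par, lmax = 100L, nodes = 192L)),
    s_iso = exp(-ub * d_iso),
    d_par = d_par, d_iso = d_iso
  )
}

# predicted NODDI signal for par = (f_iso, f_in, log_kappa, theta, phi)
noddi_predict <- function(par, cache) {
  f_iso <- par[1]; f_in <- par[2]; kappa <- exp(par[3])
  mu <- c(sin(par[4]) * cos(par[5]), sin(par[4]) * sin(par[5]), cos(par[4]))
  ca <- as.numeric(cache$G %*% mu)
  P <- legendre_table(ca, cache$lmax)
  g <- watson_legendre_coefs(kappa, cache$lmax)
  t1 <- watson_tau1(kappa)
  d_perp <- cache$d_par * (1 - f_in)
  e_par <- d_perp + (cache$d_par - d_perp) * t1
  e_perp <- d_perp + (cache$d_par - d_perp) * (1 - t1) / 2
  s <- numeric(length(cache$b))
  for (k in seq_along(cache$ub)) {
    i <- cache$idx[[k]]
    bb <- cache$ub[k]
    s_in <- as.numeric(P[i, , drop = FALSE] %*% (g * cache$klg[[k]]))
    s_en <- exp(-bb * (e_perp + (e_par - e_perp) * ca[i]^2))
    s[i] <- (1 - f_iso) * (f_in * s_in + (1 - f_in) * s_en) +
      f_iso * cache$s_iso[k]
  }
  s
}

#' Fit the NODDI model
#'
#' Multi-start bounded nonlinear least squares over
#' `(f_iso, f_in, kappa, mu)` on all volumes, with `d_par` and `d_iso`
#' fixed. The mean orientation is initialized from the principal
#' eigenvector of a low-b tensor fit; `kappa` and the fractions from a
#' small grid, keeping the best `n_starts` grid points for refinement.
#'
#' @param signals matrix locations x volumes, b0-normalized (use
#'   [spherical_mean()]'s b0 or normalize upstream).
#' @param protocol a [make_protocol()] table.
#' @param n_starts refinement starts per location.
#' @param d_par,d_iso fixed diffusivities, um^2/ms.
#' @return tibble of class `noddi_fit`: `f_iso`, `f_in` (fneurite_NODDI),
#'   `kappa`, `odi`, orientation `mux/muy/muz`, `objective`, `converged`,
#'   `flagged`.
#' @export
fit_noddi <- function(signals, protocol, n_starts = 3L,
                      d_par = 1.7, d_iso = 3.0) {
  if (is.vector(signals)) signals <- matrix(signals, 1)
  st <- shell_table(protocol)
  if (sum(st$b > 0) < 3) stop("need >= 3 nonzero shells", call. = FALSE)
  cache <- noddi_proto_cache(protocol, d_par, d_iso)
  dti <- fit_dti(signals, protocol)
  n <- nrow(signals)
  lower <- c(0, 0, log(1e-3), -Inf, -Inf)
  upper <- c(1, 1, log(128), Inf, Inf)
  grid <- expand.grid(f_iso = c(0.02, 0.3), f_in = c(0.2, 0.5, 0.8),
                      kappa = c(0.5, 2, 8, 32))

  out <- tibble::tibble(
    f_iso = NA_real_, f_in = NA_real_, kappa = NA_real_, odi = NA_real_,
    mux = NA_real_, muy = NA_real_, muz = NA_real_,
    objective = NA_real_, converged = FALSE, flagged = FALSE, .rows = n
  )
  for (i in seq_len(n)) {
    y <- signals[i, ]
    if (!all(is.finite(y))) { out$flagged[i] <- TRUE; next }
    mu0 <- c(dti$e1x[i], dti$e1y[i], dti$e1z[i])
    if (any(!is.finite(mu0))) mu0 <- c(0, 0, 1)
    th0 <- acos(pmin(pmax(mu0[3], -1), 1))
    ph0 <- atan2(mu0[2], mu0[1])
    obj <- function(p) {
      r <- noddi_predict(p, cache) - y
      sum(r * r)
    }
    sc <- apply(grid, 1, function(gr)
      obj(c(gr[1], gr[2], log(gr[3]), th0, ph0)))
    best <- order(sc)[seq_len(n_starts)]
    fits <- lapply(best, function(k) {
      p0 <- c(grid$f_iso[k], grid$f_in[k], log(grid$kappa[k]), th0, ph0)
      tryCatch(
        optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(maxit = 200, factr = 1e4)),
        error = function(e) NULL)
    })
    fits <- fits[!vapply(fits, is.null, logical(1))]
    if (!length(fits)) { out$flagged[i] <- TRUE; next }
    vals <- vapply(fits, function(f) f$value, numeric(1))
    f <- fits[[which.min(vals)]]
    p <- f$par
    mu <- c(sin(p[4]) * cos(p[5]), sin(p[4]) * sin(p[5]), cos(p[4]))
    out$f_iso[i] <- p[1]; out$f_in[i] <- p[2]
    out$kappa[i] <- exp(p[3]); out$odi[i] <- odi_from_kappa(exp(p[3]))
    out$mux[i] <- mu[1]; out$muy[i] <- mu[2]; out$muz[i] <- mu[3]
    out$objective[i] <- f$value
    out$converged[i] <- f$convergence == 0
  }
  class(out) <- c("noddi_fit", class(out))
  out
}
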