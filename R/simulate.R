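# Forward simulation of diffusion signals from parameter tables.

#' Add magnitude (Rician) or Gaussian noise to signals
#'
#' Rician: two independent Gaussian channels of sd `1/snr` added to the
#' complex signal, magnitude taken. SNR is defined at b = 0 for
#' unit-normalized signals.
#'
#' @param signal numeric vector/matrix of noiseless signals.
#' @param snr signal-to-noise ratio at b = 0 (must be > 0).
#' @param noise_model `"rician"`, `"gaussian"` or `"none"`.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return noisy signals, same shape.
#' @export
add_noise <- function(signal, snr, noise_model = c("rician", "gaussian", "none"),
                      seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (noise_model == "none") return(signal)
  if (!is.numeric(snr) || snr <= 0) {
    stop("snr must be > 0 when noise is enabled", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sigma <- 1 / snr
  n <- length(signal)
  if (noise_model == "gaussian") {
    out <- signal + rnorm(n, 0, sigma)
  } else {
    out <- sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  }
  if (is.matrix(signal)) out <- matrix(out, nrow(signal), ncol(signal))
  out
}

#' Simulate multi-shell signals for a table of locations
#'
#' Forward-simulates one signal row per location from the chosen
#' compartment model, then applies the noise model. Signals are
#' normalized (b = 0 signal 1 before noise).
#'
#' @param params tibble, one row per location. Columns by model:
#'   `sandi`: `f_ec`, `f_in`, `r_s`, `D_in`, `D_ec`, optional stick
#'   orientation `mux`, `muy`, `muz` (random if absent);
#'   `noddi`: `f_iso`, `f_in`, `kappa`, optional `mux/muy/muz`;
#'   `dti`: tensor components `dxx`, `dyy`, `dzz`, `dxy`, `dxz`, `dyz`.
#' @param protocol a [make_protocol()] table.
#' @param model compartment model.
#' @param snr signal-to-noise ratio at b = 0.
#' @param noise_model `"rician"` (default), `"gaussian"`, `"none"`.
#' @param seed integer seed.
#' @return matrix locations x volumes.
#' @export
simulate_signals <- function(params, protocol,
                             model = c("sandi", "noddi", "dti"),
                             snr = 50, noise_model = c("rician", "gaussian", "none"),
                             seed = 1L) {
  model <- match.arg(model)
  noise_model <- match.arg(noise_model)
  n <- nrow(params)
  set.seed(seed)
  mu <- stick_orientations(params, n)
  b <- protocol$b
  G <- cbind(protocol$gx, protocol$gy, protocol$gz)
  delta <- attr(protocol, "delta"); Delta <- attr(protocol, "Delta")
  S <- matrix(NA_real_, n, nrow(protocol))

  if (model == "sandi") {
    need <- c("f_ec", "f_in", "r_s", "D_in", "D_ec")
    check_cols(params, need, model)
    ub <- unique(b)
    for (i in seq_len(n)) {
      ca2 <- as.numeric(G %*% mu[i, ])^2
      s_in <- exp(-b * params$D_in[i] * ca2)
      s_is_b <- vapply(ub, function(bb)
        sphere_gpd_sphmean(bb, params$r_s[i], delta, Delta), numeric(1))
      s_is <- s_is_b[match(b, ub)]
      s_ec <- exp(-b * params$D_ec[i])
      S[i, ] <- (1 - params$f_ec[i]) *
        (params$f_in[i] * s_in + (1 - params$f_in[i]) * s_is) +
        params$f_ec[i] * s_ec
    }
  } else if (model == "noddi") {
    need <- c("f_iso", "f_in", "kappa")
    check_cols(params, need, model)
    for (i in seq_len(n)) {
      p <- noddi_params(params$f_iso[i], params$f_in[i], params$kappa[i],
                        mu = mu[i, ])
      S[i, ] <- noddi_signal(p, protocol)
    }
  } else {
    need <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")
    check_cols(params, need, model)
    for (i in seq_len(n)) {
      D <- matrix(c(params$dxx[i], params$dxy[i], params$dxz[i],
                    params$dxy[i], params$dyy[i], params$dyz[i],
                    params$dxz[i], params$dyz[i], params$dzz[i]), 3, 3)
      S[i, ] <- tensor_signal(tensor_params(D), protocol)
    }
  }
  add_noise(S, snr, noise_model, seed = NULL)
}

check_cols <- function(params, need, model) {
  miss <- setdiff(need, names(params))
  if (length(miss)) {
    stop("params for model '", model, "' lack column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

stick_orientations <- function(params, n) {
  if (all(c("mux", "muy", "muz") %in% names(params))) {
    mu <- cbind(params$mux, params$muy, params$muz)
  } else {
    mu <- matrix(rnorm(3 * n), n, 3)
  }
  mu / sqrt(rowSums(mu^2))
}
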