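# Diffusion tensor fitting by weighted linear least squares.

#' Fit the diffusion tensor
#'
#' Log-linear weighted least squares using all volumes with
#' `b <= max_b` (the conventional low-b subset: here b = 0, 0.5 and 1.2
#' ms/um^2 of the default protocol). A first ordinary LS pass supplies
#' the weights (squared predicted signals) for the second pass.
#'
#' @param signals matrix locations x volumes.
#' @param protocol a [make_protocol()] table.
#' @param max_b largest b-value entering the fit, ms/um^2.
#' @return tibble of class `dti_fit`, one row per location: `s0`, tensor
#'   components `dxx`...`dyz`, eigenvalues `l1 >= l2 >= l3`, principal
#'   eigenvector `e1x/e1y/e1z`, `fa`, `md`, `flagged`.
#' @export
fit_dti <- function(signals, protocol, max_b = 1.2) {
  if (is.vector(signals)) signals <- matrix(signals, 1)
  use <- which(protocol$b <= max_b + 1e-9)
  if (length(use) < 7) {
    stop("need at least 7 volumes at b <= max_b", call. = FALSE)
  }
  b <- protocol$b[use]
  G <- cbind(protocol$gx, protocol$gy, protocol$gz)[use, , drop = FALSE]
  X <- cbind(1, -b * G[, 1]^2, -b * G[, 2]^2, -b * G[, 3]^2,
             -2 * b * G[, 1] * G[, 2], -2 * b * G[, 1] * G[, 3],
             -2 * b * G[, 2] * G[, 3])
  if (qr(X)$rank < 7) stop("rank-deficient tensor design", call. = FALSE)
  n <- nrow(signals)
  Y <- signals[, use, drop = FALSE]
  bad_sig <- Y <= 0 | !is.finite(Y)
  Yl <- log(pmax(Y, 1e-12))

  # OLS pass (shared design across locations)
  XtXi <- solve(crossprod(X))
  B <- Yl %*% X %*% XtXi # n x 7

  out <- tibble::tibble(
    s0 = NA_real_, dxx = NA_real_, dyy = NA_real_, dzz = NA_real_,
    dxy = NA_real_, dxz = NA_real_, dyz = NA_real_,
    l1 = NA_real_, l2 = NA_real_, l3 = NA_real_,
    e1x = NA_real_, e1y = NA_real_, e1z = NA_real_,
    fa = NA_real_, md = NA_real_, flagged = FALSE, .rows = n
  )
  for (i in seq_len(n)) {
    if (any(bad_sig[i, ])) { out$flagged[i] <- TRUE; next }
    # WLS pass, weights = squared predicted signal
    w <- as.numeric(exp(X %*% B[i, ]))^2
    XtWX <- crossprod(X, w * X)
    bet <- tryCatch(solve(XtWX, crossprod(X, w * Yl[i, ])),
                    error = function(e) NULL)
    if (is.null(bet)) { out$flagged[i] <- TRUE; next }
    D <- matrix(c(bet[2], bet[5], bet[6],
                  bet[5], bet[3], bet[7],
                  bet[6], bet[7], bet[4]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    fm <- fa_md(e$values)
    out$s0[i] <- exp(bet[1])
    out$dxx[i] <- D[1, 1]; out$dyy[i] <- D[2, 2]; out$dzz[i] <- D[3, 3]
    out$dxy[i] <- D[1, 2]; out$dxz[i] <- D[1, 3]; out$dyz[i] <- D[2, 3]
    out$l1[i] <- e$values[1]; out$l2[i] <- e$values[2]; out$l3[i] <- e$values[3]
    out$e1x[i] <- e$vectors[1, 1]; out$e1y[i] <- e$vectors[2, 1]
    out$e1z[i] <- e$vectors[3, 1]
    out$fa[i] <- fm$fa; out$md[i] <- fm$md
  }
  class(out) <- c("dti_fit", class(out))
  attr(out, "n_volumes") <- length(use)
  attr(out, "max_b") <- max_b
  out
}
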