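# SANDI estimation on per-shell spherical means by multi-start bounded
# nonlinear least squares (intra-soma diffusivity fixed at 3.0 um^2/ms).
#
# Identifiability note: with a 6-shell protocol the direction-averaged
# decay leaves the fully-free 5-parameter problem with an almost exactly
# flat ridge (trading f_in against D_in/D_ec/r_s); the residual along
# that ridge sits far below any realistic noise floor, so unregularized
# estimates smear along it. The default estimator therefore fixes the
# intra-neurite diffusivity at 1.7 um^2/ms (the same convention NODDI
# uses for the same reason); `free_d_in = TRUE` fits it.

#' Default SANDI fitting bounds
#' @return list of `lower`/`upper` named vectors over
#'   `(f_ec, f_in, r_s, D_in, D_ec)`.
#' @export
sandi_bounds <- function() {
  list(
    lower = c(f_ec = 0, f_in = 0, r_s = 1, D_in = 0.1, D_ec = 0.1),
    upper = c(f_ec = 1, f_in = 1, r_s = 12, D_in = 3, D_ec = 3)
  )
}

# smooth per-shell sphere-signal interpolators over the radius bounds
sandi_sphere_spline <- function(b, delta, Delta, D_is = 3.0,
                                r_range = c(0.5, 12.5)) {
  key <- paste0("sphspl_", paste(signif(c(b, delta, Delta, D_is), 10),
                                 collapse = "_"))
  if (!is.null(the[[key]])) return(the[[key]])
  r <- seq(r_range[1], r_range[2], by = 0.05)
  s <- vapply(r, function(rr) sphere_gpd_sphmean(b, rr, delta, Delta, D_is),
              numeric(1))
  f <- stats::splinefun(r, s, method = "natural")
  the[[key]] <- f
  f
}

#' Fit the SANDI model to per-shell spherical means
#'
#' Bounded Levenberg-Marquardt on the direction-averaged signal decay;
#' free parameters `(f_ec, f_in, r_s, D_ec)` with `D_in` fixed at
#' 1.7 um^2/ms by default (see the identifiability note in the source;
#' `free_d_in = TRUE` adds `D_in` to the free set), `D_is` fixed at
#' 3.0 um^2/ms; multi-start from a fixed grid plus seeded jitter.
#' Derived maps `fneurite`, `fsoma`, `fextracellular` and `rsoma` are
#' appended (the three fractions sum to 1 exactly by construction).
#'
#' @param sphmeans matrix locations x shells of b0-normalized spherical
#'   means (see [spherical_mean()]).
#' @param b shell b-values, ms/um^2.
#' @param delta,Delta pulse timings, ms.
#' @param bounds a [sandi_bounds()] list.
#' @param n_starts number of optimization starts.
#' @param seed seed for start jitter.
#' @param free_d_in fit the intra-neurite diffusivity instead of fixing
#'   it at `d_in_fixed`.
#' @param d_in_fixed value of `D_in` when not fitted, um^2/ms.
#' @param D_is fixed intra-soma diffusivity, um^2/ms.
#' @return tibble of class `sandi_fit`: estimates, `objective`,
#'   `converged`, `flagged`, `bounds_hit`, derived maps.
#' @export
fit_sandi <- function(sphmeans, b, delta = 7, Delta = 24,
                      bounds = sandi_bounds(), n_starts = 5L, seed = 1L,
                      free_d_in = FALSE, d_in_fixed = 1.7, D_is = 3.0) {
  if (is.vector(sphmeans)) sphmeans <- matrix(sphmeans, 1)
  stopifnot(ncol(sphmeans) == length(b))
  if (sum(b > 0) < 4) stop("need >= 4 nonzero shells", call. = FALSE)
  nz <- b > 0
  bn <- b[nz]
  spl <- lapply(bn, function(bb) sandi_sphere_spline(bb, delta, Delta, D_is))
  set.seed(seed)
  n <- nrow(sphmeans)

  free <- if (free_d_in) c(1:5) else c(1, 2, 3, 5) # indices into 5-vector
  lo5 <- bounds$lower; hi5 <- bounds$upper
  lo <- lo5[free]; hi <- hi5[free]
  base_starts <- rbind(
    c(0.3, 0.5, 6, 1.5, 1.0),
    c(0.6, 0.3, 4, 2.0, 1.5),
    c(0.1, 0.7, 9, 1.0, 0.7),
    c(0.5, 0.5, 8, 2.5, 2.0),
    c(0.8, 0.2, 5, 1.2, 0.5)
  )
  starts5 <- base_starts[rep_len(seq_len(nrow(base_starts)), n_starts), ,
                         drop = FALSE]
  if (n_starts > nrow(base_starts)) {
    extra <- (nrow(base_starts) + 1):n_starts
    jit <- matrix(runif(length(extra) * 5, 0.9, 1.1), length(extra))
    starts5[extra, ] <- pmin(pmax(starts5[extra, , drop = FALSE] * jit,
                                  rep(lo5, each = length(extra)) * 1.01),
                             rep(hi5, each = length(extra)) * 0.99)
  }

  stick_fixed <- if (!free_d_in) stick_sphmean(bn, d_in_fixed) else NULL
  model5 <- function(p) {
    s_in <- if (free_d_in) stick_sphmean(bn, p[4]) else stick_fixed
    s_is <- vapply(seq_along(bn), function(k) spl[[k]](p[3]), numeric(1))
    s_ec <- exp(-bn * p[5])
    (1 - p[1]) * (p[2] * s_in + (1 - p[2]) * s_is) + p[1] * s_ec
  }

  est <- matrix(NA_real_, n, 5)
  objective <- rep(NA_real_, n)
  converged <- rep(FALSE, n)
  flagged <- rep(FALSE, n)
  bounds_hit <- rep(FALSE, n)
  for (i in seq_len(n)) {
    y <- sphmeans[i, nz]
    if (!all(is.finite(y))) { flagged[i] <- TRUE; next }
    best <- NULL
    for (s in seq_len(nrow(starts5))) {
      p5 <- starts5[s, ]
      if (!free_d_in) p5[4] <- d_in_fixed
      f <- tryCatch(
        minpack.lm::nls.lm(
          par = p5[free],
          lower = lo, upper = hi,
          fn = function(q) {
            p5[free] <- q
            model5(p5) - y
          },
          control = minpack.lm::nls.lm.control(maxiter = 150, ptol = 1e-12,
                                               ftol = 1e-12)),
        error = function(e) NULL)
      if (is.null(f)) next
      val <- sum(f$fvec^2)
      if (is.null(best) || val < best$val) best <- list(val = val, fit = f)
    }
    if (is.null(best)) { flagged[i] <- TRUE; next }
    p5 <- starts5[1, ]
    p5[4] <- d_in_fixed
    p5[free] <- best$fit$par
    est[i, ] <- p5
    objective[i] <- best$val
    converged[i] <- best$fit$info %in% 1:4
    bounds_hit[i] <- any(p5[free] <= lo + 1e-6) || any(p5[free] >= hi - 1e-6)
  }
  der <- sandi_derived_fractions(est[, 1], est[, 2])
  out <- tibble::tibble(
    f_ec = est[, 1], f_in = est[, 2], r_s = est[, 3],
    D_in = est[, 4], D_ec = est[, 5],
    fneurite = der$fneurite, fsoma = der$fsoma,
    fextracellular = der$fextracellular, rsoma = est[, 3],
    objective = objective, converged = converged,
    flagged = flagged, bounds_hit = bounds_hit
  )
  class(out) <- c("sandi_fit", class(out))
  attr(out, "free_d_in") <- free_d_in
  out
}
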