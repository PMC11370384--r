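# Spin-test permutation for correlating two surface maps while
# preserving spatial autocorrelation: one map is rigidly shifted in the
# unfolded (AP, PD) rectangle with toroidal wrap-around and resampled by
# nearest vertex.

# nearest-vertex raster lookup over the unit unfolded square, cached
spin_lookup <- function(mesh, res = NULL) {
  if (is.null(res)) {
    res <- c(max(64L, 2L * mesh$grid$n_ap), max(32L, 2L * mesh$grid$n_pd))
  }
  key <- paste0("spin_", mesh$grid$n_ap, "_", mesh$grid$n_pd, "_",
                mesh$grid$notch, "_", mesh$n_vertex, "_",
                paste(res, collapse = "x"))
  if (!is.null(the[[key]])) return(the[[key]])
  ca <- (seq_len(res[1]) - 0.5) / res[1]
  cp <- (seq_len(res[2]) - 0.5) / res[2]
  lut <- matrix(0L, res[1], res[2])
  chunk <- 64L
  for (s in seq(1, res[1], by = chunk)) {
    e <- min(s + chunk - 1L, res[1])
    da <- outer(ca[s:e], mesh$ap, "-")^2
    for (j in seq_len(res[2])) {
      d <- da + matrix((cp[j] - mesh$pd)^2, e - s + 1, mesh$n_vertex,
                       byrow = TRUE)
      lut[s:e, j] <- max.col(-d, ties.method = "first")
    }
  }
  out <- list(lut = lut, res = res)
  the[[key]] <- out
  out
}

#' Spin test for two surface maps
#'
#' Observed Pearson correlation of `map_a` and `map_b` across vertices;
#' the null distribution is built by `n_perm` rigid random shifts of
#' `map_a` in unfolded (AP, PD) space with toroidal wrap-around,
#' resampled by nearest vertex. Two-sided add-one permutation p-value:
#' `p = (1 + #\{|R_null| >= |R_obs|\}) / (n_perm + 1)`.
#'
#' @param map_a,map_b per-vertex numeric vectors on `mesh`.
#' @param mesh a [hipp_template_mesh()] (supplies unfolded coordinates).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return tibble: `r`, `p`, `n_perm`, `n_vertex`.
#' @export
spin_test <- function(map_a, map_b, mesh, n_perm = 2500L, seed = 1L) {
  stopifnot(length(map_a) == mesh$n_vertex,
            length(map_b) == mesh$n_vertex)
  if (is.null(mesh[["ap"]]) || is.null(mesh[["pd"]])) {
    stop("mesh lacks unfolded coordinates", call. = FALSE)
  }
  ok <- is.finite(map_a) & is.finite(map_b)
  r_obs <- cor(map_a[ok], map_b[ok])
  lk <- spin_lookup(mesh)
  set.seed(seed)
  u <- matrix(runif(2 * n_perm), n_perm, 2)
  r_null <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    sa <- (mesh$ap + u[k, 1]) %% 1
    sp <- (mesh$pd + u[k, 2]) %% 1
    ia <- pmin(floor(sa * lk$res[1]) + 1L, lk$res[1])
    ip <- pmin(floor(sp * lk$res[2]) + 1L, lk$res[2])
    perm <- map_a[lk$lut[cbind(ia, ip)]]
    ok_k <- is.finite(perm) & is.finite(map_b)
    r_null[k] <- cor(perm[ok_k], map_b[ok_k])
  }
  p <- (1 + sum(abs(r_null) >= abs(r_obs), na.rm = TRUE)) / (n_perm + 1)
  tibble::tibble(r = r_obs, p = p, n_perm = n_perm, n_vertex = sum(ok))
}

#' Smooth random surface field (for calibration studies)
#'
#' Gaussian random field on the unfolded grid: white noise smoothed by a
#' separable Gaussian kernel, sampled at the mesh vertices.
#'
#' @param mesh a [hipp_template_mesh()].
#' @param fwhm smoothing kernel FWHM in unfolded units (fraction of the
#'   rectangle).
#' @param seed integer seed, or NULL to use the RNG state.
#' @return per-vertex values, unit variance.
#' @export
smooth_random_field <- function(mesh, fwhm = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- c(96L, 48L)
  z <- matrix(rnorm(prod(res)), res[1], res[2])
  sg <- fwhm / 2.355
  ker <- function(n, sigma_cells) {
    half <- max(1L, ceiling(3 * sigma_cells))
    k <- exp(-0.5 * ((-half:half) / sigma_cells)^2)
    k / sum(k)
  }
  ka <- ker(res[1], sg * res[1])
  kp <- ker(res[2], sg * res[2])
  # circular separable convolution
  conv_circ <- function(m, k, dim) {
    half <- (length(k) - 1) / 2
    out <- m * 0
    for (o in -half:half) {
      idx <- ((seq_len(dim(m)[dim]) - 1 + o) %% dim(m)[dim]) + 1
      out <- out + k[o + half + 1] *
        (if (dim == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE])
    }
    out
  }
  z <- conv_circ(conv_circ(z, ka, 1), kp, 2)
  ia <- pmin(floor(mesh$ap * res[1]) + 1L, res[1])
  ip <- pmin(floor(mesh$pd * res[2]) + 1L, res[2])
  v <- z[cbind(ia, ip)]
  (v - mean(v)) / sd(v)
}
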