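# Surface construction from coordinate fields, and volume-to-surface
# sampling.

#' Trilinear sampling of a volume at world points
#'
#' Corners with undefined (NA, off-mask) values are dropped and the
#' remaining corner weights renormalized, so interpolation degrades
#' gracefully at the mask edge; a point with no defined corner is NA.
#'
#' @param vol 3-D array.
#' @param pts `n x 3` world coordinates (mm).
#' @param origin world position of voxel `(1, 1, 1)`.
#' @param voxel_mm isotropic voxel size.
#' @return sampled values (NA where undefined).
#' @export
trilinear_sample <- function(vol, pts, origin, voxel_mm) {
  d <- dim(vol)
  u <- sweep(pts, 2, origin) / voxel_mm + 1 # continuous 1-based index
  i0 <- pmin(pmax(floor(u), 1), matrix(rep(d - 1L, each = nrow(u)), ncol = 3))
  fr <- u - i0
  fr <- pmin(pmax(fr, 0), 1)
  lin <- function(ii) (ii[, 3] - 1) * d[1] * d[2] + (ii[, 2] - 1) * d[1] + ii[, 1]
  acc <- numeric(nrow(u))
  wsum <- numeric(nrow(u))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * fr[, 1] + (1 - dx) * (1 - fr[, 1])) *
      (dy * fr[, 2] + (1 - dy) * (1 - fr[, 2])) *
      (dz * fr[, 3] + (1 - dz) * (1 - fr[, 3]))
    val <- vol[lin(i0 + rep(c(dx, dy, dz), each = nrow(u)))]
    def <- !is.na(val)
    acc[def] <- acc[def] + (w * val)[def]
    wsum[def] <- wsum[def] + w[def]
  }
  out <- acc / wsum
  out[wsum < 1e-9] <- NA_real_
  out
}

# coordinate triple (ap, pd, io) interpolated at world points
sample_coords <- function(coords, pts) {
  cbind(
    trilinear_sample(coords$ap$field, pts, coords$origin, coords$voxel_mm),
    trilinear_sample(coords$pd$field, pts, coords$origin, coords$voxel_mm),
    trilinear_sample(coords$io$field, pts, coords$origin, coords$voxel_mm)
  )
}

#' Place a surface at a laminar (IO) level of a coordinate field
#'
#' Each template vertex `(ap, pd)` is mapped to the world point where
#' the three Laplace coordinates equal `(ap, pd, io_level)`: nearest
#' gray-matter voxel in coordinate space, refined by Gauss-Newton on the
#' trilinearly interpolated fields.
#'
#' @param coords a [solve_coordinates()] result.
#' @param template a [hipp_template_mesh()].
#' @param io_level target inner-outer level (0.5 = midthickness).
#' @param n_iter Gauss-Newton iterations.
#' @return the template with `vertices` (world mm), `io_level`, and
#'   `place_error` (max |coordinate residual| per vertex) filled in.
#' @export
place_level_surface <- function(coords, template, io_level = 0.5,
                                n_iter = 6L) {
  stopifnot(io_level >= 0, io_level <= 1)
  mask_idx <- which(!is.na(coords$io$field))
  iov <- coords$io$field[mask_idx]
  near <- abs(iov - io_level) <= max(0.12, 1.5 / 20)
  if (!any(near)) near <- abs(iov - io_level) <= stats::quantile(abs(iov - io_level), 0.2)
  cand <- mask_idx[near]
  # thin the candidate set to one voxel per (ap, pd) cell: only an
  # initial guess is needed, Gauss-Newton does the refinement
  capv <- coords$ap$field[cand]
  cpdv <- coords$pd$field[cand]
  cell <- paste(round(capv * 120), round(cpdv * 120))
  first <- !duplicated(cell)
  cand <- cand[first]; capv <- capv[first]; cpdv <- cpdv[first]
  pos <- arrayInd(cand, dim(coords$io$field))
  world <- sweep((pos - 1) * coords$voxel_mm, 2, coords$origin, "+")

  V <- template$n_vertex
  target <- cbind(template$ap, template$pd, io_level)
  x <- matrix(NA_real_, V, 3)
  # nearest candidate voxel in (ap, pd) space, chunked
  chunk <- 500L
  for (s in seq(1, V, by = chunk)) {
    e <- min(s + chunk - 1L, V)
    da <- outer(template$ap[s:e], capv, "-")^2
    dp <- outer(template$pd[s:e], cpdv, "-")^2
    best <- max.col(-(da + dp), ties.method = "first")
    x[s:e, ] <- world[best, , drop = FALSE]
  }

  h <- 0.5 * coords$voxel_mm
  x_best <- x
  best_res <- rep(Inf, V)
  for (it in seq_len(n_iter)) {
    f <- sample_coords(coords, x)
    res <- f - target
    rn <- sqrt(rowSums(res^2))
    improved <- is.finite(rn) & rn < best_res
    best_res[improved] <- rn[improved]
    x_best[improved, ] <- x[improved, , drop = FALSE]
    # numerical Jacobian, central differences, vectorized over vertices
    J <- array(NA_real_, c(V, 3, 3)) # [vertex, coord, axis]
    for (ax in 1:3) {
      dx <- matrix(0, V, 3); dx[, ax] <- h
      J[, , ax] <- (sample_coords(coords, x + dx) -
                      sample_coords(coords, x - dx)) / (2 * h)
    }
    # solve 3x3 per vertex (explicit inverse)
    a <- J[, 1, 1]; b <- J[, 1, 2]; cc <- J[, 1, 3]
    dd <- J[, 2, 1]; ee <- J[, 2, 2]; ff <- J[, 2, 3]
    g <- J[, 3, 1]; hh <- J[, 3, 2]; ii <- J[, 3, 3]
    det <- a * (ee * ii - ff * hh) - b * (dd * ii - ff * g) +
      cc * (dd * hh - ee * g)
    det[!is.finite(det) | abs(det) < 1e-12] <- NA
    i11 <- (ee * ii - ff * hh) / det; i12 <- (cc * hh - b * ii) / det
    i13 <- (b * ff - cc * ee) / det
    i21 <- (ff * g - dd * ii) / det; i22 <- (a * ii - cc * g) / det
    i23 <- (cc * dd - a * ff) / det
    i31 <- (dd * hh - ee * g) / det; i32 <- (b * g - a * hh) / det
    i33 <- (a * ee - b * dd) / det
    step <- cbind(
      i11 * res[, 1] + i12 * res[, 2] + i13 * res[, 3],
      i21 * res[, 1] + i22 * res[, 2] + i23 * res[, 3],
      i31 * res[, 1] + i32 * res[, 2] + i33 * res[, 3]
    )
    step[!is.finite(step)] <- 0
    # damp large steps to stay within the interpolable region
    sn <- sqrt(rowSums(step^2))
    cap <- 2 * coords$voxel_mm
    scale <- ifelse(sn > cap, cap / sn, 1)
    x <- x - step * scale
  }
  f <- sample_coords(coords, x)
  rn <- sqrt(rowSums((f - target)^2))
  improved <- is.finite(rn) & rn < best_res
  best_res[improved] <- rn[improved]
  x_best[improved, ] <- x[improved, , drop = FALSE]
  f <- sample_coords(coords, x_best)
  out <- template
  out$vertices <- x_best
  out$io_level <- io_level
  out$place_error <- apply(abs(f - target), 1, max)
  out
}

#' Midthickness surface of a coordinate field
#'
#' @param coords a [solve_coordinates()] result.
#' @param template a [hipp_template_mesh()].
#' @return placed `hipp_mesh` (see [place_level_surface()]).
#' @export
midthickness_surface <- function(coords, template = hipp_template_mesh()) {
  place_level_surface(coords, template, io_level = 0.5)
}

#' Sample a volume onto surface vertices
#'
#' `method = "enclosing"` takes the value of the voxel containing each
#' vertex (half-open voxel boxes `(lo, hi]`, so a vertex exactly on a
#' face belongs to the lower-index voxel); `"trilinear"` interpolates
#' (used for smooth maps such as tissue probabilities).
#'
#' @param vol 3-D array.
#' @param surface a placed `hipp_mesh`.
#' @param origin,voxel_mm volume geometry.
#' @param method `"enclosing"` or `"trilinear"`.
#' @return per-vertex values (NA outside the volume).
#' @export
sample_to_surface <- function(vol, surface, origin, voxel_mm,
                              method = c("enclosing", "trilinear")) {
  method <- match.arg(method)
  stopifnot(!is.null(surface$vertices))
  pts <- surface$vertices
  if (method == "trilinear") {
    return(trilinear_sample(vol, pts, origin, voxel_mm))
  }
  d <- dim(vol)
  # voxel k covers (center - h/2, center + h/2]: a vertex exactly on a
  # face belongs to the lower-index voxel
  ii <- ceiling(sweep(pts, 2, origin) / voxel_mm - 0.5) + 1
  ok <- ii[, 1] >= 1 & ii[, 1] <= d[1] & ii[, 2] >= 1 & ii[, 2] <= d[2] &
    ii[, 3] >= 1 & ii[, 3] <= d[3]
  out <- rep(NA_real_, nrow(pts))
  lin <- (ii[ok, 3] - 1) * d[1] * d[2] + (ii[ok, 2] - 1) * d[1] + ii[ok, 1]
  out[ok] <- vol[lin]
  out
}
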