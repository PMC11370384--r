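# Gradient vector fields of the Laplace coordinates and orientation
# (cosine-similarity) maps.

#' Gradient of a scalar coordinate volume on a mask
#'
#' Central differences where both neighbors are defined, one-sided at
#' mask edges. Vectors are in 1/mm units.
#'
#' @param psi scalar array (NA off-mask), e.g. a [solve_laplace()] field.
#' @param voxel_mm isotropic voxel size.
#' @return list: `g` array `dims x 3`, and `flagged` logical array marking
#'   voxels where any component had no defined neighbor (gradient NA).
#' @export
gradient_field <- function(psi, voxel_mm) {
  d <- dim(psi)
  g <- array(NA_real_, c(d, 3))
  flagged <- array(FALSE, d)
  def <- !is.na(psi)
  shift <- function(a, ax, by) {
    r <- array(NA_real_, d)
    idx_src <- lapply(d, seq_len); idx_dst <- idx_src
    if (by == 1) { idx_dst[[ax]] <- 1:(d[ax] - 1); idx_src[[ax]] <- 2:d[ax] }
    else { idx_dst[[ax]] <- 2:d[ax]; idx_src[[ax]] <- 1:(d[ax] - 1) }
    do.call(`[<-`, c(list(r), idx_dst, list(do.call(`[`, c(list(a), idx_src)))))
  }
  for (ax in 1:3) {
    fwd <- shift(psi, ax, 1)   # value at +1 along ax
    bwd <- shift(psi, ax, -1)  # value at -1 along ax
    has_f <- !is.na(fwd); has_b <- !is.na(bwd)
    comp <- array(NA_real_, d)
    both <- def & has_f & has_b
    comp[both] <- (fwd[both] - bwd[both]) / (2 * voxel_mm)
    fo <- def & has_f & !has_b
    comp[fo] <- (fwd[fo] - psi[fo]) / voxel_mm
    bo <- def & !has_f & has_b
    comp[bo] <- (psi[bo] - bwd[bo]) / voxel_mm
    none <- def & !has_f & !has_b
    flagged <- flagged | fo | bo | none
    g[, , , ax] <- comp
  }
  list(g = g, flagged = flagged)
}

#' Voxel-wise absolute cosine similarity of two vector volumes
#'
#' `|cos(theta)|` between the two vectors at each voxel; absolute value
#' because diffusion peaks are antipodally symmetric, giving the 0-1
#' range (0 orthogonal, 1 parallel or antiparallel). Degenerate
#' (near-zero or undefined) vectors give NA.
#'
#' @param a,b arrays `dims x 3`.
#' @param eps vectors with norm below `eps` count as degenerate.
#' @return array of cosine similarities in `[0, 1]` (NA where undefined).
#' @export
cosine_similarity <- function(a, b, eps = 1e-12) {
  stopifnot(identical(dim(a), dim(b)))
  dot <- a[, , , 1] * b[, , , 1] + a[, , , 2] * b[, , , 2] +
    a[, , , 3] * b[, , , 3]
  na <- sqrt(a[, , , 1]^2 + a[, , , 2]^2 + a[, , , 3]^2)
  nb <- sqrt(b[, , , 1]^2 + b[, , , 2]^2 + b[, , , 3]^2)
  out <- abs(dot) / (na * nb)
  out[!is.finite(out) | na < eps | nb < eps] <- NA_real_
  pmin(out, 1)
}

#' Orientation maps from coordinate gradients and a peak orientation field
#'
#' Long-axis, tangential and radial cosine-similarity channels:
#' `|cos|` of the angle between the first fODF peak (or any orientation
#' field) and the gradients of the AP, PD and IO Laplace coordinates.
#'
#' @param coords a [solve_coordinates()] result.
#' @param peaks array `dims x 3` of peak orientations.
#' @return list of class `orientation_maps` with channels `long_axis`,
#'   `tangential`, `radial`.
#' @export
orientation_maps <- function(coords, peaks) {
  gA <- gradient_field(coords$ap$field, coords$voxel_mm)$g
  gP <- gradient_field(coords$pd$field, coords$voxel_mm)$g
  gI <- gradient_field(coords$io$field, coords$voxel_mm)$g
  structure(list(
    long_axis = cosine_similarity(gA, peaks),
    tangential = cosine_similarity(gP, peaks),
    radial = cosine_similarity(gI, peaks)
  ), class = "orientation_maps")
}
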