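# Standard midthickness surface template on the unfolded rectangle.
#
# A quasi-regular n_ap x n_pd grid in unfolded (AP, PD) space, with a
# small triangular notch of vertices removed at two opposite corners
# (tapering, as the anterior uncus and posterior tail do); the standard
# template (107 x 68 grid, 7-vertex notches) has exactly 7262 vertices.

SUBFIELDS <- c("subiculum", "CA1", "CA2", "CA3", "DG/CA4")
# proximal-distal band proportions (subiculum -> DG/CA4)
SUBFIELD_PROP <- c(0.22, 0.30, 0.10, 0.14, 0.24)
AP_BINS <- c("uncus", "anterior_lateral", "body_anterior",
             "body_posterior", "tail")
AP_BIN_CUTS <- c(0.15, 0.35, 0.60, 0.80)

#' Standard unfolded hippocampal surface template
#'
#' @param n_ap,n_pd grid size along the anterior-posterior and
#'   proximal-distal axes.
#' @param notch number of vertices removed at each of the two tapered
#'   corners (anterior-proximal and posterior-distal).
#' @param unfold_size_mm nominal physical size (AP, PD) of the unfolded
#'   rectangle, used as the flat reference for gyrification.
#' @return object of class `hipp_mesh`: `n_vertex`, unfolded coordinates
#'   `ap`/`pd` in `[0, 1]`, triangle index matrix `faces`, `subfield` and
#'   `ap_bin` factors, optional world `vertices` (NULL until placed).
#' @export
hipp_template_mesh <- function(n_ap = 107, n_pd = 68, notch = 7,
                               unfold_size_mm = c(33, 15)) {
  stopifnot(n_ap >= 2, n_pd >= 2, notch >= 0)
  grid <- expand.grid(i = seq_len(n_ap), j = seq_len(n_pd))
  keep <- rep(TRUE, nrow(grid))
  if (notch > 0) {
    lev1 <- (grid$i - 1) + (grid$j - 1)            # corner (1, 1)
    lev2 <- (n_ap - grid$i) + (n_pd - grid$j)      # corner (n_ap, n_pd)
    keep <- keep & !notch_member(lev1, grid$i, notch)
    keep <- keep & !notch_member(lev2, grid$i, notch)
  }
  old_id <- which(keep)
  new_id <- integer(nrow(grid))
  new_id[old_id] <- seq_along(old_id)

  # faces on the full grid, filtered to surviving vertices
  ci <- rep(seq_len(n_ap - 1), n_pd - 1)
  cj <- rep(seq_len(n_pd - 1), each = n_ap - 1)
  v00 <- (cj - 1) * n_ap + ci
  v10 <- v00 + 1
  v01 <- v00 + n_ap
  v11 <- v01 + 1
  tri <- rbind(cbind(v00, v10, v01), cbind(v10, v11, v01))
  ok <- keep[tri[, 1]] & keep[tri[, 2]] & keep[tri[, 3]]
  faces <- matrix(new_id[tri[ok, ]], ncol = 3)

  ap <- (grid$i[keep] - 1) / (n_ap - 1)
  pd <- (grid$j[keep] - 1) / (n_pd - 1)
  structure(list(
    n_vertex = length(old_id),
    ap = ap, pd = pd, faces = faces,
    subfield = subfield_of_pd(pd),
    ap_bin = ap_bin_of_ap(ap),
    unfold_size_mm = unfold_size_mm,
    grid = list(n_ap = n_ap, n_pd = n_pd, notch = notch),
    vertices = NULL
  ), class = "hipp_mesh")
}

# first `notch` vertices of a corner in anti-diagonal order
notch_member <- function(level, i, notch) {
  ord <- order(level, i)
  rank <- integer(length(level))
  rank[ord] <- seq_along(ord)
  rank <= notch
}

#' Subfield label from the proximal-distal coordinate
#' @param pd proximal-distal coordinate in `[0, 1]`.
#' @return factor over subiculum, CA1, CA2, CA3, DG/CA4.
#' @export
subfield_of_pd <- function(pd) {
  cuts <- cumsum(SUBFIELD_PROP)[1:4]
  factor(SUBFIELDS[findInterval(pd, cuts) + 1], levels = SUBFIELDS)
}

#' Long-axis bin from the anterior-posterior coordinate
#' @param ap anterior-posterior coordinate in `[0, 1]`.
#' @return factor over the 5 long-axis bins.
#' @export
ap_bin_of_ap <- function(ap) {
  factor(AP_BINS[findInterval(ap, AP_BIN_CUTS) + 1], levels = AP_BINS)
}

#' Per-vertex area of a triangulated surface
#'
#' One third of the summed areas of incident triangles.
#'
#' @param vertices `n x 2` or `n x 3` coordinate matrix.
#' @param faces triangle index matrix.
#' @return numeric vector of vertex areas.
#' @export
vertex_areas <- function(vertices, faces) {
  v <- as.matrix(vertices)
  if (ncol(v) == 2) v <- cbind(v, 0)
  a <- v[faces[, 2], ] - v[faces[, 1], ]
  b <- v[faces[, 3], ] - v[faces[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  tarea <- 0.5 * sqrt(rowSums(cr^2))
  out <- numeric(nrow(v))
  for (k in 1:3) {
    acc <- tapply(tarea, faces[, k], sum)
    ix <- as.integer(names(acc))
    out[ix] <- out[ix] + acc / 3
  }
  out
}
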