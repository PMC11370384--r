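# Laplace coordinate fields on a voxel mask.
#
# Discretization: 7-point stencil on the 6-connected mask. Dirichlet
# conditions are anchored on the *faces* between the mask and the
# source/sink label voxels (ghost value 2c - v), so the 0 and 1 level
# sets sit on the mask boundary faces rather than at label voxel centers.
# Mask voxels facing background get reflecting (Neumann) ghosts. Solved
# with red-black successive over-relaxation.

#' Solve Laplace's equation on a labelled voxel domain
#'
#' @param labels integer label array.
#' @param mask_label label of the domain (gray matter).
#' @param source_label,sink_label boundary labels fixed to 0 and 1.
#' @param tol convergence: maximum absolute update below `tol`.
#' @param max_iter iteration cap.
#' @param omega SOR relaxation factor.
#' @return list of class `laplace_field`: `field` (array, NA off-mask),
#'   `iterations`, `converged`, `max_update`.
#' @export
solve_laplace <- function(labels, mask_label = 1L, source_label, sink_label,
                          tol = 1e-6, max_iter = 1e5, omega = 1.9) {
  d <- dim(labels)
  mask <- labels == mask_label
  n <- sum(mask)
  if (n == 0) stop("empty mask", call. = FALSE)
  idx <- which(mask)
  pos <- arrayInd(idx, d)
  vox_id <- array(0L, d)
  vox_id[idx] <- seq_len(n)

  # neighbor bookkeeping per mask voxel: interior neighbor ids, and counts
  # of source / sink / background faces
  nb_id <- matrix(0L, n, 6)
  n_src <- integer(n); n_snk <- integer(n); n_bg <- integer(n)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (k in 1:6) {
    p <- sweep(pos, 2, offs[k, ], "+")
    inside <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
      p[, 3] >= 1 & p[, 3] <= d[3]
    lin <- rep(NA_integer_, n)
    lin[inside] <- (p[inside, 3] - 1L) * d[1] * d[2] +
      (p[inside, 2] - 1L) * d[1] + p[inside, 1]
    lab <- rep(LBL_BG, n)
    lab[inside] <- labels[lin[inside]]
    is_mask_nb <- inside & lab == mask_label
    nb_id[is_mask_nb, k] <- vox_id[lin[is_mask_nb]]
    n_src <- n_src + (lab == source_label)
    n_snk <- n_snk + (lab == sink_label)
    n_bg <- n_bg + (!is_mask_nb & lab != source_label & lab != sink_label)
  }

  # connectivity check: every connected component must touch a boundary
  comp <- mask_components(nb_id)
  touches <- tapply(n_src + n_snk > 0, comp, any)
  if (!all(touches)) {
    bad <- names(touches)[!touches][1]
    stop("mask component ", bad, " touches neither source nor sink",
         call. = FALSE)
  }

  # v_i * (6 - n_bg + n_src + n_snk) = sum(interior v_j) + 2 * n_snk
  denom <- 6 - n_bg + n_src + n_snk
  const <- 2 * n_snk
  v <- rep(0.5, n)
  red <- (rowSums(pos) %% 2) == 0
  groups <- list(which(red), which(!red))
  max_upd <- Inf
  it <- 0L
  while (it < max_iter && max_upd > tol) {
    it <- it + 1L
    max_upd <- 0
    for (g in groups) {
      s <- numeric(length(g))
      for (k in 1:6) {
        nb <- nb_id[g, k]
        has <- nb > 0L
        s[has] <- s[has] + v[nb[has]]
      }
      gs <- (s + const[g]) / denom[g]
      upd <- omega * (gs - v[g])
      v[g] <- v[g] + upd
      max_upd <- max(max_upd, max(abs(upd)))
    }
  }
  field <- array(NA_real_, d)
  field[idx] <- v
  structure(list(field = field, iterations = it,
                 converged = max_upd <= tol, max_update = max_upd),
            class = "laplace_field")
}

# connected-component labels from the interior-neighbor table
mask_components <- function(nb_id) {
  n <- nrow(nb_id)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nb <- unique(as.vector(nb_id[frontier, ]))
      nb <- nb[nb > 0L]
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' Solve all three hippocampal coordinate fields of a phantom
#'
#' @param phantom a [make_slab_phantom()] (or any object with a `labels`
#'   array using the same label scheme).
#' @param tol,max_iter,omega passed to [solve_laplace()].
#' @return list of class `coordinate_field` with `ap`, `pd`, `io`
#'   (`laplace_field`s), plus `mask`, `voxel_mm`, `origin`.
#' @export
solve_coordinates <- function(phantom, tol = 1e-6, max_iter = 1e5,
                              omega = 1.9) {
  ap <- solve_laplace(phantom$labels, LBL_GM, LBL_AP_SRC, LBL_AP_SINK,
                      tol = tol, max_iter = max_iter, omega = omega)
  pd <- solve_laplace(phantom$labels, LBL_GM, LBL_PD_SRC, LBL_PD_SINK,
                      tol = tol, max_iter = max_iter, omega = omega)
  io <- solve_laplace(phantom$labels, LBL_GM, LBL_IO_SRC, LBL_IO_SINK,
                      tol = tol, max_iter = max_iter, omega = omega)
  structure(list(ap = ap, pd = pd, io = io,
                 mask = phantom$labels == LBL_GM,
                 voxel_mm = phantom$voxel_mm, origin = phantom$origin),
            class = "coordinate_field")
}

#' Distance (in voxels) to the mask boundary
#'
#' Chebyshev-style erosion count used to exclude the boundary rim when
#' comparing solved fields with analytic coordinates.
#'
#' @param mask logical array.
#' @return integer array; 1 on the outermost mask layer.
#' @export
mask_rim_depth <- function(mask) {
  depth <- array(0L, dim(mask))
  cur <- mask
  k <- 0L
  while (any(cur)) {
    k <- k + 1L
    depth[cur] <- k
    inner <- cur
    # erode: keep voxels whose 6 neighbors are all inside `cur`
    d <- dim(cur)
    keep <- cur
    for (ax in 1:3) for (by in c(1L, -1L)) {
      shifted <- array(FALSE, d)
      idx_src <- lapply(d, seq_len); idx_dst <- idx_src
      if (by == 1L) { idx_dst[[ax]] <- 1:(d[ax] - 1); idx_src[[ax]] <- 2:d[ax] }
      else { idx_dst[[ax]] <- 2:d[ax]; idx_src[[ax]] <- 1:(d[ax] - 1) }
      shifted <- do.call(`[<-`, c(list(shifted), idx_dst,
                                  list(do.call(`[`, c(list(cur), idx_src)))))
      keep <- keep & shifted
    }
    if (identical(keep, cur)) break
    cur <- keep
  }
  depth
}
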