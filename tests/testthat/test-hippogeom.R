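# Laplace coordinates, gradients, surfaces, sampling, parcellation,
# macrostructure.

test_that("Laplace solver reproduces harmonic oracles", {
  slab <- fx_slab()
  cs <- fx_slab_coords()
  # straight slab: all three fields affine -> exact to solver tolerance
  for (w in c("ap", "pd", "io")) {
    expect_true(cs[[w]]$converged)
    err <- abs(cs[[w]]$field - slab[[w]])
    expect_lt(max(err, na.rm = TRUE), 1e-4)
  }
  # curved slab: log-radial depth solution (concentric-annulus oracle)
  # within the documented 0.02 band off the 2-voxel rim, 1% off a
  # 4-voxel rim
  ph <- fx_phantom()
  co <- fx_coords()
  depth <- mask_rim_depth(ph$labels == 1)
  expect_lt(max(abs(co$io$field - ph$io)[depth > 2]), 0.02)
  expect_lt(max(abs(co$io$field - ph$io)[depth > 4]), 0.01)
  # maximum principle: interior strictly inside (0, 1)
  gm <- ph$labels == 1
  for (w in c("ap", "pd", "io")) {
    expect_within(co[[w]]$field[gm], 1e-12, 1 - 1e-12)
  }
})

test_that("disconnected mask components are reported", {
  lab <- array(0L, c(12, 5, 5))
  lab[2:4, 2:4, 2:4] <- 1L
  lab[9:11, 2:4, 2:4] <- 1L # island touching no boundary
  lab[1, 2:4, 2:4] <- 2L
  lab[5, 2:4, 2:4] <- 3L
  expect_error(solve_laplace(lab, 1L, 2L, 3L), "component")
})

test_that("gradient fields match analytic directions and flag edges", {
  slab <- fx_slab()
  cs <- fx_slab_coords()
  g <- gradient_field(cs$io$field, slab$voxel_mm)
  gm <- slab$labels == 1
  inner <- mask_rim_depth(gm) > 1
  # affine field: gradient along x with magnitude 1/thickness
  expect_equal(max(abs(g$g[, , , 1][inner] - 1 / 4)), 0, tolerance = 1e-4)
  expect_lt(max(abs(g$g[, , , 2][inner])), 1e-4)
  # constant field -> zero vectors flagged nowhere but magnitude 0
  cvol <- slab$io; cvol[gm] <- 0.7
  g0 <- gradient_field(cvol, slab$voxel_mm)
  expect_lt(max(abs(g0$g[, , , 1][inner])), 1e-12)
  # curved phantom: numerical gradient within 2 degrees of analytic,
  # away from edges (5-voxel margin: the difference stencil widens the
  # boundary influence zone)
  ph <- fx_phantom()
  co <- fx_coords()
  deep <- mask_rim_depth(ph$labels == 1) > 5
  for (w in c("ap", "io")) {
    gn <- gradient_field(co[[w]]$field, ph$voxel_mm)$g
    ga <- phantom_analytic_gradient(ph, w)
    ang <- acos(pmin(cosine_similarity(gn, ga)[deep], 1)) * 180 / pi
    expect_lt(max(ang, na.rm = TRUE), 2)
  }
})

test_that("cosine similarity hits the parallel/orthogonal anchors", {
  d <- c(2, 2, 2)
  a <- array(0, c(d, 3)); b <- array(0, c(d, 3))
  a[, , , 1] <- 1
  b[, , , 1] <- 3 # parallel, different magnitude
  expect_equal(as.vector(cosine_similarity(a, b)), rep(1, 8))
  b2 <- array(0, c(d, 3)); b2[, , , 2] <- 1 # orthogonal
  expect_equal(as.vector(cosine_similarity(a, b2)), rep(0, 8))
  b3 <- array(0, c(d, 3)); b3[, , , 1] <- -1 # antiparallel
  expect_equal(as.vector(cosine_similarity(a, b3)), rep(1, 8))
  # degenerate vector -> NA
  b4 <- array(0, c(d, 3))
  expect_true(all(is.na(cosine_similarity(a, b4))))
})

test_that("orientation maps separate the hippocampal axes on the phantom", {
  ph <- fx_phantom()
  co <- fx_coords()
  om <- orientation_maps(co, phantom_analytic_gradient(ph, "ap"))
  off <- mask_rim_depth(ph$labels == 1) > 2
  expect_gte(min(om$long_axis[off], na.rm = TRUE), 0.98)
  expect_lte(max(om$radial[off], na.rm = TRUE), 0.1)
  for (ch in c("long_axis", "tangential", "radial")) {
    expect_within(om[[ch]], 0, 1)
  }
})

test_that("template mesh has the standard vertex count and full labels", {
  tm <- hipp_template_mesh()
  expect_equal(tm$n_vertex, 7262)
  expect_false(anyNA(tm$subfield))
  expect_false(anyNA(tm$ap_bin))
  expect_equal(nlevels(tm$subfield), 5)
  expect_equal(nlevels(tm$ap_bin), 5)
  expect_within(tm$ap, 0, 1)
  expect_within(tm$pd, 0, 1)
  # faces index surviving vertices only
  expect_within(tm$faces, 1, tm$n_vertex)
})

test_that("midthickness placement lands on the IO = 0.5 level set", {
  cs <- fx_slab_coords()
  tm <- hipp_template_mesh(n_ap = 21, n_pd = 11, notch = 0)
  mid <- midthickness_surface(cs, tm)
  expect_equal(mid$n_vertex, nrow(mid$vertices))
  # straight slab: geometric mid-plane x = 0 within half a voxel
  expect_lte(max(abs(mid$vertices[, 1])), 0.5 * 0.5 + 1e-9)
  # curved slab: vertex IO values within [0.45, 0.55] at resolved
  # vertices (edge vertices whose placement residual exceeds 0.05 are
  # flagged and excluded, per the placement contract)
  co <- fx_coords()
  mid_c <- midthickness_surface(co, fx_small_mesh())
  io_at <- sample_coords(co, mid_c$vertices)[, 3]
  resolved <- mid_c$place_error < 0.05
  expect_gt(mean(resolved, na.rm = TRUE), 0.95)
  expect_within(io_at[resolved], 0.45, 0.55)
})

test_that("enclosing sampling takes the containing voxel's value", {
  slab <- fx_slab()
  cs <- fx_slab_coords()
  tm <- hipp_template_mesh(n_ap = 11, n_pd = 7, notch = 0)
  mid <- midthickness_surface(cs, tm)
  cvol <- slab$io; cvol[!is.na(cvol)] <- 3.5
  expect_equal(unique(na.omit(
    sample_to_surface(cvol, mid, slab$origin, slab$voxel_mm))), 3.5)
  # linear ramp: enclosing returns the exact containing-voxel value
  d <- slab$dims
  ramp <- array(rep(seq_len(d[1]), d[2] * d[3]), d)
  got <- sample_to_surface(ramp, mid, slab$origin, slab$voxel_mm)
  # direct voxel lookup oracle: voxel k covers (c_k - h/2, c_k + h/2],
  # i.e. a face point belongs to the lower-index voxel
  ii <- ceiling(sweep(mid$vertices, 2, slab$origin) / slab$voxel_mm - 0.5) + 1
  expect_equal(got, ramp[ii])
  # face tie-break: vertex exactly on a voxel face goes to the lower-index
  # voxel (half-open boxes)
  surf <- mid
  surf$vertices <- matrix(slab$origin + c(0.5, 0, 0) * slab$voxel_mm, 1)
  expect_equal(sample_to_surface(ramp, surf, slab$origin, slab$voxel_mm), 1)
})

test_that("parcel averages are exact and order-invariant", {
  lab <- factor(c("a", "a", "b", "b", "b", "c", "c", "c", "c", "c"))
  v <- c(1, 3, 2, 4, 6, 10, 10, 10, 5, 5)
  pa <- parcel_average(v, lab)
  expect_equal(pa$mean, c(2, 4, 8)) # hand-computed
  # vertex order invariance
  o <- c(7, 2, 9, 1, 5, 3, 10, 8, 4, 6)
  pa2 <- parcel_average(v[o], lab[o])
  expect_equal(pa2$mean, pa$mean)
  # indicator map: its parcel mean 1, others 0
  ind <- as.numeric(lab == "b")
  expect_equal(parcel_average(ind, lab)$mean, c(0, 1, 0))
  # constant surface
  expect_equal(parcel_average(rep(7, 10), lab)$mean, rep(7, 3))
  # missing values excluded; empty parcel warns
  v2 <- v; v2[lab == "a"] <- NA
  expect_warning(pa3 <- parcel_average(v2, lab), "empty parcel")
  expect_true(is.na(pa3$mean[1]))
})

test_that("hemisphere averaging is a plain mean and relabel-invariant", {
  d <- tibble::tibble(
    subject_id = rep(c("s1", "s2"), each = 2),
    hemisphere = rep(c("L", "R"), 2),
    age = rep(c(9, 15), each = 2),
    value = c(1, 3, 10, 20)
  )
  h <- average_hemispheres(d)
  expect_equal(sort(h$value), c(2, 15))
  d2 <- d; d2$hemisphere <- rev(d$hemisphere)
  expect_equal(dplyr::arrange(average_hemispheres(d2), subject_id)$value,
               dplyr::arrange(h, subject_id)$value)
})

test_that("macrostructure metrics match slab geometry and scaling laws", {
  slab <- fx_slab()
  cs <- fx_slab_coords()
  tm <- hipp_template_mesh(n_ap = 21, n_pd = 11, notch = 0,
                           unfold_size_mm = c(20, 10))
  mac <- macrostructure(cs, tm)
  # thickness equals the slab thickness within half a voxel
  expect_lt(abs(median(mac$thickness_mm, na.rm = TRUE) - 4), 0.25)
  # subfield volumes sum to the exact voxel-count volume
  expect_equal(sum(mac$volume$volume_mm3), 20 * 10 * 4)
  # flat slab with matching unfolded size: gyrification ~ 1 away from
  # the tapered mesh edges
  expect_equal(median(mac$gyrification, na.rm = TRUE), 1, tolerance = 0.05)
  # scaling law on the mesh quantities: scaling vertices by s scales
  # vertex areas by s^2 and the inner/outer pair distance by s
  a1 <- vertex_areas(mac$midthickness$vertices, mac$midthickness$faces)
  a2 <- vertex_areas(mac$midthickness$vertices * 2, mac$midthickness$faces)
  expect_equal(a2, 4 * a1, tolerance = 1e-12)
})
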