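# Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

fx_protocol <- function() memo("protocol", function() make_protocol(seed = 101L))

fx_phantom <- function() memo("phantom", function() make_slab_phantom())

fx_coords <- function() memo("coords", function() solve_coordinates(fx_phantom()))

# coarse straight slab (exact affine oracle): 4 mm thick, 0.5 mm voxels
fx_slab <- function() memo("slab", function()
  make_slab_phantom(voxel_mm = 0.5, length_mm = 20, width_mm = 10,
                    thickness_mm = 4, bend_radius_mm = Inf))

fx_slab_coords <- function() memo("slab_coords", function()
  solve_coordinates(fx_slab()))

fx_small_mesh <- function() memo("small_mesh", function()
  hipp_template_mesh(n_ap = 25, n_pd = 12, notch = 0))

expect_within <- function(x, lo, hi) {
  expect_true(all(x >= lo & x <= hi, na.rm = TRUE))
}

# shell index per protocol volume (for building per-shell-constant signals)
protocol_shell_index <- function(proto) {
  st <- shell_table(proto)
  idx <- integer(nrow(proto))
  for (k in seq_len(nrow(st))) idx[st$volumes[[k]]] <- k
  idx
}
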