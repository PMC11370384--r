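# NIfTI and plain-text interchange.

#' Write a 3-D array (or slab-phantom labels) as NIfTI
#'
#' @param vol numeric/integer 3-D array.
#' @param path output `.nii`/`.nii.gz` path.
#' @param voxel_mm isotropic voxel size.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_mm = 1) {
  img <- RNifti::asNifti(vol, reference = NULL)
  RNifti::pixdim(img) <- rep(voxel_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param path NIfTI file path.
#' @return array with attribute `voxel_mm`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_mm") <- RNifti::pixdim(img)[1]
  out
}

#' Write per-vertex metric data (long-format CSV twin of a metric file)
#'
#' Columns `vertex`, `ap`, `pd`, `subfield`, `ap_bin`, then one column
#' per metric channel.
#'
#' @param mesh a [hipp_template_mesh()].
#' @param metrics named list/tibble of per-vertex vectors.
#' @param path CSV path.
#' @export
write_surface_metrics <- function(mesh, metrics, path) {
  df <- tibble::tibble(vertex = seq_len(mesh$n_vertex), ap = mesh$ap,
                       pd = mesh$pd,
                       subfield = as.character(mesh$subfield),
                       ap_bin = as.character(mesh$ap_bin))
  for (nm in names(metrics)) df[[nm]] <- metrics[[nm]]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
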