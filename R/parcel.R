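# Parcel averaging and macrostructural metrics.

#' Average per-vertex values within parcels
#'
#' Unweighted mean over non-missing vertices per parcel.
#'
#' @param values per-vertex numeric vector, or a matrix with one row per
#'   observation (e.g. subject-hemisphere) and one column per vertex.
#' @param labels per-vertex factor (subfield or long-axis bin).
#' @return tibble with `parcel` and `mean` (vector input), or a tibble
#'   with one row per observation x parcel (`row`, `parcel`, `mean`).
#' @export
parcel_average <- function(values, labels) {
  labels <- as.factor(labels)
  if (is.matrix(values)) {
    stopifnot(ncol(values) == length(labels))
    out <- purrr::map_dfr(levels(labels), function(lv) {
      cols <- which(labels == lv)
      tibble::tibble(
        row = seq_len(nrow(values)), parcel = lv,
        mean = rowMeans(values[, cols, drop = FALSE], na.rm = TRUE)
      )
    })
    out$mean[is.nan(out$mean)] <- NA_real_
    out$parcel <- factor(out$parcel, levels = levels(labels))
    return(dplyr::arrange(out, .data$row, .data$parcel))
  }
  stopifnot(length(values) == length(labels))
  m <- tapply(values, labels, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  })
  if (anyNA(m)) warning("empty parcel(s): ", paste(names(m)[is.na(m)], collapse = ", "))
  tibble::tibble(parcel = factor(names(m), levels = levels(labels)),
                 mean = as.numeric(m))
}

#' Average hemispheres within subjects
#'
#' @param data long tibble with at least `subject_id`, `hemisphere` and
#'   value columns.
#' @param value name of the value column.
#' @return tibble with hemispheres averaged out; all columns other than
#'   `hemisphere` and the value column act as grouping keys.
#' @export
average_hemispheres <- function(data, value = "value") {
  grp <- setdiff(names(data), c("hemisphere", value))
  dplyr::summarise(dplyr::group_by(data, dplyr::across(dplyr::all_of(grp))),
                   "{value}" := mean(.data[[value]], na.rm = TRUE),
                   .groups = "drop")
}

#' Macrostructural metrics of a coordinate field + surface
#'
#' Simplified, monotone definitions suited to testing: per-subfield
#' volume is voxel count times voxel volume (subfield assigned from the
#' PD coordinate); thickness is the Euclidean distance between paired
#' inner and outer surface vertices, rescaled for the laminar inset; and
#' gyrification is the ratio of native to unfolded vertex area.
#'
#' @param coords a [solve_coordinates()] result.
#' @param template a [hipp_template_mesh()].
#' @param inset laminar inset for the inner/outer pair in IO units;
#'   `NULL` (default) picks one voxel's IO increment from the field
#'   gradient.
#' @return list of class `macrostructure`: `volume` tibble
#'   (per subfield, mm^3), per-vertex `thickness_mm`, per-vertex
#'   `gyrification`, and the placed `midthickness` surface.
#' @export
macrostructure <- function(coords, template = hipp_template_mesh(),
                           inset = NULL) {
  # subfield volume from the PD coordinate of mask voxels
  pdv <- coords$pd$field[!is.na(coords$pd$field)]
  sf <- subfield_of_pd(pdv)
  vol <- tibble::tibble(
    subfield = factor(levels(sf), levels = levels(sf)),
    volume_mm3 = as.numeric(table(sf)) * coords$voxel_mm^3
  )

  mid <- place_level_surface(coords, template, 0.5)
  if (is.null(inset)) {
    gI <- gradient_field(coords$io$field, coords$voxel_mm)$g
    gmag <- sqrt(gI[, , , 1]^2 + gI[, , , 2]^2 + gI[, , , 3]^2)
    step_io <- median(gmag, na.rm = TRUE) * coords$voxel_mm
    inset <- min(max(step_io, 0.02), 0.3)
  }
  inner <- place_level_surface(coords, template, inset)
  outer <- place_level_surface(coords, template, 1 - inset)
  th <- sqrt(rowSums((outer$vertices - inner$vertices)^2)) / (1 - 2 * inset)
  bad <- inner$place_error > 0.05 | outer$place_error > 0.05
  th[bad] <- NA_real_

  native_area <- vertex_areas(mid$vertices, mid$faces)
  unf <- cbind(mid$ap * template$unfold_size_mm[1],
               mid$pd * template$unfold_size_mm[2])
  unfold_area <- vertex_areas(unf, mid$faces)
  gyr <- native_area / unfold_area

  structure(list(volume = vol, thickness_mm = th, gyrification = gyr,
                 midthickness = mid, inset = inset),
            class = "macrostructure")
}
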