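# broom-style tidiers for the package's result objects.

#' @method tidy sandi_fit
#' @export
tidy.sandi_fit <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$location <- seq_len(nrow(out))
  tidyr::pivot_longer(
    out[, c("location", "f_ec", "f_in", "r_s", "D_in", "D_ec",
            "fneurite", "fsoma", "fextracellular")],
    -"location", names_to = "parameter", values_to = "estimate")
}

#' @method glance sandi_fit
#' @export
glance.sandi_fit <- function(x, ...) {
  tibble::tibble(
    n_locations = nrow(x),
    n_converged = sum(x$converged, na.rm = TRUE),
    n_flagged = sum(x$flagged),
    bounds_hit_fraction = mean(x$bounds_hit, na.rm = TRUE),
    median_objective = median(x$objective, na.rm = TRUE)
  )
}

#' @method tidy noddi_fit
#' @export
tidy.noddi_fit <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$location <- seq_len(nrow(out))
  tidyr::pivot_longer(out[, c("location", "f_iso", "f_in", "kappa", "odi")],
                      -"location", names_to = "parameter",
                      values_to = "estimate")
}

#' @method glance noddi_fit
#' @export
glance.noddi_fit <- function(x, ...) {
  tibble::tibble(
    n_locations = nrow(x),
    n_converged = sum(x$converged, na.rm = TRUE),
    n_flagged = sum(x$flagged),
    median_objective = median(x$objective, na.rm = TRUE)
  )
}

#' @method tidy dti_fit
#' @export
tidy.dti_fit <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$location <- seq_len(nrow(out))
  tidyr::pivot_longer(out[, c("location", "fa", "md", "l1", "l2", "l3")],
                      -"location", names_to = "parameter",
                      values_to = "estimate")
}

#' @method glance dti_fit
#' @export
glance.dti_fit <- function(x, ...) {
  tibble::tibble(
    n_locations = nrow(x),
    n_flagged = sum(x$flagged),
    n_volumes = attr(x, "n_volumes"),
    max_b = attr(x, "max_b")
  )
}

#' @method tidy contrast_map
#' @export
tidy.contrast_map <- function(x, ...) tibble::as_tibble(x)

#' @method glance contrast_map
#' @export
glance.contrast_map <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n"), df = attr(x, "df"),
    n_vertex = nrow(x), n_masked = sum(!is.finite(x$t_age)),
    mean_abs_t = mean(abs(x$t_age), na.rm = TRUE)
  )
}
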