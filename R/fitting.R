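# Shared fitting utilities: shell grouping and spherical (powder) means.

#' Per-shell spherical mean signals, b0-normalized
#'
#' Averages the signal across gradient directions within each shell and
#' normalizes by the mean b = 0 signal. Locations with a non-positive
#' b = 0 mean are flagged invalid (all NA).
#'
#' @param signals matrix locations x volumes (or a vector for one
#'   location).
#' @param shells a [shell_table()] (or a protocol, converted internally).
#' @return list: `sphmean` matrix locations x shells (b = 0 column is 1),
#'   `b` shell b-values, `valid` logical per location.
#' @export
spherical_mean <- function(signals, shells) {
  if (inherits(shells, "dmri_protocol")) shells <- shell_table(shells)
  if (is.vector(signals)) signals <- matrix(signals, 1)
  if (!any(shells$b == 0)) stop("need at least one b = 0 volume", call. = FALSE)
  M <- vapply(seq_len(nrow(shells)), function(k) {
    rowMeans(signals[, shells$volumes[[k]], drop = FALSE])
  }, numeric(nrow(signals)))
  M <- matrix(M, nrow(signals))
  b0 <- M[, which(shells$b == 0)[1]]
  valid <- is.finite(b0) & b0 > 0
  out <- M / b0
  out[!valid, ] <- NA_real_
  list(sphmean = out, b = shells$b, valid = valid)
}
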