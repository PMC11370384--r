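# Multi-shell acquisition protocol: b-values, unit gradient directions and
# pulse timings. The default reproduces a 6-shell Connectom-style protocol
# (b = 0, 0.5, 1.2, 2.4, 4.0, 6.0 ms/um^2 with 14/30/30/60/60/60 volumes).

#' Default 6-shell specification
#'
#' @return list of `(b, n)` pairs, b in ms/um^2.
#' @export
default_shell_spec <- function() {
  list(
    list(b = 0,   n = 14),
    list(b = 0.5, n = 30),
    list(b = 1.2, n = 30),
    list(b = 2.4, n = 60),
    list(b = 4.0, n = 60),
    list(b = 6.0, n = 60)
  )
}

#' Build a multi-shell diffusion acquisition protocol
#'
#' Directions are spread per shell by electrostatic repulsion of antipodal
#' point pairs on the unit sphere, starting from a seeded random
#' configuration. b = 0 "shells" get the +z placeholder direction.
#'
#' @param shell_spec list of `list(b =, n =)` entries; default
#'   [default_shell_spec()].
#' @param delta gradient pulse duration, ms.
#' @param Delta pulse separation, ms. Must exceed `delta`.
#' @param seed integer seed for the direction initialization.
#' @return tibble of class `dmri_protocol` with one row per volume
#'   (columns `volume`, `b`, `gx`, `gy`, `gz`, `shell`) and attributes
#'   `delta`, `Delta`.
#' @export
make_protocol <- function(shell_spec = default_shell_spec(),
                          delta = 7, Delta = 24, seed = 1L) {
  bvals <- vapply(shell_spec, function(s) s$b, numeric(1))
  ns <- vapply(shell_spec, function(s) s$n, numeric(1))
  if (any(bvals < 0)) stop("b-values must be >= 0", call. = FALSE)
  if (!(Delta > delta && delta > 0)) {
    stop("pulse timings must satisfy Delta > delta > 0", call. = FALSE)
  }
  if (any(ns < 1)) stop("each shell needs at least one volume", call. = FALSE)

  rows <- vector("list", length(shell_spec))
  seeds <- child_seeds(seed, length(shell_spec))
  for (k in seq_along(shell_spec)) {
    n <- as.integer(ns[k])
    if (bvals[k] == 0) {
      dirs <- matrix(rep(c(0, 0, 1), each = n), n, 3)
    } else {
      dirs <- repulsion_directions(n, seed = seeds[k])
    }
    rows[[k]] <- tibble::tibble(
      b = bvals[k], gx = dirs[, 1], gy = dirs[, 2], gz = dirs[, 3],
      shell = k - 1L
    )
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, volume = dplyr::row_number(), .before = 1)
  attr(out, "delta") <- delta
  attr(out, "Delta") <- Delta
  class(out) <- c("dmri_protocol", class(out))
  out
}

#' Electrostatic-repulsion direction set
#'
#' Minimizes the Coulomb energy of antipodally symmetric points by
#' projected gradient descent on the sphere.
#'
#' @param n number of directions.
#' @param seed integer seed.
#' @param n_iter descent iterations.
#' @return `n` by 3 matrix of unit vectors.
#' @export
repulsion_directions <- function(n, seed = 1L, n_iter = 300L) {
  stopifnot(n >= 1)
  set.seed(seed)
  x <- matrix(rnorm(3 * n), n, 3)
  x <- x / sqrt(rowSums(x^2))
  if (n == 1) return(x)
  step <- 0.05
  for (it in seq_len(n_iter)) {
    g <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d1 <- sweep(x[-i, , drop = FALSE], 2, x[i, ], "-")   # from +x_j
      d2 <- sweep(-x[-i, , drop = FALSE], 2, x[i, ], "-")  # from -x_j
      r1 <- pmax(sqrt(rowSums(d1^2)), 1e-6)
      r2 <- pmax(sqrt(rowSums(d2^2)), 1e-6)
      g[i, ] <- -colSums(d1 / r1^3) - colSums(d2 / r2^3)
    }
    x <- x + step * g / n
    x <- x / sqrt(rowSums(x^2))
  }
  x
}

#' Minimum pairwise angle of an antipodal direction set
#' @param dirs matrix of unit row vectors.
#' @return minimum angle in degrees, identifying u with -u.
#' @export
min_pairwise_angle <- function(dirs) {
  ca <- abs(tcrossprod(dirs))
  diag(ca) <- 0
  acos(pmin(max(ca), 1)) * 180 / pi
}

#' Group protocol volumes into shells
#'
#' @param protocol a `dmri_protocol`.
#' @param b_tol b-values closer than this are one shell.
#' @return tibble with one row per shell: `shell`, `b`, `n`, and a
#'   list-column `volumes` of volume indices.
#' @export
shell_table <- function(protocol, b_tol = 0.05) {
  b <- protocol$b
  ub <- sort(unique(round(b / b_tol) * b_tol))
  grp <- vapply(b, function(x) which.min(abs(ub - x)), integer(1))
  tibble::tibble(
    shell = seq_along(ub) - 1L,
    b = ub,
    n = as.integer(tabulate(grp, length(ub))),
    volumes = lapply(seq_along(ub), function(k) which(grp == k))
  )
}

#' Write / read FSL-style bvals and bvecs with a JSON timing sidecar
#'
#' @param protocol a `dmri_protocol`.
#' @param prefix file path prefix; writes `<prefix>.bval`, `<prefix>.bvec`,
#'   `<prefix>_timing.json`.
#' @return `prefix`, invisibly.
#' @export
write_protocol <- function(protocol, prefix) {
  writeLines(paste(format(protocol$b * 1000, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  bv <- rbind(protocol$gx, protocol$gy, protocol$gz)
  writeLines(apply(bv, 1, function(r) paste(format(r, trim = TRUE), collapse = " ")),
             paste0(prefix, ".bvec"))
  jsonlite::write_json(
    list(delta_ms = attr(protocol, "delta"), Delta_ms = attr(protocol, "Delta"),
         b_units = "s/mm^2 in .bval; ms/um^2 internally"),
    paste0(prefix, "_timing.json"), auto_unbox = TRUE
  )
  invisible(prefix)
}

#' @rdname write_protocol
#' @param b_units units in the bval file: `"s/mm2"` (FSL convention,
#'   converted by x 1e-3) or `"ms/um2"`.
#' @export
read_protocol <- function(prefix, b_units = c("s/mm2", "ms/um2")) {
  b_units <- match.arg(b_units)
  b <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  if (b_units == "s/mm2") b <- b * 1e-3
  bv <- unname(as.matrix(read.table(paste0(prefix, ".bvec"))))
  timing <- jsonlite::read_json(paste0(prefix, "_timing.json"))
  out <- tibble::tibble(
    volume = seq_along(b), b = b,
    gx = bv[1, ], gy = bv[2, ], gz = bv[3, ],
    shell = NA_integer_
  )
  st <- shell_table(out)
  for (k in seq_len(nrow(st))) out$shell[st$volumes[[k]]] <- st$shell[k]
  attr(out, "delta") <- timing$delta_ms
  attr(out, "Delta") <- timing$Delta_ms
  class(out) <- c("dmri_protocol", class(out))
  out
}
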