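# Vertex-wise age-contrast maps and positional-gradient correlation.

#' Vertex-wise age contrast map
#'
#' At every vertex fits `DV ~ age + sex + age:sex` by OLS across
#' subjects (hemisphere-averaged input) and extracts the t-statistic of
#' the age coefficient, `t_age = beta_age / SE(beta_age)`. Vertices
#' with (near-)constant DV are masked.
#'
#' @param Y matrix subjects x vertices (hemisphere-averaged metric).
#' @param subjects tibble with one row per row of `Y`: `age`, `sex`.
#' @return tibble of class `contrast_map`: `vertex`, `t_age`,
#'   `beta_age`; attributes `n`, `df`.
#' @export
vertexwise_age_contrast <- function(Y, subjects) {
  stopifnot(nrow(Y) == nrow(subjects),
            all(c("age", "sex") %in% names(subjects)))
  sexf <- factor(subjects$sex, levels = c("F", "M"))
  X <- model.matrix(~ age * sex,
                    data = data.frame(age = subjects$age, sex = sexf))
  n <- nrow(X); pcol <- ncol(X)
  df <- n - pcol
  if (df < 1) stop("too few subjects for the vertex model", call. = FALSE)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y) # pcol x V
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / df
  se_age <- sqrt(sigma2 * XtXi[2, 2])
  t_age <- B[2, ] / se_age
  degenerate <- apply(Y, 2, function(v) sd(v) < 1e-12) | se_age < 1e-14
  t_age[degenerate] <- NA_real_
  out <- tibble::tibble(vertex = seq_len(ncol(Y)), t_age = t_age,
                        beta_age = B[2, ])
  attr(out, "n") <- n
  attr(out, "df") <- df
  class(out) <- c("contrast_map", class(out))
  out
}

#' Contrived positional gradients on the template
#'
#' The unfolded AP and PD coordinates themselves, as reference gradient
#' maps spanning `[0, 1]`.
#'
#' @param mesh a [hipp_template_mesh()].
#' @return tibble: `vertex`, `ap`, `pd`.
#' @export
positional_gradients <- function(mesh) {
  tibble::tibble(vertex = seq_len(mesh$n_vertex), ap = mesh$ap, pd = mesh$pd)
}

#' Correlate an age-contrast map with the positional gradients
#'
#' Absolute Pearson correlations of the t-map with the AP and PD
#' positional gradients across vertices, plus the mean absolute t
#' (a coarse total age-effect size). Masked vertices are excluded
#' pairwise.
#'
#' @param tmap a [vertexwise_age_contrast()] map (or numeric vector).
#' @param mesh a [hipp_template_mesh()].
#' @return tibble: `r_ap`, `r_pd` (absolute), `mean_abs_t`, `n_vertex`.
#' @export
gradient_correlation <- function(tmap, mesh) {
  t <- if (is.numeric(tmap)) tmap else tmap$t_age
  stopifnot(length(t) == mesh$n_vertex)
  ok <- is.finite(t)
  if (sum(ok) < 3 || sd(t[ok]) < 1e-12) {
    warning("degenerate t-map; correlations undefined")
    return(tibble::tibble(r_ap = NA_real_, r_pd = NA_real_,
                          mean_abs_t = mean(abs(t[ok])),
                          n_vertex = sum(ok)))
  }
  tibble::tibble(
    r_ap = abs(cor(t[ok], mesh$ap[ok])),
    r_pd = abs(cor(t[ok], mesh$pd[ok])),
    mean_abs_t = mean(abs(t[ok])),
    n_vertex = sum(ok)
  )
}
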