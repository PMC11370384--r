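# Tiered Pearson screening, nested-model F-tests, FDR.

#' Minimum screening alpha from a Bonferroni family
#'
#' The minimum alpha at which a screening correlation is reported equals
#' a Bonferroni correction for a family of `n_tests` hypotheses (one
#' metric across the 5 subfields) at family-wise level `fwer`.
#'
#' @param n_tests family size.
#' @param fwer family-wise error rate.
#' @return the per-test alpha.
#' @export
screening_alpha <- function(n_tests = 5, fwer = 0.05) fwer / n_tests

#' Tiered Pearson screening of a metric against age
#'
#' Pearson R with a two-sided p-value, reported against the tiered
#' alphas 0.01 (the Bonferroni minimum), 0.005 and 0.0005.
#'
#' @param x,y numeric vectors (e.g. age and a parcel-averaged metric).
#' @param tiers significance tiers, most lenient first.
#' @return tibble: `r`, `p`, `n`, `tier` (factor `"ns"` or the most
#'   conservative tier passed).
#' @export
pearson_screen <- function(x, y, tiers = c(0.01, 0.005, 0.0005)) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3 finite pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = length(x),
                          tier = factor("undefined",
                                        levels = c("undefined", "ns", tiers))))
  }
  ct <- cor.test(x, y, method = "pearson")
  passed <- tiers[ct$p.value < tiers]
  tier <- if (length(passed)) as.character(min(passed)) else "ns"
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 tier = factor(tier, levels = c("undefined", "ns", tiers)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvals p-values in `[0, 1]`.
#' @return step-up adjusted p-values (monotone, capped at 1).
#' @export
fdr_bh <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  p.adjust(pvals, method = "BH")
}

#' F-test between nested linear models
#'
#' `F = ((RSS_r - RSS_f) / (df_r - df_f)) / (RSS_f / df_f)`, with the
#' p-value from the F distribution. The reduced model's terms must be a
#' subset of the full model's.
#'
#' @param data data frame.
#' @param full,reduced model formulas.
#' @return tibble: `f`, `df1`, `df2`, `p`, `rss_full`, `rss_reduced`, `n`.
#' @export
nested_f_test <- function(data, full, reduced) {
  tf <- attr(stats::terms(full, data = data), "term.labels")
  tr <- attr(stats::terms(reduced, data = data), "term.labels")
  if (!all(tr %in% tf)) {
    stop("models are not nested: reduced terms must be a subset of full terms",
         call. = FALSE)
  }
  mf <- lm(full, data = data)
  mr <- lm(reduced, data = data)
  rss_f <- sum(stats::residuals(mf)^2)
  rss_r <- sum(stats::residuals(mr)^2)
  df_f <- mf$df.residual
  df_r <- mr$df.residual
  df1 <- df_r - df_f
  if (df1 <= 0) stop("full model adds no parameters", call. = FALSE)
  f <- ((rss_r - rss_f) / df1) / (rss_f / df_f)
  tibble::tibble(f = f, df1 = df1, df2 = df_f,
                 p = pf(f, df1, df_f, lower.tail = FALSE),
                 rss_full = rss_f, rss_reduced = rss_r, n = nrow(mf$model))
}

#' Canned nested tests of the developmental battery
#'
#' Long-format input with columns `value`, `age`, `parcel` and a
#' stratifier. `age_by_group_test()` tests the age-by-group interaction
#' (group = sex or hemisphere) on top of the full parcel model;
#' `age_by_parcel_test()` tests whether age slopes differ across
#' parcels. Treatment contrasts; reference levels are the first factor
#' levels (subiculum, F, L).
#'
#' @param data long tibble: `value`, `age`, `parcel`, and `group` for
#'   the interaction test.
#' @return [nested_f_test()] tibble.
#' @export
age_by_group_test <- function(data) {
  stopifnot(all(c("value", "age", "parcel", "group") %in% names(data)))
  nested_f_test(
    data,
    full = value ~ age + parcel + group + age:parcel + group:parcel + age:group,
    reduced = value ~ age + parcel + group + age:parcel + group:parcel
  )
}

#' @rdname age_by_group_test
#' @export
age_by_parcel_test <- function(data) {
  stopifnot(all(c("value", "age", "parcel") %in% names(data)))
  if ("group" %in% names(data)) {
    return(nested_f_test(
      data,
      full = value ~ age + parcel + group + age:parcel + group:parcel + age:group,
      reduced = value ~ age + parcel + group + group:parcel + age:group
    ))
  }
  nested_f_test(data, full = value ~ age + parcel + age:parcel,
                reduced = value ~ age + parcel)
}
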