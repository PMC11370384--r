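# Synthetic developmental cohort.

#' Generate a cross-sectional cohort
#'
#' Ages are drawn uniformly over `[age_min, age_max]` (uniform sampling
#' maximizes power for slope estimation; a triangular "young-skewed"
#' option mimics cohorts with more children than adolescents). Each
#' subject contributes one row per hemisphere.
#'
#' @param n number of subjects.
#' @param age_min,age_max age range, years.
#' @param male_fraction proportion of male subjects in `[0, 1]`.
#' @param seed integer seed.
#' @param age_dist `"uniform"` or `"young_skewed"` (linearly decreasing
#'   density over the age range).
#' @return tibble of class `cohort` with columns `subject_id`, `age`,
#'   `sex` (`"M"`/`"F"`), `hemisphere` (`"L"`/`"R"`); `2 n` rows.
#' @export
make_cohort <- function(n, age_min = 8, age_max = 19, male_fraction = 0.5,
                        seed = 1L, age_dist = c("uniform", "young_skewed")) {
  age_dist <- match.arg(age_dist)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  if (age_max < age_min) stop("invalid age range", call. = FALSE)
  if (male_fraction < 0 || male_fraction > 1) {
    stop("male_fraction must be in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  u <- runif(n)
  age <- switch(age_dist,
    uniform = age_min + u * (age_max - age_min),
    # density 2(1 - x) on [0, 1]: inverse cdf 1 - sqrt(1 - u)
    young_skewed = age_min + (1 - sqrt(1 - u)) * (age_max - age_min)
  )
  n_male <- round(n * male_fraction)
  sex <- sample(rep(c("M", "F"), c(n_male, n - n_male)))
  subj <- tibble::tibble(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    age = age, sex = sex
  )
  out <- tidyr::crossing(subj, hemisphere = c("L", "R"))
  out <- dplyr::arrange(out, .data$subject_id, .data$hemisphere)
  class(out) <- c("cohort", class(out))
  out
}

#' Write / read a cohort CSV
#' @param cohort a [make_cohort()] tibble.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort)[, c("subject_id", "age", "sex", "hemisphere")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("subject_id", "age", "sex", "hemisphere") %in% names(out)))
  class(out) <- c("cohort", class(out))
  out
}
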