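# Ground-truth developmental effect specifications for the generator.

#' Effect specification table for synthetic parameter surfaces
#'
#' One row per metric: linear age trend, an extra slope for males
#' (age-by-sex interaction), a fixed spatial pattern along one unfolded
#' axis, vertex noise, and validity bounds used for clamping.
#'
#' @param ... rows as named lists overriding defaults, keyed by metric.
#' @return tibble of class `effect_spec`.
#' @details The defaults encode the qualitative developmental profile the
#'   statistical battery is designed to detect in children/adolescents
#'   (ages about 8-19): neurite signal fraction rising with age and
#'   varying along the long axis, extracellular fraction and mean
#'   diffusivity falling (MD varying along the proximal-distal axis),
#'   a slowly shrinking apparent soma radius, flat ODI, plus
#'   age-by-sex interaction slopes on fneurite and MD. Units: signal
#'   fractions unitless, `rsoma` um, `md` um^2/ms, slopes per year.
#' @export
default_effects <- function(...) {
  base <- tibble::tribble(
    ~metric,          ~baseline, ~age_slope, ~sex_slope_delta, ~spatial_pattern, ~spatial_amplitude, ~vertex_noise_sd, ~lo,  ~hi,
    "fneurite",        0.22,      0.006,      0.004,           "AP-linear",       0.04,               0.02,            0,    1,
    "fextracellular",  0.45,     -0.006,      0.000,           "uniform",         0.00,               0.02,            0,    1,
    "rsoma",           8.0,      -0.08,      -0.06,            "uniform",         0.00,               0.40,            3,    11,
    "odi",             0.50,      0.000,      0.000,           "uniform",         0.00,               0.03,            0.05, 0.95,
    "md",              0.90,     -0.008,     -0.004,           "PD-linear",       0.06,               0.03,            0.3,  2.5,
    "din",             1.70,      0.000,      0.000,           "uniform",         0.00,               0.00,            0.1,  3,
    "dec",             1.00,      0.000,      0.000,           "uniform",         0.00,               0.00,            0.1,  3
  )
  mods <- list(...)
  for (nm in names(mods)) {
    i <- which(base$metric == nm)
    if (!length(i)) stop("unknown metric: ", nm, call. = FALSE)
    for (f in names(mods[[nm]])) base[[f]][i] <- mods[[nm]][[f]]
  }
  class(base) <- c("effect_spec", class(base))
  base
}

#' Zero-effect specification (null generator)
#' @return `default_effects()` with all slopes, deltas and spatial
#'   amplitudes set to zero.
#' @export
null_effects <- function() {
  e <- default_effects()
  e$age_slope <- 0
  e$sex_slope_delta <- 0
  e$spatial_amplitude <- 0
  e
}

#' Generate per-subject ground-truth parameter surfaces
#'
#' For each cohort row (subject x hemisphere) and template vertex,
#' `metric = baseline + age_slope (age - age_ref) +
#' sex_slope_delta (age - age_ref) [sex == M] +
#' spatial_amplitude (coord - 1/2) + noise`, truncated to the metric's
#' bounds with the truncation recorded in a clamp mask. The soma
#' fraction is derived as `fsoma = 1 - fneurite - fextracellular`
#' (rescaling the two generated fractions where their sum would leave
#' less than 2% soma signal), so the three fractions sum to 1 at every
#' vertex.
#'
#' @param cohort a [make_cohort()] tibble.
#' @param effects an [default_effects()] table.
#' @param mesh a [hipp_template_mesh()].
#' @param seed integer seed.
#' @param age_ref centering age, years.
#' @return object of class `parameter_surfaces`: list `metrics` of
#'   matrices (cohort rows x vertices, including derived `fsoma`),
#'   `clamped` masks, plus `cohort`, `mesh`, `effects`, `age_ref`.
#' @export
make_parameter_surfaces <- function(cohort, effects = default_effects(),
                                    mesh = hipp_template_mesh(), seed = 1L,
                                    age_ref = 13.5) {
  stopifnot(inherits(cohort, "cohort"))
  bad <- setdiff(effects$metric,
                 c("fneurite", "fextracellular", "rsoma", "odi", "md",
                   "din", "dec"))
  if (length(bad)) stop("unknown metric name(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  set.seed(seed)
  n <- nrow(cohort)
  V <- mesh$n_vertex
  dage <- cohort$age - age_ref
  male <- as.numeric(cohort$sex == "M")
  metrics <- list()
  clamped <- list()
  for (i in seq_len(nrow(effects))) {
    e <- effects[i, ]
    subj <- e$baseline + e$age_slope * dage + e$sex_slope_delta * dage * male
    spat <- switch(e$spatial_pattern,
      uniform = rep(0, V),
      `AP-linear` = e$spatial_amplitude * (mesh$ap - 0.5),
      `PD-linear` = e$spatial_amplitude * (mesh$pd - 0.5),
      stop("unknown spatial_pattern: ", e$spatial_pattern, call. = FALSE)
    )
    m <- outer(subj, rep(1, V)) + outer(rep(1, n), spat)
    if (e$vertex_noise_sd > 0) m <- m + rnorm(n * V, 0, e$vertex_noise_sd)
    cl <- m < e$lo | m > e$hi
    m[m < e$lo] <- e$lo
    m[m > e$hi] <- e$hi
    metrics[[e$metric]] <- m
    clamped[[e$metric]] <- cl
  }
  # keep the fraction triple on the simplex with >= 2% soma signal
  s <- metrics$fneurite + metrics$fextracellular
  over <- s > 0.98
  if (any(over)) {
    sc <- 0.98 / s[over]
    metrics$fneurite[over] <- metrics$fneurite[over] * sc
    metrics$fextracellular[over] <- metrics$fextracellular[over] * sc
    clamped$fneurite[over] <- TRUE
    clamped$fextracellular[over] <- TRUE
  }
  metrics$fsoma <- 1 - metrics$fneurite - metrics$fextracellular
  clamped$fsoma <- clamped$fneurite | clamped$fextracellular
  structure(list(metrics = metrics, clamped = clamped, cohort = cohort,
                 mesh = mesh, effects = effects, age_ref = age_ref,
                 seed = seed),
            class = "parameter_surfaces")
}
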