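# End-to-end orchestration: simulate -> fit -> surface stats -> report.

#' Pipeline configuration
#'
#' Reduced-scale defaults (desk-scale demo); `full_scale = TRUE` switches
#' to the study-sized configuration (88 subjects, the 7262-vertex
#' template, 2500 spin permutations).
#'
#' @param seed master seed; every stage derives its own child seed.
#' @param n_subjects cohort size.
#' @param mesh surface template.
#' @param shell_spec protocol shells.
#' @param delta,Delta pulse timings, ms.
#' @param effects generator effect table.
#' @param snr b = 0 signal-to-noise ratio.
#' @param noise_model `"rician"`, `"gaussian"` or `"none"`.
#' @param sandi_starts multi-start count for the SANDI stage.
#' @param n_perm spin-test permutations.
#' @param metrics metrics carried through fitting and statistics.
#' @param out_dir optional output directory (CSV/JSON written there).
#' @param full_scale use study-scale sizes.
#' @return config list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 30,
                            mesh = hipp_template_mesh(n_ap = 25, n_pd = 10,
                                                      notch = 0),
                            shell_spec = default_shell_spec(),
                            delta = 7, Delta = 24,
                            effects = default_effects(),
                            snr = 50, noise_model = "rician",
                            sandi_starts = 3L, n_perm = 200L,
                            metrics = c("fneurite", "fsoma",
                                        "fextracellular", "rsoma", "md"),
                            out_dir = NULL, full_scale = FALSE) {
  if (full_scale) {
    n_subjects <- 88
    mesh <- hipp_template_mesh()
    n_perm <- 2500L
  }
  structure(list(
    seed = as.integer(seed), n_subjects = n_subjects, mesh = mesh,
    shell_spec = shell_spec, delta = delta, Delta = Delta,
    effects = effects, snr = snr, noise_model = noise_model,
    sandi_starts = as.integer(sandi_starts), n_perm = as.integer(n_perm),
    metrics = metrics, out_dir = out_dir,
    fixed_constants = list(d_par = 1.7, d_iso = 3.0, d_is = 3.0,
                           d_in_fixed = 1.7)
  ), class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Stages: cohort and protocol generation; ground-truth parameter
#' surfaces with developmental effects; per-vertex signal simulation and
#' model fitting (SANDI on spherical means, DTI on the low-b subset);
#' hemisphere averaging; parcel-averaged tiered Pearson screening;
#' nested-model F-tests with FDR; vertex-wise age contrasts with
#' positional-gradient correlations; and a spin-test matrix between the
#' age-contrast maps.
#'
#' @param config a [pipeline_config()].
#' @return list of class `hippomicro_pipeline` with elements `cohort`,
#'   `protocol`, `truth`, `estimates` (subject-hemisphere x vertex
#'   matrices per metric), `subject_maps` (hemisphere-averaged),
#'   `screening`, `ftests`, `contrasts`, `gradient_correlations`,
#'   `spin`, `slope_recovery`, and `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- child_seeds(config$seed, 10)
  mesh <- config$mesh
  V <- mesh$n_vertex

  cohort <- make_cohort(config$n_subjects, seed = seeds[1])
  protocol <- make_protocol(config$shell_spec, config$delta, config$Delta,
                            seed = seeds[2])
  truth <- make_parameter_surfaces(cohort, config$effects, mesh,
                                   seed = seeds[3])

  # --- signal simulation + fitting, one subject-hemisphere at a time
  low_b <- protocol[protocol$b <= 1.2 + 1e-9, ]
  class(low_b) <- class(protocol)
  attr(low_b, "delta") <- config$delta; attr(low_b, "Delta") <- config$Delta
  n_rows <- nrow(cohort)
  est <- lapply(config$metrics, function(m) matrix(NA_real_, n_rows, V))
  names(est) <- config$metrics
  st <- shell_table(protocol)
  row_seeds <- child_seeds(seeds[4], 2 * n_rows)
  for (r in seq_len(n_rows)) {
    fec <- truth$metrics$fextracellular[r, ]
    fn <- truth$metrics$fneurite[r, ]
    pars <- tibble::tibble(
      f_ec = fec, f_in = ifelse(fec < 1, fn / (1 - fec), 0),
      r_s = truth$metrics$rsoma[r, ],
      D_in = truth$metrics$din[r, ], D_ec = truth$metrics$dec[r, ]
    )
    S <- simulate_signals(pars, protocol, model = "sandi", snr = config$snr,
                          noise_model = config$noise_model,
                          seed = row_seeds[2 * r - 1])
    sm <- spherical_mean(S, st)
    fs <- fit_sandi(sm$sphmean, sm$b, config$delta, config$Delta,
                    n_starts = config$sandi_starts, seed = seeds[5])
    md <- truth$metrics$md[r, ]
    dpar <- tibble::tibble(dxx = md, dyy = md, dzz = md,
                           dxy = 0, dxz = 0, dyz = 0)
    Sd <- simulate_signals(dpar, low_b, model = "dti", snr = config$snr,
                           noise_model = config$noise_model,
                           seed = row_seeds[2 * r])
    fd <- fit_dti(Sd, low_b)
    for (m in config$metrics) {
      est[[m]][r, ] <- switch(m,
        fneurite = fs$fneurite, fsoma = fs$fsoma,
        fextracellular = fs$fextracellular, rsoma = fs$rsoma,
        md = fd$md, fa = fd$fa,
        stop("metric not produced by the fitting stage: ", m))
    }
  }

  # --- hemisphere averaging to subject level
  subj <- dplyr::distinct(cohort, .data$subject_id, .data$age, .data$sex)
  iL <- match(paste0(subj$subject_id, "L"),
              paste0(cohort$subject_id, cohort$hemisphere))
  iR <- match(paste0(subj$subject_id, "R"),
              paste0(cohort$subject_id, cohort$hemisphere))
  subject_maps <- lapply(est, function(m) (m[iL, , drop = FALSE] +
                                             m[iR, , drop = FALSE]) / 2)

  # --- parcel tables (subfield and long-axis), both granularities
  parcel_long <- dplyr::bind_rows(lapply(config$metrics, function(m) {
    dplyr::bind_rows(
      dplyr::mutate(cbind(cohort[rep(seq_len(n_rows),
                                     each = nlevels(mesh$subfield)), ],
                          parcel_table(est[[m]], mesh$subfield)),
                    metric = m, axis = "subfield"),
      dplyr::mutate(cbind(cohort[rep(seq_len(n_rows),
                                     each = nlevels(mesh$ap_bin)), ],
                          parcel_table(est[[m]], mesh$ap_bin)),
                    metric = m, axis = "long_axis")
    )
  }))

  # --- tiered Pearson screening on hemisphere-averaged parcel means
  havg <- average_hemispheres(parcel_long, value = "value")
  screening <- dplyr::group_modify(
    dplyr::group_by(havg, .data$metric, .data$axis, .data$parcel),
    ~ {
      ok <- is.finite(.x$age) & is.finite(.x$value)
      if (sum(ok) < 3) {
        tibble::tibble(r = NA_real_, p = NA_real_, n = sum(ok),
                       tier = factor("undefined"))
      } else {
        pearson_screen(.x$age, .x$value)
      }
    })
  screening <- dplyr::ungroup(screening)

  # --- nested F-tests with FDR per family
  ftests <- dplyr::bind_rows(lapply(config$metrics, function(m) {
    dh <- dplyr::filter(havg, .data$metric == m, .data$axis == "subfield")
    dh$group <- dh$sex
    t_sex <- age_by_group_test(dh)
    db <- dplyr::filter(parcel_long, .data$metric == m,
                        .data$axis == "subfield")
    db$group <- db$hemisphere
    t_hemi <- age_by_group_test(db)
    t_parc <- age_by_parcel_test(dh)
    dplyr::bind_rows(
      dplyr::mutate(t_sex, test = "age_by_sex", metric = m),
      dplyr::mutate(t_hemi, test = "age_by_hemisphere", metric = m),
      dplyr::mutate(t_parc, test = "age_by_subfield_slope", metric = m)
    )
  }))
  ftests <- dplyr::mutate(dplyr::group_by(ftests, .data$test),
                          p_adj = fdr_bh(.data$p))
  ftests <- dplyr::ungroup(ftests)

  # --- vertex-wise contrasts + positional-gradient correlations
  contrasts <- lapply(subject_maps, vertexwise_age_contrast, subjects = subj)
  gradcor <- dplyr::bind_rows(lapply(config$metrics, function(m) {
    dplyr::mutate(gradient_correlation(contrasts[[m]], mesh), metric = m)
  }))

  # --- spin-test matrix between age-contrast maps
  pairs <- utils::combn(config$metrics, 2)
  spin <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    dplyr::mutate(spin_test(contrasts[[a]]$t_age, contrasts[[b]]$t_age,
                            mesh, n_perm = config$n_perm, seed = seeds[6]),
                  map_a = a, map_b = b)
  }))

  # --- ground-truth slope recovery (subject-mean metric vs age)
  p_male <- mean(subj$sex == "M")
  slope_recovery <- dplyr::bind_rows(lapply(config$metrics, function(m) {
    em <- rowMeans(subject_maps[[m]])
    fitm <- lm(em ~ subj$age)
    i <- match(m, config$effects$metric)
    # population-average slope: age_slope plus the male share of the
    # sex-specific extra slope; fsoma's truth is implied by the two
    # generated fractions
    true_slope <- if (!is.na(i)) {
      config$effects$age_slope[i] + p_male * config$effects$sex_slope_delta[i]
    } else if (m == "fsoma") {
      iN <- match("fneurite", config$effects$metric)
      iE <- match("fextracellular", config$effects$metric)
      -(config$effects$age_slope[iN] +
          p_male * config$effects$sex_slope_delta[iN]) -
        (config$effects$age_slope[iE] +
           p_male * config$effects$sex_slope_delta[iE])
    } else NA_real_
    tibble::tibble(metric = m, est_slope = unname(coef(fitm)[2]),
                   se_slope = sqrt(vcov(fitm)[2, 2]),
                   true_slope = true_slope)
  }))

  out <- structure(list(
    cohort = cohort, protocol = protocol, truth = truth, estimates = est,
    subject_maps = subject_maps, subjects = subj, screening = screening,
    ftests = ftests, contrasts = contrasts,
    gradient_correlations = gradcor, spin = spin,
    slope_recovery = slope_recovery, config = config
  ), class = "hippomicro_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out)
  out
}

# long parcel table for one metric matrix (rows x V) and a label factor
parcel_table <- function(m, labels) {
  pa <- parcel_average(m, labels)
  tibble::tibble(parcel = pa$parcel, value = pa$mean)
}

write_pipeline_outputs <- function(x) {
  dir.create(x$config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- x$config$out_dir
  write_cohort(x$cohort, file.path(od, "cohort.csv"))
  write_protocol(x$protocol, file.path(od, "protocol"))
  write.csv(x$screening, file.path(od, "screening.csv"), row.names = FALSE)
  write.csv(x$ftests, file.path(od, "ftests.csv"), row.names = FALSE)
  write.csv(x$gradient_correlations,
            file.path(od, "gradient_correlations.csv"), row.names = FALSE)
  write.csv(x$spin, file.path(od, "spin_tests.csv"), row.names = FALSE)
  cfg <- x$config
  cfg$mesh <- list(n_ap = cfg$mesh$grid$n_ap, n_pd = cfg$mesh$grid$n_pd,
                   notch = cfg$mesh$grid$notch,
                   n_vertex = cfg$mesh$n_vertex)
  cfg$out_dir <- NULL
  jsonlite::write_json(cfg, file.path(od, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(od)
}

#' @export
print.hippomicro_pipeline <- function(x, ...) {
  cat("hippomicro pipeline run\n")
  cat("  subjects:", nrow(x$subjects), " vertices:", x$config$mesh$n_vertex,
      " seed:", x$config$seed, "\n")
  cat("  screening rows:", nrow(x$screening),
      " | F-tests:", nrow(x$ftests),
      " | spin pairs:", nrow(x$spin), "\n")
  invisible(x)
}
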