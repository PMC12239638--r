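#' Read and validate a pipeline configuration
#'
#' A configuration is a YAML file or list with either a `simulate` block
#' (generator overrides plus `seed`) or an `inputs` block with file paths
#' (`landmarks`: wide CSV with a `plane` column, or one path per plane;
#' `pedigree`; `individuals`: per-individual covariate/genotype CSV), plus
#' analysis settings: `trait_definitions` (path, optional), `min_length_cm`,
#' `outlier_sd`, `permutations`, `n_sims`, `n_starts` (optimiser starts
#' per mixed-model fit), `seed` (mandatory), `traits`
#' (optional subset), `planes`, and `output_dir`.
#'
#' @param config A list or path to a YAML file.
#' @return A validated config list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("pipeline config needs a seed", call. = FALSE)
  defaults <- list(min_length_cm = 9, outlier_sd = 4, permutations = 999,
                   n_sims = 10000L, n_starts = 3L,
                   planes = c("body", "small_xsec", "large_xsec"),
                   output_dir = "morphoquant_results")
  for (nm in names(defaults)) if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$simulate) && is.null(config$inputs)) {
    stop("config needs either a `simulate` block or an `inputs` block", call. = FALSE)
  }
  if (!is.null(config$inputs)) {
    fields <- c("landmarks", "pedigree", "individuals")
    present <- fields[vapply(fields, function(f) !is.null(config$inputs[[f]]),
                             logical(1))]
    if (length(setdiff(fields, present))) {
      stop("inputs block is missing: ",
           paste(setdiff(fields, present), collapse = ", "), call. = FALSE)
    }
    paths <- unlist(config$inputs[fields])
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stop("input file(s) not found: ",
                              paste(missing, collapse = ", "), call. = FALSE)
  }
  config
}

#' Run the full analysis pipeline
#'
#' Orchestrates: data loading (or simulation), individual-level filtering
#' with an audit log, missing-landmark imputation, generalized Procrustes
#' alignment, outlier-configuration exclusion and re-alignment, trait
#' extraction, the multivariate shape model with RRPP tests per plane, the
#' per-trait animal models (ML coefficients with Satterthwaite type-III
#' tests; genotype-free REML for variance components), and the variance
#' decomposition. Writes three report tables (shape MANOVA, trait
#' coefficients, decomposition), a plain-text audit log and a JSON manifest
#' into `output_dir`; the run is deterministic given the seed.
#'
#' @param config A config list or YAML path (see [pipeline_config()]).
#' @return Invisibly, a list with the three tables, the audit, and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  # --- stage: inputs -------------------------------------------------------
  if (!is.null(config$simulate)) {
    overrides <- config$simulate
    overrides$seed <- NULL
    sim_cfg <- do.call(simulation_config, overrides)
    sim <- simulate_dataset(sim_cfg, seed = config$seed, landmarks = TRUE)
    individuals <- sim$individuals
    landmarks <- sim$landmarks
    pedigree <- sim$breeding$pedigree
    say("simulate: ", nrow(individuals), " individuals, ",
        dplyr::n_distinct(landmarks$plane), " planes")
  } else {
    pedigree <- read_pedigree(config$inputs$pedigree)
    individuals <- tibble::as_tibble(
      utils::read.csv(config$inputs$individuals, na.strings = c("", "NA"))
    )
    individuals$vgll3 <- encode_additive_genotype(individuals$vgll3)
    individuals$six6 <- encode_additive_genotype(individuals$six6)
    lm_paths <- config$inputs$landmarks
    landmarks <- if (length(lm_paths) > 1L || !is.null(names(lm_paths))) {
      dplyr::bind_rows(purrr::imap(as.list(lm_paths), function(p, plane) {
        read_landmarks(p, plane = plane)
      }))
    } else {
      read_landmarks(lm_paths[[1]])
    }
    say("inputs: ", nrow(individuals), " individuals, ",
        dplyr::n_distinct(landmarks$plane), " planes")
  }

  # --- stage: filter -------------------------------------------------------
  filtered <- filter_individuals(individuals, min_length_cm = config$min_length_cm)
  audit <- filter_audit(filtered)
  say("filter: ", nrow(individuals) - nrow(filtered), " individuals removed (",
      paste(audit$rule, audit$n_removed, sep = "=", collapse = ", "), ")")
  landmarks <- landmarks[landmarks$specimen_id %in% filtered$id, ]

  # --- stage: align (per plane) -------------------------------------------
  planes <- intersect(config$planes, unique(landmarks$plane))
  outlier_log <- list()
  aligned <- list()
  clean_landmarks <- list()
  for (plane in planes) {
    lm_p <- landmarks[landmarks$plane == plane, ]
    lm_p <- impute_missing_landmarks(lm_p)
    gpa0 <- gpa_align(lm_p)
    flags <- flag_outlier_configurations(gpa0, sd_threshold = config$outlier_sd)
    bad <- flags[flags$exclude, ]
    outlier_log[[plane]] <- bad
    if (nrow(bad)) {
      lm_p <- dplyr::anti_join(lm_p, bad, by = c("specimen_id", "plane", "replicate"))
    }
    aligned[[plane]] <- if (nrow(bad)) gpa_align(lm_p) else gpa0
    clean_landmarks[[plane]] <- lm_p
    say("align[", plane, "]: ", nrow(aligned[[plane]]$meta), " configurations, ",
        nrow(bad), " excluded as outliers, ",
        aligned[[plane]]$iterations, " GPA iterations")
  }

  # --- stage: traits -------------------------------------------------------
  defs <- read_trait_definitions(config$trait_definitions)
  if (!is.null(config$traits)) defs <- defs[intersect(names(defs), config$traits)]
  traits <- extract_traits(dplyr::bind_rows(clean_landmarks), defs)
  trait_tbl <- build_trait_table(traits, filtered)
  say("traits: ", dplyr::n_distinct(traits$trait), " traits, ",
      nrow(traits), " measurements")

  # --- stage: shape MANOVA -------------------------------------------------
  covars <- dplyr::distinct(trait_tbl, .data$specimen_id, .data$L, .data$CF,
                            .data$feed, .data$tank, .data$sex, .data$family,
                            .data$vgll3, .data$six6)
  manova_tbl <- purrr::imap(aligned, function(gpa, plane) {
    dat <- dplyr::inner_join(shape_coordinates(gpa), covars, by = "specimen_id")
    dat <- ensure_reference_levels(dat)
    fit <- withCallingHandlers(
      fit_shape_model(dat, ~ L + CF + feed + tank + sex + vgll3 + six6 + family,
                      permutations = config$permutations, seed = config$seed,
                      drop_aliased = TRUE),
      morphoquant_singular_sscp = function(w) invokeRestart("muffleWarning")
    )
    dplyr::mutate(fit$terms, plane = plane, .before = 1L)
  })
  manova_tbl <- dplyr::bind_rows(manova_tbl)
  say("manova: ", nrow(manova_tbl), " term tests across ", length(aligned), " planes")

  # --- stage: animal models and decomposition ------------------------------
  rel <- additive_relationship_inverse(pedigree)
  coef_rows <- list()
  decomp_rows <- list()
  for (tr in unique(trait_tbl$trait)) {
    fit_ml <- fit_animal_model(trait_tbl, tr, relationship = rel, method = "ML",
                               n_starts = config$n_starts)
    tests <- satterthwaite_type3(fit_ml)
    coef_rows[[tr]] <- dplyr::mutate(
      dplyr::left_join(fit_ml$coefficients,
                       tests[, c("term", "df_den", "F", "p")], by = "term"),
      trait = tr, .before = 1L
    )
    fit_full <- fit_animal_model(trait_tbl, tr,
                                 fixed = ~ L + CF + feed + sex,
                                 relationship = rel, method = "REML",
                                 n_starts = config$n_starts)
    tr_mean <- mean(average_replicates(trait_tbl[trait_tbl$trait == tr, ])$value)
    genos <- dplyr::distinct(trait_tbl[trait_tbl$trait == tr, ],
                             .data$specimen_id, .data$vgll3, .data$six6)
    decomp_rows[[tr]] <- decompose_variance(
      fit_full, fit_ml, genos, trait_mean = tr_mean,
      n_sims = config$n_sims, seed = config$seed
    )
    say("animal[", tr, "]: logLik(ML) = ", signif(fit_ml$loglik, 7),
        ", V_A = ", signif(fit_full$varcomp[["animal"]], 4))
  }
  coef_tbl <- dplyr::bind_rows(coef_rows)
  decomp_tbl <- dplyr::bind_rows(decomp_rows)

  # --- stage: report -------------------------------------------------------
  out <- config$output_dir
  utils::write.csv(manova_tbl, file.path(out, "shape_manova.csv"), row.names = FALSE)
  utils::write.csv(coef_tbl, file.path(out, "trait_coefficients.csv"), row.names = FALSE)
  utils::write.csv(decomp_tbl, file.path(out, "variance_decomposition.csv"),
                   row.names = FALSE)
  audit_lines <- c(
    "filter audit (rule: individuals removed)",
    sprintf("  %s: %d", audit$rule, audit$n_removed),
    "outlier configurations excluded per plane",
    sprintf("  %s: %d", names(outlier_log),
            vapply(outlier_log, nrow, integer(1))),
    "stage log",
    paste0("  ", log_lines)
  )
  writeLines(audit_lines, file.path(out, "audit.txt"))
  manifest <- list(
    package = "morphoquant",
    version = as.character(utils::packageVersion("morphoquant")),
    seed = config$seed,
    permutations = config$permutations,
    n_sims = config$n_sims,
    n_individuals_in = nrow(individuals),
    n_individuals_retained = nrow(filtered),
    planes = as.list(vapply(aligned, function(g) nrow(g$meta), integer(1))),
    n_traits = dplyr::n_distinct(coef_tbl$trait)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("report: tables written to ", out)
  invisible(list(shape_manova = manova_tbl, trait_coefficients = coef_tbl,
                 variance_decomposition = decomp_tbl, audit = audit,
                 outliers = outlier_log, manifest = manifest))
}
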