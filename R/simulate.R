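#' Configuration for the synthetic-data generator
#'
#' Defaults reproduce the study conditions: 11 two-by-two factorial breeding
#' units (44 parents, 44 families), offspring numbers giving roughly 820
#' individuals after filtering, 8 rearing tanks with feed restriction in
#' half, a bimodal fork-length distribution whose lower mode sits below the
#' 9 cm inclusion threshold, planted missing genotypes/sex and precociously
#' mature males matching the reported exclusion counts, and trait-model
#' ground truth (variance components and allele-substitution effects) inside
#' the reported ranges. Every parameter can be overridden.
#'
#' @param ... Named overrides of the defaults listed in the function body.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    n_units = 11L,
    offspring_per_family = 21L,
    n_tanks = 8L,
    six6_parent_freq_L = 0.3,
    # trait model ground truth (trait units: cm, for a ~2 cm trait)
    mu = 2.0,
    beta = c(L = 0.15, CF = 0.01, feed = -0.05, sex = 0.02,
             vgll3 = -0.05, six6 = 0.03),
    dominance = NULL,       # named vector, e.g. c(vgll3 = 0.03): het deviation
    interaction = NULL,     # named vector, e.g. c(vgll3 = 0.05): L x locus
    varcomp = c(animal = 0.003, tank = 0.001, id = 0.012, error = 0.004),
    replicate_fraction = 0.9,
    # fork length (cm): bimodal mixture; lower mode below the 9 cm filter
    length_lower_mean = 8, length_lower_sd = 0.4, length_lower_weight = 0.075,
    length_upper_mean = 12.5, length_upper_sd = 1.2,
    condition_mean = 1.0, condition_sd = 0.08,
    # planted exclusions (assigned among upper-mode fish, mutually disjoint)
    n_missing_vgll3 = 2L, n_missing_six6 = 12L, n_missing_sex = 4L,
    n_mature_males = 19L,
    # landmark generator
    landmark_noise_sd = 0.01,        # digitising noise per replicate (cm)
    landmark_individual_sd = 0.02,   # individual deviation field (cm)
    landmark_replicate_fraction = 0.9,
    landmark_missing_rate = 2e-4,
    n_corrupt_configs = 0L,          # configs given 2 grossly displaced landmarks
    corrupt_magnitude = 1.0          # displacement (cm) for corrupted landmarks
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  cfg[names(override)] <- override
  stopifnot(cfg$n_units >= 1L, all(cfg$varcomp >= 0))
  structure(cfg, class = "sim_config")
}

#' Simulate the factorial breeding design
#'
#' Each unit has two males and two females; within each sex one parent is
#' homozygous EE and the other LL at vgll3. All four male-by-female crosses
#' are made, so offspring vgll3 genotypes are fixed within family (EE, EL,
#' LE, LL across the four families of a unit). six6 was not part of the
#' breeding design: parental six6 genotypes are drawn from Hardy-Weinberg
#' proportions at the configured allele frequency and offspring six6 by
#' Mendelian sampling, so the locus segregates within families.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @return A list with `pedigree` (a `ped_tbl`), `genotypes` (tibble `id`,
#'   `vgll3`, `six6`, `sex`, `family`, `is_parent`) and `families`.
#' @export
simulate_breeding <- function(config = simulation_config(), seed = 1L) {
  set.seed(seed)
  units <- seq_len(config$n_units)
  parents <- purrr::map(units, function(u) {
    tibble::tibble(
      id = sprintf("U%02d_%s", u, c("M_E", "M_L", "F_E", "F_L")),
      sex = c("male", "male", "female", "female"),
      vgll3 = c(0L, 2L, 0L, 2L),
      unit = u
    )
  })
  parents <- dplyr::bind_rows(parents)
  # six6 parental genotypes: HWE at the configured L frequency
  pL <- config$six6_parent_freq_L
  parents$six6 <- stats::rbinom(nrow(parents), 1L, pL) + stats::rbinom(nrow(parents), 1L, pL)

  crosses <- tidyr::expand_grid(unit = units, sire_type = c("M_E", "M_L"),
                                dam_type = c("F_E", "F_L"))
  crosses <- dplyr::mutate(crosses,
    sire = sprintf("U%02d_%s", .data$unit, .data$sire_type),
    dam = sprintf("U%02d_%s", .data$unit, .data$dam_type),
    family = sprintf("F%02d_%s%s", .data$unit,
                     sub("^[MF]_", "", .data$sire_type), sub("^[MF]_", "", .data$dam_type))
  )
  six6_geno <- stats::setNames(parents$six6, parents$id)
  draw_allele <- function(code, n) {
    # number of L alleles transmitted by a parent of additive code `code`
    ifelse(rep(code == 1L, n), stats::rbinom(n, 1L, 0.5), as.integer(code / 2L))
  }
  offspring <- purrr::pmap(crosses, function(unit, sire_type, dam_type, sire, dam, family) {
    n_off <- config$offspring_per_family
    vg <- (if (sire_type == "M_L") 1L else 0L) + (if (dam_type == "F_L") 1L else 0L)
    six6_off <- draw_allele(six6_geno[[sire]], n_off) + draw_allele(six6_geno[[dam]], n_off)
    tibble::tibble(
      id = sprintf("%s_%02d", family, seq_len(n_off)),
      sire = sire, dam = dam, family = family, unit = unit,
      vgll3 = vg,
      six6 = six6_off,
      sex = sample(c("female", "male"), n_off, replace = TRUE)
    )
  })
  offspring <- dplyr::bind_rows(offspring)

  pedigree <- as_pedigree(dplyr::bind_rows(
    tibble::tibble(id = parents$id, sire = NA_character_, dam = NA_character_),
    offspring[, c("id", "sire", "dam")]
  ))
  genotypes <- dplyr::bind_rows(
    dplyr::mutate(parents[, c("id", "vgll3", "six6", "sex")],
                  family = NA_character_, is_parent = TRUE),
    dplyr::mutate(offspring[, c("id", "vgll3", "six6", "sex", "family")],
                  is_parent = FALSE)
  )
  list(pedigree = pedigree, genotypes = genotypes,
       families = crosses[, c("unit", "family", "sire", "dam")])
}

#' Simulate trait values and covariates with known ground truth
#'
#' Generates, for every offspring: tank (balanced random), feed treatment
#' (restricted in half the tanks), bimodal fork length, weight via a
#' Fulton-condition draw, and a trait following the animal-model equation --
#' fixed effects on scaled length, scaled condition factor, feed, sex and
#' the two loci; random effects `animal` (covariance `V_animal * A` via the
#' Cholesky factor of the pedigree relationship matrix, shared polygenic
#' background), `tank`, `id`, and replicate-level `error`. A configured
#' fraction of individuals is measured twice. Missing genotypes/sex and
#' mature males are planted among upper-mode fish in mutually disjoint sets.
#'
#' @param breeding Result of [simulate_breeding()].
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @return A `trait_tbl` (trait name `"synthetic_trait"`) with all model
#'   covariates; the ground-truth record is attached as attribute
#'   `"truth"` (see [simulation_truth()]).
#' @export
simulate_traits <- function(breeding, config = simulation_config(), seed = 1L) {
  set.seed(seed)
  geno <- breeding$genotypes
  off <- geno[!geno$is_parent, ]
  n <- nrow(off)
  tank <- sample(rep_len(seq_len(config$n_tanks), n))
  feed <- ifelse(tank <= config$n_tanks / 2, "ad_libitum", "restricted")
  lower <- stats::runif(n) < config$length_lower_weight
  fork_length <- ifelse(
    lower,
    stats::rnorm(n, config$length_lower_mean, config$length_lower_sd),
    stats::rnorm(n, config$length_upper_mean, config$length_upper_sd)
  )
  fork_length <- pmax(fork_length, 4)
  K <- stats::rnorm(n, config$condition_mean, config$condition_sd)
  weight <- K * fork_length^3 / 100

  # random effects
  A <- additive_relationship_matrix(breeding$pedigree)
  La <- t(chol(A + diag(1e-10, nrow(A))))
  a_all <- sqrt(config$varcomp[["animal"]]) * as.numeric(La %*% stats::rnorm(nrow(A)))
  names(a_all) <- rownames(A)
  tank_eff <- stats::rnorm(config$n_tanks, 0, sqrt(config$varcomp[["tank"]]))
  id_eff <- stats::rnorm(n, 0, sqrt(config$varcomp[["id"]]))

  Ls <- scale_covariate(fork_length)
  CFs <- scale_covariate(fulton_condition_factor(weight, fork_length))
  b <- config$beta
  fixed_part <- config$mu + b[["L"]] * Ls + b[["CF"]] * CFs +
    b[["feed"]] * (feed == "restricted") + b[["sex"]] * (off$sex == "male") +
    b[["vgll3"]] * off$vgll3 + b[["six6"]] * off$six6
  if (!is.null(config$dominance)) {
    for (locus in names(config$dominance)) {
      fixed_part <- fixed_part + config$dominance[[locus]] * (off[[locus]] == 1L)
    }
  }
  if (!is.null(config$interaction)) {
    for (locus in names(config$interaction)) {
      fixed_part <- fixed_part + config$interaction[[locus]] * Ls * off[[locus]]
    }
  }
  latent <- fixed_part + a_all[off$id] + tank_eff[tank] + id_eff

  n_rep <- 1L + (stats::runif(n) < config$replicate_fraction)
  rows <- tibble::tibble(
    specimen_id = rep(off$id, n_rep),
    plane = "body",
    replicate = purrr::list_c(purrr::map(n_rep, seq_len)),
    trait = "synthetic_trait",
    latent = rep(latent, n_rep)
  )
  rows$value <- rows$latent + stats::rnorm(nrow(rows), 0, sqrt(config$varcomp[["error"]]))
  rows$latent <- NULL

  ind <- tibble::tibble(
    id = off$id, family = off$family, unit = off$family, tank = tank, feed = feed,
    fork_length = fork_length, weight = weight, sex = off$sex,
    vgll3 = off$vgll3, six6 = off$six6, mature_male = FALSE
  )
  ind$unit <- NULL

  # plant exclusions among upper-mode fish, disjoint sets, study counts
  eligible <- which(ind$fork_length >= 9)
  n_plant <- config$n_missing_vgll3 + config$n_missing_six6 +
    config$n_missing_sex + config$n_mature_males
  if (n_plant > length(eligible)) {
    stop("planted exclusion counts (", n_plant, ") exceed the ",
         length(eligible), " upper-mode fish; reduce the n_missing_*/",
         "n_mature_males config fields for small designs", call. = FALSE)
  }
  planted <- sample(eligible, n_plant)
  idx <- split(planted, rep(c("vgll3", "six6", "sex", "mature"),
                            c(config$n_missing_vgll3, config$n_missing_six6,
                              config$n_missing_sex, config$n_mature_males)))
  ind$vgll3[idx$vgll3] <- NA_integer_
  ind$six6[idx$six6] <- NA_integer_
  ind$sex[idx$sex] <- NA_character_
  ind$mature_male[idx$mature] <- TRUE

  out <- build_trait_table(rows, ind)
  attr(out, "truth") <- simulation_truth(config, off, ind)
  out
}

#' Ground truth record for a simulated trait table
#'
#' Collects the planted parameter values and the derived true summaries the
#' recovery tests compare against: total additive genetic variance
#' (polygenic plus realised locus contributions `2 p q beta^2`),
#' heritability, repeatability, and the expected filter audit computed with
#' the same rule precedence the filter uses.
#'
#' @param config The `sim_config` used.
#' @param offspring Offspring genotype tibble (true codes, before planting
#'   missingness).
#' @param individuals The per-individual table with planted missingness.
#' @return A list; also attached to [simulate_traits()] output as attribute
#'   `"truth"`.
#' @export
simulation_truth <- function(config, offspring, individuals) {
  vc <- config$varcomp
  locus_var <- function(locus) {
    fr <- allele_frequencies(offspring[[locus]])
    2 * fr$freq_L * fr$freq_E * config$beta[[locus]]^2
  }
  V_locus <- c(vgll3 = locus_var("vgll3"), six6 = locus_var("six6"))
  V_A <- vc[["animal"]] + sum(V_locus)
  keep <- rep(TRUE, nrow(individuals))
  audit <- list()
  claim <- function(bad, rule) {
    bad <- bad & keep
    audit[[rule]] <<- sum(bad)
    keep <<- keep & !bad
  }
  claim(individuals$fork_length < 9, "short_length")
  claim(is.na(individuals$vgll3), "missing_vgll3")
  claim(is.na(individuals$six6), "missing_six6")
  claim(is.na(individuals$sex), "missing_sex")
  claim(individuals$mature_male, "mature_male")
  list(
    mu = config$mu, beta = config$beta, varcomp = vc,
    V_locus = V_locus, V_A = V_A,
    h2 = if (V_A + vc[["tank"]] + vc[["id"]] > 0)
      V_A / (V_A + vc[["tank"]] + vc[["id"]]) else NA_real_,
    h2_polygenic = if (vc[["animal"]] + vc[["tank"]] + vc[["id"]] > 0)
      heritability(vc[["animal"]], vc[["tank"]], vc[["id"]]) else NA_real_,
    repeatability = if (vc[["id"]] + vc[["error"]] > 0)
      repeatability_pct(vc[["id"]], vc[["error"]]) else NA_real_,
    pct_VA = 100 * V_locus / V_A,
    expected_audit = tibble::tibble(rule = names(audit),
                                    n_removed = unlist(audit, use.names = FALSE)),
    n_retained = sum(keep)
  )
}

# Landmark templates (cm, for a 12.5 cm reference fish); 0-based indices
# match the default trait definitions.
landmark_template <- function(plane) {
  switch(plane,
    body = matrix(c(
      0.00, 0.00,    # 0 snout tip
      1.10, 0.15,    # 1 eye centre
      0.85, 0.15,    # 2 orbit anterior
      1.40, 0.15,    # 3 orbit posterior
      1.10, 0.42,    # 4 orbit dorsal
      1.10, -0.12,   # 5 orbit ventral
      0.30, -0.40,   # 6 ventral head point
      2.60, 0.00,    # 7 operculum posterior
      2.20, -0.75,   # 8 operculum ventral
      2.30, 0.75,    # 9 operculum dorsal
      3.00, -0.90,   # 10 pectoral fin anterior insertion
      4.20, -1.10,   # 11 pectoral fin tip
      5.20, 1.10,    # 12 dorsal fin anterior
      6.80, 1.20,    # 13 dorsal fin posterior
      6.00, -1.10,   # 14 pelvic fin
      9.20, 0.75,    # 15 adipose fin / peduncle anterior
      7.80, -1.00,   # 16 anal fin anterior
      8.90, -0.85,   # 17 anal fin posterior
      10.80, 0.40,   # 18 caudal peduncle end
      11.20, 0.00,   # 19 tail fin insertion
      12.40, 0.00    # 20 tail fin tip
    ), ncol = 2L, byrow = TRUE),
    small_xsec = matrix(c(
      0.00, 0.65, 0.00, -0.65, 0.00, 0.00, -0.12, 0.00, 0.12, 0.00,
      -0.55, 0.00, -0.73, 0.00, 0.55, 0.00, 0.73, 0.00
    ), ncol = 2L, byrow = TRUE),
    large_xsec = matrix(c(
      0.00, 1.05, 0.00, -1.05, 0.75, 0.70, 0.75, -0.70, -0.75, 0.70,
      -0.75, -0.70, -0.125, 0.00, 0.125, 0.00, 1.00, 0.00, 1.23, 0.00,
      1.00, 0.44, 1.00, -0.44, -1.00, 0.00, -1.235, 0.00, -1.00, 0.44,
      -1.00, -0.44
    ), ncol = 2L, byrow = TRUE),
    stop("unknown plane: ", plane, call. = FALSE)
  )
}

# Per-allele-dose displacement fields (cm): six6 elongates the head on the
# body plane; vgll3 narrows the small cross-section outline.
displacement_field <- function(plane, locus) {
  k <- nrow(landmark_template(plane))
  D <- matrix(0, k, 2L)
  if (plane == "body" && locus == "six6") {
    D[1, 1] <- -0.040                      # snout tip forward
    D[2:6, 1] <- -0.020                    # eye region forward
    D[7, 1] <- -0.010
  }
  if (plane == "small_xsec" && locus == "vgll3") {
    tmpl <- landmark_template(plane)
    # pull the lateral outline landmarks (0-based 5-8) toward the midline
    D[c(6, 7, 8, 9), 1] <- -0.010 * sign(tmpl[c(6, 7, 8, 9), 1])
  }
  D
}

#' Simulate landmark configurations consistent with a covariate table
#'
#' Each specimen's configuration is the plane template scaled
#' allometrically by fork length, displaced by the planted per-locus
#' genotype fields, jittered by an individual deviation field (shared across
#' replicates; the source of individual variance in derived traits) and by
#' digitising noise (per replicate; the source of measurement error), then
#' rigidly rotated and translated. A configured fraction of specimens is
#' landmarked twice; optional gross corruption (two landmarks displaced by
#' `corrupt_magnitude`) and missing landmarks exercise the quality filters.
#'
#' @param individuals Per-individual tibble with `id`, `fork_length`,
#'   `vgll3`, `six6` (missing genotypes contribute no displacement).
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @param planes Planes to generate.
#' @return A `landmark_tbl` across the requested planes, with attribute
#'   `"corrupted"` naming the configurations given gross corruption.
#' @export
simulate_landmarks <- function(individuals, config = simulation_config(), seed = 1L,
                               planes = c("body", "small_xsec", "large_xsec")) {
  set.seed(seed)
  out <- list()
  corrupted <- character(0)
  ref_len <- config$length_upper_mean
  for (plane in planes) {
    tmpl <- landmark_template(plane)
    k <- nrow(tmpl)
    Dv <- displacement_field(plane, "vgll3")
    Ds <- displacement_field(plane, "six6")
    n_rep <- 1L + (stats::runif(nrow(individuals)) < config$landmark_replicate_fraction)
    corrupt_pick <- if (config$n_corrupt_configs > 0L) {
      sample(nrow(individuals), min(config$n_corrupt_configs, nrow(individuals)))
    } else integer(0)
    blocks <- purrr::map(seq_len(nrow(individuals)), function(i) {
      ind <- individuals[i, ]
      scale_i <- ind$fork_length / ref_len
      vg <- if (is.na(ind$vgll3)) 0 else ind$vgll3
      sx <- if (is.na(ind$six6)) 0 else ind$six6
      base <- (tmpl + vg * Dv + sx * Ds) * scale_i
      indiv <- matrix(stats::rnorm(2L * k, 0, config$landmark_individual_sd), k, 2L)
      purrr::map(seq_len(n_rep[i]), function(r) {
        m <- base + indiv +
          matrix(stats::rnorm(2L * k, 0, config$landmark_noise_sd), k, 2L)
        if (i %in% corrupt_pick && r == 1L) {
          lms <- sample(k, 2L)
          m[lms, ] <- m[lms, ] + config$corrupt_magnitude
          corrupted <<- c(corrupted, paste(ind$id, plane, sep = "/"))
        }
        th <- stats::runif(1, -pi / 18, pi / 18)
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
        m <- m %*% R + matrix(stats::runif(2, -1, 1), k, 2L, byrow = TRUE)
        if (config$landmark_missing_rate > 0) {
          drop <- stats::runif(k) < config$landmark_missing_rate
          m[drop, ] <- NA_real_
        }
        tibble::tibble(specimen_id = ind$id, plane = plane, replicate = r,
                       landmark = 0:(k - 1L), x = m[, 1L], y = m[, 2L])
      })
    })
    out[[plane]] <- dplyr::bind_rows(purrr::list_flatten(blocks))
  }
  res <- validate_landmark_tbl(dplyr::bind_rows(out))
  attr(res, "corrupted") <- unique(corrupted)
  res
}

#' Simulate a complete dataset (breeding, traits, optional landmarks)
#'
#' @param config A `sim_config`.
#' @param seed Integer seed; sub-stages use `seed`, `seed + 1`, `seed + 2`.
#' @param landmarks Also generate landmark configurations (slower).
#' @return A list with `breeding`, `traits` (a `trait_tbl` with the
#'   `"truth"` attribute), `individuals`, and optionally `landmarks`.
#' @export
simulate_dataset <- function(config = simulation_config(), seed = 1L,
                             landmarks = FALSE) {
  breeding <- simulate_breeding(config, seed)
  traits <- simulate_traits(breeding, config, seed + 1L)
  individuals <- dplyr::distinct(
    traits[, c("specimen_id", "family", "tank", "feed", "fork_length", "weight",
               "sex", "vgll3", "six6", "mature_male")]
  )
  individuals <- dplyr::rename(individuals, id = "specimen_id")
  out <- list(breeding = breeding, traits = traits, individuals = individuals)
  if (landmarks) {
    out$landmarks <- simulate_landmarks(individuals, config, seed + 2L)
  }
  out
}
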