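test_that("the factorial breeding design matches the study structure", {
  br <- simulate_breeding(simulation_config(), seed = 1)
  geno <- br$genotypes
  parents <- geno[geno$is_parent, ]
  expect_equal(nrow(parents), 44L)
  expect_equal(nrow(br$families), 44L)
  # per unit: one EE and one LL parent per sex at vgll3
  per_unit <- dplyr::count(parents,
                           unit = sub("_.*", "", parents$id), sex, vgll3)
  expect_true(all(per_unit$n == 1L))
  # offspring vgll3 is determined by the cross of homozygous parents
  off <- geno[!geno$is_parent, ]
  fam <- dplyr::inner_join(off, br$families, by = "family")
  ee <- fam[grepl("EE$", fam$family), ]
  ll <- fam[grepl("LL$", fam$family), ]
  het <- fam[grepl("(EL|LE)$", fam$family), ]
  expect_true(all(ee$vgll3 == 0L))
  expect_true(all(ll$vgll3 == 2L))
  expect_true(all(het$vgll3 == 1L))
  # pedigree is valid and covers everyone
  A <- additive_relationship_matrix(br$pedigree)
  expect_true(all(geno$id %in% rownames(A)))
})

test_that("six6 segregation follows Mendelian expectations", {
  cfg <- simulation_config(offspring_per_family = 200L, n_units = 2L,
                           six6_parent_freq_L = 0.5)
  br <- simulate_breeding(cfg, seed = 5)
  off <- br$genotypes[!br$genotypes$is_parent, ]
  fam <- dplyr::inner_join(off, br$families, by = "family")
  parents <- br$genotypes[br$genotypes$is_parent, ]
  code <- stats::setNames(parents$six6, parents$id)
  pvals <- purrr::map_dbl(unique(fam$family), function(f) {
    rows <- fam[fam$family == f, ]
    s <- code[[rows$sire[1]]]; d <- code[[rows$dam[1]]]
    # transmission probabilities for each parent
    pr <- function(g) c(`0` = c(1, 0.5, 0)[g + 1], `1` = c(0, 0.5, 1)[g + 1])
    probs <- outer(pr(s), pr(d))  # offspring L-allele counts 0/1/1/2
    expected <- c(probs[1, 1], probs[1, 2] + probs[2, 1], probs[2, 2])
    obs <- tabulate(rows$six6 + 1L, 3L)
    keep <- expected > 0
    if (sum(keep) == 1L) return(1)
    suppressWarnings(stats::chisq.test(obs[keep], p = expected[keep])$p.value)
  })
  expect_gt(min(pvals), 0.01 / length(pvals))
})

test_that("the generator is deterministic given the seed", {
  cfg <- simulation_config(offspring_per_family = 5L, n_units = 3L)
  a <- simulate_dataset(cfg, seed = 4, landmarks = TRUE)
  b <- simulate_dataset(cfg, seed = 4, landmarks = TRUE)
  expect_identical(a$traits$value, b$traits$value)
  expect_identical(a$landmarks, b$landmarks)
  c <- simulate_dataset(cfg, seed = 5)
  expect_false(identical(a$traits$value, c$traits$value))
})

test_that("degenerate settings produce a constant trait", {
  cfg <- simulation_config(
    offspring_per_family = 4L, n_units = 2L,
    beta = c(L = 0, CF = 0, feed = 0, sex = 0, vgll3 = 0, six6 = 0),
    varcomp = c(animal = 0, tank = 0, id = 0, error = 0),
    n_missing_vgll3 = 0L, n_missing_six6 = 0L, n_missing_sex = 0L,
    n_mature_males = 0L
  )
  sim <- simulate_dataset(cfg, seed = 2)
  expect_equal(unique(sim$traits$value), cfg$mu)
})

test_that("planted allele-substitution effects appear in genotype means", {
  cfg <- simulation_config(offspring_per_family = 40L,
                           varcomp = c(animal = 0, tank = 0, id = 0.001,
                                       error = 0.001))
  diffs <- purrr::map_dbl(1:5, function(s) {
    sim <- simulate_dataset(cfg, seed = 200 + s)
    tt <- sim$traits[!duplicated(sim$traits$specimen_id), ]
    mean(tt$value[tt$vgll3 == 2], na.rm = TRUE) -
      mean(tt$value[tt$vgll3 == 0], na.rm = TRUE)
  })
  expect_lt(abs(mean(diffs) - 2 * simulation_config()$beta[["vgll3"]]), 0.015)
})

test_that("full sibs covary at half the planted additive genetic variance", {
  cfg <- simulation_config(offspring_per_family = 2L,
                           beta = c(L = 0, CF = 0, feed = 0, sex = 0,
                                    vgll3 = 0, six6 = 0),
                           varcomp = c(animal = 0.4, tank = 0, id = 0, error = 1e-8),
                           replicate_fraction = 0)
  pairs <- purrr::map(1:40, function(s) {
    sim <- simulate_dataset(cfg, seed = 300 + s)
    tt <- sim$traits
    wide <- tidyr::pivot_wider(
      dplyr::mutate(dplyr::group_by(tt, .data$family),
                    pos = dplyr::row_number()),
      id_cols = "family", names_from = "pos", values_from = "value"
    )
    as.matrix(wide[, c("1", "2")])
  })
  m <- do.call(rbind, pairs)
  cc <- stats::cov(m[, 1], m[, 2])
  expect_equal(cc, 0.2, tolerance = 0.06)
})

test_that("simulated landmarks reduce to the template without noise or effects", {
  cfg <- simulation_config(landmark_noise_sd = 0, landmark_individual_sd = 0,
                           landmark_missing_rate = 0,
                           landmark_replicate_fraction = 0)
  ind <- tibble::tibble(id = paste0("f", 1:4), fork_length = c(10, 11, 12, 13),
                        vgll3 = 0L, six6 = 0L)
  lm <- simulate_landmarks(ind, cfg, seed = 1, planes = "body")
  g <- gpa_align(lm)
  expect_lt(utils::tail(g$objective_trace, 1), 1e-16)
})

test_that("planted landmark corruption is caught by the outlier filter", {
  cfg <- simulation_config(n_corrupt_configs = 1L, corrupt_magnitude = 1.5,
                           landmark_missing_rate = 0,
                           landmark_noise_sd = 0.01, landmark_individual_sd = 0.015)
  ind <- tibble::tibble(id = sprintf("f%03d", 1:120),
                        fork_length = stats::rnorm(120, 12, 1),
                        vgll3 = 1L, six6 = 1L)
  lm <- simulate_landmarks(ind, cfg, seed = 8, planes = "body")
  corrupted <- attr(lm, "corrupted")
  expect_length(corrupted, 1L)
  flags <- flag_outlier_configurations(gpa_align(lm))
  flagged <- flags[flags$exclude, ]
  expect_true(sub("/.*", "", corrupted) %in% flagged$specimen_id)
})

test_that("planted missing landmarks appear and are imputable", {
  cfg <- simulation_config(landmark_missing_rate = 0.01,
                           landmark_replicate_fraction = 0)
  ind <- tibble::tibble(id = sprintf("f%03d", 1:80),
                        fork_length = stats::rnorm(80, 12, 1),
                        vgll3 = 1L, six6 = 1L)
  lm <- simulate_landmarks(ind, cfg, seed = 3, planes = "small_xsec")
  expect_gt(sum(is.na(lm$x)), 0)
  imp <- impute_missing_landmarks(lm)
  expect_false(anyNA(imp$x))
})

test_that("the ground-truth audit matches the filter on the same data", {
  sim <- simulate_dataset(simulation_config(), seed = 21)
  truth <- attr(sim$traits, "truth")
  audit <- filter_audit(filter_individuals(sim$individuals))
  expect_identical(audit, truth$expected_audit)
  expect_identical(audit$n_removed[audit$rule == "missing_six6"], 12L)
  expect_identical(audit$n_removed[audit$rule == "mature_male"], 19L)
})
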