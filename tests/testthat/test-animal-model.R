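test_that("fixed-effects-only fits equal ordinary least squares", {
  set.seed(1)
  n <- 80
  d <- tibble::tibble(specimen_id = paste0("i", 1:n),
                      x1 = stats::rnorm(n), x2 = stats::rnorm(n))
  d$value <- 1 + 2 * d$x1 - 0.5 * d$x2 + stats::rnorm(n)
  fit <- fit_animal_model(d, fixed = ~ x1 + x2, random = character(0), method = "ML")
  ols <- stats::lm(value ~ x1 + x2, data = d)
  expect_equal(fit$coefficients$estimate, unname(stats::coef(ols)), tolerance = 1e-8)
  # ML log-likelihood matches stats::logLik for the linear model
  expect_equal(fit$loglik, as.numeric(stats::logLik(ols)), tolerance = 1e-8)
})

test_that("balanced one-way REML equals the closed-form ANOVA estimator", {
  for (s in 1:3) {
    set.seed(100 + s)
    a <- 12; n0 <- 6
    group <- rep(paste0("g", 1:a), each = n0)
    y <- rep(stats::rnorm(a, 0, 1.3), each = n0) + stats::rnorm(a * n0, 0, 0.8)
    d <- tibble::tibble(specimen_id = group, value = y)
    fit <- fit_animal_model(d, fixed = ~ 1, random = "id", method = "REML")
    oracle <- anova_varcomp(y, group)
    expect_equal(fit$varcomp[["id"]], unname(oracle["between"]), tolerance = 1e-6)
    expect_equal(fit$varcomp[["error"]], unname(oracle["within"]), tolerance = 1e-6)
  }
})

test_that("REML/ML match lme4 with an identity relationship matrix", {
  skip_if_not_installed("lme4")
  set.seed(7)
  n_id <- 50
  ped <- founder_pedigree(paste0("i", 1:n_id))
  rel <- additive_relationship_inverse(ped)
  d <- tibble::tibble(specimen_id = rep(ped$id, each = 2),
                      x = rep(stats::rnorm(n_id), each = 2))
  u <- stats::rnorm(n_id, 0, 1.2)
  d$value <- 1 + 0.6 * d$x + u[match(d$specimen_id, ped$id)] +
    stats::rnorm(nrow(d), 0, 0.6)
  for (method in c("REML", "ML")) {
    fit <- fit_animal_model(d, fixed = ~ x, random = "animal",
                            relationship = rel, method = method)
    lf <- lme4::lmer(value ~ x + (1 | specimen_id), data = d,
                     REML = method == "REML")
    expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
    expect_equal(unname(fit$varcomp),
                 unname(c(as.data.frame(lme4::VarCorr(lf))$vcov)),
                 tolerance = 1e-4)
    expect_equal(fit$coefficients$estimate, unname(lme4::fixef(lf)),
                 tolerance = 1e-6)
    expect_equal(fit$coefficients$se,
                 unname(sqrt(diag(as.matrix(stats::vcov(lf))))), tolerance = 1e-4)
  }
})

test_that("with identity A and one row per individual, animal == iid individual", {
  set.seed(9)
  n <- 70
  ped <- founder_pedigree(paste0("i", 1:n))
  d <- tibble::tibble(specimen_id = ped$id, x = stats::rnorm(n))
  d$value <- 2 + d$x + stats::rnorm(n, 0, 1) + stats::rnorm(n, 0, 0.8)
  f_animal <- fit_animal_model(d, fixed = ~ x, random = "animal",
                               relationship = additive_relationship_inverse(ped),
                               method = "REML")
  f_id <- fit_animal_model(d, fixed = ~ x, random = "id", method = "REML")
  expect_equal(f_animal$loglik, f_id$loglik, tolerance = 1e-6)
  expect_equal(unname(f_animal$varcomp[["animal"]]), unname(f_id$varcomp[["id"]]),
               tolerance = 1e-4)
  expect_equal(f_animal$coefficients$estimate, f_id$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("a zero variance component lands at the boundary without failure", {
  set.seed(3)
  n <- 60
  ped <- founder_pedigree(paste0("i", 1:n))
  d <- tibble::tibble(specimen_id = rep(ped$id, each = 2))
  d$value <- stats::rnorm(nrow(d))  # no individual or genetic signal at all
  fit <- fit_animal_model(d, fixed = ~ 1, random = c("id", "animal"),
                          relationship = additive_relationship_inverse(ped),
                          method = "REML")
  expect_lt(fit$varcomp[["animal"]], 0.05)
  expect_true(all(fit$varcomp >= 0))
})

test_that("unmatched individuals and rank-deficient designs raise errors", {
  ped <- founder_pedigree(c("a", "b"))
  d <- tibble::tibble(specimen_id = c("a", "b", "zz"), value = c(1, 2, 3))
  expect_error(
    fit_animal_model(d, fixed = ~ 1, random = "animal",
                     relationship = additive_relationship_inverse(ped)),
    "absent from the relationship"
  )
  d2 <- tibble::tibble(specimen_id = paste0("i", 1:20), x = stats::rnorm(20))
  d2$dup <- d2$x
  d2$value <- stats::rnorm(20)
  expect_error(fit_animal_model(d2, fixed = ~ x + dup, random = character(0)),
               "aliased")
})

test_that("Satterthwaite df reduce to classical values", {
  # no variance parameters: df = n - p exactly
  set.seed(4)
  n <- 40
  d <- tibble::tibble(specimen_id = paste0("i", 1:n), x = stats::rnorm(n))
  d$value <- 1 + d$x + stats::rnorm(n)
  fit <- fit_animal_model(d, fixed = ~ x, random = character(0), method = "REML")
  st <- satterthwaite_type3(fit)
  expect_equal(st$df_den, rep(n - 2, nrow(st)), tolerance = 1e-4)
  # classical balanced two-group comparison: df = n1 + n2 - 2
  d2 <- tibble::tibble(specimen_id = paste0("i", 1:n),
                       g = rep(c("a", "b"), each = n / 2))
  d2$value <- stats::rnorm(n) + (d2$g == "b")
  fit2 <- fit_animal_model(d2, fixed = ~ g, random = character(0), method = "REML")
  st2 <- satterthwaite_type3(fit2)
  expect_equal(st2$df_den[st2$term == "g"], n - 2, tolerance = 1e-4)
  tt <- stats::t.test(value ~ g, data = d2, var.equal = TRUE)
  expect_equal(st2$F[st2$term == "g"], unname(tt$statistic)^2, tolerance = 1e-8)
})

test_that("Satterthwaite df match the classical split-plot denominator", {
  # whole-plot treatment applied to tanks: classical df = n_tanks - 2
  set.seed(11)
  n_tank <- 10; per <- 8
  d <- tibble::tibble(
    specimen_id = paste0("i", 1:(n_tank * per)),
    tank = rep(paste0("t", 1:n_tank), each = per),
    trt = rep(c("ctl", "trt"), each = per * n_tank / 2)
  )
  d$value <- 0.5 * (d$trt == "trt") +
    rep(stats::rnorm(n_tank, 0, 1), each = per) + stats::rnorm(nrow(d), 0, 0.5)
  fit <- fit_animal_model(d, fixed = ~ trt, random = "tank", method = "REML")
  st <- satterthwaite_type3(fit)
  expect_equal(st$df_den[st$term == "trt"], n_tank - 2, tolerance = 0.5)
  skip_if_not_installed("lme4")
  lf <- lme4::lmer(value ~ trt + (1 | tank), data = d, REML = TRUE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
})

test_that("AIC model comparison distinguishes additive from dominant loci", {
  set.seed(22)
  n <- 400
  ped <- founder_pedigree(paste0("i", 1:n))
  rel <- additive_relationship_inverse(ped)
  base <- tibble::tibble(
    specimen_id = ped$id,
    vgll3 = sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25)),
    six6 = sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  )
  # purely additive data: the extra factor parameter is not supported
  d_add <- dplyr::mutate(base, value = 0.3 * vgll3 + stats::rnorm(n, 0, 0.5))
  cmp_add <- compare_additive_dominance(d_add, locus = "vgll3", fixed = ~ vgll3 + six6,
                                        random = character(0))
  expect_false(cmp_add$meaningful)
  expect_lt(cmp_add$delta, 2)
  # full dominance (EL behaves like LL): factor/dominance model preferred
  d_dom <- dplyr::mutate(base, value = 0.5 * (vgll3 >= 1) + stats::rnorm(n, 0, 0.5))
  cmp_dom <- compare_additive_dominance(d_dom, locus = "vgll3", fixed = ~ vgll3 + six6,
                                        random = character(0))
  expect_true(cmp_dom$meaningful)
  expect_identical(cmp_dom$models$model,
                   c("additive", "factor", "het_as_LL", "het_as_EE"))
  # the matching constrained coding wins among the dominance variants
  aics <- cmp_dom$models$AIC
  expect_lt(aics[cmp_dom$models$model == "het_as_LL"],
            aics[cmp_dom$models$model == "het_as_EE"])
})

test_that("length-by-genotype interaction is detected when planted, not otherwise", {
  set.seed(33)
  n <- 500
  ped <- founder_pedigree(paste0("i", 1:n))
  base <- tibble::tibble(
    specimen_id = ped$id, L = stats::rnorm(n),
    vgll3 = sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25)),
    six6 = sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  )
  d0 <- dplyr::mutate(base, value = 0.2 * L - 0.1 * vgll3 + stats::rnorm(n, 0, 0.4))
  r0 <- length_genotype_interaction(d0, fixed = ~ L + vgll3 + six6,
                                    random = character(0))
  expect_true(all(abs(r0$interaction_tests$t) < 4))
  expect_lt(max(abs(r0$main_effect_shift$shift)), 0.1)
  d1 <- dplyr::mutate(base, value = 0.2 * L - 0.1 * vgll3 + 0.3 * L * vgll3 +
                        stats::rnorm(n, 0, 0.4))
  r1 <- length_genotype_interaction(d1, fixed = ~ L + vgll3 + six6,
                                    random = character(0))
  expect_gt(abs(r1$interaction_tests$t[r1$interaction_tests$term == "L:vgll3"]), 2)
})
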