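test_that("Pillai's trace reduces to eta-squared for one response", {
  expect_equal(pillai_trace(matrix(3), matrix(1)), 0.75)
  expect_equal(pillai_trace(matrix(0), matrix(2)), 0)
  for (s in 1:50) {
    set.seed(s)
    n <- sample(15:40, 1)
    g <- factor(sample(letters[1:3], n, replace = TRUE))
    y <- stats::rnorm(n)
    a <- stats::anova(stats::lm(y ~ g))
    eta2 <- a$`Sum Sq`[1] / sum(a$`Sum Sq`)
    fit <- suppressWarnings(
      fit_shape_model(tibble::tibble(g = g, r = y), ~ g, response = "r",
                      permutations = 5, seed = s)
    )
    expect_equal(fit$terms$pillai, eta2, tolerance = 1e-10)
  }
})

test_that("Pillai's trace equals the eigenvalue-sum oracle and stats::manova", {
  set.seed(21)
  n <- 50
  d <- tibble::tibble(g = factor(sample(c("a", "b", "c"), n, replace = TRUE)),
                      r1 = stats::rnorm(n), r2 = stats::rnorm(n))
  fit <- suppressWarnings(fit_shape_model(d, ~ g, response = c("r1", "r2"),
                                          permutations = 5, seed = 1))
  mv <- summary(stats::manova(cbind(r1, r2) ~ g, data = d), test = "Pillai")
  expect_equal(fit$terms$pillai, mv$stats["g", "Pillai"], tolerance = 1e-10)
  # direct eigen oracle: sum lambda_i / (1 + lambda_i) for eigen(H E^-1)
  X <- stats::model.matrix(~ g, d)
  Y <- as.matrix(d[, c("r1", "r2")])
  q <- qr(X)
  E <- crossprod(Y - qr.fitted(q, Y))
  H <- crossprod(sweep(Y, 2, colMeans(Y))) - E
  lam <- eigen(H %*% solve(E))$values
  expect_equal(fit$terms$pillai, sum(Re(lam) / (1 + Re(lam))), tolerance = 1e-8)
})

test_that("type-III marginal SS equals sequential SS in balanced orthogonal designs", {
  set.seed(5)
  d <- tidyr::expand_grid(a = factor(c("x", "y")), b = factor(c("p", "q")),
                          rep = 1:6)
  d$r1 <- stats::rnorm(nrow(d)); d$r2 <- stats::rnorm(nrow(d))
  fit <- suppressWarnings(fit_shape_model(d, ~ a + b, response = c("r1", "r2"),
                                          permutations = 5, seed = 1))
  # sequential (type-I) SSCP via successive model comparisons, both orders
  for (term in c("a", "b")) {
    X0 <- stats::model.matrix(stats::reformulate(setdiff(c("a", "b"), term)), d)
    X1 <- stats::model.matrix(~ a + b, d)
    Y <- as.matrix(d[, c("r1", "r2")])
    E0 <- crossprod(Y - qr.fitted(qr(X0), Y))
    E1 <- crossprod(Y - qr.fitted(qr(X1), Y))
    expect_equal(fit$terms$pillai[fit$terms$term == term],
                 pillai_trace(E0 - E1, E1, warn = FALSE), tolerance = 1e-12)
  }
})

test_that("shape-model design checks catch rank deficiency", {
  set.seed(9)
  d <- tibble::tibble(x = stats::rnorm(20), r = stats::rnorm(20))
  d$x2 <- d$x  # aliased copy
  suppressWarnings(
    expect_error(fit_shape_model(d, ~ x + x2, response = "r",
                                 permutations = 5, seed = 1),
                 "aliased")
  )
  # intercept-only fitted values are column means
  f0 <- suppressWarnings(
    fit_shape_model(d, ~ 1, response = "r", permutations = 5, seed = 1)
  )
  expect_equal(unique(as.numeric(round(f0$fitted, 12))), round(mean(d$r), 12))
})

test_that("RRPP p-values respect the permutation floor and reproduce by seed", {
  set.seed(31)
  n <- 40
  d <- tibble::tibble(g = factor(rep(c("a", "b"), each = n / 2)),
                      r = c(stats::rnorm(n / 2), stats::rnorm(n / 2, 5)))
  fit <- fit_shape_model(d, ~ g, response = "r", permutations = 199, seed = 4)
  expect_equal(fit$terms$p, 1 / 200)  # observed beats every permutation
  expect_gte(fit$terms$p, 1 / (fit$permutations + 1))
  fit2 <- fit_shape_model(d, ~ g, response = "r", permutations = 199, seed = 4)
  expect_identical(fit$terms, fit2$terms)  # bit-for-bit given the seed
  fit3 <- fit_shape_model(d, ~ g, response = "r", permutations = 199, seed = 5)
  expect_false(identical(fit$terms$z, fit3$terms$z))
  expect_warning(fit_shape_model(d, ~ g, response = "r", permutations = 19, seed = 1),
                 "unstable")
})

test_that("RRPP p-values are roughly uniform under the null", {
  ps <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    d <- tibble::tibble(x = stats::rnorm(30),
                        r1 = stats::rnorm(30), r2 = stats::rnorm(30))
    suppressWarnings(
      fit_shape_model(d, ~ x, response = c("r1", "r2"),
                      permutations = 59, seed = s)$terms$p
    )
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps <= 0.05), 0.15)
})

test_that("z standard deviates respond to signal and support the log option", {
  set.seed(12)
  n <- 60
  d <- tibble::tibble(g = factor(rep(c("a", "b"), each = n / 2)))
  d$r1 <- stats::rnorm(n) + 2 * (d$g == "b")
  d$r2 <- stats::rnorm(n)
  f <- fit_shape_model(d, ~ g, response = c("r1", "r2"),
                       permutations = 199, seed = 2)
  expect_gt(f$terms$z, 3)
  flog <- fit_shape_model(d, ~ g, response = c("r1", "r2"),
                          permutations = 199, seed = 2, z_transform = "log")
  expect_gt(flog$terms$z, 2)
  expect_false(identical(f$terms$z, flog$terms$z))
})

test_that("shape effect vectors are linear in the contrast and magnification", {
  set.seed(17)
  n <- 50
  cons <- matrix(stats::rnorm(12), 6, 2)
  code <- sample(0:2, n, replace = TRUE)
  mats <- lapply(seq_len(n), function(i) {
    m <- cons
    m[2, 1] <- m[2, 1] + 0.1 * code[i]   # planted displacement at landmark 1
    m + matrix(stats::rnorm(12, 0, 0.01), 6, 2)
  })
  g <- gpa_align(lm_tbl(mats))
  dat <- dplyr::inner_join(shape_coordinates(g),
                           tibble::tibble(specimen_id = paste0("s", 1:n),
                                          vgll3 = code),
                           by = "specimen_id")
  fit <- suppressWarnings(
    fit_shape_model(dat, ~ vgll3, permutations = 49, seed = 1)
  )
  v10 <- shape_effect_vectors(fit, "vgll3", magnification = 10)
  v1 <- shape_effect_vectors(fit, "vgll3", magnification = 1)
  expect_equal(v10$dx, 10 * v1$dx)
  expect_equal(v10$dy, 10 * v1$dy)
  mag <- sqrt(v1$dx^2 + v1$dy^2)
  expect_equal(which.max(mag), 2L)  # largest displacement at the planted landmark
  expect_error(shape_effect_vectors(fit, "six6"), "not in the model")
  # zero-coefficient term gives zero vectors
  dat$noise <- stats::rnorm(n)
  fit2 <- suppressWarnings(fit_shape_model(dat, ~ vgll3 + noise,
                                           permutations = 9, seed = 1))
  v0 <- shape_effect_vectors(fit2, "noise")
  expect_lt(max(abs(c(v0$dx, v0$dy))), 0.5)  # near zero, noise-level only
})
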