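#' Narrow-sense heritability
#'
#' `h2 = V_animal / (V_animal + V_tank + V_ID)`. Measurement error
#' (`V_error`) is deliberately excluded from the denominator: with repeated
#' measurements the individual term absorbs the biological residual, and
#' heritability refers to the individual-level phenotype.
#'
#' @param V_animal,V_tank,V_ID Non-negative variance components (trait
#'   units squared).
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(V_animal, V_tank, V_ID) {
  check_nonneg(V_animal, V_tank, V_ID)
  den <- V_animal + V_tank + V_ID
  if (any(den <= 0)) stop("zero denominator in heritability", call. = FALSE)
  V_animal / den
}

#' Percent repeatability of trait measurements
#'
#' `R = 100 * V_ID / (V_ID + V_error)`: the share of measurement variance
#' attributable to individuals rather than replicate measurement error.
#'
#' @param V_ID,V_error Non-negative variance components.
#' @return Percentage in `[0, 100]`.
#' @export
repeatability_pct <- function(V_ID, V_error) {
  check_nonneg(V_ID, V_error)
  den <- V_ID + V_error
  if (any(den <= 0)) stop("zero denominator in repeatability", call. = FALSE)
  100 * V_ID / den
}

#' Percent contribution of a biallelic locus to additive genetic variance
#'
#' `100 * 2 p q (beta^2 - se^2) / V_animal`, the sampling-bias-corrected
#' allele-substitution variance of the locus relative to the total additive
#' genetic variance; negative estimates are truncated to zero.
#'
#' @param beta Allele-substitution effect (E to L) from the
#'   genotype-including fit.
#' @param se_beta Its standard error.
#' @param freq_L,freq_E Allele frequencies (must sum to 1).
#' @param V_animal Total additive genetic variance (from the genotype-free
#'   model), must be positive.
#' @return Percentage (>= 0).
#' @export
locus_va_contribution <- function(beta, se_beta, freq_L, freq_E, V_animal) {
  if (any(V_animal <= 0)) stop("V_animal must be positive", call. = FALSE)
  if (any(abs(freq_L + freq_E - 1) > 1e-8) || any(freq_L < 0 | freq_L > 1)) {
    stop("allele frequencies must lie in [0, 1] and sum to 1", call. = FALSE)
  }
  pmax(0, 100 * 2 * freq_L * freq_E * (beta^2 - se_beta^2) / V_animal)
}

#' Evolvability (mean-standardised additive genetic variance)
#'
#' `I_A = V_A / mean^2`; unitless, interpreted as the expected proportional
#' response of the trait mean to unit selection.
#'
#' @param V_A Additive genetic variance (>= 0).
#' @param trait_mean Trait mean (non-zero).
#' @return `I_A` (>= 0).
#' @export
evolvability <- function(V_A, trait_mean) {
  check_nonneg(V_A)
  if (any(trait_mean == 0)) stop("trait mean must be non-zero", call. = FALSE)
  V_A / trait_mean^2
}

check_nonneg <- function(...) {
  vals <- c(...)
  if (any(vals < 0, na.rm = TRUE)) stop("variance components must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Simulation-based confidence interval for a derived statistic
#'
#' Draws `n_sims` variance-component vectors from the large-sample sampling
#' distribution of the fit (Gaussian at the estimates with covariance from
#' the inverse information, truncated at zero; `scale = "log"` draws
#' log-normally instead), evaluates `derived` on each draw, and reports
#' rank-based summaries: with `n_sims = 10000` the 95% interval endpoints are exactly
#' the 250th and 9750th order statistics and the median is the midpoint of
#' the 5000th and 5001st.
#'
#' @param fit An `animal_model`.
#' @param derived A function of one argument (the named variance-component
#'   vector: `id`, `tank`, `animal`, `error` as present) returning one
#'   number.
#' @param n_sims Number of draws (default 10000).
#' @param seed Integer seed (mandatory: results are deterministic given the
#'   seed).
#' @param scale Sampling scale for the variance-component draws:
#'   `"natural"` (default, truncated Gaussian) or `"log"` (log-normal).
#' @return A tibble with `median`, `ci_low`, `ci_high`, `n_sims`.
#' @export
posterior_ci <- function(fit, derived, n_sims = 10000L, seed,
                         scale = c("natural", "log")) {
  stopifnot(inherits(fit, "animal_model"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  draws <- varcomp_draws(fit, n_sims, seed, scale)
  vals <- apply(draws, 1L, derived)
  ok <- is.finite(vals)
  if (sum(ok) < n_sims) {
    stop("only ", sum(ok), " of ", n_sims, " draws gave a finite statistic",
         call. = FALSE)
  }
  s <- sort(vals)
  lo <- s[max(1L, floor(0.025 * n_sims))]
  hi <- s[ceiling(0.975 * n_sims)]
  med <- if (n_sims %% 2L == 0L) mean(s[n_sims / 2L + 0:1]) else s[(n_sims + 1L) / 2L]
  tibble::tibble(median = med, ci_low = lo, ci_high = hi, n_sims = n_sims)
}

# n_sims x k matrix of variance-component draws from the large-sample
# sampling distribution. Default: Gaussian on the natural scale, truncated
# at (essentially) zero -- calibrated against the empirical sampling spread
# of REML estimates in simulation. "log" draws log-normally instead
# (guaranteed positive, slightly conservative for ratio statistics).
varcomp_draws <- function(fit, n_sims, seed, scale = c("natural", "log")) {
  scale <- match.arg(scale)
  vc <- fit$varcomp
  k <- length(vc)
  V <- vc_vcov(fit, scale)
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  rot <- e$vectors %*% diag(sqrt(lam), k)
  set.seed(seed)
  z <- matrix(stats::rnorm(n_sims * k), n_sims, k)
  draws <- if (scale == "log") {
    exp(sweep(z %*% t(rot), 2L, log(vc), "+"))
  } else {
    pmax(sweep(z %*% t(rot), 2L, vc, "+"), max(vc) * 1e-12)
  }
  colnames(draws) <- names(vc)
  draws
}

#' Decompose trait variance into quantitative-genetic summaries
#'
#' Assembles, for one trait, the full decomposition: total additive genetic
#' variance `V_A` (the animal variance of the genotype-free REML fit),
#' heritability, evolvability, percent repeatability, and the percent
#' contributions of vgll3 and six6 (allele-substitution effects and their
#' standard errors from the genotype-including fit, allele frequencies from
#' the data). Point (plug-in) estimates and rank-based medians with 95% CIs
#' from [posterior_ci()] are both reported, since a simulation median and a
#' plug-in estimate can differ for ratio statistics.
#'
#' @param fit_full Genotype-free REML `animal_model` (fixed effects without
#'   vgll3/six6) — the source of all variance components.
#' @param fit_geno Genotype-including fit (ML) — the source of
#'   `beta`/`se` for the two loci. May be `NULL`, in which case locus
#'   contributions are omitted.
#' @param genotypes Tibble with one row per individual and columns `vgll3`,
#'   `six6` (additive codes) used for allele frequencies.
#' @param trait_mean Mean trait value (for evolvability).
#' @param n_sims,seed Passed to [posterior_ci()].
#' @return A one-row `variance_decomposition` tibble.
#' @export
decompose_variance <- function(fit_full, fit_geno = NULL, genotypes = NULL,
                               trait_mean, n_sims = 10000L, seed = 1L,
                               scale = c("natural", "log")) {
  stopifnot(inherits(fit_full, "animal_model"))
  vc <- fit_full$varcomp
  need <- c("id", "tank", "animal", "error")
  if (!all(need %in% names(vc))) {
    stop("fit_full must have id, tank and animal random terms", call. = FALSE)
  }
  stat_fns <- list(
    V_A = function(v) v[["animal"]],
    h2 = function(v) heritability(v[["animal"]], v[["tank"]], v[["id"]]),
    I_A = function(v) evolvability(v[["animal"]], trait_mean),
    repeatability = function(v) repeatability_pct(v[["id"]], v[["error"]])
  )
  loci <- character(0)
  if (!is.null(fit_geno)) {
    stopifnot(!is.null(genotypes))
    for (locus in intersect(c("vgll3", "six6"), fit_geno$coefficients$term)) {
      row <- fit_geno$coefficients[fit_geno$coefficients$term == locus, ]
      fr <- allele_frequencies(genotypes[[locus]])
      b <- row$estimate; s <- row$se
      stat_fns[[paste0("pct_VA_", locus)]] <- local({
        b <- b; s <- s; fr <- fr
        function(v) locus_va_contribution(b, s, fr$freq_L, fr$freq_E, v[["animal"]])
      })
      loci <- c(loci, locus)
    }
  }
  draws <- varcomp_draws(fit_full, n_sims, seed, match.arg(scale))
  out <- purrr::imap(stat_fns, function(fn, name) {
    est <- fn(vc)
    vals <- sort(apply(draws, 1L, fn))
    ok <- is.finite(vals)
    if (sum(ok) < n_sims) stop("only ", sum(ok), " of ", n_sims,
                               " draws gave a finite ", name, call. = FALSE)
    med <- if (n_sims %% 2L == 0L) mean(vals[n_sims / 2L + 0:1]) else vals[(n_sims + 1L) / 2L]
    tibble::tibble(
      statistic = name, estimate = est, median = med,
      ci_low = vals[max(1L, floor(0.025 * n_sims))],
      ci_high = vals[ceiling(0.975 * n_sims)]
    )
  })
  res <- dplyr::bind_rows(out)
  res <- dplyr::mutate(res, trait = fit_full$trait %||% NA_character_, .before = 1L)
  class(res) <- unique(c("variance_decomposition", class(res)))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
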