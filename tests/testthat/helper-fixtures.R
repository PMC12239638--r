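# Shared fixtures and independent oracles, built in code at test time.

# long landmark tibble from a list of k x 2 matrices (one plane)
lm_tbl <- function(mats, plane = "body", ids = NULL, replicates = NULL) {
  k <- nrow(mats[[1]])
  if (is.null(ids)) ids <- paste0("s", seq_along(mats))
  if (is.null(replicates)) replicates <- rep(1L, length(mats))
  dplyr::bind_rows(purrr::pmap(list(mats, ids, replicates), function(m, id, r) {
    tibble::tibble(specimen_id = id, plane = plane, replicate = as.integer(r),
                   landmark = 0:(k - 1L), x = m[, 1], y = m[, 2])
  }))
}

similarity_transform <- function(m, theta, s, t) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  s * m %*% R + matrix(t, nrow(m), 2, byrow = TRUE)
}

# random valid pedigree: founders plus offspring whose parents precede them
random_pedigree <- function(n, n_founders = max(2L, n %/% 3L), seed = 1L) {
  set.seed(seed)
  id <- paste0("i", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1L):n) {
    pool <- seq_len(i - 1L)
    pick <- sample(pool, min(2L, length(pool)))
    sire[i] <- id[pick[1]]
    if (length(pick) > 1L && stats::runif(1) < 0.9) dam[i] <- id[pick[2]]
  }
  tibble::tibble(id = id, sire = sire, dam = dam)
}

# gene-dropping Monte-Carlo oracle for expected additive relatedness:
# drop two independent founder alleles down the pedigree (vectorised across
# drops) and estimate A_ij as twice the probability that a random allele
# from i is IBD to a random allele from j; the diagonal comes out as
# 1 + inbreeding automatically. Per-entry MC standard error is bounded by
# 2 * sqrt(0.25 / n_drops) since each drop contributes a value in [0, 1].
gene_drop_A <- function(ped, n_drops = 1e4, seed = 1L) {
  ped <- morphoquant::as_pedigree(ped)
  set.seed(seed)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  a1 <- a2 <- matrix(0L, n, n_drops)
  for (i in seq_len(n)) {
    a1[i, ] <- if (is.na(si[i])) 2L * i - 1L else {
      pick <- stats::runif(n_drops) < 0.5
      ifelse(pick, a1[si[i], ], a2[si[i], ])
    }
    a2[i, ] <- if (is.na(di[i])) 2L * i else {
      pick <- stats::runif(n_drops) < 0.5
      ifelse(pick, a1[di[i], ], a2[di[i], ])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      f <- (mean(a1[i, ] == a1[j, ]) + mean(a1[i, ] == a2[j, ]) +
            mean(a2[i, ] == a1[j, ]) + mean(a2[i, ] == a2[j, ])) / 4
      A[i, j] <- A[j, i] <- 2 * f
    }
  }
  A
}

# balanced one-way REML oracle: ANOVA estimator of the group variance
anova_varcomp <- function(y, group) {
  a <- length(unique(group)); n0 <- length(y) / a
  gm <- tapply(y, group, mean)
  msb <- n0 * sum((gm - mean(y))^2) / (a - 1)
  msw <- sum((y - gm[group])^2) / (length(y) - a)
  c(between = (msb - msw) / n0, within = msw)
}

founder_pedigree <- function(ids) {
  tibble::tibble(id = ids, sire = NA_character_, dam = NA_character_)
}
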