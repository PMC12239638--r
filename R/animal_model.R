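#' Fit a pedigree-based linear mixed ("animal") model for one trait
#'
#' Univariate mixed model
#' `y = X beta + u_ID + u_tank + u_animal + e`, where `u_ID` is an i.i.d.
#' individual effect (separating repeat-measurement error from individual
#' deviation), `u_tank` an i.i.d. rearing-tank effect, and `u_animal` the
#' additive genetic effect with covariance `sigma2_a * A` for the pedigree
#' relationship matrix A. Estimation maximises the (restricted) likelihood
#' over log-variance components, solving Henderson's mixed-model equations
#' with a sparse Cholesky factorisation (`A^-1` from Henderson's rules), with
#' multi-start bounded quasi-Newton optimisation to avoid boundary traps.
#'
#' Use `method = "ML"` when fixed-effect estimates or AIC comparisons are
#' wanted, `method = "REML"` for unbiased variance components.
#'
#' @param data A `trait_tbl` or any tibble with columns `specimen_id`,
#'   `value`, the fixed-effect covariates, and `tank` if used. If a `trait`
#'   column is present, `trait` selects the rows. Repeated measurements are
#'   rows sharing `specimen_id`.
#' @param trait Trait name to model (ignored when `data` has no `trait`
#'   column).
#' @param fixed Right-hand-side formula of fixed effects (default
#'   `~ L + CF + feed + sex + vgll3 + six6`; the genotype columns are the
#'   additive 0/1/2 codes).
#' @param random Character subset of `c("id", "tank", "animal")`.
#' @param relationship Result of [additive_relationship_inverse()] (or a
#'   pedigree coercible by [as_pedigree()]); required when `"animal"` is in
#'   `random`. All `specimen_id` values must appear in its ids.
#' @param method `"REML"` or `"ML"`.
#' @param n_starts Number of optimiser starts (default 3).
#' @param tol Relative convergence tolerance (default 1e-8).
#' @return An `animal_model` object with elements `coefficients` (tibble
#'   with `term`, `estimate`, `se`), `varcomp` (named vector, trait units
#'   squared), `loglik`, `AIC`, `method`, `n`, `convergence`, and internals
#'   used by [satterthwaite_type3()] and [posterior_ci()].
#' @export
fit_animal_model <- function(data, trait = NULL,
                             fixed = ~ L + CF + feed + sex + vgll3 + six6,
                             random = c("id", "tank", "animal"),
                             relationship = NULL,
                             method = c("REML", "ML"),
                             n_starts = 3L, tol = 1e-8) {
  method <- match.arg(method)
  random <- if (length(random)) match.arg(random, c("id", "tank", "animal"),
                                          several.ok = TRUE) else character(0)
  if ("trait" %in% names(data) && !is.null(trait)) {
    data <- data[data$trait == trait, , drop = FALSE]
    if (!nrow(data)) stop("no rows for trait '", trait, "'", call. = FALSE)
  }
  data <- ensure_reference_levels(data)
  trm <- stats::terms(stats::update(fixed, value ~ .))
  mf <- stats::model.frame(trm, data = data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(trm, mf)
  design_qr(X)  # rank check with aliased-column error
  n <- length(y)
  p <- ncol(X)

  ids <- as.character(data$specimen_id)
  rterms <- list()
  if ("id" %in% random) {
    f <- factor(ids)
    rterms$id <- list(
      Z = Matrix::sparse.model.matrix(~ f - 1),
      Ginv = Matrix::Diagonal(nlevels(f)), logdet_unit = 0, levels = levels(f)
    )
  }
  if ("tank" %in% random) {
    if (!"tank" %in% names(data)) stop("random tank term needs a tank column", call. = FALSE)
    f <- factor(as.character(data$tank))
    rterms$tank <- list(
      Z = Matrix::sparse.model.matrix(~ f - 1),
      Ginv = Matrix::Diagonal(nlevels(f)), logdet_unit = 0, levels = levels(f)
    )
  }
  if ("animal" %in% random) {
    if (is.null(relationship)) stop("random animal term needs `relationship`", call. = FALSE)
    if (!is.list(relationship) || is.null(relationship$Ainv)) {
      relationship <- additive_relationship_inverse(relationship)
    }
    miss <- setdiff(unique(ids), relationship$ids)
    if (length(miss)) {
      stop("individual(s) absent from the relationship matrix: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    m <- length(relationship$ids)
    Z <- Matrix::sparseMatrix(i = seq_len(n), j = match(ids, relationship$ids),
                              x = 1, dims = c(n, m))
    rterms$animal <- list(Z = Z, Ginv = relationship$Ainv,
                          logdet_unit = relationship$logdet,
                          levels = relationship$ids)
  }

  comp_names <- c(names(rterms), "error")
  k_vc <- length(comp_names)

  if (!length(rterms)) {
    # fixed-effects-only: closed-form (generalised) least squares
    fit0 <- stats::lm.fit(X, y)
    rss <- sum(fit0$residuals^2)
    s2 <- if (method == "REML") rss / (n - p) else rss / n
    XtXinv <- chol2inv(chol(crossprod(X)))
    ldet_XtX <- log_det_sym(crossprod(X))
    neg2ll <- function(vc) {
      se2 <- vc[["error"]]
      if (method == "REML") {
        (n - p) * log(2 * pi) + (n - p) * log(se2) + ldet_XtX + rss / se2
      } else {
        n * log(2 * pi) + n * log(se2) + rss / se2
      }
    }
    vc <- c(error = s2)
    ll <- -0.5 * neg2ll(vc)
    out <- list(
      coefficients = tibble::tibble(term = colnames(X),
                                    estimate = unname(fit0$coefficients),
                                    se = sqrt(diag(XtXinv) * s2)),
      vcov_beta = XtXinv * s2,
      varcomp = vc, loglik = ll,
      AIC = -2 * ll + 2 * (p + 1), method = method, n = n, p = p,
      convergence = list(converged = TRUE, message = "closed form"),
      neg2ll = neg2ll, beta_at = function(vc) {
        list(beta = unname(fit0$coefficients), vcov = XtXinv * vc[["error"]])
      },
      X = X, y = y, term_assign = attr(X, "assign"),
      term_labels = attr(trm, "term.labels"), fixed = fixed, trait = trait,
      random = character(0), comp_names = "error"
    )
    class(out) <- "animal_model"
    return(out)
  }

  Zt <- Matrix::t(do.call(cbind, lapply(rterms, `[[`, "Z")))
  q_each <- vapply(rterms, function(r) ncol(r$Z), integer(1))
  blocks <- lapply(rterms, `[[`, "Ginv")
  ZtZ <- Matrix::tcrossprod(Zt)
  ZtX <- Zt %*% X
  Zty <- as.numeric(Zt %*% y)
  Xty <- as.numeric(crossprod(X, y))
  XtX <- crossprod(X)
  yty <- sum(y^2)
  logdet_units <- vapply(rterms, function(r) r$logdet_unit, numeric(1))

  Ginv_at <- function(vc) {
    Matrix::bdiag(purrr::map2(blocks, vc[names(rterms)], function(B, s2) B / s2))
  }
  symfact <- NULL
  eval_fit <- function(vc, want_beta = FALSE) {
    se2 <- vc[["error"]]
    Czz <- ZtZ / se2 + Ginv_at(vc)
    fact <- tryCatch({
      Csym <- Matrix::forceSymmetric(Czz)
      if (is.null(symfact)) {
        symfact <<- Matrix::Cholesky(Csym, LDL = FALSE, perm = TRUE)
        symfact
      } else {
        update(symfact, Csym)  # reuse the symbolic factorisation
      }
    }, error = function(e) tryCatch(
      Matrix::Cholesky(Matrix::forceSymmetric(Czz), LDL = FALSE, perm = TRUE),
      error = function(e2) NULL
    ))
    if (is.null(fact)) return(NULL)
    ldet_Czz <- 2 * as.numeric(Matrix::determinant(fact, sqrt = TRUE)$modulus)
    CinvZtX <- Matrix::solve(fact, ZtX / se2, system = "A")
    CinvZty <- Matrix::solve(fact, Zty / se2, system = "A")
    S <- as.matrix(XtX / se2 - crossprod(as.matrix(ZtX / se2), as.matrix(CinvZtX)))
    S <- (S + t(S)) / 2
    chS <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(chS)) return(NULL)
    ldet_S <- 2 * sum(log(diag(chS)))
    rhs <- Xty / se2 - as.numeric(crossprod(as.matrix(ZtX / se2), matrix(CinvZty, ncol = 1)))
    beta <- backsolve(chS, backsolve(chS, rhs, transpose = TRUE))
    u <- as.numeric(Matrix::solve(fact, (Zty - as.numeric(ZtX %*% beta)) / se2, system = "A"))
    yPy <- yty / se2 - sum(beta * Xty) / se2 - sum(u * Zty) / se2
    log_G <- sum(q_each * log(vc[names(rterms)])) + sum(logdet_units)
    log_R <- n * log(se2)
    n2ll <- if (method == "REML") {
      (n - p) * log(2 * pi) + log_R + log_G + ldet_Czz + ldet_S + yPy
    } else {
      n * log(2 * pi) + log_R + log_G + ldet_Czz + yPy
    }
    if (!is.finite(n2ll)) return(NULL)
    out <- list(n2ll = n2ll)
    if (want_beta) {
      out$beta <- beta
      out$vcov <- chol2inv(chS)
      out$u <- u
    }
    out
  }
  neg2ll <- function(vc) {
    r <- eval_fit(vc)
    if (is.null(r)) Inf else r$n2ll
  }

  vy <- stats::var(y)
  obj <- function(phi) neg2ll(stats::setNames(exp(phi), comp_names))
  lower <- rep(log(vy * 1e-10), k_vc)
  upper <- rep(log(vy * 1e4), k_vc)
  start_scales <- c(1, 0.2, 5, 0.05, 25)[seq_len(max(1L, n_starts))]
  fits <- purrr::map(start_scales, function(s) {
    phi0 <- log(pmin(pmax(rep(vy / (k_vc + 1), k_vc) * s, exp(lower)), exp(upper)))
    tryCatch(
      stats::nlminb(phi0, obj, lower = lower, upper = upper,
                    control = list(rel.tol = tol, iter.max = 500L)),
      error = function(e) NULL
    )
  })
  fits <- purrr::compact(fits)
  fits <- purrr::keep(fits, function(f) is.finite(f$objective))
  if (!length(fits)) {
    stop("animal model failed to converge from any start; trait '", trait, "'",
         call. = FALSE)
  }
  best <- fits[[which.min(purrr::map_dbl(fits, "objective"))]]
  vc <- stats::setNames(exp(best$par), comp_names)
  final <- eval_fit(vc, want_beta = TRUE)
  if (is.null(final)) stop("likelihood evaluation failed at the optimum", call. = FALSE)
  ll <- -0.5 * final$n2ll
  out <- list(
    coefficients = tibble::tibble(term = colnames(X),
                                  estimate = as.numeric(final$beta),
                                  se = sqrt(pmax(diag(final$vcov), 0))),
    vcov_beta = final$vcov,
    varcomp = vc,
    loglik = ll,
    AIC = -2 * ll + 2 * (p + k_vc),
    method = method, n = n, p = p,
    convergence = list(converged = best$convergence == 0, message = best$message,
                       objective = best$objective,
                       starts = purrr::map_dbl(fits, "objective")),
    neg2ll = neg2ll,
    beta_at = function(vc) {
      r <- eval_fit(vc, want_beta = TRUE)
      if (is.null(r)) stop("likelihood evaluation failed", call. = FALSE)
      list(beta = as.numeric(r$beta), vcov = r$vcov)
    },
    X = X, y = y,
    term_assign = attr(X, "assign"),
    term_labels = attr(trm, "term.labels"),
    random_levels = purrr::map(rterms, "levels"),
    fixed = fixed, trait = trait, random = names(rterms),
    comp_names = comp_names
  )
  class(out) <- "animal_model"
  out
}

# stable log-determinant of a symmetric positive definite matrix
log_det_sym <- function(M) 2 * sum(log(diag(chol((M + t(M)) / 2))))

# Fixed factor reference levels matching the reported sign conventions:
# feed ad libitum -> restricted, sex female -> male.
ensure_reference_levels <- function(data) {
  relevel_chr <- function(x, first) {
    lev <- unique(as.character(x))
    factor(as.character(x), levels = c(intersect(first, lev), sort(setdiff(lev, first))))
  }
  if ("feed" %in% names(data) && !is.factor(data$feed)) {
    data$feed <- relevel_chr(data$feed, c("ad_libitum", "ad libitum"))
  }
  if ("sex" %in% names(data) && !is.factor(data$sex)) {
    data$sex <- relevel_chr(data$sex, "female")
  }
  if ("tank" %in% names(data)) data$tank <- factor(as.character(data$tank))
  if ("family" %in% names(data) && !is.factor(data$family)) {
    data$family <- factor(as.character(data$family))
  }
  data
}

#' @export
print.animal_model <- function(x, ...) {
  cat("Animal model (", x$method, ") for trait ",
      if (is.null(x$trait)) "<value>" else x$trait, "\n", sep = "")
  cat("  n =", x$n, " logLik =", signif(x$loglik, 7), " AIC =", signif(x$AIC, 7), "\n")
  cat("Variance components:\n")
  print(signif(x$varcomp, 5))
  cat("Fixed effects:\n")
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

# Finite-difference Hessian of -2*loglik in the variance components, on the
# natural or log scale, computed only over components away from the zero
# boundary (a boundary component's curvature is not estimable from central
# differences; its rows are returned as NA and handled by vc_vcov).
vc_hessian <- function(fit, scale = c("natural", "log")) {
  scale <- match.arg(scale)
  vc <- fit$varcomp
  k <- length(vc)
  free <- vc > 1e-8 * sum(vc)
  f <- if (scale == "log") {
    function(phi) fit$neg2ll(stats::setNames(exp(phi), names(vc)))
  } else {
    function(v) fit$neg2ll(stats::setNames(v, names(vc)))
  }
  # absolute step on the log scale (1% multiplicative change); scaled to the
  # component size on the natural scale
  x0 <- if (scale == "log") log(vc) else vc
  h <- if (scale == "log") rep(0.01, k) else pmax(vc * 0.005, 0)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x0)
  for (i in which(free)) {
    for (j in which(free)[which(free) >= i]) {
      if (i == j) {
        xp <- x0; xp[i] <- x0[i] + h[i]
        xm <- x0; xm[i] <- x0[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x0; xpp[c(i, j)] <- x0[c(i, j)] + h[c(i, j)]
        xpm <- x0; xpm[i] <- x0[i] + h[i]; xpm[j] <- x0[j] - h[j]
        xmp <- x0; xmp[i] <- x0[i] - h[i]; xmp[j] <- x0[j] + h[j]
        xmm <- x0; xmm[c(i, j)] <- x0[c(i, j)] - h[c(i, j)]
        H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  dimnames(H) <- list(names(vc), names(vc))
  attr(H, "free") <- free
  H
}

# Asymptotic covariance of the variance components: 2 * H^-1 over the
# components away from the zero boundary (boundary components get zero
# rows: their sampling distribution collapses onto the constraint). Falls
# back to a pseudo-inverse when the free-block information is singular.
vc_vcov <- function(fit, scale = c("natural", "log")) {
  scale <- match.arg(scale)
  H <- vc_hessian(fit, scale)
  free <- attr(H, "free")
  k <- length(fit$varcomp)
  V <- matrix(0, k, k, dimnames = list(names(fit$varcomp), names(fit$varcomp)))
  if (any(free)) {
    Hf <- H[free, free, drop = FALSE]
    Hf[!is.finite(Hf)] <- 0
    Hf <- (Hf + t(Hf)) / 2
    inv <- tryCatch(chol2inv(chol(Hf)), error = function(e) NULL)
    if (is.null(inv)) {
      rlang::warn("singular variance-component information; using pseudo-inverse",
                  class = "morphoquant_singular_info")
      e <- eigen(Hf, symmetric = TRUE)
      pos <- e$values > max(e$values, 0) * 1e-10
      inv <- e$vectors[, pos, drop = FALSE] %*%
        (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
    }
    V[free, free] <- 2 * inv
  }
  V
}

#' Type-III F tests with Satterthwaite denominator degrees of freedom
#'
#' For each fixed-effect term, an F statistic on its model-matrix columns
#' with denominator degrees of freedom from the Satterthwaite approximation:
#' for a 1-df contrast `c`, `df = 2 v^2 / (g' V g)` where
#' `v = c' cov(beta) c`, `g` its gradient in the variance components
#' (finite differences) and `V` the asymptotic covariance of the variance
#' components; multi-df terms combine eigencontrast dfs in the standard way.
#' With no variance parameters beyond the residual this reduces exactly to
#' the classical `n - p`.
#'
#' @param fit An `animal_model` (REML recommended).
#' @return A tibble `term`, `df_num`, `df_den`, `F`, `p`.
#' @export
satterthwaite_type3 <- function(fit) {
  stopifnot(inherits(fit, "animal_model"))
  vc0 <- fit$varcomp
  beta <- fit$coefficients$estimate
  C0 <- fit$vcov_beta
  if (!length(fit$random)) {
    # no variance parameters beyond the residual: classical df, exactly
    one_df <- function(cvec) fit$n - fit$p
    Vvc <- NULL
  } else {
    Vvc <- vc_vcov(fit, "natural")
    k <- length(vc0)
    h <- pmax(vc0 * 0.01, 1e-12)
    dC <- purrr::map(seq_len(k), function(i) {
      vp <- vc0; vp[i] <- vc0[i] + h[i]
      vm <- vc0; vm[i] <- max(vc0[i] - h[i], vc0[i] * 1e-6)
      (fit$beta_at(vp)$vcov - fit$beta_at(vm)$vcov) / (vp[i] - vm[i])
    })
    fell_back <- FALSE
    one_df <- function(cvec) {
      v <- drop(crossprod(cvec, C0 %*% cvec))
      g <- vapply(dC, function(D) drop(crossprod(cvec, D %*% cvec)), numeric(1))
      den <- drop(crossprod(g, Vvc %*% g))
      if (!is.finite(den) || den <= 0) {
        if (!fell_back) {
          fell_back <<- TRUE
          rlang::warn("contrast-variance gradient not estimable; falling back to residual df",
                      class = "morphoquant_satterthwaite_fallback")
        }
        return(fit$n - fit$p)
      }
      2 * v^2 / den
    }
  }
  labels <- fit$term_labels
  assign <- fit$term_assign
  rows <- purrr::imap(c(`(Intercept)` = 0L, stats::setNames(seq_along(labels), labels)),
    function(t_idx, label) {
      cols <- which(assign == t_idx)
      if (!length(cols)) return(NULL)
      L <- diag(length(beta))[cols, , drop = FALSE]
      q <- nrow(L)
      M <- L %*% C0 %*% t(L)
      Fstat <- drop(crossprod(L %*% beta, solve(M, L %*% beta))) / q
      if (q == 1L) {
        df <- one_df(drop(L))
      } else {
        e <- eigen((M + t(M)) / 2, symmetric = TRUE)
        Ltil <- (t(e$vectors) %*% L) / sqrt(e$values)
        nus <- apply(Ltil, 1L, one_df)
        # each eigencontrast contributes nu/(nu-2); an (effectively) infinite
        # nu contributes its limit 1
        contrib <- ifelse(is.finite(nus), pmax(nus, 2 + 1e-8), NA)
        contrib <- ifelse(is.na(contrib), 1, contrib / (contrib - 2))
        E <- sum(contrib)
        df <- if (E > q) 2 * E / (E - q) else Inf
      }
      tibble::tibble(term = label, df_num = q, df_den = df, F = Fstat,
                     p = stats::pf(Fstat, q, df, lower.tail = FALSE))
    })
  dplyr::bind_rows(rows)
}

#' Compare additive and non-additive (dominance) genotype models
#'
#' Fits, by maximum likelihood, the additive model (0/1/2 code), the free
#' 3-level factor model, and the two constrained dominance codings
#' (heterozygote equal to LL; heterozygote equal to EE) for one locus, and
#' reports AICs. `delta = AIC_additive - AIC_factor`; a difference of at
#' least 2 flags meaningful support for non-additivity.
#'
#' @inheritParams fit_animal_model
#' @param locus `"vgll3"` or `"six6"`.
#' @return A list with `models` (tibble `model`, `AIC`, `logLik`,
#'   `converged`), `delta`, and `meaningful` (`delta >= 2`).
#' @export
compare_additive_dominance <- function(data, trait = NULL, locus = c("vgll3", "six6"),
                                       fixed = ~ L + CF + feed + sex + vgll3 + six6,
                                       random = c("id", "tank", "animal"),
                                       relationship = NULL, ...) {
  locus <- match.arg(locus)
  if ("trait" %in% names(data) && !is.null(trait)) data <- data[data$trait == trait, ]
  code <- data[[locus]]
  variants <- list(
    additive = function(d) d,
    factor = function(d) { d[[locus]] <- factor(decode_additive_genotype(code)); d },
    het_as_LL = function(d) { d[[locus]] <- as.integer(code >= 1L); d },
    het_as_EE = function(d) { d[[locus]] <- as.integer(code == 2L); d }
  )
  models <- purrr::imap(variants, function(fun, name) {
    fit <- tryCatch(
      fit_animal_model(fun(data), trait = NULL, fixed = fixed, random = random,
                       relationship = relationship, method = "ML", ...),
      error = function(e) NULL
    )
    tibble::tibble(
      model = name,
      AIC = if (is.null(fit)) NA_real_ else fit$AIC,
      logLik = if (is.null(fit)) NA_real_ else fit$loglik,
      converged = !is.null(fit) && isTRUE(fit$convergence$converged)
    )
  })
  models <- dplyr::bind_rows(models)
  delta <- models$AIC[models$model == "additive"] - models$AIC[models$model == "factor"]
  list(models = models, delta = delta, meaningful = isTRUE(delta >= 2))
}

#' Length-by-genotype interaction check
#'
#' Refits the trait model with `L:vgll3` and `L:six6` interaction terms and
#' reports the interaction t-values together with the change in the main
#' genetic-effect estimates relative to the base model. Used to check that
#' locus-trait associations are not mediated by length.
#'
#' @inheritParams fit_animal_model
#' @return A list with `base` and `interaction` fits, `interaction_tests`
#'   (tibble `term`, `estimate`, `se`, `t`) and `main_effect_shift` (tibble
#'   comparing vgll3/six6 estimates across models).
#' @export
length_genotype_interaction <- function(data, trait = NULL,
                                        fixed = ~ L + CF + feed + sex + vgll3 + six6,
                                        random = c("id", "tank", "animal"),
                                        relationship = NULL, ...) {
  base <- fit_animal_model(data, trait, fixed = fixed, random = random,
                           relationship = relationship, method = "ML", ...)
  fx_int <- stats::update(fixed, ~ . + L:vgll3 + L:six6)
  inter <- fit_animal_model(data, trait, fixed = fx_int, random = random,
                            relationship = relationship, method = "ML", ...)
  itests <- dplyr::filter(inter$coefficients, grepl(":", .data$term))
  itests <- dplyr::mutate(itests, t = .data$estimate / .data$se)
  shift <- dplyr::inner_join(
    dplyr::filter(base$coefficients, .data$term %in% c("vgll3", "six6")),
    dplyr::filter(inter$coefficients, .data$term %in% c("vgll3", "six6")),
    by = "term", suffix = c("_base", "_interaction")
  )
  shift <- dplyr::mutate(shift, shift = .data$estimate_interaction - .data$estimate_base)
  list(base = base, interaction = inter, interaction_tests = itests,
       main_effect_shift = shift)
}
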