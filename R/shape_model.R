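#' Shape coordinates as a wide modelling table
#'
#' Turns a Procrustes alignment into one row per specimen with coordinate
#' columns `x0, y0, x1, y1, ...`, averaging replicate configurations (the
#' convention for the shape regression, where one value per individual is
#' required).
#'
#' @param alignment A `gpa_alignment`.
#' @param average Average replicates per specimen (default `TRUE`).
#' @return A tibble with `specimen_id`, `plane`, and coordinate columns.
#' @export
shape_coordinates <- function(alignment, average = TRUE) {
  aligned <- alignment$aligned
  if (average) {
    aligned <- dplyr::summarise(
      dplyr::group_by(aligned, .data$specimen_id, .data$plane, .data$landmark),
      x = mean(.data$x), y = mean(.data$y), .groups = "drop"
    )
  }
  long <- tidyr::pivot_longer(aligned, c("x", "y"), names_to = "axis", values_to = "value")
  long <- dplyr::mutate(long, col = paste0(.data$axis, .data$landmark))
  wide <- tidyr::pivot_wider(long[, c("specimen_id", "plane", "col", "value")],
                             names_from = "col", values_from = "value")
  k <- max(aligned$landmark) + 1L
  ord <- as.vector(rbind(paste0("x", 0:(k - 1L)), paste0("y", 0:(k - 1L))))
  wide[, c("specimen_id", "plane", ord)]
}

#' Pillai's trace from effect and residual SSCP matrices
#'
#' `trace(H (H + E)^-1)`, computed through the eigendecomposition of
#' `H + E`; a symmetric pseudo-inverse is used (with a warning) when
#' `H + E` is singular, as it always is for Procrustes shape variables,
#' whose rank is below the raw coordinate count.
#'
#' @param effect_sscp,residual_sscp Conformable symmetric matrices (sums of
#'   squares and cross-products for the effect and the residual).
#' @param warn Emit the singularity warning (default `TRUE`).
#' @return The Pillai trace statistic.
#' @export
pillai_trace <- function(effect_sscp, residual_sscp, warn = TRUE) {
  H <- as.matrix(effect_sscp)
  T <- H + as.matrix(residual_sscp)
  eig <- eigen((T + t(T)) / 2, symmetric = TRUE)
  tol <- max(dim(T)) * .Machine$double.eps * max(abs(eig$values), 0)
  pos <- eig$values > tol
  if (!all(pos) && warn) {
    rlang::warn("singular H + E; Pillai's trace computed on the non-null subspace",
                class = "morphoquant_singular_sscp")
  }
  if (!any(pos)) return(0)
  V <- eig$vectors[, pos, drop = FALSE]
  Tinv <- V %*% (t(V) / eig$values[pos])
  sum(diag(Tinv %*% H))
}

# Residual-maker products for a design matrix: returns fitted-projector via QR.
design_qr <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  qr_x
}

fit_resid <- function(qr_x, Y) {
  F <- qr.fitted(qr_x, Y)
  list(fitted = F, resid = Y - F)
}

#' Multivariate shape model with residual-randomization permutation tests
#'
#' Fits the linear model `Y = X beta` for a multivariate response (Procrustes
#' shape variables or any numeric matrix) and tests every term with type-III
#' (marginal) sums of squares and cross-products: for each term the reduced
#' model excluding only that term is fitted, the effect SSCP is
#' `E_reduced - E_full`, and significance comes from residual randomization
#' (RRPP): reduced-model residual rows are permuted, added back to the
#' reduced-model fitted values, and the statistic is recomputed. Reported per
#' term: Pillai's trace, a permutation standard deviate `z`, and the
#' permutation p-value `(count(perm >= obs) + 1) / (B + 1)`.
#'
#' Tank and family enter as fixed dummy-coded terms in the study's shape
#' model; pass them as factors in `data`.
#'
#' @param data A data frame holding the covariates and the response columns.
#' @param formula Right-hand-side formula of model terms, e.g.
#'   `~ L + CF + feed + tank + sex + vgll3 + six6 + family`.
#' @param response Character vector of response column names; defaults to
#'   every column matching `^[xy][0-9]+$` (the [shape_coordinates()] layout).
#' @param permutations Number of random permutations B (default 999; fewer
#'   than 99 triggers a warning).
#' @param seed Integer seed for the permutation schedule (mandatory for
#'   reproducibility).
#' @param z_transform `"none"` (default) computes the standard deviate on raw
#'   statistics, `"log"` on log-transformed statistics.
#' @param drop_aliased With the study design some terms overlap exactly
#'   (feed treatment is assigned at tank level; the vgll3 genotype is fixed
#'   within each family), making the dummy-coded design rank deficient. The
#'   default (`FALSE`) raises an error naming the aliased columns;
#'   `TRUE` drops the aliased columns of later terms (with a message), the
#'   behaviour of standard multivariate-regression software, so that earlier
#'   terms keep their full degrees of freedom.
#' @return A `shape_model` object; see [tidy.shape_model()].
#' @export
fit_shape_model <- function(data, formula, response = NULL, permutations = 999,
                            seed = 1L, z_transform = c("none", "log"),
                            drop_aliased = FALSE) {
  z_transform <- match.arg(z_transform)
  if (permutations < 99) {
    rlang::warn("fewer than 99 permutations: p-values will be unstable")
  }
  if (is.null(response)) response <- grep("^[xy][0-9]+$", names(data), value = TRUE)
  if (!length(response)) stop("no response columns found", call. = FALSE)
  Y <- as.matrix(data[, response, drop = FALSE])
  storage.mode(Y) <- "double"
  n <- nrow(Y)
  trm <- stats::terms(formula)
  mf <- stats::model.frame(trm, data = data)
  X <- stats::model.matrix(trm, mf)
  if (n <= ncol(X)) stop("more design columns than observations", call. = FALSE)
  assign <- attr(X, "assign")
  term_labels <- attr(trm, "term.labels")
  if (drop_aliased) {
    q0 <- qr(X)
    if (q0$rank < ncol(X)) {
      dropped <- q0$pivot[(q0$rank + 1L):ncol(X)]
      message("dropping ", length(dropped), " aliased design column(s): ",
              paste(colnames(X)[dropped], collapse = ", "))
      keep_cols <- sort(q0$pivot[seq_len(q0$rank)])
      X <- X[, keep_cols, drop = FALSE]
      assign <- assign[keep_cols]
    }
  }
  qr_full <- design_qr(X)
  full <- fit_resid(qr_full, Y)
  E_full <- crossprod(full$resid)
  rank_warn <- qr(E_full)$rank < ncol(E_full)
  if (rank_warn) {
    rlang::warn("response SSCP is singular; Pillai computed on the non-null subspace",
                class = "morphoquant_singular_sscp")
  }
  set.seed(seed)
  perms <- replicate(permutations, sample.int(n))

  results <- purrr::imap(term_labels, function(label, t_idx) {
    keep <- assign != t_idx
    qr_red <- design_qr(X[, keep, drop = FALSE])
    red <- fit_resid(qr_red, Y)
    E_red <- crossprod(red$resid)
    obs <- pillai_trace(E_red - E_full, E_full, warn = FALSE)
    null <- numeric(permutations)
    for (b in seq_len(permutations)) {
      Yb <- red$fitted + red$resid[perms[, b], , drop = FALSE]
      Eb_full <- crossprod(Yb - qr.fitted(qr_full, Yb))
      Eb_red <- crossprod(Yb - qr.fitted(qr_red, Yb))
      null[b] <- pillai_trace(Eb_red - Eb_full, Eb_full, warn = FALSE)
    }
    dist <- c(obs, null)
    zdist <- if (z_transform == "log") log(pmax(dist, .Machine$double.xmin)) else dist
    sd_null <- stats::sd(zdist)
    z <- if (sd_null > 0) (zdist[1L] - mean(zdist)) / sd_null else NA_real_
    tibble::tibble(
      term = label,
      df = sum(!keep),
      pillai = obs,
      z = z,
      p = (sum(null >= obs) + 1) / (permutations + 1)
    )
  })

  structure(
    list(
      terms = dplyr::bind_rows(results),
      coefficients = qr.coef(qr_full, Y),
      fitted = full$fitted,
      residuals = full$resid,
      design = X,
      assign = assign,
      term_labels = term_labels,
      response = response,
      n = n,
      permutations = permutations,
      seed = seed,
      z_transform = z_transform,
      formula = formula
    ),
    class = "shape_model"
  )
}

#' @export
print.shape_model <- function(x, ...) {
  cat("Shape model (type-III RRPP,", x$permutations, "permutations)\n")
  cat("  n =", x$n, " responses =", length(x$response), "\n\n")
  print(as.data.frame(x$terms), digits = 4)
  invisible(x)
}

#' Genotype shape-displacement vectors
#'
#' Per-landmark displacement of the predicted shape between two values of a
#' numeric model term (by default an allele substitution from code `from = 0`
#' to `to = 2`), with all other covariates held fixed; by linearity the other
#' covariates cancel. Displacements are multiplied by `magnification` for
#' display (the conventional exaggeration of small shape effects).
#'
#' @param fit A `shape_model` whose response columns follow the
#'   `x0, y0, ...` layout.
#' @param term Name of a numeric single-column model term (e.g. `"vgll3"`).
#' @param from,to Term values contrasted (default 0 to 2, i.e. EE to LL).
#' @param magnification Display magnification (default 10).
#' @return A tibble `landmark`, `dx`, `dy`.
#' @export
shape_effect_vectors <- function(fit, term, from = 0, to = 2, magnification = 10) {
  stopifnot(inherits(fit, "shape_model"))
  t_idx <- match(term, fit$term_labels)
  if (is.na(t_idx)) stop("term '", term, "' is not in the model", call. = FALSE)
  cols <- which(fit$assign == t_idx)
  if (length(cols) != 1L) {
    stop("term '", term, "' is not a single-column (numeric) term", call. = FALSE)
  }
  disp <- (to - from) * fit$coefficients[cols, ] * magnification
  if (!all(grepl("^[xy][0-9]+$", fit$response))) {
    stop("effect vectors need the x0, y0, ... response layout of shape_coordinates()",
         call. = FALSE)
  }
  lm_idx <- as.integer(sub("^[xy]", "", fit$response))
  axis <- substr(fit$response, 1L, 1L)
  tibble::tibble(landmark = lm_idx[axis == "x"],
                 dx = unname(disp[axis == "x"]),
                 dy = unname(disp[axis == "y"]))
}
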