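#' Tidy the term table of a shape model
#' @param x A `shape_model`.
#' @param ... Unused.
#' @return A tibble `term`, `df`, `pillai`, `z`, `p`.
#' @export
tidy.shape_model <- function(x, ...) x$terms

#' One-row summary of a shape model
#' @param x A `shape_model`.
#' @param ... Unused.
#' @export
glance.shape_model <- function(x, ...) {
  tibble::tibble(n = x$n, n_responses = length(x$response),
                 permutations = x$permutations, seed = x$seed,
                 z_transform = x$z_transform)
}

#' Tidy the fixed effects of an animal model
#'
#' @param x An `animal_model`.
#' @param tests Add Satterthwaite type-III F tests (slower).
#' @param ... Unused.
#' @return A tibble `term`, `estimate`, `se` (plus `df_den`, `F`, `p` when
#'   `tests = TRUE`).
#' @export
tidy.animal_model <- function(x, tests = FALSE, ...) {
  out <- x$coefficients
  if (tests) {
    out <- dplyr::left_join(out, satterthwaite_type3(x)[, c("term", "df_den", "F", "p")],
                            by = "term")
  }
  out
}

#' One-row summary of an animal model
#' @param x An `animal_model`.
#' @param ... Unused.
#' @return A tibble with fit statistics and variance components.
#' @export
glance.animal_model <- function(x, ...) {
  vc <- tibble::as_tibble(as.list(stats::setNames(x$varcomp,
                                                  paste0("V_", names(x$varcomp)))))
  dplyr::bind_cols(
    tibble::tibble(n = x$n, method = x$method, logLik = x$loglik, AIC = x$AIC,
                   converged = isTRUE(x$convergence$converged)),
    vc
  )
}

#' Tidy an alignment: the Procrustes shape variables
#' @param x A `gpa_alignment`.
#' @param ... Unused.
#' @export
tidy.gpa_alignment <- function(x, ...) x$aligned

#' One-row summary of a Procrustes alignment
#' @param x A `gpa_alignment`.
#' @param ... Unused.
#' @export
glance.gpa_alignment <- function(x, ...) {
  tibble::tibble(n_configurations = nrow(x$meta),
                 n_landmarks = nrow(x$consensus),
                 iterations = x$iterations,
                 objective = utils::tail(x$objective_trace, 1L))
}
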