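#' Read trait definitions from a YAML config
#'
#' A definition has a `name`, a `plane`, a `type` (`distance`,
#' `mean_distance` or `centroid_size`) and the 0-based landmark indices it
#' uses (`landmarks` for distance/centroid-size, `pairs` for averaged
#' distances; `landmarks: all` means every landmark on the plane). Distances
#' measured on both body sides, or paired measures generally, are expressed
#' as `mean_distance` and averaged prior to analysis.
#'
#' @param path Path to a YAML file; the packaged default transcribes the 21
#'   study traits.
#' @return A `trait_defs` list.
#' @export
read_trait_definitions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "trait_definitions.yaml", package = "morphoquant")
  }
  raw <- yaml::read_yaml(path)
  defs <- purrr::map(raw$traits, function(d) {
    stopifnot(!is.null(d$name), !is.null(d$plane), !is.null(d$type))
    d$type <- match.arg(d$type, c("distance", "mean_distance", "centroid_size"))
    if (d$type == "mean_distance") {
      d$pairs <- purrr::map(d$pairs, as.integer)
      stopifnot(all(lengths(d$pairs) == 2L))
    } else if (d$type == "distance") {
      d$landmarks <- as.integer(d$landmarks)
      stopifnot(length(d$landmarks) == 2L)
    } else if (!identical(d$landmarks, "all")) {
      d$landmarks <- as.integer(d$landmarks)
    }
    d
  })
  names(defs) <- purrr::map_chr(defs, "name")
  if (anyDuplicated(names(defs))) stop("duplicate trait names in ", path, call. = FALSE)
  structure(defs, class = "trait_defs")
}

#' Default trait definitions (the 21 study traits)
#' @return A `trait_defs` list.
#' @export
default_trait_definitions <- function() read_trait_definitions()

trait_value <- function(def, coords) {
  k <- nrow(coords)
  used <- switch(def$type,
    distance = def$landmarks,
    mean_distance = unlist(def$pairs),
    centroid_size = if (identical(def$landmarks, "all")) 0:(k - 1L) else def$landmarks
  )
  if (any(used < 0L | used >= k)) {
    stop("trait '", def$name, "' references landmark(s) ",
         paste(setdiff(used, 0:(k - 1L)), collapse = ", "),
         " absent from plane '", def$plane, "' (", k, " landmarks)", call. = FALSE)
  }
  switch(def$type,
    distance = sqrt(sum((coords[def$landmarks[1L] + 1L, ] - coords[def$landmarks[2L] + 1L, ])^2)),
    mean_distance = mean(purrr::map_dbl(def$pairs, function(p) {
      sqrt(sum((coords[p[1L] + 1L, ] - coords[p[2L] + 1L, ])^2))
    })),
    centroid_size = centroid_size(coords[used + 1L, , drop = FALSE])
  )
}

#' Extract trait values from landmark configurations
#'
#' Distance traits are computed on the raw (unscaled) coordinates, so values
#' are in cm; centroid-size traits on the designated landmark subset.
#' Replicate measurements are kept as separate rows so downstream models can
#' separate individual and measurement variance; use
#' [average_replicates()] when one value per individual is needed.
#'
#' @param landmarks A complete (imputed) `landmark_tbl`, any mix of planes.
#' @param defs A `trait_defs` list; defaults to the packaged 21 traits.
#' @return A tibble `specimen_id`, `plane`, `replicate`, `trait`, `value`.
#' @export
extract_traits <- function(landmarks, defs = default_trait_definitions()) {
  if (anyNA(landmarks$x)) {
    stop("landmarks contain missing values; impute before extracting traits", call. = FALSE)
  }
  planes <- unique(landmarks$plane)
  rows <- purrr::map(defs, function(def) {
    if (!def$plane %in% planes) return(NULL)
    dat <- landmarks_to_array(landmarks[landmarks$plane == def$plane, ])
    vals <- apply(dat$coords, 3L, function(m) trait_value(def, m))
    dplyr::mutate(dat$meta, trait = def$name, value = vals)
  })
  dplyr::bind_rows(rows)
}

#' Average replicate measurements within individuals
#'
#' @param traits A long trait tibble from [extract_traits()].
#' @return The same tibble with one row per specimen and trait
#'   (`replicate = 1`).
#' @export
average_replicates <- function(traits) {
  dplyr::summarise(
    dplyr::group_by(traits, .data$specimen_id, .data$plane, .data$trait),
    value = mean(.data$value), .groups = "drop"
  ) |>
    dplyr::mutate(replicate = 1L, .after = "plane")
}

#' Fulton's condition factor
#'
#' `K = 100 * weight / length^3` with weight in g and fork length in cm; a
#' standard fish body-condition index (K near 1 for a well-conditioned
#' salmonid).
#'
#' @param weight_g Body weight in grams.
#' @param length_cm Fork length in centimetres.
#' @return Numeric vector of condition factors.
#' @export
fulton_condition_factor <- function(weight_g, length_cm) {
  if (any(weight_g <= 0, na.rm = TRUE) || any(length_cm <= 0, na.rm = TRUE)) {
    stop("weight and length must be positive", call. = FALSE)
  }
  100 * weight_g / length_cm^3
}

#' Centre and scale a covariate
#'
#' Centred to mean zero and scaled to unit sample standard deviation
#' (n - 1 denominator), the convention used for length and condition factor
#' in all models.
#'
#' @param values Numeric vector with at least two distinct non-missing
#'   values.
#' @return The scaled vector.
#' @export
scale_covariate <- function(values) {
  v <- values[!is.na(values)]
  if (length(unique(v)) < 2L) stop("cannot scale a constant covariate", call. = FALSE)
  (values - mean(v)) / stats::sd(v)
}

#' Filter individuals by study inclusion rules
#'
#' Applies, in order: fork length below `min_length_cm` (strict `<`),
#' missing genotype/sex columns listed in `require`, and (optionally)
#' precociously mature males flagged in a logical `mature_male` column. Each
#' removed row is counted under the first rule it fails, so audit counts sum
#' to rows removed.
#'
#' @param data Per-individual tibble with `fork_length` plus the required
#'   columns.
#' @param min_length_cm Exclusion threshold on fork length (default 9 cm).
#' @param require Columns that must be non-missing (default vgll3, six6,
#'   sex).
#' @param drop_mature_males Drop rows with `mature_male == TRUE` when the
#'   column is present.
#' @return The filtered tibble, with the audit log (tibble `rule`,
#'   `n_removed`) attached as attribute `"audit"`; retrieve with
#'   [filter_audit()].
#' @export
filter_individuals <- function(data, min_length_cm = 9,
                               require = c("vgll3", "six6", "sex"),
                               drop_mature_males = TRUE) {
  stopifnot("fork_length" %in% names(data))
  keep <- rep(TRUE, nrow(data))
  audit <- list()
  claim <- function(bad, rule) {
    bad <- bad & keep
    audit[[rule]] <<- sum(bad)
    keep <<- keep & !bad
  }
  claim(!is.na(data$fork_length) & data$fork_length < min_length_cm, "short_length")
  for (col in require) {
    stopifnot(col %in% names(data))
    claim(is.na(data[[col]]), paste0("missing_", col))
  }
  if (drop_mature_males && "mature_male" %in% names(data)) {
    claim(!is.na(data$mature_male) & data$mature_male, "mature_male")
  }
  out <- data[keep, , drop = FALSE]
  attr(out, "audit") <- tibble::tibble(
    rule = names(audit), n_removed = unlist(audit, use.names = FALSE)
  )
  out
}

#' Retrieve the audit log attached by [filter_individuals()]
#' @param data A tibble returned by [filter_individuals()].
#' @return A tibble with `rule` and `n_removed`.
#' @export
filter_audit <- function(data) {
  a <- attr(data, "audit", exact = TRUE)
  if (is.null(a)) stop("no audit log attached; was this filtered?", call. = FALSE)
  a
}

#' Build the modelling trait table
#'
#' Joins extracted trait values to the per-individual covariate/genotype
#' table and adds the model covariates: scaled fork length `L`, Fulton's
#' condition factor and its scaled version `CF`. Scaling is done across
#' individuals (not replicate rows) so replicate structure cannot tilt the
#' covariate distribution.
#'
#' @param traits Long trait tibble (`specimen_id`, `plane`, `replicate`,
#'   `trait`, `value`).
#' @param individuals Per-individual tibble with `id`, `fork_length`,
#'   `weight`, `sex`, `feed`, `tank`, `family`, `vgll3`, `six6`.
#' @return A `trait_tbl` tibble: one row per trait measurement with all
#'   model covariates.
#' @export
build_trait_table <- function(traits, individuals) {
  ind <- dplyr::mutate(
    individuals,
    condition_factor = fulton_condition_factor(.data$weight, .data$fork_length),
    L = scale_covariate(.data$fork_length),
    CF = scale_covariate(.data$condition_factor)
  )
  out <- dplyr::inner_join(traits, ind, by = c(specimen_id = "id"))
  class(out) <- unique(c("trait_tbl", class(out)))
  out
}

#' Composite trait from standardised components
#'
#' Replicates are averaged per individual, each component trait is z-scored
#' across individuals, and the composite is the (weighted) mean of the
#' z-scores. Individuals missing any component get a missing composite.
#'
#' @param traits Long trait tibble.
#' @param components Character vector of at least two trait names.
#' @param weights Optional weights, one per component (default equal).
#' @param name Name of the new trait (default the components joined by
#'   `+`).
#' @return The input tibble with the composite trait rows appended
#'   (`replicate = 1`, plane of the first component).
#' @export
composite_trait <- function(traits, components, weights = NULL, name = NULL) {
  stopifnot(length(components) >= 2L)
  if (is.null(weights)) weights <- rep(1, length(components))
  stopifnot(length(weights) == length(components))
  weights <- weights / sum(weights)
  if (is.null(name)) name <- paste(components, collapse = "+")
  avg <- average_replicates(traits[traits$trait %in% components, ])
  missing <- setdiff(components, unique(avg$trait))
  if (length(missing)) stop("component trait(s) not present: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  z <- dplyr::mutate(dplyr::group_by(avg, .data$trait),
                     z = as.numeric(scale(.data$value)))
  z <- dplyr::ungroup(z)
  wtbl <- tibble::tibble(trait = components, w = weights)
  z <- dplyr::inner_join(z, wtbl, by = "trait")
  comp <- dplyr::summarise(
    dplyr::group_by(z, .data$specimen_id),
    value = if (dplyr::n() == length(components)) sum(.data$w * .data$z) else NA_real_,
    .groups = "drop"
  )
  comp <- dplyr::mutate(comp, plane = avg$plane[match(components[1L], avg$trait)],
                        replicate = 1L, trait = name)
  dplyr::bind_rows(traits, comp[, c("specimen_id", "plane", "replicate", "trait", "value")])
}
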