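#' Read a pedigree from a three-column CSV
#'
#' The file must have a header `id,sire,dam`. Empty fields (or `NA`) denote
#' unknown parents, which are treated as founders. Rows need not be sorted;
#' a topological order (parents before offspring) is established internally.
#'
#' @param path Path to a CSV file with columns `id`, `sire`, `dam`.
#' @return A tibble of class `ped_tbl` with character columns `id`, `sire`,
#'   `dam` (`NA` = unknown parent), topologically ordered.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", na.strings = c("", "NA"))
  names(raw) <- tolower(names(raw))
  if (!all(c("id", "sire", "dam") %in% names(raw))) {
    stop("pedigree CSV must have columns id, sire, dam", call. = FALSE)
  }
  as_pedigree(raw[, c("id", "sire", "dam")])
}

#' Build a pedigree table from a data frame
#'
#' Validates pedigree invariants (unique ids, no individual its own ancestor)
#' and sorts records so that parents precede their offspring. Parents that are
#' named but never appear as individuals are added as founder records, with a
#' message.
#'
#' @param data A data frame with columns `id`, `sire`, `dam`.
#' @return A `ped_tbl` tibble, topologically ordered.
#' @export
as_pedigree <- function(data) {
  ped <- tibble::tibble(
    id   = as.character(data$id),
    sire = as.character(data$sire),
    dam  = as.character(data$dam)
  )
  ped$sire[!is.na(ped$sire) & ped$sire == ""] <- NA_character_
  ped$dam[!is.na(ped$dam) & ped$dam == ""] <- NA_character_
  if (anyNA(ped$id) || any(ped$id == "")) stop("pedigree ids must be non-missing", call. = FALSE)
  if (anyDuplicated(ped$id)) {
    stop("duplicated pedigree ids: ", paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "),
         call. = FALSE)
  }
  parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$id)
  if (length(parents)) {
    message("adding ", length(parents), " unlisted parent(s) as founders: ",
            paste(utils::head(parents, 5), collapse = ", "),
            if (length(parents) > 5) ", ..." else "")
    ped <- dplyr::bind_rows(
      tibble::tibble(id = parents, sire = NA_character_, dam = NA_character_),
      ped
    )
  }
  ped <- ped_toposort(ped)
  class(ped) <- c("ped_tbl", class(ped))
  ped
}

# Kahn's algorithm; errors on cycles (an individual that is its own ancestor).
ped_toposort <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    stop("pedigree contains a cycle (an individual is its own ancestor)", call. = FALSE)
  }
  ped[order, , drop = FALSE]
}

#' Additive (numerator) relationship matrix from a pedigree
#'
#' Uses the standard tabular recursion: for individual `i` with parents `s`
#' and `d`, `A[i, i] = 1 + A[s, d] / 2` and `A[i, j] = (A[j, s] + A[j, d]) / 2`
#' for previously processed `j`. Unknown parents contribute 0 (founders are
#' non-inbred and mutually unrelated).
#'
#' @param pedigree A data frame coercible via [as_pedigree()].
#' @return A dense symmetric numeric matrix with dimnames = individual ids,
#'   ordered parents-before-offspring.
#' @export
additive_relationship_matrix <- function(pedigree) {
  ped <- if (inherits(pedigree, "ped_tbl")) pedigree else as_pedigree(pedigree)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (is.na(s)) 0 else A[j, s]) + (if (is.na(d)) 0 else A[j, d]))
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules: `A^-1 = sum_i alpha_i * w_i w_i'` where `w_i` has 1 at
#' `i` and -1/2 at each known parent, and `alpha_i = 1 / d_i` with
#' `d_i = 1 - (F_s + F_d) / 4 - ...` computed from parental inbreeding
#' (diagonal of A). Also returns `log det A = sum log d_i`, used by the
#' animal-model likelihood.
#'
#' @param pedigree A data frame coercible via [as_pedigree()].
#' @return A list with `Ainv` (a `dsCMatrix`), `logdet` (log determinant of
#'   A) and `ids`.
#' @export
additive_relationship_inverse <- function(pedigree) {
  ped <- if (inherits(pedigree, "ped_tbl")) pedigree else as_pedigree(pedigree)
  A <- additive_relationship_matrix(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  Fi <- unname(diag(A)) - 1  # inbreeding coefficients
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  logdet <- 0
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    dsd <- 1 -
      (if (!is.na(s)) 0.25 * (1 + Fi[s]) else 0) -
      (if (!is.na(d)) 0.25 * (1 + Fi[d]) else 0)
    logdet <- logdet + log(dsd)
    alpha <- 1 / dsd
    mem <- c(i, s, d); w <- c(1, -0.5, -0.5)
    keep <- !is.na(mem)
    mem <- mem[keep]; w <- w[keep]
    for (a in seq_along(mem)) for (b in seq_along(mem)) {
      ii <- c(ii, mem[a]); jj <- c(jj, mem[b]); xx <- c(xx, alpha * w[a] * w[b])
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Ainv <- Matrix::forceSymmetric(Matrix::drop0(Ainv))
  list(Ainv = Ainv, logdet = logdet, ids = ped$id)
}

#' Encode a biallelic genotype string additively
#'
#' Counts L alleles: `"EE" -> 0`, `"EL"`/`"LE" -> 1`, `"LL" -> 2`. Numeric
#' input already in `{0, 1, 2}` is passed through, so files may mix both
#' encodings. Vectorised; `NA` propagates.
#'
#' @param genotype Character (or numeric) vector of genotypes.
#' @return Integer vector of L-allele counts in `{0, 1, 2}`.
#' @export
encode_additive_genotype <- function(genotype) {
  if (is.numeric(genotype)) {
    bad <- !is.na(genotype) & !genotype %in% c(0, 1, 2)
    if (any(bad)) stop("numeric genotype codes must be 0, 1 or 2", call. = FALSE)
    return(as.integer(genotype))
  }
  g <- toupper(trimws(as.character(genotype)))
  g[g == ""] <- NA_character_
  out <- rep(NA_integer_, length(g))
  known <- c(EE = 0L, EL = 1L, LE = 1L, LL = 2L, `0` = 0L, `1` = 1L, `2` = 2L)
  hit <- match(g, names(known))
  bad <- is.na(hit) & !is.na(g)
  if (any(bad)) {
    stop("invalid genotype string(s): ", paste(unique(g[bad]), collapse = ", "),
         " (expected EE/EL/LE/LL or 0/1/2)", call. = FALSE)
  }
  out[!is.na(hit)] <- known[hit[!is.na(hit)]]
  out
}

#' Decode an additive genotype code to its genotype string
#'
#' @param code Integer vector in `{0, 1, 2}`.
#' @return Character vector `"EE"`, `"EL"` or `"LL"`.
#' @export
decode_additive_genotype <- function(code) {
  if (any(!is.na(code) & !code %in% c(0, 1, 2))) {
    stop("codes must be 0, 1 or 2", call. = FALSE)
  }
  c("EE", "EL", "LL")[as.integer(code) + 1L]
}

#' Allele frequencies from additive genotype codes
#'
#' @param codes Vector of codes in `{0, 1, 2}` (L-allele counts); `NA`
#'   dropped.
#' @return A tibble with one row: `freq_E`, `freq_L`, `n` (individuals used).
#' @export
allele_frequencies <- function(codes) {
  codes <- codes[!is.na(codes)]
  if (!length(codes)) stop("no non-missing genotype codes", call. = FALSE)
  if (any(!codes %in% c(0, 1, 2))) stop("codes must be 0, 1 or 2", call. = FALSE)
  freq_L <- sum(codes) / (2 * length(codes))
  tibble::tibble(freq_E = 1 - freq_L, freq_L = freq_L, n = length(codes))
}

#' Read a genotype table
#'
#' Expects columns `id`, `vgll3`, `six6`, `sex`; genotypes may be given as
#' EE/EL/LE/LL strings or 0/1/2 codes and are returned as additive codes.
#'
#' @param path Path to a CSV file.
#' @return A tibble with `id`, `vgll3`, `six6` (integer codes) and `sex`.
#' @export
read_genotypes <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", na.strings = c("", "NA"))
  names(raw) <- tolower(names(raw))
  need <- c("id", "vgll3", "six6", "sex")
  if (!all(need %in% names(raw))) {
    stop("genotype CSV must have columns id, vgll3, six6, sex", call. = FALSE)
  }
  tibble::tibble(
    id = raw$id,
    vgll3 = encode_additive_genotype(raw$vgll3),
    six6 = encode_additive_genotype(raw$six6),
    sex = ifelse(is.na(raw$sex), NA_character_, tolower(raw$sex))
  )
}
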