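#' Read landmark configurations
#'
#' Supported formats: classic TPS (`LM=`, pairs of coordinates, `ID=`,
#' optional `SCALE=` and `IMAGE=` records) and a wide CSV dialect with
#' columns `id, plane, replicate, x0, y0, x1, y1, ...`. Missing landmarks are
#' flagged as `NA` coordinates (TPS: coordinates of `-999`; CSV: empty
#' cells), never zero-filled.
#'
#' Landmark indices are 0-based throughout, matching the trait-definition
#' convention.
#'
#' @param path File path.
#' @param format `"tps"` or `"csv"`; guessed from the file extension by
#'   default.
#' @param plane Plane label to attach when the file does not carry one
#'   (TPS files); one of `"body"`, `"small_xsec"`, `"large_xsec"`.
#' @return A `landmark_tbl`: a long tibble with columns `specimen_id`,
#'   `plane`, `replicate`, `landmark` (0-based integer), `x`, `y`.
#' @export
read_landmarks <- function(path, format = c("auto", "tps", "csv"), plane = "body") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  }
  out <- if (format == "tps") read_landmarks_tps(path, plane) else read_landmarks_csv(path)
  validate_landmark_tbl(out, where = path)
}

read_landmarks_tps <- function(path, plane) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (!length(starts)) stop("no LM= records found in TPS file: ", path, call. = FALSE)
  ends <- c(starts[-1L] - 1L, length(lines))
  seen <- character(0)
  blocks <- purrr::map2(starts, ends, function(s, e) {
    k <- as.integer(sub("^LM\\s*=\\s*", "", lines[s], ignore.case = TRUE))
    body <- lines[(s + 1L):e]
    coord_lines <- utils::head(body, k)
    if (length(coord_lines) < k || any(!grepl("^[-0-9.eE+ \t]+$", coord_lines))) {
      stop("TPS block starting at line ", s, " has fewer than LM=", k,
           " coordinate lines", call. = FALSE)
    }
    xy <- do.call(rbind, lapply(strsplit(coord_lines, "[ \t]+"), as.numeric))
    if (ncol(xy) != 2L) stop("TPS coordinates must be x y pairs", call. = FALSE)
    meta <- body[-seq_len(k)]
    getrec <- function(tag) {
      hit <- grep(paste0("^", tag, "\\s*="), meta, ignore.case = TRUE)
      if (length(hit)) sub(paste0("^", tag, "\\s*=\\s*"), "", meta[hit[1L]], ignore.case = TRUE) else NA_character_
    }
    id <- getrec("ID")
    if (is.na(id)) id <- paste0("specimen", length(seen) + 1L)
    scale <- suppressWarnings(as.numeric(getrec("SCALE")))
    if (!is.na(scale)) xy <- xy * scale
    xy[xy <= -999] <- NA_real_
    xy[rowSums(is.na(xy)) > 0L, ] <- NA_real_
    rep_i <- sum(seen == id) + 1L
    seen <<- c(seen, id)
    tibble::tibble(
      specimen_id = id, plane = plane, replicate = rep_i,
      landmark = seq_len(k) - 1L, x = xy[, 1L], y = xy[, 2L]
    )
  })
  dplyr::bind_rows(blocks)
}

read_landmarks_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  names(raw) <- tolower(names(raw))
  if (!"id" %in% names(raw)) stop("landmark CSV needs an id column", call. = FALSE)
  if (!"plane" %in% names(raw)) raw$plane <- "body"
  if (!"replicate" %in% names(raw)) raw$replicate <- 1L
  xcols <- grep("^x[0-9]+$", names(raw), value = TRUE)
  k <- length(xcols)
  if (!k) stop("landmark CSV needs x0,y0,x1,y1,... columns", call. = FALSE)
  idx <- sort(as.integer(sub("^x", "", xcols)))
  if (!identical(idx, 0:(k - 1L))) {
    stop("landmark columns must be consecutive from x0/y0", call. = FALSE)
  }
  missing_y <- setdiff(paste0("y", idx), names(raw))
  if (length(missing_y)) stop("missing columns: ", paste(missing_y, collapse = ", "), call. = FALSE)
  long <- purrr::map(idx, function(j) {
    tibble::tibble(
      specimen_id = as.character(raw$id),
      plane = as.character(raw$plane),
      replicate = as.integer(raw$replicate),
      landmark = j,
      x = as.numeric(raw[[paste0("x", j)]]),
      y = as.numeric(raw[[paste0("y", j)]])
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(long), .data$specimen_id, .data$replicate, .data$landmark)
  out$x[is.na(out$y)] <- NA_real_
  out$y[is.na(out$x)] <- NA_real_
  out
}

validate_landmark_tbl <- function(tbl, where = "input") {
  counts <- dplyr::summarise(
    dplyr::group_by(tbl, .data$plane, .data$specimen_id, .data$replicate),
    k = dplyr::n(), .groups = "drop"
  )
  bad <- dplyr::group_by(counts, .data$plane)
  bad <- dplyr::filter(bad, .data$k != .data$k[1L])
  if (nrow(bad)) {
    stop("inconsistent landmark count in ", where, " for specimen(s): ",
         paste(unique(bad$specimen_id), collapse = ", "), call. = FALSE)
  }
  if (any(is.finite(tbl$x) != is.finite(tbl$y))) {
    stop("landmark coordinates must be missing pairwise in ", where, call. = FALSE)
  }
  class(tbl) <- unique(c("landmark_tbl", class(tbl)))
  tbl
}

#' Write landmark configurations to a TPS file
#'
#' Missing landmarks are written as `-999 -999`. One block per
#' specimen/replicate; replicates appear as repeated `ID=` blocks in
#' replicate order, which [read_landmarks()] maps back to replicate numbers.
#'
#' @param landmarks A `landmark_tbl` (single plane).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landmarks_tps <- function(landmarks, path) {
  stopifnot(length(unique(landmarks$plane)) == 1L)
  groups <- dplyr::group_split(
    dplyr::arrange(landmarks, .data$specimen_id, .data$replicate, .data$landmark),
    .data$specimen_id, .data$replicate
  )
  con <- file(path, "w")
  on.exit(close(con))
  for (g in groups) {
    writeLines(paste0("LM=", nrow(g)), con)
    xy <- cbind(g$x, g$y)
    xy[is.na(xy)] <- -999
    writeLines(sprintf("%.6f %.6f", xy[, 1L], xy[, 2L]), con)
    writeLines(paste0("ID=", g$specimen_id[1L]), con)
  }
  invisible(path)
}

# landmark_tbl -> k x 2 x n array + per-config metadata (one plane).
landmarks_to_array <- function(landmarks) {
  stopifnot(length(unique(landmarks$plane)) == 1L)
  landmarks <- dplyr::arrange(landmarks, .data$specimen_id, .data$replicate, .data$landmark)
  meta <- dplyr::distinct(landmarks, .data$specimen_id, .data$plane, .data$replicate)
  k <- nrow(landmarks) / nrow(meta)
  arr <- array(NA_real_, dim = c(k, 2L, nrow(meta)))
  arr[, 1L, ] <- matrix(landmarks$x, nrow = k)
  arr[, 2L, ] <- matrix(landmarks$y, nrow = k)
  list(coords = arr, meta = meta)
}

array_to_landmarks <- function(coords, meta) {
  k <- dim(coords)[1L]
  out <- tidyr::uncount(meta, weights = k)
  out$landmark <- rep(0:(k - 1L), nrow(meta))
  out$x <- as.vector(coords[, 1L, ])
  out$y <- as.vector(coords[, 2L, ])
  validate_landmark_tbl(out)
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all landmarks from
#' their centroid (centre of gravity); the standard geometric-morphometrics
#' size measure, in the units of the input coordinates (cm here).
#'
#' @param coords A k x 2 numeric matrix of landmark coordinates (no missing
#'   values; impute first).
#' @return A single non-negative number.
#' @export
centroid_size <- function(coords) {
  coords <- as.matrix(coords)
  if (anyNA(coords)) stop("centroid size undefined with missing landmarks; impute first", call. = FALSE)
  ctr <- colMeans(coords)
  sqrt(sum(sweep(coords, 2L, ctr)^2))
}

#' Centroid sizes for every configuration in a landmark table
#'
#' @param landmarks A `landmark_tbl` (single plane).
#' @return A tibble `specimen_id`, `plane`, `replicate`, `centroid_size`.
#' @export
centroid_sizes <- function(landmarks) {
  dat <- landmarks_to_array(landmarks)
  cs <- apply(dat$coords, 3L, centroid_size)
  dplyr::mutate(dat$meta, centroid_size = cs)
}
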