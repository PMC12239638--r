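#' Generalized Procrustes analysis of landmark configurations
#'
#' Iterative superimposition removing translation, scale and rotation:
#' every configuration is centred, scaled to unit centroid size, and rotated
#' onto the current consensus by the SVD-optimal proper rotation (reflections
#' are corrected by a sign flip of the smallest singular vector, preserving
#' chirality). The consensus is recomputed each sweep and iteration stops
#' when the summed squared deviation from the consensus changes by less than
#' `tol`. Aligned configurations keep centroid size exactly 1.
#'
#' @param landmarks A `landmark_tbl` with complete configurations (no missing
#'   landmarks) on one plane, at least two configurations.
#' @param tol Convergence tolerance on the change in the Procrustes
#'   objective (sum of squared deviations from the consensus).
#' @param max_iter Maximum number of sweeps; exceeding it is an error.
#' @return An object of class `gpa_alignment`: list with `aligned` (a
#'   `landmark_tbl` of shape variables), `consensus` (tibble `landmark`,
#'   `x`, `y`), `centroid_sizes` (tibble, original sizes in cm), `meta`,
#'   `iterations` and `objective_trace`.
#' @export
gpa_align <- function(landmarks, tol = 1e-8, max_iter = 100L) {
  dat <- landmarks_to_array(landmarks)
  coords <- dat$coords
  n <- dim(coords)[3L]
  if (n < 2L) stop("generalized Procrustes analysis needs at least 2 configurations", call. = FALSE)
  if (anyNA(coords)) {
    stop("missing landmarks present; impute with impute_missing_landmarks() first", call. = FALSE)
  }
  cs <- apply(coords, 3L, centroid_size)
  if (any(cs <= 0)) stop("degenerate configuration with zero centroid size", call. = FALSE)
  for (i in seq_len(n)) {
    coords[, , i] <- sweep(coords[, , i], 2L, colMeans(coords[, , i]))
    coords[, , i] <- coords[, , i] / cs[i]
  }
  consensus <- coords[, , 1L]
  consensus <- consensus / centroid_size(consensus)
  trace <- numeric(0)
  obj_old <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      coords[, , i] <- coords[, , i] %*% kabsch_rotation(coords[, , i], consensus)
    }
    consensus <- apply(coords, c(1L, 2L), mean)
    obj <- sum(sweep(coords, c(1L, 2L), consensus)^2)
    trace <- c(trace, obj)
    if (is.finite(obj_old) && obj_old - obj < tol) break
    if (iter >= max_iter) {
      stop("GPA did not converge after ", max_iter, " iterations; objective trace: ",
           paste(signif(utils::tail(trace, 5), 6), collapse = ", "), call. = FALSE)
    }
    obj_old <- obj
  }
  structure(
    list(
      aligned = array_to_landmarks(coords, dat$meta),
      consensus = tibble::tibble(landmark = 0:(dim(coords)[1L] - 1L),
                                 x = consensus[, 1L], y = consensus[, 2L]),
      centroid_sizes = dplyr::mutate(dat$meta, centroid_size = cs),
      meta = dat$meta,
      iterations = iter,
      objective_trace = trace
    ),
    class = "gpa_alignment"
  )
}

#' @export
print.gpa_alignment <- function(x, ...) {
  cat("Generalized Procrustes alignment\n")
  cat("  configurations:", nrow(x$meta), " landmarks:", nrow(x$consensus), "\n")
  cat("  iterations:", x$iterations,
      " objective:", signif(utils::tail(x$objective_trace, 1L), 6), "\n")
  invisible(x)
}

# Optimal proper rotation R (det = +1) minimising ||X R - Y||^2.
kabsch_rotation <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Procrustes distance between two configurations
#'
#' Full Procrustes superimposition (centring, unit centroid size, optimal
#' proper rotation) followed by the root summed squared difference.
#'
#' @param a,b k x 2 coordinate matrices.
#' @return A non-negative number.
#' @export
procrustes_distance <- function(a, b) {
  a <- scale(as.matrix(a), scale = FALSE); a <- a / sqrt(sum(a^2))
  b <- scale(as.matrix(b), scale = FALSE); b <- b / sqrt(sum(b^2))
  sqrt(sum((a %*% kabsch_rotation(a, b) - b)^2))
}

# Thin-plate-spline interpolation coefficients mapping src (k x 2, complete)
# onto dst (k x 2); returns a function evaluating the warp at new points.
tps_warp <- function(src, dst) {
  k <- nrow(src)
  U <- function(r2) ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))  # r^2 log r
  D2 <- as.matrix(stats::dist(src))^2
  K <- U(D2)
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  W <- solve(L, rhs)
  function(pts) {
    pts <- matrix(pts, ncol = 2L)
    d2 <- outer(rowSums(pts^2), rowSums(src^2), "+") - 2 * pts %*% t(src)
    d2[d2 < 0] <- 0
    U(d2) %*% W[seq_len(k), , drop = FALSE] +
      cbind(1, pts) %*% W[k + 1:3, , drop = FALSE]
  }
}

#' Impute missing landmarks by thin-plate-spline warping
#'
#' For each configuration with missing landmarks, a thin-plate spline is
#' fitted from the consensus positions of the observed landmarks to their
#' observed coordinates, and the missing landmarks are read off the warped
#' consensus. The warp reproduces affine maps exactly, so affinely distorted
#' specimens are imputed without error. Observed coordinates are never
#' modified.
#'
#' @param landmarks A `landmark_tbl`, possibly with missing landmarks.
#' @param reference A `gpa_alignment` (its consensus drives the warp) or a
#'   k x 2 reference matrix. If `NULL`, a GPA of the complete configurations
#'   in `landmarks` is used.
#' @param min_observed Minimum observed landmarks per configuration
#'   (at least 3, the thin-plate spline minimum).
#' @return A `landmark_tbl` with all landmarks filled in.
#' @export
impute_missing_landmarks <- function(landmarks, reference = NULL, min_observed = 3L) {
  if (!anyNA(landmarks$x)) return(landmarks)
  if (is.null(reference)) {
    dat <- landmarks_to_array(landmarks)
    complete <- apply(dat$coords, 3L, function(m) !anyNA(m))
    if (sum(complete) < 2L) stop("not enough complete configurations to build a reference", call. = FALSE)
    keep <- dat$meta[complete, ]
    reference <- gpa_align(dplyr::semi_join(landmarks, keep,
                                            by = c("specimen_id", "plane", "replicate")))
  }
  ref <- if (inherits(reference, "gpa_alignment")) {
    as.matrix(reference$consensus[, c("x", "y")])
  } else {
    as.matrix(reference)
  }
  dat <- landmarks_to_array(landmarks)
  coords <- dat$coords
  for (i in seq_len(dim(coords)[3L])) {
    m <- coords[, , i]
    miss <- is.na(m[, 1L])
    if (!any(miss)) next
    if (sum(!miss) < max(3L, min_observed)) {
      stop("configuration ", dat$meta$specimen_id[i], " has fewer than ",
           max(3L, min_observed), " observed landmarks; cannot impute", call. = FALSE)
    }
    warp <- tps_warp(ref[!miss, , drop = FALSE], m[!miss, , drop = FALSE])
    m[miss, ] <- warp(ref[miss, , drop = FALSE])
    coords[, , i] <- m
  }
  array_to_landmarks(coords, dat$meta)
}

#' Flag outlier configurations after Procrustes alignment
#'
#' For every aligned landmark the Euclidean deviation from the consensus is
#' compared with the root-mean-square deviation of that landmark across all
#' configurations. A landmark is an outlier when its deviation exceeds
#' `sd_threshold` times that RMS deviation; a configuration is excluded when
#' it has two or more outlier landmarks (a single stray landmark is
#' retained).
#'
#' @param alignment A `gpa_alignment`.
#' @param sd_threshold Multiplier on the per-landmark RMS deviation
#'   (default 4).
#' @return A tibble with `specimen_id`, `plane`, `replicate`,
#'   `n_outlier_landmarks`, `exclude`.
#' @export
flag_outlier_configurations <- function(alignment, sd_threshold = 4) {
  stopifnot(inherits(alignment, "gpa_alignment"))
  dat <- landmarks_to_array(alignment$aligned)
  cons <- as.matrix(alignment$consensus[, c("x", "y")])
  dev <- sweep(dat$coords, c(1L, 2L), cons)
  d <- sqrt(dev[, 1L, ]^2 + dev[, 2L, ]^2)          # k x n distances
  d <- matrix(d, nrow = nrow(cons))
  rms <- sqrt(rowMeans(d^2))
  out <- d > sd_threshold * rms
  n_out <- colSums(out)
  dplyr::mutate(dat$meta, n_outlier_landmarks = as.integer(n_out),
                exclude = n_out >= 2L)
}
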