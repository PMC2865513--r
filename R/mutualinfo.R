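#' Resolve a bin count for histogram estimators
#'
#' `"auto"` applies the cube-root rule `floor(n^(1/3))` clamped to
#' \[5, 50\]: about 27 bins per axis at n = 20,000 and about 10 at the
#' typical trajectory length of ~1,000 frames. With a fixed modest bin
#' count the histogram estimator of strongly dependent variables is biased
#' low by discretization alone, so the default grows slowly with n.
#'
#' @param bins Positive integer (>= 2) or `"auto"`.
#' @param n Sample size.
#' @return Integer bin count.
#' @export
resolve_bins <- function(bins, n) {
  if (identical(bins, "auto")) return(as.integer(clamp(floor(n^(1 / 3)), 5, 50)))
  if (!is.numeric(bins) || bins < 2) stop("bins must be >= 2 or 'auto'")
  as.integer(bins)
}

bin_indices <- function(x, nb, range = NULL) {
  lo <- if (is.null(range)) min(x) else range[1]
  hi <- if (is.null(range)) max(x) else range[2]
  if (hi - lo <= 0) return(rep(1L, length(x)))     # constant variable: one bin
  br <- seq(lo, hi, length.out = nb + 1)
  findInterval(x, br, all.inside = TRUE)
}

#' Plug-in histogram mutual information
#'
#' The Shannon mutual information `I(X, Y) = sum P(x, y) ln[P(x, y) /
#' (P_X(x) P_Y(y))]` of two real-valued series, estimated from their joint
#' histogram on an equal-width grid (bin edges from each variable's
#' min-max range unless `range_x`/`range_y` are given). The plug-in
#' estimate is non-negative and equals zero when a variable is constant
#' (single occupied bin). Reported in nats.
#'
#' @param x,y Paired numeric vectors (equal length, n >= 4).
#' @param bins_x,bins_y Bins per axis (integer or `"auto"`, see
#'   [resolve_bins()]).
#' @param range_x,range_y Optional fixed `c(lo, hi)` binning ranges.
#' @return Mutual information in nats.
#' @export
histogram_mi <- function(x, y, bins_x = "auto", bins_y = bins_x,
                         range_x = NULL, range_y = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must be paired (equal length)")
  if (n < 4) stop("at least 4 paired samples are required")
  nbx <- resolve_bins(bins_x, n)
  nby <- resolve_bins(bins_y, n)
  ix <- bin_indices(x, nbx, range_x)
  iy <- bin_indices(y, nby, range_y)
  joint <- table(ix, iy) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  max(mi, 0)
}

#' Mutual information extrapolated to infinite sample size
#'
#' The plug-in histogram MI is biased upward at finite n, to first order
#' linearly in k = 1/n. The estimator computes the MI on random subsamples
#' at several fractions of the data, fits a straight line to the (k, MI)
#' points, and reports the intercept at k = 0 (infinite data).
#'
#' @param x,y Paired numeric vectors.
#' @param bins Bins per axis (integer or `"auto"`, resolved at the full
#'   sample size and held fixed across subsamples).
#' @param fractions Subsample fractions (default 1, 1/2, 1/4, 1/8).
#' @param replicates Random subsamples per fraction (default 10;
#'   the full-data fraction is computed once).
#' @param seed Optional integer making the subsampling reproducible; the
#'   caller's RNG state is left untouched.
#' @return Object of class `mi_estimate`: `value` (the intercept, nats),
#'   `slope`, and the subsample table (`n`, `k`, `mi` per evaluation).
#' @export
extrapolated_mi <- function(x, y, bins = "auto",
                            fractions = c(1, 0.5, 0.25, 0.125),
                            replicates = 10, seed = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must be paired (equal length)")
  stopifnot(all(fractions > 0), all(fractions <= 1), replicates >= 1)
  nb <- resolve_bins(bins, n)
  n_min <- ceiling(n * min(fractions))
  if (n_min < 10 * nb) {
    stop(sprintf(paste0("smallest subsample (%d) is below the minimum of ",
                        "10 x bins = %d; provide at least %d samples"),
                 n_min, 10 * nb, ceiling(10 * nb / min(fractions))))
  }
  rows <- with_seed(seed, {
    out <- list()
    for (f in sort(fractions, decreasing = TRUE)) {
      m <- round(n * f)
      reps <- if (f == 1) 1L else replicates
      for (r in seq_len(reps)) {
        idx <- if (f == 1) seq_len(n) else sample.int(n, m)
        out[[length(out) + 1]] <- data.frame(
          n = m, k = 1 / m,
          mi = histogram_mi(x[idx], y[idx], bins_x = nb, bins_y = nb))
      }
    }
    do.call(rbind, out)
  })
  fit <- stats::lm(mi ~ k, data = rows)
  structure(list(value = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 subsamples = rows, bins = nb, n = n),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("MI = %.4f nats (k->0 intercept; %d bins/axis, n = %d, slope %.3g)\n",
              x$value, x$bins, x$n, x$slope))
  invisible(x)
}

#' Mutual-information matrix between reaction coordinates
#'
#' Pairwise extrapolated MI between named coordinates (e.g. the quaternary
#' projection and the four tertiary projections), as used to quantify which
#' subunits are coupled to the quaternary transition.
#'
#' @param coords Named list of [projection_series()] (shared frame times)
#'   or plain numeric vectors of equal length.
#' @param pairs Optional list of length-2 character vectors naming the
#'   pairs to evaluate; default: all unordered pairs of distinct
#'   coordinates.
#' @param ... Passed to [extrapolated_mi()] (`bins`, `fractions`,
#'   `replicates`).
#' @param seed Optional integer seed; pair `i` uses `seed + i` so the
#'   whole matrix is reproducible.
#' @return Symmetric numeric matrix of MI values (nats) with an
#'   `estimates` attribute holding the per-pair `mi_estimate` objects.
#' @export
mi_matrix <- function(coords, pairs = NULL, ..., seed = NULL) {
  stopifnot(length(coords) >= 2, !is.null(names(coords)))
  vals <- lapply(coords, function(s) {
    if (inherits(s, "projection_series")) s$value else as.numeric(s)
  })
  if (length(unique(vapply(vals, length, integer(1)))) != 1) {
    stop("all coordinates must have the same number of frames")
  }
  times <- lapply(coords, function(s) {
    if (inherits(s, "projection_series")) s$time else NULL
  })
  times <- times[!vapply(times, is.null, logical(1))]
  if (length(times) > 1 &&
      !all(vapply(times[-1], function(t) all(t == times[[1]]), logical(1)))) {
    stop("coordinate series have mismatched frame times")
  }
  ids <- names(coords)
  if (is.null(pairs)) {
    pairs <- utils::combn(ids, 2, simplify = FALSE)
  }
  M <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  est <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    e <- extrapolated_mi(vals[[p[1]]], vals[[p[2]]], ...,
                         seed = if (is.null(seed)) NULL else seed + i)
    M[p[1], p[2]] <- M[p[2], p[1]] <- e$value
    est[[paste(p, collapse = "|")]] <- e
  }
  attr(M, "estimates") <- est
  M
}

#' Average MI matrices across trajectories
#'
#' Entry-wise mean of per-trajectory MI matrices, e.g. to average the
#' quaternary-tertiary coupling over several independent transitions.
#'
#' @param matrices List of matrices from [mi_matrix()] with identical
#'   dimnames.
#' @return The mean matrix.
#' @export
average_mi_matrices <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
}
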