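#' PCA subspace from reference crystal structures
#'
#' Builds the low-dimensional subspace spanned by a set of reference
#' structures (e.g. the T, R and R2 states of hemoglobin): the references
#' are iteratively superposed onto their running mean, and a PCA of the
#' resulting coordinate ensemble yields at most `k - 1` non-degenerate
#' eigenvectors for `k` structures. With the three hemoglobin references
#' exactly two eigenvalues are non-zero and the eigenvectors span the
#' R-R2-T plane; projections onto them visualize quaternary transitions.
#'
#' @param references List of >= 2 `tetramer_model`s.
#' @param spec Atom selection (default C-alpha + heme atoms).
#' @param labels Structure names; defaults to `names(references)` or
#'   `ref1..refk`. The sign of each eigenvector is fixed so the first
#'   reference (conventionally T) has a non-negative coordinate.
#' @param n_vectors Number of eigenvectors to keep (default 2, capped at
#'   the covariance rank).
#' @return Object of class `pc_basis`: mean coordinates (`N x 3` nm), kept
#'   `eigenvectors` (`3N x m`, orthonormal), all `eigenvalues` (nm^2),
#'   the atom `keys`, `selection`, `labels`, and `ref_projections`
#'   (`k x m`, the references' own coordinates in the subspace).
#' @export
build_xray_pca <- function(references, spec = selection_spec("calpha_heme"),
                           labels = NULL, n_vectors = 2) {
  k <- length(references)
  if (k < 2) stop("at least 2 reference structures are required")
  labels <- labels %||% names(references) %||% paste0("ref", seq_len(k))
  cs <- common_selection(references, spec)
  keys <- cs[[1]]$keys
  coords <- lapply(cs, `[[`, "xyz")

  # iterative superposition onto the running mean
  target <- coords[[1]]
  for (iter in 1:20) {
    fitted <- lapply(coords, function(x) {
      sp <- kabsch_superpose(x, target)
      apply_superposition(sp, x)
    })
    new_target <- Reduce(`+`, fitted) / k
    delta <- max(abs(new_target - target))
    target <- new_target
    if (delta < 1e-12) break
  }
  mean_coords <- target

  X <- do.call(rbind, lapply(fitted, flatten_xyz))     # k x 3N
  Xc <- sweep(X, 2, flatten_xyz(mean_coords))
  sv <- svd(Xc)
  eigenvalues <- sv$d^2 / (k - 1)
  rank <- sum(eigenvalues > 1e-12)
  m <- min(n_vectors, rank)
  if (m < 1) stop("reference structures are numerically identical")
  vec <- sv$v[, seq_len(m), drop = FALSE]

  # sign convention: the first reference projects non-negatively
  proj <- Xc %*% vec
  for (j in seq_len(m)) {
    anchor <- which(abs(proj[, j]) > 1e-12)[1]
    if (!is.na(anchor) && proj[anchor, j] < 0) {
      vec[, j] <- -vec[, j]
      proj[, j] <- -proj[, j]
    }
  }
  rownames(proj) <- labels

  structure(list(mean_coords = mean_coords, eigenvectors = vec,
                 eigenvalues = eigenvalues, keys = keys, selection = spec,
                 labels = labels, ref_projections = proj),
            class = "pc_basis")
}

#' @export
print.pc_basis <- function(x, ...) {
  cat("X-ray PC basis from", length(x$labels), "structures (",
      paste(x$labels, collapse = ", "), ")\n")
  cat("  eigenvalues (nm^2):",
      paste(format(x$eigenvalues, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Project frames onto the crystal-structure eigenvectors
#'
#' Each frame is superposed onto the basis mean over the basis selection,
#' then its centered coordinates are dotted with the eigenvectors.
#'
#' @param frames A `tetramer_model` or list of them.
#' @param basis A `pc_basis` from [build_xray_pca()].
#' @return Named list of [projection_series()] (`pc1`, `pc2`, ...) in nm.
#' @export
project_frames <- function(frames, basis) {
  if (inherits(frames, "tetramer_model")) frames <- list(frames)
  mean_flat <- flatten_xyz(basis$mean_coords)
  proj <- vapply(frames, function(f) {
    x <- match_selection(f, basis$selection, basis$keys)
    sp <- kabsch_superpose(x, basis$mean_coords)
    as.vector(crossprod(basis$eigenvectors,
                        flatten_xyz(apply_superposition(sp, x)) - mean_flat))
  }, numeric(ncol(basis$eigenvectors)))
  proj <- matrix(proj, nrow = ncol(basis$eigenvectors))
  times <- vapply(frames, `[[`, numeric(1), "frame_time")
  out <- lapply(seq_len(nrow(proj)), function(j) {
    projection_series(times, proj[j, ], coordinate_id = paste0("pc", j),
                      units = "nm")
  })
  names(out) <- paste0("pc", seq_along(out))
  out
}

#' Normalized difference-vector reaction coordinate
#'
#' The displacement between two endpoint structures, normalized so the
#' `plus` endpoint (T or t) projects to +1 and the `minus` endpoint (R or
#' r) to -1. The quaternary coordinate uses the C-alpha + heme atoms of the
#' whole tetramer; a tertiary coordinate restricts the selection to one
#' subunit (plus its heme) and superposes on that subunit only, so it
#' measures the internal t-r rearrangement. `half_span` is half the
#' coordinate-space distance between the endpoints, in nm: the raw
#' projection corresponding to a normalized value of 1.
#'
#' @param endpoint_plus,endpoint_minus `tetramer_model`s (conventionally
#'   the T/t and R/r structures).
#' @param scope `"quaternary"` or `"tertiary"`.
#' @param subunit Required for tertiary scope: one subunit label.
#' @param spec Optional custom [selection_spec()] overriding the defaults.
#' @param labels Length-2 structure names for the plus/minus endpoints.
#' @return Object of class `difference_vector`.
#' @export
build_difference_vector <- function(endpoint_plus, endpoint_minus,
                                    scope = c("quaternary", "tertiary"),
                                    subunit = NULL, spec = NULL,
                                    labels = c("T", "R")) {
  scope <- match.arg(scope)
  if (is.null(spec)) {
    spec <- if (scope == "quaternary") {
      selection_spec("calpha_heme")
    } else {
      if (is.null(subunit) || !(subunit %in% SUBUNITS)) {
        stop("tertiary scope requires subunit in ",
             paste(SUBUNITS, collapse = ", "))
      }
      selection_spec("calpha_heme", subunits = subunit)
    }
  }
  cs <- common_selection(list(endpoint_plus, endpoint_minus), spec)
  fit_coords <- cs[[2]]$xyz                       # minus endpoint = fit frame
  sp <- kabsch_superpose(cs[[1]]$xyz, fit_coords)
  plus_fitted <- apply_superposition(sp, cs[[1]]$xyz)
  diff <- flatten_xyz(plus_fitted) - flatten_xyz(fit_coords)
  span <- sqrt(sum(diff^2))
  if (span < 1e-9) stop("endpoints are identical: zero-length difference vector")
  direction <- diff / span
  raw_minus <- sum(flatten_xyz(fit_coords) * direction)
  raw_plus <- raw_minus + span
  structure(list(
    direction = direction, half_span = span / 2,
    midpoint_offset = (raw_plus + raw_minus) / 2,
    fit_coords = fit_coords, keys = cs[[2]]$keys, selection = spec,
    scope = scope, subunit = subunit,
    endpoint_plus = labels[1], endpoint_minus = labels[2]
  ), class = "difference_vector")
}

#' @export
print.difference_vector <- function(x, ...) {
  cat(sprintf("%s difference vector %s(+1) <- %s(-1)%s: half span %.4g nm\n",
              x$scope, x$endpoint_plus, x$endpoint_minus,
              if (is.null(x$subunit)) "" else paste0(" [", x$subunit, "]"),
              x$half_span))
  invisible(x)
}

#' Normalized projection of frames onto a difference vector
#'
#' Each frame is superposed onto the vector's fit frame over the vector's
#' selection (whole tetramer for quaternary, one subunit for tertiary),
#' then projected and scaled so the defining endpoints map to exactly
#' +1 and -1. Values beyond +-1 are legal: conformations "beyond" the
#' endpoint structures occur.
#'
#' @param frames A `tetramer_model` or list of them.
#' @param dv A [build_difference_vector()] result.
#' @return A scalar for a single frame, otherwise a [projection_series()]
#'   with units `"normalized"`.
#' @export
normalized_projection <- function(frames, dv) {
  single <- inherits(frames, "tetramer_model")
  if (single) frames <- list(frames)
  vals <- vapply(frames, function(f) {
    x <- match_selection(f, dv$selection, dv$keys)
    sp <- kabsch_superpose(x, dv$fit_coords)
    raw <- sum(flatten_xyz(apply_superposition(sp, x)) * dv$direction)
    (raw - dv$midpoint_offset) / dv$half_span
  }, numeric(1))
  if (single) return(vals)
  times <- vapply(frames, `[[`, numeric(1), "frame_time")
  id <- if (dv$scope == "quaternary") "quaternary" else dv$subunit
  projection_series(times, vals, coordinate_id = id, units = "normalized")
}

#' Assign quaternary states from a normalized projection
#'
#' A frame is assigned to the R state if its normalized quaternary
#' projection is below -0.5, to the T state if above +0.5, and is left
#' unassigned otherwise (boundary values are unassigned: the rule uses
#' strict inequalities).
#'
#' @param series A normalized [projection_series()].
#' @return Data frame of class `state_assignment` with columns `time` and
#'   `state` (factor with levels R, T, unassigned).
#' @export
assign_quaternary_state <- function(series) {
  if (!is_normalized_series(series)) {
    stop("state assignment requires a normalized projection series")
  }
  state <- rep("unassigned", nrow(series))
  state[series$value < -0.5] <- "R"
  state[series$value > +0.5] <- "T"
  out <- data.frame(time = series$time,
                    state = factor(state, levels = c("R", "T", "unassigned")))
  class(out) <- c("state_assignment", "data.frame")
  out
}

#' Conditional tertiary-state populations
#'
#' Histograms of the normalized tertiary projections of each subunit,
#' conditioned on the quaternary state (R or T) of the tetramer; frames
#' with unassigned quaternary state are excluded. Each (subunit, state)
#' histogram is normalized to unit area. Empty classes are flagged in the
#' `empty_classes` attribute, not raised as errors.
#'
#' @param series_tert Named list (by subunit) of normalized
#'   [projection_series()].
#' @param states A `state_assignment` with the same frame times.
#' @param breaks Histogram bin edges (default 40 bins on \[-2, 2\], covering
#'   the populated range beyond the endpoint structures).
#' @return Data frame with columns `subunit`, `quaternary_state`,
#'   `bin_left`, `bin_right`, `count`, `density`.
#' @export
tertiary_population <- function(series_tert, states,
                                breaks = seq(-2, 2, length.out = 41)) {
  stopifnot(inherits(states, "state_assignment"), length(series_tert) > 0)
  widths <- diff(breaks)
  rows <- list()
  empty <- character(0)
  for (su in names(series_tert)) {
    s <- series_tert[[su]]
    if (!is_normalized_series(s)) stop("tertiary series must be normalized")
    if (nrow(s) != nrow(states) || any(s$time != states$time)) {
      stop("tertiary series and state assignment must share frame times")
    }
    for (st in c("R", "T")) {
      v <- s$value[states$state == st]
      cnt <- if (length(v) == 0) {
        rep(0L, length(widths))
      } else {
        v <- clamp(v, breaks[1], breaks[length(breaks)])
        as.integer(table(cut(v, breaks, include.lowest = TRUE)))
      }
      dens <- if (sum(cnt) > 0) cnt / sum(cnt) / widths else rep(0, length(widths))
      if (sum(cnt) == 0) empty <- c(empty, paste(su, st, sep = "/"))
      rows[[length(rows) + 1]] <- data.frame(
        subunit = su, quaternary_state = st,
        bin_left = breaks[-length(breaks)], bin_right = breaks[-1],
        count = cnt, density = dens, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "empty_classes") <- empty
  out
}
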