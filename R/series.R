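#' Time series of a scalar reaction coordinate
#'
#' Lightweight container used for PCA projections, normalized
#' difference-vector projections, rotRMSD traces and rotation angles.
#'
#' @param times Frame times in ns.
#' @param values Coordinate values (units in `units`).
#' @param coordinate_id Short identifier, e.g. `"quaternary"` or `"beta1"`.
#' @param units `"nm"`, `"normalized"` or `"degrees"`.
#' @return A data frame of class `projection_series` with columns `time`
#'   and `value` and attributes `coordinate_id` and `units`.
#' @export
projection_series <- function(times, values, coordinate_id = "coord",
                              units = c("nm", "normalized", "degrees")) {
  units <- match.arg(units)
  stopifnot(length(times) == length(values))
  out <- data.frame(time = as.numeric(times), value = as.numeric(values))
  attr(out, "coordinate_id") <- coordinate_id
  attr(out, "units") <- units
  class(out) <- c("projection_series", "data.frame")
  out
}

#' @export
print.projection_series <- function(x, ...) {
  cat(sprintf("Projection series '%s' (%s), %d frames\n",
              attr(x, "coordinate_id"), attr(x, "units"), nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf("  t in [%g, %g] ns, value in [%g, %g]\n",
                min(x$time), max(x$time), min(x$value), max(x$value)))
  }
  invisible(x)
}

is_normalized_series <- function(x) {
  identical(attr(x, "units"), "normalized")
}

#' Drop frames after the closest approach to a reference
#'
#' Truncates a series at the global minimum of a companion rotRMSD trace
#' (earliest minimum on ties): frames after the closest approach to the
#' target state are removed, e.g. before mutual-information analysis of a
#' transition.
#'
#' @param series A [projection_series()] to truncate.
#' @param rotrmsd_series A [projection_series()] of rotRMSD values with the
#'   same frame times.
#' @return The truncated `series`.
#' @export
truncate_at_closest_approach <- function(series, rotrmsd_series) {
  if (nrow(series) != nrow(rotrmsd_series) ||
      any(series$time != rotrmsd_series$time)) {
    stop("series and rotrmsd_series must share frame times")
  }
  imin <- which.min(rotrmsd_series$value)  # earliest global minimum
  out <- series[seq_len(imin), , drop = FALSE]
  attributes(out)[c("coordinate_id", "units")] <-
    attributes(series)[c("coordinate_id", "units")]
  class(out) <- class(series)
  out
}
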