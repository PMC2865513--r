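#' Center-of-mass axis of the alpha2-beta2 dimer
#'
#' The line connecting the COM of the alpha2 subunit to the COM of the
#' beta2 subunit, after superposing the frame's alpha1-beta1 backbone onto
#' the reference's -- a rigid-body orientation marker for the dimer whose
#' rotation signals the quaternary transition.
#'
#' @param frame,reference `tetramer_model`s with all four subunits.
#' @return Object of class `dimer_axis`: `origin` (COM of alpha2, nm),
#'   `tip` (COM of beta2, nm), `direction` (unit 3-vector).
#' @export
dimer_axis <- function(frame, reference) {
  spec1 <- selection_spec("backbone", subunits = c("alpha1", "beta1"))
  d1 <- common_selection(list(frame, reference), spec1)
  sp <- kabsch_superpose(d1[[1]]$xyz, d1[[2]]$xyz)
  anchored <- frame
  anchored$xyz <- apply_superposition(sp, frame$xyz)
  origin <- center_of_mass(anchored, "alpha2")
  tip <- center_of_mass(anchored, "beta2")
  v <- tip - origin
  len <- sqrt(sum(v^2))
  if (len < 1e-12) stop("degenerate dimer axis: coincident subunit COMs")
  structure(list(origin = origin, tip = tip, direction = v / len),
            class = "dimer_axis")
}

#' Angle between two dimer axes
#'
#' @param frame_axis,reference_axis `dimer_axis` objects.
#' @return Angle in degrees, in \[0, 180\].
#' @export
axis_rotation_angle <- function(frame_axis, reference_axis) {
  stopifnot(inherits(frame_axis, "dimer_axis"),
            inherits(reference_axis, "dimer_axis"))
  d <- clamp(sum(frame_axis$direction * reference_axis$direction), -1, 1)
  acos(d) * 180 / pi
}

#' Minimal rotation mapping one axis direction onto another
#'
#' The rotation about the normalized cross product of the two directions,
#' by the angle between them. For parallel directions the angle is 0 and
#' the axis is undefined (flagged, not an error); for antiparallel
#' directions the axis is ambiguous and an error is raised.
#'
#' @param a,b `dimer_axis` objects.
#' @return Object of class `rotation_descriptor`: unit `axis` (or `NA`s
#'   with attribute `undefined_axis` when the angle is 0) and `angle`
#'   in degrees.
#' @export
minimal_rotation_between_axes <- function(a, b) {
  stopifnot(inherits(a, "dimer_axis"), inherits(b, "dimer_axis"))
  u <- a$direction
  v <- b$direction
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(cr^2))
  d <- sum(u * v)
  if (s < 1e-12) {
    if (d > 0) {
      rd <- rotation_descriptor(rep(NA_real_, 3), 0)
      attr(rd, "undefined_axis") <- TRUE
      return(rd)
    }
    stop("antiparallel axes: minimal rotation axis is ambiguous")
  }
  rotation_descriptor(cr / s, atan2(s, d) * 180 / pi)
}

rotation_descriptor <- function(axis, angle_deg) {
  structure(list(axis = axis, angle = angle_deg),
            class = "rotation_descriptor")
}

#' @export
print.rotation_descriptor <- function(x, ...) {
  cat(sprintf("Rotation: %.3f deg about (%s)\n", x$angle,
              paste(format(x$axis, digits = 4), collapse = ", ")))
  invisible(x)
}

# Axis/angle extraction from a proper rotation matrix; robust near 180 deg
# via the eigendecomposition of the symmetric part.
rotation_to_axis_angle <- function(R) {
  tr <- sum(diag(R))
  anti <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  s <- sqrt(sum(anti^2)) / 2          # |sin(theta)|
  angle <- atan2(s, (tr - 1) / 2)
  if (s > 1e-8) {
    axis <- anti / (2 * s)
  } else if (angle < 1e-8) {
    return(rotation_descriptor(rep(NA_real_, 3), 0))
  } else {
    # theta ~ pi: axis is the eigenvector of (R + I) with largest eigenvalue
    e <- eigen((R + t(R)) / 2 + diag(3), symmetric = TRUE)
    axis <- e$vectors[, 1]
    axis <- axis / sqrt(sum(axis^2))
  }
  rotation_descriptor(axis, angle * 180 / pi)
}

#' Full rigid-body rotation of the alpha2-beta2 dimer
#'
#' After anchoring the frame on the reference's alpha1-beta1 backbone, the
#' optimal rotation mapping the frame's alpha2-beta2 backbone onto the
#' reference's is extracted as an axis/angle descriptor. Between the
#' classic R and T hemoglobin crystal structures this is the well-known
#' 12-15 degree dimer rotation.
#'
#' @param frame,reference `tetramer_model`s with all four subunits.
#' @return A `rotation_descriptor` (angle in \[0, 180\] degrees).
#' @export
dimer_rotation_angle <- function(frame, reference) {
  spec1 <- selection_spec("backbone", subunits = c("alpha1", "beta1"))
  spec2 <- selection_spec("backbone", subunits = c("alpha2", "beta2"))
  d1 <- common_selection(list(frame, reference), spec1)
  sp <- kabsch_superpose(d1[[1]]$xyz, d1[[2]]$xyz)
  d2 <- common_selection(list(frame, reference), spec2)
  anchored <- apply_superposition(sp, d2[[1]]$xyz)
  sp2 <- kabsch_superpose(anchored, d2[[2]]$xyz)
  rotation_to_axis_angle(sp2$rotation)
}

#' Dimer-axis rotation angle along a trajectory
#'
#' Per-frame [axis_rotation_angle()] of the alpha2-beta2 COM axis against
#' the reference structure's axis.
#'
#' @param frames List of `tetramer_model`s.
#' @param reference Reference `tetramer_model` (conventionally the T
#'   structure).
#' @return A [projection_series()] in degrees.
#' @export
rotation_timeseries <- function(frames, reference) {
  if (inherits(frames, "tetramer_model")) frames <- list(frames)
  ref_axis <- dimer_axis(reference, reference)
  vals <- vapply(frames, function(f) {
    axis_rotation_angle(dimer_axis(f, reference), ref_axis)
  }, numeric(1))
  times <- vapply(frames, `[[`, numeric(1), "frame_time")
  projection_series(times, vals, coordinate_id = "axis_angle",
                    units = "degrees")
}
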