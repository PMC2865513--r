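#' Least-squares superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) RMSD between two paired point sets. The transform maps
#' `mobile` onto `reference`: `y = R x + t` for column vectors, i.e.
#' `mobile %*% t(R)` shifted by `t` for row-wise coordinate matrices.
#'
#' @param mobile,reference `N x 3` coordinate matrices (nm), `N >= 3`.
#' @param weights Optional per-atom non-negative weights (default uniform).
#' @return An object of class `superposition`: list with `rotation`
#'   (3x3, det +1), `translation` (length-3, nm) and `rmsd_fit` (nm).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3, ncol(reference) == 3)
  n <- nrow(mobile)
  if (nrow(reference) != n) stop("mobile and reference must have equal shapes")
  if (n < 3) stop("at least 3 points are required")
  w <- if (is.null(weights)) rep(1, n) else weights
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)

  sv_q <- svd(Q * sqrt(w))$d
  if (sv_q[2] < 1e-10 * max(sv_q[1], 1e-300)) {
    stop("degenerate (collinear) reference point set: rotation is not unique")
  }

  H <- crossprod(P * w, Q)            # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cr - as.vector(R %*% cm)
  fitted <- P %*% t(R)
  rmsd_fit <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  structure(list(rotation = R, translation = tr, rmsd_fit = rmsd_fit),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("Superposition: rmsd_fit =", format(x$rmsd_fit, digits = 6), "nm\n")
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sp A `superposition` from [kabsch_superpose()].
#' @param xyz `N x 3` coordinate matrix.
#' @return Transformed `N x 3` matrix.
#' @export
apply_superposition <- function(sp, xyz) {
  sweep(xyz %*% t(sp$rotation), 2, sp$translation, `+`)
}

#' Root-mean-square deviation between coordinate sets
#'
#' @param a,b `N x 3` coordinate matrices (nm).
#' @param fit If `TRUE`, `a` is optimally superposed onto `b` first;
#'   if `FALSE` the raw deviation is reported.
#' @param weights Optional per-atom weights (used for both fit and RMSD).
#' @return RMSD in nm.
#' @export
rmsd <- function(a, b, fit = TRUE, weights = NULL) {
  stopifnot(is.matrix(a), is.matrix(b), ncol(a) == 3,
            nrow(a) == nrow(b))
  if (nrow(a) == 0) stop("empty coordinate sets")
  if (fit) return(kabsch_superpose(a, b, weights)$rmsd_fit)
  w <- if (is.null(weights)) rep(1, nrow(a)) else weights
  w <- w / sum(w)
  sqrt(sum(w * rowSums((a - b)^2)))
}

#' RMSD between two models over a selection
#'
#' Resolves `spec` on both models, intersects common atoms, and computes
#' the (optionally fitted) RMSD.
#'
#' @param frame,reference `tetramer_model`s.
#' @param spec A [selection_spec()]; default whole-tetramer backbone.
#' @param fit Superpose before measuring (default `TRUE`).
#' @return RMSD in nm.
#' @export
model_rmsd <- function(frame, reference, spec = selection_spec("backbone"),
                       fit = TRUE) {
  cs <- common_selection(list(frame, reference), spec)
  rmsd(cs[[1]]$xyz, cs[[2]]$xyz, fit = fit)
}

#' Rotation-sensitive RMSD (rotRMSD)
#'
#' The backbone RMSD of the alpha2-beta2 dimer evaluated after superposing
#' only the alpha1-beta1 dimer onto the reference -- a distance measure that
#' is particularly sensitive to the rotation of the two dimers with respect
#' to each other, i.e. to the quaternary state. Both the anchoring fit and
#' the RMSD evaluation use the same reference structure.
#'
#' @param frame,reference `tetramer_model`s.
#' @param mode Atom set for both dimers (default `"backbone"`).
#' @return rotRMSD in nm.
#' @export
rot_rmsd <- function(frame, reference, mode = "backbone") {
  spec1 <- selection_spec(mode, subunits = c("alpha1", "beta1"))
  spec2 <- selection_spec(mode, subunits = c("alpha2", "beta2"))
  d1 <- common_selection(list(frame, reference), spec1)
  sp <- kabsch_superpose(d1[[1]]$xyz, d1[[2]]$xyz)
  d2 <- common_selection(list(frame, reference), spec2)
  rmsd(apply_superposition(sp, d2[[1]]$xyz), d2[[2]]$xyz, fit = FALSE)
}

#' rotRMSD time series over a trajectory
#'
#' @param frames List of `tetramer_model`s.
#' @param reference Reference `tetramer_model`.
#' @param mode Atom set (default `"backbone"`).
#' @return A [projection_series()] in nm.
#' @export
rot_rmsd_series <- function(frames, reference, mode = "backbone") {
  if (inherits(frames, "tetramer_model")) frames <- list(frames)
  vals <- vapply(frames, rot_rmsd, numeric(1), reference = reference, mode = mode)
  times <- vapply(frames, `[[`, numeric(1), "frame_time")
  projection_series(times, vals, coordinate_id = "rotRMSD", units = "nm")
}

#' Mass-weighted center of mass of a subunit
#'
#' Heavy atoms of the subunit only; heme atoms are excluded from the
#' subunit COM (they are labeled `HEM1`..`HEM4`, not as the subunit).
#'
#' @param model A `tetramer_model`.
#' @param subunit Subunit or heme label present in the model.
#' @return Length-3 position in nm.
#' @export
center_of_mass <- function(model, subunit) {
  idx <- which(model$atoms$subunit == subunit)
  if (length(idx) == 0) stop("no atoms labeled ", subunit)
  m <- model$atoms$mass[idx]
  colSums(model$xyz[idx, , drop = FALSE] * m) / sum(m)
}
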