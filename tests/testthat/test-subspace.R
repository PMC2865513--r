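# Helper: frames at fixed interpolation weights between the toy endpoints.
blend_frames <- function(toy, weights) {
  lapply(seq_along(weights), function(i) {
    w <- weights[i]
    m <- toy$endpoint_T
    m$xyz <- (1 - w) * toy$endpoint_T$xyz + w * toy$endpoint_R$xyz
    m$frame_time <- i - 1
    m
  })
}

test_that("PCA rank is bounded by k - 1 and collinear references give rank 1", {
  # three structures where C is the midpoint of A and B: rank 1
  a <- toy_default$endpoint_T
  b <- toy_default$endpoint_R
  mid <- blend_frames(toy_default, 0.5)[[1]]
  basis1 <- build_xray_pca(list(A = a, B = b, C = mid))
  expect_equal(sum(basis1$eigenvalues > 1e-12), 1)

  # generic k structures: rank k - 1 (verified for k = 2, 3, 4)
  for (k in 2:4) {
    seeds <- seq_len(k)
    refs <- lapply(seeds, function(s) {
      make_toy_tetramer(10, quat_angle_deg = 5 * s, tert_amplitude = 0.1,
                        seed = s)$endpoint_R
    })
    basis <- build_xray_pca(refs)
    expect_equal(sum(basis$eigenvalues > 1e-12), k - 1)
  }
  expect_error(build_xray_pca(list(a)), "at least 2")
})

test_that("three references span a plane that preserves their distances", {
  t_ref <- toy_default$endpoint_T
  r_ref <- toy_default$endpoint_R
  r2_ref <- make_toy_tetramer(10, quat_angle_deg = 7, tert_amplitude = 0.3,
                              seed = 12)$endpoint_R
  basis <- build_xray_pca(list(T = t_ref, R = r_ref, R2 = r2_ref))
  expect_equal(sum(basis$eigenvalues > 1e-12), 2)
  # eigenvectors orthonormal
  g <- crossprod(basis$eigenvectors)
  expect_equal(g, diag(2), tolerance = 1e-12, ignore_attr = TRUE)
  # sign convention: first reference has non-negative coordinates
  expect_true(all(basis$ref_projections["T", ] >= -1e-12))

  # pairwise 2-D distances equal the post-superposition 3N-space distances
  proj <- project_frames(list(t_ref, r_ref, r2_ref), basis)
  P2 <- cbind(proj$pc1$value, proj$pc2$value)
  cs <- hbquat:::common_selection(list(t_ref, r_ref, r2_ref), basis$selection)
  fitted <- lapply(cs, function(s) {
    sp <- kabsch_superpose(s$xyz, basis$mean_coords)
    hbquat:::flatten_xyz(apply_superposition(sp, s$xyz))
  })
  for (i in 1:2) for (j in (i + 1):3) {
    d2d <- sqrt(sum((P2[i, ] - P2[j, ])^2))
    d3n <- sqrt(sum((fitted[[i]] - fitted[[j]])^2))
    expect_equal(d2d, d3n, tolerance = 1e-9)
  }
  # projecting the references recovers their stored subspace coordinates
  expect_equal(P2, unname(basis$ref_projections), tolerance = 1e-9)
})

test_that("projection is invariant under rigid transforms and zero at the mean", {
  refs <- list(T = toy_default$endpoint_T, R = toy_default$endpoint_R,
               R2 = make_toy_tetramer(10, 7, 0.3, seed = 12)$endpoint_R)
  basis <- build_xray_pca(refs)
  frame <- blend_frames(toy_default, 0.3)[[1]]
  base <- project_frames(frame, basis)
  set.seed(4)
  R <- hbquat:::random_rotation(1)[[1]]
  moved <- transform_model(frame, R, c(3, -1, 2))
  got <- project_frames(moved, basis)
  expect_equal(got$pc1$value, base$pc1$value, tolerance = 1e-9)
  expect_equal(got$pc2$value, base$pc2$value, tolerance = 1e-9)

  mean_frame <- toy_default$endpoint_T
  mean_frame$xyz[select_atoms(mean_frame, basis$selection)$index, ] <-
    basis$mean_coords
  pm <- project_frames(mean_frame, basis)
  expect_equal(abs(pm$pc1$value), 0, tolerance = 1e-9)
  expect_equal(abs(pm$pc2$value), 0, tolerance = 1e-9)
})

test_that("difference vectors normalize their endpoints to exactly +/-1", {
  dv <- build_difference_vector(toy_default$endpoint_T,
                                toy_default$endpoint_R, "quaternary")
  expect_equal(normalized_projection(toy_default$endpoint_T, dv), 1,
               tolerance = 1e-12)
  expect_equal(normalized_projection(toy_default$endpoint_R, dv), -1,
               tolerance = 1e-12)
  # swapped endpoints: same half-span, negated direction
  dv_sw <- build_difference_vector(toy_default$endpoint_R,
                                   toy_default$endpoint_T, "quaternary")
  expect_equal(dv_sw$half_span, dv$half_span, tolerance = 1e-9)
  expect_equal(normalized_projection(toy_default$endpoint_T, dv_sw), -1,
               tolerance = 1e-12)
  # midpoint morph projects to 0
  mid <- blend_frames(toy_default, 0.5)[[1]]
  expect_equal(normalized_projection(mid, dv), 0, tolerance = 1e-9)
  # identical endpoints are rejected
  expect_error(build_difference_vector(toy_default$endpoint_T,
                                       toy_default$endpoint_T, "quaternary"),
               "identical")
})

test_that("tertiary vectors have the constructed half-span and scope", {
  toy <- make_toy_tetramer(10, quat_angle_deg = 14, tert_amplitude = 0.35,
                           seed = 6)
  # unrotated subunits carry exactly the constructed half-span
  for (su in c("alpha1", "beta1")) {
    dv <- build_difference_vector(toy$endpoint_T, toy$endpoint_R, "tertiary",
                                  subunit = su)
    expect_equal(dv$half_span, 0.35, tolerance = 1e-9)
  }
  # rotated subunits agree within the rotation-induced distortion (the
  # tertiary field rides on a 14-degree rotated dimer, order 1-2%)
  for (su in c("alpha2", "beta2")) {
    dv <- build_difference_vector(toy$endpoint_T, toy$endpoint_R, "tertiary",
                                  subunit = su)
    expect_equal(dv$half_span, 0.35, tolerance = 0.02)
  }
  expect_error(build_difference_vector(toy$endpoint_T, toy$endpoint_R,
                                       "tertiary"), "subunit")
})

test_that("a noiseless linear morph projects exactly linearly", {
  tr <- make_transition_trajectory(toy_default,
                                   morph_spec(n_frames = 41, seed = 2))
  s <- tr$truth$s
  dv <- build_difference_vector(toy_default$endpoint_T,
                                toy_default$endpoint_R, "quaternary")
  p <- normalized_projection(tr$frames, dv)
  expect_lt(max(abs(p$value - (1 - 2 * s))), 1e-9)
  expect_true(is.data.frame(p))
  expect_identical(attr(p, "units"), "normalized")

  # pure tertiary morph (no quaternary rotation): tertiary projections are
  # exactly linear too
  tr0 <- make_transition_trajectory(toy_no_quat,
                                    morph_spec(n_frames = 21, seed = 2))
  for (su in c("alpha1", "beta2")) {
    dvt <- build_difference_vector(toy_no_quat$endpoint_T,
                                   toy_no_quat$endpoint_R, "tertiary",
                                   subunit = su)
    pt <- normalized_projection(tr0$frames, dvt)
    expect_lt(max(abs(pt$value - (1 - 2 * tr0$truth$s))), 1e-9)
  }
})

test_that("values beyond +/-1 are legal projections", {
  # extrapolate past the R endpoint
  m <- toy_default$endpoint_T
  m$xyz <- (1 - 1.4) * toy_default$endpoint_T$xyz +
    1.4 * toy_default$endpoint_R$xyz
  dv <- build_difference_vector(toy_default$endpoint_T,
                                toy_default$endpoint_R, "quaternary")
  expect_lt(normalized_projection(m, dv), -1)
})

test_that("quaternary states follow the +/-0.5 rule with strict inequalities", {
  s <- projection_series(0:6, c(-0.7, -0.5, -0.2, 0, 0.2, 0.5, 0.6),
                         coordinate_id = "quaternary", units = "normalized")
  st <- assign_quaternary_state(s)
  expect_equal(as.character(st$state),
               c("R", "unassigned", "unassigned", "unassigned",
                 "unassigned", "unassigned", "T"))
  raw <- projection_series(0:2, c(0.1, 0.2, 0.3), units = "nm")
  expect_error(assign_quaternary_state(raw), "normalized")
})

test_that("tertiary populations are conditional unit-area histograms", {
  set.seed(31)
  n <- 10000
  quat <- projection_series(seq_len(n), c(rep(0.8, n / 2), rep(-0.8, n / 2)),
                            units = "normalized")
  states <- assign_quaternary_state(quat)
  # in T: mixture 0.8 N(-1, 0.1) + 0.2 N(+1, 0.1); in R: uniform on [-1, 1]
  tval <- ifelse(stats::runif(n / 2) < 0.8, stats::rnorm(n / 2, -1, 0.1),
                 stats::rnorm(n / 2, 1, 0.1))
  rval <- stats::runif(n / 2, -1, 1)
  tert <- list(beta1 = projection_series(seq_len(n), c(tval, rval),
                                         units = "normalized"))
  pop <- tertiary_population(tert, states)
  for (st in c("R", "T")) {
    h <- pop[pop$quaternary_state == st, ]
    expect_equal(sum(h$density * (h$bin_right - h$bin_left)), 1,
                 tolerance = 1e-9)
  }
  # mixture weight near -1 recovered within 0.05
  hT <- pop[pop$quaternary_state == "T", ]
  w_low <- sum(hT$count[hT$bin_right <= 0]) / sum(hT$count)
  expect_equal(w_low, 0.8, tolerance = 0.05)
  # uniform class is flat within sampling error
  hR <- pop[pop$quaternary_state == "R", ]
  occupied <- hR[hR$bin_left >= -1 & hR$bin_right <= 1, ]
  expect_lt(max(abs(occupied$density - 0.5)), 0.1)
  # empty classes are flagged, not errors
  all_T <- assign_quaternary_state(
    projection_series(seq_len(n), rep(0.9, n), units = "normalized"))
  pop2 <- tertiary_population(tert, all_T)
  expect_true("beta1/R" %in% attr(pop2, "empty_classes"))
  expect_equal(sum(pop2$count[pop2$quaternary_state == "R"]), 0)
})
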