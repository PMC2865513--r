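test_that("toy construction is deterministic and validates arguments", {
  a <- make_toy_tetramer(8, 12, 0.15, seed = 5)
  b <- make_toy_tetramer(8, 12, 0.15, seed = 5)
  expect_identical(a$endpoint_T$xyz, b$endpoint_T$xyz)
  expect_identical(a$endpoint_R$xyz, b$endpoint_R$xyz)
  c2 <- make_toy_tetramer(8, 12, 0.15, seed = 6)
  expect_false(identical(a$endpoint_R$xyz, c2$endpoint_R$xyz))
  expect_error(make_toy_tetramer(3), "n_res")
})

test_that("degenerate toys make degenerate reaction coordinates", {
  flat <- make_toy_tetramer(8, quat_angle_deg = 0, tert_amplitude = 0, seed = 1)
  expect_equal(flat$endpoint_T$xyz, flat$endpoint_R$xyz)
  expect_error(build_difference_vector(flat$endpoint_T, flat$endpoint_R,
                                       "quaternary"), "identical")
})

test_that("the generating quaternary angle and tertiary span are recovered", {
  toy <- make_toy_tetramer(10, quat_angle_deg = 14, tert_amplitude = 0,
                           seed = 2)
  rd <- dimer_rotation_angle(toy$endpoint_R, toy$endpoint_T)
  expect_equal(rd$angle, 14, tolerance = 1e-6)

  # tertiary half-span equals the construction amplitude, and matches the
  # direct displacement norm of the stored per-subunit field
  toy2 <- make_toy_tetramer(10, quat_angle_deg = 0, tert_amplitude = 0.5,
                            seed = 2)
  for (su in hbquat:::SUBUNITS) {
    dv <- build_difference_vector(toy2$endpoint_T, toy2$endpoint_R,
                                  "tertiary", subunit = su)
    rows <- toy2$sub_rows[[su]]
    sel <- toy2$endpoint_T$atoms$name[rows] == "CA" |
      toy2$endpoint_T$atoms$is_heme[rows]
    direct <- sqrt(sum(toy2$delta_tert[[su]][sel, ]^2)) / 2
    expect_equal(dv$half_span, 0.5, tolerance = 1e-9)
    expect_equal(dv$half_span, direct, tolerance = 1e-9)
  }
})

test_that("trajectories are deterministic and follow their schedule", {
  spec <- morph_spec(n_frames = 25, noise_sigma = 0.02, seed = 11)
  t1 <- make_transition_trajectory(toy_default, spec)
  t2 <- make_transition_trajectory(toy_default, spec)
  expect_identical(t1$frames[[17]]$xyz, t2$frames[[17]]$xyz)
  expect_identical(t1$truth, t2$truth)

  # noiseless fully coupled morph: endpoints at +1 and -1, truth s linear
  tr <- make_transition_trajectory(toy_default, morph_spec(n_frames = 11))
  dv <- build_difference_vector(toy_default$endpoint_T, toy_default$endpoint_R,
                                "quaternary")
  expect_equal(normalized_projection(tr$frames[[1]], dv), 1, tolerance = 1e-12)
  expect_equal(normalized_projection(tr$frames[[11]], dv), -1,
               tolerance = 1e-12)
  expect_equal(tr$truth$s, seq(0, 1, length.out = 11))
  expect_equal(tr$truth$c_beta1, tr$truth$s)   # coupling 1, lag 0

  # sigmoidal schedule spans [0, 1] monotonically; partial path stops early
  sig <- hbquat:::morph_schedule(morph_spec(n_frames = 50,
                                            schedule = "sigmoidal"))
  expect_equal(range(sig), c(0, 1))
  expect_true(all(diff(sig) > 0))
  part <- make_transition_trajectory(toy_default,
                                     morph_spec(n_frames = 11, s_max = 0.5))
  expect_equal(max(part$truth$s), 0.5)
  expect_gt(normalized_projection(part$frames[[11]], dv), -0.01)

  # lag shifts the tertiary schedule; invalid lags are rejected
  lag <- make_transition_trajectory(
    toy_default, morph_spec(n_frames = 20,
                            lags = c(alpha1 = 5, beta1 = 0, alpha2 = 0,
                                     beta2 = 0)))
  expect_equal(lag$truth$c_alpha1[1:6], rep(0, 6))
  expect_equal(lag$truth$c_alpha1[20], lag$truth$s[15])
  expect_error(morph_spec(n_frames = 10,
                          lags = c(alpha1 = 10, beta1 = 0, alpha2 = 0,
                                   beta2 = 0)),
               "lags")
  expect_error(morph_spec(couplings = c(alpha1 = 2, beta1 = 1, alpha2 = 1,
                                        beta2 = 1)),
               "couplings")
})

test_that("pipeline recovery of the quaternary ground truth scales with noise", {
  sigma <- 0.02
  tr <- make_transition_trajectory(
    toy_default, morph_spec(n_frames = 40, noise_sigma = sigma, seed = 9))
  dv <- build_difference_vector(toy_default$endpoint_T, toy_default$endpoint_R,
                                "quaternary")
  p <- normalized_projection(tr$frames, dv)
  resid <- p$value - (1 - 2 * tr$truth$s)
  # noise propagation: projecting N(0, sigma) coordinate noise onto a unit
  # 3N-vector and dividing by the half-span leaves sd = sigma / half_span
  bound <- sigma / dv$half_span
  expect_lt(sqrt(mean(resid^2)), 3 * bound)
})

test_that("gaussian pair generator matches its specification", {
  g <- make_gaussian_pairs(0, 1e5, seed = 8)
  expect_lt(abs(stats::cor(g$x, g$y)), 0.02)
  g2 <- make_gaussian_pairs(0.8, 2e4, seed = 8)
  expect_equal(stats::cor(g2$x, g2$y), 0.8, tolerance = 0.02)
  expect_identical(make_gaussian_pairs(0.8, 100, seed = 1),
                   make_gaussian_pairs(0.8, 100, seed = 1))
  expect_error(make_gaussian_pairs(1, 10), "rho")
})

test_that("MI ordering follows the generator couplings", {
  # beta subunits coupled (0.9), alpha uncoupled (0.1): MI(quat, beta) must
  # exceed MI(quat, alpha); a scaled-down version of the acceptance sweep
  hits <- 0
  for (s in 1:5) {
    toy <- make_toy_tetramer(8, 14, 0.25, seed = 40 + s)
    tr <- make_transition_trajectory(
      toy, morph_spec(n_frames = 800,
                      couplings = c(alpha1 = 0.1, beta1 = 0.9,
                                    alpha2 = 0.1, beta2 = 0.9),
                      noise_sigma = 0.01, seed = 50 + s))
    dv <- build_difference_vector(toy$endpoint_T, toy$endpoint_R, "quaternary")
    coords <- list(quaternary = normalized_projection(tr$frames, dv))
    for (su in hbquat:::SUBUNITS) {
      dvt <- build_difference_vector(toy$endpoint_T, toy$endpoint_R,
                                     "tertiary", subunit = su)
      coords[[su]] <- normalized_projection(tr$frames, dvt)
    }
    M <- mi_matrix(coords,
                   pairs = lapply(hbquat:::SUBUNITS,
                                  function(su) c("quaternary", su)),
                   seed = 60 + s)
    mi_beta <- mean(c(M["quaternary", "beta1"], M["quaternary", "beta2"]))
    mi_alpha <- mean(c(M["quaternary", "alpha1"], M["quaternary", "alpha2"]))
    hits <- hits + (mi_beta > mi_alpha)
  }
  expect_equal(hits, 5)
})
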