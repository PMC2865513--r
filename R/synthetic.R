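# Synthetic tetramers and morphing trajectories with known quaternary and
# tertiary ground truth. The geometry is an abstract helix-like toy, not a
# hemoglobin model: it reproduces the statistical structure the analyses
# assume (a rigid dimer rotation coupled to subunit-internal rearrangements
# plus noise), so every pipeline stage can be validated without structure
# downloads.

# One helical C-alpha trace with N, C, O backbone satellites, plus a
# 5-atom dummy "heme" group near the subunit center.
toy_subunit_atoms <- function(n_res, chain, resseq0 = 1) {
  i <- seq_len(n_res)
  ca <- cbind(0.23 * cos(i * 100 * pi / 180),
              0.23 * sin(i * 100 * pi / 180),
              0.15 * i)
  # backbone satellites at fixed local offsets from each CA
  off <- list(N = c(0.05, 0.10, -0.05), C = c(-0.06, -0.08, 0.05),
              O = c(-0.10, -0.02, 0.12))
  atoms <- list()
  xyz <- list()
  for (r in i) {
    for (nm in c("N", "CA", "C", "O")) {
      atoms[[length(atoms) + 1]] <- data.frame(
        name = nm, resname = "ALA", chain = chain, resseq = resseq0 + r - 1,
        element = substr(nm, 1, 1), is_heme = FALSE, stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1]] <- if (nm == "CA") ca[r, ] else ca[r, ] + off[[nm]]
    }
  }
  hem_center <- colMeans(ca) + c(0.45, 0, 0)
  hem_names <- c("FE", "C1", "C2", "C3", "C4")
  hem_el <- c("FE", "C", "C", "C", "C")
  hem_off <- rbind(c(0, 0, 0), c(0.2, 0, 0), c(-0.2, 0, 0),
                   c(0, 0.2, 0), c(0, -0.2, 0))
  for (h in 1:5) {
    atoms[[length(atoms) + 1]] <- data.frame(
      name = hem_names[h], resname = "HEM", chain = chain,
      resseq = resseq0 + n_res + 99, element = hem_el[h], is_heme = TRUE,
      stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1]] <- hem_center + hem_off[h, ]
  }
  list(atoms = do.call(rbind, atoms), xyz = do.call(rbind, xyz))
}

# Remove the rigid-body content of a displacement field u over the subset
# `sel` of atoms: after projection, sum(u[sel]) = 0 and sum(x[sel] x u[sel])
# = 0, so a least-squares fit of the deformed subset onto the original is
# exactly the identity. Atoms outside `sel` keep their (adjusted) values.
project_out_rigid <- function(u, x, sel) {
  xs <- sweep(x[sel, , drop = FALSE], 2, colMeans(x[sel, , drop = FALSE]))
  n <- nrow(xs)
  basis <- cbind(
    rep(c(1, 0, 0), times = n), rep(c(0, 1, 0), times = n),
    rep(c(0, 0, 1), times = n),
    flatten_xyz(cbind(0, -xs[, 3], xs[, 2])),
    flatten_xyz(cbind(xs[, 3], 0, -xs[, 1])),
    flatten_xyz(cbind(-xs[, 2], xs[, 1], 0))
  )
  dim(basis) <- c(3 * n, 6)
  q <- qr.Q(qr(basis))
  v <- flatten_xyz(u[sel, , drop = FALSE])
  v <- v - q %*% crossprod(q, v)
  u[sel, ] <- unflatten_xyz(as.vector(v))
  u
}

# Smooth low-frequency deformation field along the chain, seeded, with the
# rigid modes projected out over the C-alpha + heme atoms of the subunit.
toy_deformation <- function(atoms, xyz, amplitude) {
  ridx <- atoms$resseq - min(atoms$resseq[!atoms$is_heme]) + 1
  ridx[atoms$is_heme] <- max(ridx[!atoms$is_heme]) + 1
  t <- ridx / max(ridx)
  u <- matrix(0, nrow(xyz), 3)
  for (d in 1:3) {
    ph <- stats::runif(2, 0, 2 * pi)
    u[, d] <- sin(2 * pi * t + ph[1]) + 0.5 * sin(4 * pi * t + ph[2])
  }
  sel <- atoms$name == "CA" | atoms$is_heme
  u <- project_out_rigid(u, xyz, sel)
  nrm <- sqrt(sum(u[sel, ]^2))
  if (nrm < 1e-12) return(u * 0)
  u * (2 * amplitude / nrm)   # half-span over the calpha_heme set = amplitude
}

#' Build a synthetic toy tetramer with known endpoints
#'
#' Constructs two endpoint conformations of an abstract four-subunit
#' "tetramer" (helix-like chains A-D with dummy heme groups): the T
#' endpoint is the base geometry; the R endpoint differs by a rigid
#' rotation of the alpha2-beta2 dimer about a fixed axis through its COM
#' (the quaternary transition) plus a smooth subunit-internal deformation
#' of each subunit (the tertiary transitions). The construction is
#' additive, the tertiary fields carry no rigid-body component over the
#' C-alpha + heme atoms (so each subunit's tertiary half-span equals
#' `tert_amplitude` exactly), and the stored endpoints are mutually
#' superposed, so a linear Cartesian morph between them projects exactly
#' linearly onto the quaternary difference vector.
#'
#' @param n_res Residues per subunit (>= 5).
#' @param quat_angle_deg Rigid rotation angle of alpha2-beta2 between the
#'   endpoints, degrees.
#' @param tert_amplitude Tertiary half-span per subunit, nm.
#' @param seed Integer seed for the deformation fields.
#' @return Object of class `toy_tetramer`: `endpoint_T`, `endpoint_R`
#'   (`tetramer_model`s), `delta_quat` and `delta_tert` (per-subunit)
#'   displacement fields, and the generating parameters.
#' @export
make_toy_tetramer <- function(n_res = 12, quat_angle_deg = 14,
                              tert_amplitude = 0.2, seed = 1) {
  if (n_res < 5) stop("n_res must be >= 5")
  placements <- list(
    alpha1 = list(chain = "A", shift = c(0, 0, 0), rot = diag(3)),
    beta1 = list(chain = "B", shift = c(1.6, 0.3, 0.2),
                 rot = rotation_matrix(c(0, 0, 1), 120)),
    alpha2 = list(chain = "C", shift = c(0.4, 1.7, 0.1),
                  rot = rotation_matrix(c(0, 1, 0), 180)),
    beta2 = list(chain = "D", shift = c(1.8, 1.5, 0.4),
                 rot = rotation_matrix(c(1, 0, 0), 60))
  )
  atoms <- list()
  xyz <- list()
  for (su in SUBUNITS) {
    p <- placements[[su]]
    sub <- toy_subunit_atoms(n_res, p$chain)
    atoms[[su]] <- sub$atoms
    xyz[[su]] <- sweep(sub$xyz %*% t(p$rot), 2, p$shift, `+`)
  }
  at <- do.call(rbind, atoms)
  at$subunit <- ifelse(at$is_heme,
                       paste0("HEM", match(unname(default_chain_map()[at$chain]),
                                           SUBUNITS)),
                       unname(default_chain_map()[at$chain]))
  at$parent <- unname(default_chain_map()[at$chain])
  at$serial <- seq_len(nrow(at))
  at$mass <- element_mass(at$element)
  x_t <- do.call(rbind, xyz)

  sub_rows <- lapply(SUBUNITS, function(su) which(at$parent == su))
  names(sub_rows) <- SUBUNITS

  # quaternary field: rigid rotation of the alpha2-beta2 half about an
  # oblique axis through its COM
  d2 <- c(sub_rows$alpha2, sub_rows$beta2)
  axis <- c(0.3, 0.5, 0.8)
  com2 <- colMeans(x_t[d2, , drop = FALSE])
  R <- rotation_matrix(axis, quat_angle_deg)
  delta_quat <- matrix(0, nrow(at), 3)
  delta_quat[d2, ] <- sweep(sweep(x_t[d2, , drop = FALSE], 2, com2) %*% t(R),
                            2, com2, `+`) - x_t[d2, , drop = FALSE]

  delta_tert <- with_seed(seed, {
    lapply(sub_rows, function(rows) {
      toy_deformation(at[rows, , drop = FALSE], x_t[rows, , drop = FALSE],
                      tert_amplitude)
    })
  })

  x_r <- x_t + delta_quat
  for (su in SUBUNITS) x_r[sub_rows[[su]], ] <- x_r[sub_rows[[su]], ] +
    delta_tert[[su]]

  model_T <- tetramer_model(at, x_t, frame_time = 0)
  model_R <- tetramer_model(at, x_r, frame_time = 0)

  if (quat_angle_deg != 0 || tert_amplitude != 0) {
    # store the endpoints mutually superposed over the quaternary selection,
    # so straight-line morphs between them project exactly linearly
    spec <- selection_spec("calpha_heme")
    cs <- common_selection(list(model_R, model_T), spec)
    sp <- kabsch_superpose(cs[[1]]$xyz, cs[[2]]$xyz)
    x_r <- apply_superposition(sp, x_r)
    model_R <- tetramer_model(at, x_r, frame_time = 0)
  }

  structure(list(endpoint_T = model_T, endpoint_R = model_R,
                 delta_tert = delta_tert, sub_rows = sub_rows,
                 n_res = n_res, quat_angle_deg = quat_angle_deg,
                 tert_amplitude = tert_amplitude, seed = seed),
            class = "toy_tetramer")
}

#' Morph specification for synthetic trajectories
#'
#' @param n_frames Number of frames (>= 2).
#' @param schedule `"linear"`, `"sigmoidal"`, or a numeric vector of length
#'   `n_frames` giving a custom quaternary progress variable in \[0, 1\]
#'   (0 = T endpoint, 1 = R endpoint).
#' @param s_max Final quaternary progress (1 = full T-to-R transition,
#'   < 1 = partial).
#' @param couplings Named per-subunit coupling of the tertiary coordinate
#'   to the quaternary progress, each in \[0, 1\].
#' @param lags Named per-subunit lag, in frames, of the tertiary schedule.
#' @param noise_sigma Isotropic Gaussian coordinate noise, nm.
#' @param dt_ns Frame spacing, ns.
#' @param seed Integer seed; the whole trajectory is deterministic given
#'   the seed.
#' @return Object of class `morph_spec`.
#' @export
morph_spec <- function(n_frames = 200, schedule = "linear", s_max = 1,
                       couplings = c(alpha1 = 1, beta1 = 1, alpha2 = 1,
                                     beta2 = 1),
                       lags = c(alpha1 = 0, beta1 = 0, alpha2 = 0, beta2 = 0),
                       noise_sigma = 0, dt_ns = 0.1, seed = 1) {
  stopifnot(n_frames >= 2, noise_sigma >= 0, s_max > 0, s_max <= 1)
  couplings <- couplings[SUBUNITS]
  lags <- lags[SUBUNITS]
  if (anyNA(couplings) || any(couplings < 0) || any(couplings > 1)) {
    stop("couplings must be named for all four subunits and lie in [0, 1]")
  }
  if (anyNA(lags) || any(lags < 0)) stop("lags must be named and >= 0")
  if (any(lags >= n_frames)) stop("lags must be smaller than n_frames")
  if (is.numeric(schedule) && length(schedule) != n_frames) {
    stop("a custom schedule must have length n_frames")
  }
  structure(list(n_frames = n_frames, schedule = schedule, s_max = s_max,
                 couplings = couplings, lags = lags,
                 noise_sigma = noise_sigma, dt_ns = dt_ns, seed = seed),
            class = "morph_spec")
}

morph_schedule <- function(spec) {
  n <- spec$n_frames
  s <- if (is.numeric(spec$schedule)) {
    spec$schedule
  } else if (spec$schedule == "linear") {
    seq(0, 1, length.out = n)
  } else if (spec$schedule == "sigmoidal") {
    raw <- stats::plogis(12 * (seq(0, 1, length.out = n) - 0.5))
    (raw - raw[1]) / (raw[n] - raw[1])
  } else {
    stop("unknown schedule: ", spec$schedule)
  }
  s * spec$s_max
}

# Mean-zero Ornstein-Uhlenbeck path: the smooth "uncoupled" part of a
# tertiary coordinate, so low coupling yields structured but independent
# motion rather than white noise.
ou_path <- function(n, sd = 0.3, tau_frames = n / 10) {
  a <- exp(-1 / tau_frames)
  z <- numeric(n)
  z[1] <- stats::rnorm(1, 0, sd)
  innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - a^2))
  for (i in 2:n) z[i] <- a * z[i - 1] + innov[i - 1]
  z
}

#' Generate a synthetic transition trajectory with ground truth
#'
#' Frame `i` displaces the toy T endpoint by `s(i)` times the quaternary
#' field and, per subunit, by `c_sub(i)` times that subunit's tertiary
#' field, where `c_sub(i) = coupling * s(i - lag) + (1 - coupling) * z(i)`
#' with `z` a smooth Ornstein-Uhlenbeck path centered on 0.5. Isotropic
#' Gaussian coordinate noise is added last. With couplings 1, zero lag and
#' zero noise the trajectory is the straight Cartesian morph from the T to
#' the R endpoint.
#'
#' @param toy A [make_toy_tetramer()] result.
#' @param spec A [morph_spec()].
#' @return List with `frames` (list of `tetramer_model`s) and `truth`
#'   (data frame: `frame`, `time`, quaternary progress `s`, and the
#'   per-subunit tertiary progress `c_alpha1` .. `c_beta2`).
#' @export
make_transition_trajectory <- function(toy, spec = morph_spec()) {
  stopifnot(inherits(toy, "toy_tetramer"), inherits(spec, "morph_spec"))
  n <- spec$n_frames
  s <- morph_schedule(spec)
  x_t <- toy$endpoint_T$xyz
  delta_quat_full <- toy$endpoint_R$xyz - x_t
  for (su in SUBUNITS) {
    delta_quat_full[toy$sub_rows[[su]], ] <-
      delta_quat_full[toy$sub_rows[[su]], ] - toy$delta_tert[[su]]
  }

  with_seed(spec$seed, {
    cmat <- sapply(SUBUNITS, function(su) {
      lag <- spec$lags[[su]]
      cp <- spec$couplings[[su]]
      s_lag <- s[clamp(seq_len(n) - lag, 1, n)]
      z <- if (cp < 1) 0.5 + ou_path(n) else rep(0, n)
      cp * s_lag + (1 - cp) * z
    })
    frames <- vector("list", n)
    at <- toy$endpoint_T$atoms
    for (i in seq_len(n)) {
      x <- x_t + s[i] * delta_quat_full
      for (j in seq_along(SUBUNITS)) {
        rows <- toy$sub_rows[[SUBUNITS[j]]]
        x[rows, ] <- x[rows, ] + cmat[i, j] * toy$delta_tert[[SUBUNITS[j]]]
      }
      if (spec$noise_sigma > 0) {
        x <- x + matrix(stats::rnorm(length(x), 0, spec$noise_sigma),
                        nrow(x), 3)
      }
      frames[[i]] <- tetramer_model(at, x, frame_time = (i - 1) * spec$dt_ns)
    }
    truth <- data.frame(frame = seq_len(n), time = (seq_len(n) - 1) * spec$dt_ns,
                        s = s)
    truth[paste0("c_", SUBUNITS)] <- cmat
    list(frames = frames, truth = truth)
  })
}

#' Correlated Gaussian pairs for estimator validation
#'
#' Bivariate normal samples with unit variances and correlation `rho`.
#' The closed-form mutual information `-0.5 * ln(1 - rho^2)` makes this the
#' standard oracle for MI estimators.
#'
#' @param rho Correlation, `|rho| < 1`.
#' @param n Sample count.
#' @param seed Optional integer seed (caller RNG untouched).
#' @return Data frame with columns `x`, `y`.
#' @export
make_gaussian_pairs <- function(rho, n, seed = NULL) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  with_seed(seed, {
    x <- stats::rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
    data.frame(x = x, y = y)
  })
}

#' Closed-form Gaussian mutual information
#'
#' @param rho Correlation, `|rho| < 1`.
#' @return `-0.5 * log(1 - rho^2)` in nats.
#' @export
gaussian_mi <- function(rho) {
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1")
  -0.5 * log(1 - rho^2)
}
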