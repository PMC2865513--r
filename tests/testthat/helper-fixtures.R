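# Shared fixtures and independent oracles, built in code at test time.

# Cached small toys (deterministic) to avoid rebuilding per test.
toy_default <- make_toy_tetramer(n_res = 10, quat_angle_deg = 14,
                                 tert_amplitude = 0.2, seed = 3)
toy_no_tert <- make_toy_tetramer(n_res = 10, quat_angle_deg = 14,
                                 tert_amplitude = 0, seed = 3)
toy_no_quat <- make_toy_tetramer(n_res = 10, quat_angle_deg = 0,
                                 tert_amplitude = 0.25, seed = 3)

# Apply a rigid transformation to a whole model.
transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  model$xyz <- sweep(model$xyz %*% t(R), 2, t, `+`)
  model
}

# Minimal hand-built tetramer: 4 chains x `n_res` CA-only residues at given
# resnames, plus arbitrary extra atoms. Base CA positions are spread out so
# they never form spurious salt bridges.
bare_tetramer <- function(n_res = 3, resnames = NULL, extra = NULL) {
  rows <- list()
  xyz <- list()
  chains <- c("A", "B", "C", "D")
  for (ci in seq_along(chains)) {
    for (r in seq_len(n_res)) {
      rn <- if (is.null(resnames)) "ALA" else resnames[[chains[ci]]][r]
      rows[[length(rows) + 1]] <- data.frame(
        name = "CA", resname = rn, chain = chains[ci], resseq = r,
        element = "C", is_heme = FALSE, stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1]] <- c(10 * ci + r, 10 * ci, 0)
    }
  }
  at <- do.call(rbind, rows)
  x <- do.call(rbind, xyz)
  if (!is.null(extra)) {
    at <- rbind(at, extra[c("name", "resname", "chain", "resseq", "element",
                            "is_heme")])
    x <- rbind(x, as.matrix(extra[c("x", "y", "z")]))
  }
  cm <- default_chain_map()
  at$subunit <- ifelse(at$is_heme, paste0("HEM", match(cm[at$chain], hbquat:::SUBUNITS)),
                       unname(cm[at$chain]))
  at$parent <- unname(cm[at$chain])
  at$serial <- seq_len(nrow(at))
  at$mass <- hbquat:::element_mass(at$element)
  tetramer_model(at, x)
}

extra_atom <- function(name, resname, chain, resseq, x, y, z,
                       element = substr(name, 1, 1)) {
  data.frame(name = name, resname = resname, chain = chain, resseq = resseq,
             element = element, is_heme = FALSE, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

# ---- independent oracles -------------------------------------------------

# Brute-force salt-bridge oracle: nested loop over all residue pairs using
# its own charged-group bookkeeping.
oracle_salt_bridges <- function(model, cutoff) {
  neg_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  pos_atoms <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                    HIS = c("ND1", "NE2"))
  a <- model$atoms
  a$row <- seq_len(nrow(a))
  prot <- a[!a$is_heme & a$subunit %in% hbquat:::SUBUNITS, ]
  res <- unique(prot[c("chain", "resseq")])
  charged <- function(ch, rs, sign) {
    sub <- prot[prot$chain == ch & prot$resseq == rs, ]
    rn <- sub$resname[1]
    names <- character(0)
    if (sign < 0) {
      names <- c(names, neg_atoms[[rn]])
      if (rs == max(prot$resseq[prot$chain == ch])) names <- c(names, "O", "OXT")
    } else {
      names <- c(names, pos_atoms[[rn]])
      if (rs == min(prot$resseq[prot$chain == ch])) names <- c(names, "N")
    }
    sub$row[sub$name %in% names]
  }
  found <- character(0)
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      if (i == j) next
      ri <- res[i, ]; rj <- res[j, ]
      ai <- charged(ri$chain, ri$resseq, +1)
      aj <- charged(rj$chain, rj$resseq, -1)
      if (length(ai) == 0 || length(aj) == 0) next
      d2 <- outer(rowSums(model$xyz[ai, , drop = FALSE]^2),
                  rowSums(model$xyz[aj, , drop = FALSE]^2), `+`) -
        2 * model$xyz[ai, , drop = FALSE] %*%
          t(model$xyz[aj, , drop = FALSE])
      dmin <- min(sqrt(pmax(d2, 0)))
      if (dmin <= cutoff) {
        k1 <- paste(ri$chain, ri$resseq, sep = ":")
        k2 <- paste(rj$chain, rj$resseq, sep = ":")
        found <- c(found, paste(pmin(k1, k2), pmax(k1, k2), sep = "--"))
      }
    }
  }
  sort(unique(found))
}

# Brute-force minimum RMSD over a fixed set of random rotations (with
# optimal translation, i.e. centroids aligned), vectorized over rotations.
oracle_min_rotation_rmsd <- function(a, b, rotations) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  RT <- do.call(cbind, lapply(rotations, t))       # 3 x (3*m)
  M <- ac %*% RT                                   # n x (3*m)
  D <- M - matrix(bc, nrow(bc), ncol(RT))
  ss <- colSums(D^2)
  per_rot <- colSums(matrix(ss, nrow = 3))
  sqrt(min(per_rot) / nrow(a))
}

random_cloud <- function(n = 12, scale = 1) {
  matrix(stats::rnorm(3 * n, sd = scale), ncol = 3)
}
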