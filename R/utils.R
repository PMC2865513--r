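# Internal helpers shared across modules.

SUBUNITS <- c("alpha1", "beta1", "alpha2", "beta2")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded operations do not perturb the global stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Atomic masses (amu) for the heavy elements found in protein/heme PDB files.
ELEMENT_MASSES <- c(
  C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  FE = 55.845, ZN = 65.38, MG = 24.305, "NA" = 22.990, K = 39.098,
  CA = 40.078, CL = 35.45, CU = 63.546, MN = 54.938, H = 1.008, D = 2.014
)

element_mass <- function(element) {
  el <- toupper(trimws(element))
  m <- ELEMENT_MASSES[el]
  miss <- is.na(m)
  if (any(miss)) {
    warning(sprintf("unknown element(s) %s; using carbon mass",
                    paste(unique(el[miss]), collapse = ", ")))
    m[miss] <- ELEMENT_MASSES[["C"]]
  }
  unname(m)
}

# Uniform random rotation matrices via quaternions (Shoemake).
random_rotation <- function(n = 1) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  q <- cbind(sqrt(1 - u1) * sin(2 * pi * u2),
             sqrt(1 - u1) * cos(2 * pi * u2),
             sqrt(u1) * sin(2 * pi * u3),
             sqrt(u1) * cos(2 * pi * u3))
  lapply(seq_len(n), function(i) quat_to_rot(q[i, ]))
}

quat_to_rot <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Rotation matrix for a given axis (3-vector, any length > 0) and angle in
# degrees, via Rodrigues' formula.
rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

flatten_xyz <- function(m) as.vector(t(m))
unflatten_xyz <- function(v) matrix(v, ncol = 3, byrow = TRUE)
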