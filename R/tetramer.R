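#' Construct a labeled tetramer model
#'
#' A `tetramer_model` holds one conformation of an alpha2-beta2 tetramer:
#' an atom table with subunit labels and a coordinate matrix in nanometres.
#' Protein atoms carry one of the subunit labels `alpha1`, `beta1`,
#' `alpha2`, `beta2`; heme groups are labeled `HEM1`..`HEM4` and remember
#' the subunit whose chain they sit on (`parent`); anything else is
#' `other`. Atom order is stable across all package operations.
#'
#' @param atoms Data frame with columns `serial`, `name`, `resname`,
#'   `chain`, `resseq`, `element`, `mass`, `subunit`, `parent`, `is_heme`.
#' @param xyz Numeric `N x 3` matrix of coordinates in nm.
#' @param frame_time Time stamp in ns (0 for static structures).
#' @return An object of class `tetramer_model`.
#' @export
tetramer_model <- function(atoms, xyz, frame_time = 0) {
  stopifnot(is.data.frame(atoms), is.matrix(xyz), ncol(xyz) == 3,
            nrow(atoms) == nrow(xyz))
  req <- c("serial", "name", "resname", "chain", "resseq", "element",
           "mass", "subunit", "parent", "is_heme")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (any(!is.na(atoms$mass) & atoms$mass <= 0)) stop("atom masses must be > 0")
  if (any(!nzchar(atoms$name))) stop("atom names must be non-empty")
  for (su in SUBUNITS) {
    if (!any(atoms$subunit == su & atoms$name == "CA")) {
      stop("subunit ", su, " has no C-alpha atom")
    }
  }
  structure(list(atoms = atoms, xyz = xyz, frame_time = frame_time),
            class = "tetramer_model")
}

#' @export
print.tetramer_model <- function(x, ...) {
  cat("Tetramer model:", nrow(x$atoms), "atoms, t =", x$frame_time, "ns\n")
  tab <- table(x$atoms$subunit)
  cat(paste(sprintf("  %s: %d atoms", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
  invisible(x)
}

# Unique cross-structure atom key: chain label + residue number + atom name.
atom_keys <- function(model, idx = seq_len(nrow(model$atoms))) {
  a <- model$atoms
  paste(a$chain[idx], a$resseq[idx], a$name[idx], sep = "|")
}

#' Default chain-to-subunit map
#'
#' The convention of the 2HHB/1IRD/1BBB hemoglobin entries: chains A, B, C,
#' D are the alpha1, beta1, alpha2, beta2 subunits.
#'
#' @return Named character vector mapping chain IDs to subunit labels.
#' @export
default_chain_map <- function() {
  c(A = "alpha1", B = "beta1", C = "alpha2", D = "beta2")
}

#' Read a PDB file into tetramer models
#'
#' Parses a (possibly multi-model) PDB file via \pkg{bio3d}, converts
#' coordinates from Angstrom to nm, drops hydrogens, resolves alternate
#' locations (highest occupancy, ties broken by altloc `A`), and labels
#' chains as subunits. Heme groups (residue `HEM`) are labeled
#' `HEM1`..`HEM4` following the subunit order of their chain.
#'
#' @param path Path to a PDB file.
#' @param model_index `"all"` to return every MODEL as a list of
#'   `tetramer_model`s (a trajectory), or a single integer model number.
#' @param chain_map Named character vector chain -> subunit label; see
#'   [default_chain_map()].
#' @param dt_ns Time spacing between successive models, in ns.
#' @param t0_ns Time of the first model, in ns.
#' @return A `tetramer_model`, or a list of them when `model_index = "all"`
#'   and the file has several models.
#' @export
read_pdb <- function(path, model_index = "all", chain_map = default_chain_map(),
                     dt_ns = 1, t0_ns = 0) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (is.null(n_models) || n_models < 1) stop("PDB file contains zero models")

  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(!nzchar(trimws(element)))) {
    element <- bio3d::atom2ele(pdb)
  }
  element <- toupper(trimws(element))
  blank <- is.na(element) | !nzchar(element)
  if (any(blank)) element[blank] <- toupper(substr(trimws(at$elety[blank]), 1, 1))

  keep <- !(element %in% c("H", "D"))
  # altloc: within each (chain, resseq, insert, atom name) keep the highest
  # occupancy; ties broken in favor of altloc "A" (then alphabetical).
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  grp <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  dup_groups <- unique(grp[duplicated(grp)])
  if (length(dup_groups) > 0) {
    for (g in dup_groups) {
      idx <- which(grp == g & keep)
      if (length(idx) <= 1) next
      best <- idx[order(-occ[idx], alt[idx] != "A", alt[idx])][1]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  keep <- which(keep)

  chains <- at$chain[keep]
  resname <- trimws(at$resid[keep])
  is_heme <- resname == "HEM"
  subunit <- rep("other", length(keep))
  parent <- rep(NA_character_, length(keep))
  mapped <- chains %in% names(chain_map)
  parent[mapped] <- unname(chain_map[chains[mapped]])
  subunit[mapped & !is_heme] <- parent[mapped & !is_heme]
  # heme label index follows the subunit order alpha1, beta1, alpha2, beta2
  hem_idx <- match(parent, SUBUNITS)
  subunit[mapped & is_heme] <- paste0("HEM", hem_idx[mapped & is_heme])

  present <- unique(subunit[subunit %in% SUBUNITS])
  absent <- setdiff(SUBUNITS, present)
  if (length(absent) > 0) {
    need <- names(chain_map)[chain_map %in% absent]
    stop("missing chain(s) ", paste(need, collapse = ", "),
         " for subunit(s) ", paste(absent, collapse = ", "))
  }
  atoms <- data.frame(
    serial = at$eleno[keep],
    name = trimws(at$elety[keep]),
    resname = resname,
    chain = chains,
    resseq = at$resno[keep],
    element = element[keep],
    mass = element_mass(element[keep]),
    subunit = subunit,
    parent = parent,
    is_heme = is_heme,
    stringsAsFactors = FALSE
  )

  model_of <- function(k) {
    xyz <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE] / 10
    tetramer_model(atoms, xyz, frame_time = t0_ns + (k - 1) * dt_ns)
  }

  if (identical(model_index, "all")) {
    if (n_models == 1) return(model_of(1))
    return(lapply(seq_len(n_models), model_of))
  }
  if (!is.numeric(model_index) || model_index < 1 || model_index > n_models) {
    stop("model_index must be 'all' or an integer in 1..", n_models)
  }
  model_of(as.integer(model_index))
}

#' Write models as a multi-model PDB file
#'
#' Writes one or more `tetramer_model`s (sharing the same atom table) as a
#' multi-model PDB trajectory, converting nm back to Angstrom. Coordinates
#' round-trip through [read_pdb()] within PDB precision (1e-3 nm).
#'
#' @param frames A `tetramer_model` or list of them with identical atoms.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(frames, path) {
  if (inherits(frames, "tetramer_model")) frames <- list(frames)
  stopifnot(length(frames) >= 1)
  a <- frames[[1]]$atoms
  xyz <- do.call(rbind, lapply(frames, function(f) {
    stopifnot(nrow(f$atoms) == nrow(a))
    flatten_xyz(f$xyz * 10)
  }))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = ifelse(a$is_heme, "HETATM", "ATOM"),
    resno = a$resseq, resid = a$resname, eleno = a$serial,
    elety = a$name, chain = a$chain, elesy = a$element
  )
  invisible(path)
}
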