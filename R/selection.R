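#' Atom selection specification
#'
#' Describes which atoms enter a superposition, RMSD, PCA or reaction
#' coordinate. `calpha_heme` selects all C-alpha atoms plus the heme atoms
#' of the requested subunits (the atom set used for the crystal-structure
#' PCA); `backbone` selects N, CA, C, O; `all` selects every atom.
#'
#' @param mode One of `"calpha_heme"`, `"backbone"`, `"all"`.
#' @param subunits Subset of `c("alpha1","beta1","alpha2","beta2")`.
#' @param include_hemes Whether heme atoms of the requested subunits are
#'   included. Defaults to `TRUE` for `calpha_heme`, `FALSE` otherwise.
#' @return An object of class `selection_spec`.
#' @export
selection_spec <- function(mode = c("calpha_heme", "backbone", "all"),
                           subunits = SUBUNITS,
                           include_hemes = NULL) {
  mode <- match.arg(mode)
  bad <- setdiff(subunits, SUBUNITS)
  if (length(bad) > 0) stop("unknown subunit label(s): ", paste(bad, collapse = ", "))
  if (length(subunits) == 0) stop("at least one subunit is required")
  if (is.null(include_hemes)) include_hemes <- mode == "calpha_heme"
  structure(list(mode = mode, subunits = subunits,
                 include_hemes = include_hemes),
            class = "selection_spec")
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Resolve a selection on a model
#'
#' @param model A `tetramer_model`.
#' @param spec A [selection_spec()].
#' @return List with `xyz` (`N x 3` nm, ascending atom index), `index`
#'   (atom indices into `model$atoms`) and `keys` (cross-structure atom
#'   keys `chain|resseq|name`).
#' @export
select_atoms <- function(model, spec = selection_spec()) {
  stopifnot(inherits(model, "tetramer_model"), inherits(spec, "selection_spec"))
  a <- model$atoms
  in_subunit <- a$subunit %in% spec$subunits
  heme_ok <- spec$include_hemes & a$is_heme & (a$parent %in% spec$subunits)
  sel <- switch(spec$mode,
    calpha_heme = (in_subunit & a$name == "CA") | heme_ok,
    backbone = in_subunit & !a$is_heme & a$name %in% BACKBONE_ATOMS,
    all = in_subunit | heme_ok
  )
  idx <- which(sel)
  if (length(idx) == 0) stop("selection is empty")
  list(xyz = model$xyz[idx, , drop = FALSE],
       index = idx,
       keys = atom_keys(model, idx))
}

# Resolve a selection on several models and intersect on the atom key
# (chain, resseq, name), so structures from different PDB entries yield
# equal-length, identically ordered coordinate arrays. Order follows the
# first model's atom order.
common_selection <- function(models, spec) {
  sels <- lapply(models, select_atoms, spec = spec)
  keys <- Reduce(intersect, lapply(sels, `[[`, "keys"))
  if (length(keys) == 0) stop("no common atoms after intersection")
  keys <- sels[[1]]$keys[sels[[1]]$keys %in% keys]  # first model's order
  lapply(sels, function(s) {
    pos <- match(keys, s$keys)
    list(xyz = s$xyz[pos, , drop = FALSE], index = s$index[pos], keys = keys)
  })
}

# Match a model's selection to a fixed key set (e.g. a PCA basis or
# difference vector); errors if any key is missing.
match_selection <- function(model, spec, keys) {
  s <- select_atoms(model, spec)
  pos <- match(keys, s$keys)
  if (anyNA(pos)) {
    stop(sum(is.na(pos)), " reference atom(s) absent from frame after ",
         "common-atom matching")
  }
  s$xyz[pos, , drop = FALSE]
}
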