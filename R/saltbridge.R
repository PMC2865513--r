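# Charged-group definitions for salt-bridge detection: side-chain
# carboxylates (Asp/Glu) and the C-terminal carboxylate are negative;
# Lys/Arg/His side-chain nitrogens and the N-terminal amine are positive.
NEGATIVE_SIDECHAIN <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
POSITIVE_SIDECHAIN <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                           HIS = c("ND1", "NE2"))

# Table of candidate charged atoms: one row per atom with its sign.
charged_atoms <- function(model) {
  a <- model$atoms
  prot <- !a$is_heme & a$subunit %in% SUBUNITS
  rows <- list()
  for (rn in names(NEGATIVE_SIDECHAIN)) {
    sel <- prot & a$resname == rn & a$name %in% NEGATIVE_SIDECHAIN[[rn]]
    if (any(sel)) rows[[length(rows) + 1]] <- data.frame(idx = which(sel), sign = -1)
  }
  for (rn in names(POSITIVE_SIDECHAIN)) {
    sel <- prot & a$resname == rn & a$name %in% POSITIVE_SIDECHAIN[[rn]]
    if (any(sel)) rows[[length(rows) + 1]] <- data.frame(idx = which(sel), sign = +1)
  }
  # chain termini: N-terminal backbone N (positive), C-terminal O/OXT (negative)
  for (ch in unique(a$chain[prot])) {
    in_ch <- prot & a$chain == ch
    rs <- a$resseq[in_ch]
    nterm <- which(in_ch & a$resseq == min(rs) & a$name == "N")
    cterm <- which(in_ch & a$resseq == max(rs) & a$name %in% c("O", "OXT"))
    if (length(nterm) > 0) rows[[length(rows) + 1]] <- data.frame(idx = nterm, sign = +1)
    if (length(cterm) > 0) rows[[length(rows) + 1]] <- data.frame(idx = cterm, sign = -1)
  }
  if (length(rows) == 0) return(NULL)
  out <- unique(do.call(rbind, rows))
  # an atom listed twice (e.g. Asp that is also C-terminal) keeps one row
  out[!duplicated(out$idx), , drop = FALSE]
}

#' Detect salt bridges in a structure
#'
#' A salt bridge is a pair of oppositely charged residues whose closest
#' charged heavy atoms lie within `cutoff`. Charged groups are Asp/Glu
#' carboxylate oxygens, Lys NZ, Arg NE/NH1/NH2, His ND1/NE2, the
#' N-terminal backbone nitrogen and the C-terminal O/OXT. One bridge is
#' reported per residue pair (minimum atom-atom distance).
#'
#' @param model A `tetramer_model`.
#' @param cutoff Distance cutoff in nm (default 0.4).
#' @return Data frame of class `salt_bridges`: one row per bridged residue
#'   pair with partner identities, minimal distance (nm) and whether the
#'   bridge crosses subunits.
#' @export
detect_salt_bridges <- function(model, cutoff = 0.4) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  ca <- charged_atoms(model)
  empty <- data.frame(chain_a = character(), resseq_a = integer(),
                      resname_a = character(), atom_a = character(),
                      chain_b = character(), resseq_b = integer(),
                      resname_b = character(), atom_b = character(),
                      distance = numeric(), inter_subunit = logical())
  class(empty) <- c("salt_bridges", "data.frame")
  if (is.null(ca)) return(empty)
  a <- model$atoms
  pos <- ca$idx[ca$sign > 0]
  neg <- ca$idx[ca$sign < 0]
  if (length(pos) == 0 || length(neg) == 0) return(empty)

  # all positive x negative atom distances (charged sets are small)
  P <- model$xyz[pos, , drop = FALSE]
  Q <- model$xyz[neg, , drop = FALSE]
  d2 <- outer(rowSums(P^2), rep(1, nrow(Q))) +
    outer(rep(1, nrow(P)), rowSums(Q^2)) - 2 * P %*% t(Q)
  d <- sqrt(pmax(d2, 0))

  hits <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty)
  ip <- pos[hits[, 1]]
  iq <- neg[hits[, 2]]
  same_res <- a$chain[ip] == a$chain[iq] & a$resseq[ip] == a$resseq[iq]
  hits <- hits[!same_res, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  ip <- pos[hits[, 1]]; iq <- neg[hits[, 2]]
  dist <- d[hits]
  pair_key <- paste(a$chain[ip], a$resseq[ip], a$chain[iq], a$resseq[iq], sep = "|")
  best <- tapply(seq_along(dist), pair_key, function(ii) ii[which.min(dist[ii])])
  best <- unname(unlist(best))
  ip <- ip[best]; iq <- iq[best]; dist <- dist[best]
  ord <- order(a$chain[ip], a$resseq[ip], a$chain[iq], a$resseq[iq])
  ip <- ip[ord]; iq <- iq[ord]; dist <- dist[ord]

  out <- data.frame(
    chain_a = a$chain[ip], resseq_a = a$resseq[ip],
    resname_a = a$resname[ip], atom_a = a$name[ip],
    chain_b = a$chain[iq], resseq_b = a$resseq[iq],
    resname_b = a$resname[iq], atom_b = a$name[iq],
    distance = dist,
    inter_subunit = a$subunit[ip] != a$subunit[iq],
    stringsAsFactors = FALSE
  )
  class(out) <- c("salt_bridges", "data.frame")
  out
}

bridge_pair_keys <- function(br) {
  # unordered residue-pair key
  k1 <- paste(br$chain_a, br$resseq_a, sep = ":")
  k2 <- paste(br$chain_b, br$resseq_b, sep = ":")
  paste(pmin(k1, k2), pmax(k1, k2), sep = "--")
}

#' Residue-pair difference of two salt-bridge sets
#'
#' Returns the bridges of `present_in` whose residue pair (keyed by chain
#' and residue number, order-insensitive) does not occur in `absent_in` --
#' e.g. the bridges formed in the T state but released in the R state.
#'
#' @param present_in,absent_in `salt_bridges` data frames from
#'   [detect_salt_bridges()] on structures with compatible numbering.
#' @return A `salt_bridges` data frame (subset of `present_in`).
#' @export
diff_salt_bridges <- function(present_in, absent_in) {
  if (nrow(present_in) == 0) return(present_in)
  keep <- !(bridge_pair_keys(present_in) %in% bridge_pair_keys(absent_in))
  out <- present_in[keep, , drop = FALSE]
  class(out) <- c("salt_bridges", "data.frame")
  out
}

#' T-state-specific salt bridges of hemoglobin A
#'
#' Expands the four bridge types that are formed in the deoxy T state but
#' released in the R state over the twofold symmetry of the tetramer:
#' the inter-subunit bridges Val(alpha)1--Arg(alpha)141 and
#' Asp(alpha)126--Arg(alpha)141 between the two alpha subunits, the
#' Lys(alpha)40--His(beta)146 bridge across the alpha1-beta2 interface, and
#' the subunit-internal Asp(beta)94--His(beta)146 bridge. Each type occurs
#' in two symmetric copies, giving 8 residue pairs in total.
#'
#' @return Data frame with one row per expanded bridge: subunits, residue
#'   numbers/names of both partners, and whether the pair is inter-subunit.
#' @export
hb_t_state_salt_bridges <- function() {
  # partner_b subunit: "same" copy (intra-dimer/internal) or the "opposite"
  # symmetry mate (the alpha1<->alpha2, beta1<->beta2 relation)
  types <- data.frame(
    type_a = c("alpha", "alpha", "alpha", "beta"),
    resseq_a = c(1, 126, 40, 94),
    resname_a = c("VAL", "ASP", "LYS", "ASP"),
    type_b = c("alpha", "alpha", "beta", "beta"),
    resseq_b = c(141, 141, 146, 146),
    resname_b = c("ARG", "ARG", "HIS", "HIS"),
    copy_b = c("opposite", "opposite", "opposite", "same"),
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(types)), function(i) {
    tp <- types[i, ]
    lapply(1:2, function(k) {
      kb <- if (tp$copy_b == "same") k else 3 - k
      data.frame(
        subunit_a = paste0(tp$type_a, k), resseq_a = tp$resseq_a,
        resname_a = tp$resname_a,
        subunit_b = paste0(tp$type_b, kb), resseq_b = tp$resseq_b,
        resname_b = tp$resname_b,
        inter_subunit = !(tp$copy_b == "same" && tp$type_a == tp$type_b),
        stringsAsFactors = FALSE
      )
    })
  })
  do.call(rbind, unlist(rows, recursive = FALSE))
}
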