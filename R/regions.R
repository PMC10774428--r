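## IMGT region assignment, total CDR length, and CDR-vicinity
## construction. CDR membership is purely positional: IMGT CDR1
## spans 27-38, CDR2 56-65, CDR3 105-117 on both chains, insertion
## codes included.

#' Assign IMGT regions to every residue
#'
#' Labels each residue FR, CDR1, CDR2 or CDR3 by its IMGT number
#' (ranges 27-38, 56-65, 105-117; identical for heavy and light
#' chains). Insertion codes do not affect membership.
#'
#' @param structure An \code{\linkS4class{FvStructure}}.
#' @return The residue data.frame with an added \code{region} column.
#' @examples
#' fv <- makeMiniFv(miniFvSpec(seed = 1))
#' table(assignRegions(fv)$region)
#' @export
assignRegions <- function(structure) {
  rs <- fvResidues(structure)
  region <- rep("FR", nrow(rs))
  for (cdr in names(.CDR_BOUNDS)) {
    b <- .CDR_BOUNDS[[cdr]]
    region[rs$resno >= b[1] & rs$resno <= b[2]] <- cdr
  }
  rs$region <- region
  rs
}

#' Total IMGT CDR length
#'
#' Number of residues (insertions included) across the six CDRs --
#' the L_tot developability metric.
#'
#' @param regions Output of \code{\link{assignRegions}} covering both
#'   chains.
#' @return Integer residue count.
#' @export
totalCdrLength <- function(regions) {
  sum(regions$region != "FR")
}

## Length of one CDR on one chain (used for cohort length statistics).
cdrLength <- function(regions, chain, cdr) {
  sum(regions$chain == chain & regions$region == cdr)
}

#' Anchor residues: CDRs plus sequence flanks
#'
#' For each CDR segment on each chain, the segment's residues plus
#' the two preceding and two following residues in chain order
#' (seq_index, not IMGT-number arithmetic, so numbering gaps still
#' yield two flanking residues), truncated at chain termini.
#'
#' @param structure An \code{\linkS4class{FvStructure}}.
#' @param regions Output of \code{\link{assignRegions}}.
#' @param flank Flank width in residues per side.
#' @return Character vector of residue keys (\code{"chain:resno[insert]"})
#'   in chain order, H before L.
#' @export
buildAnchorSet <- function(structure, regions, flank = 2L) {
  keep <- logical(nrow(regions))
  for (ch in c("H", "L")) {
    for (cdr in names(.CDR_BOUNDS)) {
      idx <- which(regions$chain == ch & regions$region == cdr)
      if (!length(idx)) next
      ext <- seq(max(1L, min(idx) - flank),
                 min(nrow(regions), max(idx) + flank))
      ext <- ext[regions$chain[ext] == ch]
      keep[ext] <- TRUE
    }
  }
  ord <- order(match(regions$chain, c("H", "L")), regions$seq_index)
  sel <- ord[keep[ord]]
  resKey(regions$chain[sel], regions$resno[sel], regions$insert[sel])
}

## Minimum heavy-atom (or C-beta, falling back to CA for glycine)
## distance matrix between two residue key sets.
residueMinDistances <- function(atoms, keys_a, keys_b,
                                mode = c("min-heavy", "cb")) {
  mode <- match.arg(mode)
  akey <- resKey(atoms$chain, atoms$resno, atoms$insert)
  if (mode == "cb") {
    pick <- atoms$name == "CB" | (atoms$name == "CA" & atoms$aa == "G")
    atoms <- atoms[pick, , drop = FALSE]
    akey <- akey[pick]
  }
  sel_a <- akey %in% keys_a
  sel_b <- akey %in% keys_b
  xa <- as.matrix(atoms[sel_a, c("x", "y", "z")])
  xb <- as.matrix(atoms[sel_b, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  ka <- akey[sel_a]
  kb <- akey[sel_b]
  out <- matrix(Inf, length(keys_a), length(keys_b),
                dimnames = list(keys_a, keys_b))
  for (ia in seq_along(keys_a)) {
    ra <- ka == keys_a[ia]
    if (!any(ra)) next
    sub <- d2[ra, , drop = FALSE]
    mins <- tapply(apply(sub, 2, min), kb, min)
    out[ia, names(mins)] <- sqrt(unname(mins))
  }
  out
}

#' Build the CDR vicinity
#'
#' The residue set over which the patch metrics are computed: the
#' anchor residues plus every surface-exposed residue whose minimum
#' heavy-atom distance to any anchor is at most \code{cutoff}
#' (single pass from the anchors; membership does not propagate
#' through newly added residues). Anchors are members regardless of
#' exposure; exposure gating for scoring happens at metric time.
#'
#' @param structure An \code{\linkS4class{FvStructure}}.
#' @param anchors Residue keys from \code{\link{buildAnchorSet}}.
#' @param exposure Named logical from \code{\link{classifyExposure}}
#'   computed on the full Fv.
#' @param cutoff Distance cutoff, Angstrom.
#' @param distance_mode \code{"min-heavy"} or \code{"cb"}.
#' @return List of class \code{"CdrVicinity"}: \code{anchors},
#'   \code{members} (residue keys, anchors first), \code{cutoff}.
#' @export
buildCdrVicinity <- function(structure, anchors, exposure, cutoff = 4.5,
                             distance_mode = c("min-heavy", "cb")) {
  distance_mode <- match.arg(distance_mode)
  rs <- fvResidues(structure)
  all_keys <- resKey(rs$chain, rs$resno, rs$insert)
  candidates <- setdiff(all_keys[exposure[all_keys]], anchors)
  extra <- character(0)
  if (length(candidates) && length(anchors)) {
    dmat <- residueMinDistances(fvAtoms(structure), candidates, anchors,
                                distance_mode)
    extra <- candidates[apply(dmat, 1, min) <= cutoff]
  }
  members <- all_keys[all_keys %in% c(anchors, extra)]
  out <- list(anchors = anchors, members = members, cutoff = cutoff)
  class(out) <- "CdrVicinity"
  out
}
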