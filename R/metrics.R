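## The four structure-dependent developability metrics and the
## pairwise decomposition of the patch scores.
##
## Patch kernel: over unordered pairs (i, j) of exposed CDR-vicinity
## residues with positive weights and residue-residue distance
## d_ij <= pair_cutoff,  score = sum w_i * w_j / d_ij^exponent.
## Every contributing pair is returned, so the score always equals
## the sum of its components.

.COMPONENT_COLS <- c("chain_i", "imgt_i", "insert_i", "aa_i", "seq_index_i",
                     "chain_j", "imgt_j", "insert_j", "aa_j", "seq_index_j",
                     "distance", "contribution", "adjacent")

emptyComponents <- function() {
  data.frame(chain_i = character(0), imgt_i = integer(0),
             insert_i = character(0), aa_i = character(0),
             seq_index_i = integer(0),
             chain_j = character(0), imgt_j = integer(0),
             insert_j = character(0), aa_j = character(0),
             seq_index_j = integer(0),
             distance = numeric(0), contribution = numeric(0),
             adjacent = logical(0), stringsAsFactors = FALSE)
}

#' Pairwise surface patch score
#'
#' Generic kernel behind the hydrophobicity and charge patch metrics:
#' exposed vicinity residues with positive weight contribute
#' w_i * w_j / d^exponent for every unordered pair within
#' \code{pair_cutoff}, and the full component list is returned
#' alongside the total.
#'
#' @param structure An \code{\linkS4class{FvStructure}}.
#' @param vicinity A \code{CdrVicinity} from
#'   \code{\link{buildCdrVicinity}} built on the same exposure map.
#' @param exposure Named logical from \code{\link{classifyExposure}}.
#' @param weights Named numeric keyed by residue key
#'   (\code{"chain:resno[insert]"}); residues with weight <= 0 or
#'   missing are ignored.
#' @param pair_cutoff Maximum residue-residue distance, Angstrom.
#' @param exponent Distance exponent of the kernel.
#' @param distance_mode \code{"min-heavy"} or \code{"cb"}.
#' @return List with \code{score} (numeric) and \code{components}
#'   (data.frame, one row per contributing unordered pair; pair
#'   members ordered chain H before L, then by seq_index;
#'   \code{adjacent} marks same-chain sequence neighbours).
#' @export
patchScore <- function(structure, vicinity, exposure, weights,
                       pair_cutoff = 7.5, exponent = 2,
                       distance_mode = c("min-heavy", "cb")) {
  distance_mode <- match.arg(distance_mode)
  rs <- fvResidues(structure)
  keys <- resKey(rs$chain, rs$resno, rs$insert)
  active <- vicinity$members
  active <- active[exposure[active] & !is.na(weights[active]) &
                     weights[active] > 0]
  if (length(active) < 2)
    return(list(score = 0, components = emptyComponents()))

  ## canonical order: chain H first, then chain order
  info <- rs[match(active, keys), , drop = FALSE]
  ord <- order(match(info$chain, c("H", "L")), info$seq_index)
  active <- active[ord]
  info <- info[ord, , drop = FALSE]

  dmat <- residueMinDistances(fvAtoms(structure), active, active,
                              distance_mode)
  w <- unname(weights[active])
  pairs <- which(upper.tri(dmat) & dmat <= pair_cutoff, arr.ind = TRUE)
  if (!nrow(pairs))
    return(list(score = 0, components = emptyComponents()))
  i <- pairs[, 1]
  j <- pairs[, 2]
  d <- dmat[pairs]
  contrib <- w[i] * w[j] / d^exponent
  comp <- data.frame(
    chain_i = info$chain[i], imgt_i = info$resno[i],
    insert_i = info$insert[i], aa_i = info$aa[i],
    seq_index_i = info$seq_index[i],
    chain_j = info$chain[j], imgt_j = info$resno[j],
    insert_j = info$insert[j], aa_j = info$aa[j],
    seq_index_j = info$seq_index[j],
    distance = d, contribution = contrib,
    adjacent = info$chain[i] == info$chain[j] &
      abs(info$seq_index[i] - info$seq_index[j]) == 1L,
    stringsAsFactors = FALSE)
  ord2 <- order(-comp$contribution, comp$chain_i, comp$seq_index_i,
                comp$chain_j, comp$seq_index_j)
  comp <- comp[ord2, , drop = FALSE]
  rownames(comp) <- NULL
  list(score = sum(contrib), components = comp)
}

#' Patches of surface hydrophobicity (PSH)
#'
#' \code{\link{patchScore}} with weights equal to the normalised
#' Kyte-Doolittle hydrophobicity of each exposed vicinity residue.
#'
#' @inheritParams patchScore
#' @param scale A \code{\link{kyteDoolittle}} list.
#' @return As \code{\link{patchScore}}.
#' @export
pshScore <- function(structure, vicinity, exposure,
                     scale = kyteDoolittle(), pair_cutoff = 7.5,
                     exponent = 2, distance_mode = "min-heavy") {
  rs <- fvResidues(structure)
  w <- stats::setNames(unname(scale$normalized[rs$aa]),
                       resKey(rs$chain, rs$resno, rs$insert))
  patchScore(structure, vicinity, exposure, w, pair_cutoff, exponent,
             distance_mode)
}

#' Patches of surface positive / negative charge (PPC / PNC)
#'
#' \code{\link{patchScore}} with weights |q| restricted to positively
#' (PPC) or negatively (PNC) charged residues.
#'
#' @inheritParams patchScore
#' @param charges Named charge vector as \code{\link{chargeAssignment}}.
#' @return As \code{\link{patchScore}}.
#' @export
ppcScore <- function(structure, vicinity, exposure,
                     charges = chargeAssignment(), pair_cutoff = 7.5,
                     exponent = 2, distance_mode = "min-heavy") {
  rs <- fvResidues(structure)
  q <- unname(charges[rs$aa])
  w <- stats::setNames(ifelse(q > 0, q, 0),
                       resKey(rs$chain, rs$resno, rs$insert))
  patchScore(structure, vicinity, exposure, w, pair_cutoff, exponent,
             distance_mode)
}

#' @rdname ppcScore
#' @export
pncScore <- function(structure, vicinity, exposure,
                     charges = chargeAssignment(), pair_cutoff = 7.5,
                     exponent = 2, distance_mode = "min-heavy") {
  rs <- fvResidues(structure)
  q <- unname(charges[rs$aa])
  w <- stats::setNames(ifelse(q < 0, -q, 0),
                       resKey(rs$chain, rs$resno, rs$insert))
  patchScore(structure, vicinity, exposure, w, pair_cutoff, exponent,
             distance_mode)
}

#' Structural Fv charge symmetry parameter (SFvCSP)
#'
#' Product of the summed formal charges of the exposed residues of
#' the heavy and light variable domains. Opposite net charges give a
#' negative score (charge asymmetry, linked to self-association).
#'
#' @param structure An \code{\linkS4class{FvStructure}}.
#' @param exposure Named logical from \code{\link{classifyExposure}}.
#' @param charges Named charge vector as \code{\link{chargeAssignment}}.
#' @param scope \code{"domain"} (all exposed residues of each chain,
#'   default) or \code{"vicinity"} (CDR-vicinity members only).
#' @param vicinity Required when \code{scope = "vicinity"}.
#' @return Numeric score.
#' @export
sfvcspScore <- function(structure, exposure, charges = chargeAssignment(),
                        scope = c("domain", "vicinity"), vicinity = NULL) {
  scope <- match.arg(scope)
  rs <- fvResidues(structure)
  keys <- resKey(rs$chain, rs$resno, rs$insert)
  keep <- exposure[keys]
  if (scope == "vicinity") {
    if (is.null(vicinity)) stop("vicinity required for scope = 'vicinity'")
    keep <- keep & keys %in% vicinity$members
  }
  q <- unname(charges[rs$aa])
  sum(q[keep & rs$chain == "H"]) * sum(q[keep & rs$chain == "L"])
}

#' Compute the full five-metric developability profile
#'
#' Orchestrates the pipeline for one structure: solvent accessibility
#' (both chains together), exposure classification, region
#' assignment, anchor and CDR-vicinity construction, the three patch
#' scores with their pairwise decompositions, and the charge symmetry
#' parameter. Deterministic for fixed input and configuration.
#'
#' @param structure An \code{\linkS4class{FvStructure}}.
#' @param config A \code{\link{tapConfig}}.
#' @param max_table Maximum-SASA table; defaults to the shipped table
#'   (regenerate with \code{\link{buildMaxSasaTable}} when changing
#'   the probe).
#' @return A \code{\linkS4class{TapProfile}}.
#' @examples
#' prof <- computeTapProfile(makeMiniFv(miniFvSpec(seed = 1)))
#' tapMetrics(prof)
#' @export
computeTapProfile <- function(structure, config = tapConfig(),
                              max_table = defaultMaxSasaTable()) {
  methods::validObject(structure)
  sr <- shrakeRupley(structure, config$probe_radius, config$n_sphere_points)
  exposure <- classifyExposure(sr, max_table, config$exposure_fraction)
  regions <- assignRegions(structure)
  anchors <- buildAnchorSet(structure, regions)
  vicinity <- buildCdrVicinity(structure, anchors, exposure,
                               config$vicinity_cutoff, config$distance_mode)
  scale <- kyteDoolittle(config$hydrophobicity_range)
  charges <- chargeAssignment(config$his_charge)
  psh <- pshScore(structure, vicinity, exposure, scale,
                  config$pair_cutoff, config$distance_exponent,
                  config$distance_mode)
  ppc <- ppcScore(structure, vicinity, exposure, charges,
                  config$pair_cutoff, config$distance_exponent,
                  config$distance_mode)
  pnc <- pncScore(structure, vicinity, exposure, charges,
                  config$pair_cutoff, config$distance_exponent,
                  config$distance_mode)
  sfv <- sfvcspScore(structure, exposure, charges, config$sfvcsp_scope,
                     vicinity)
  methods::new("TapProfile", id = fvId(structure),
               lTot = as.integer(totalCdrLength(regions)),
               psh = psh$score, ppc = ppc$score, pnc = pnc$score,
               sfvcsp = sfv,
               components = list(psh = psh$components,
                                 ppc = ppc$components,
                                 pnc = pnc$components))
}

#' Top-ranked pairwise components
#'
#' Filters a component table by adjacency class (sequence-adjacent:
#' same chain, consecutive seq_index) and returns the \code{k}
#' largest contributions, ties broken lexicographically on
#' (chain, seq_index) of both members for determinism.
#'
#' @param components Component data.frame from a
#'   \code{\linkS4class{TapProfile}}.
#' @param k Number of pairs to return.
#' @param adjacency \code{"adjacent"} or \code{"non_adjacent"}.
#' @return Data.frame of at most \code{k} rows, ranked.
#' @export
topComponents <- function(components, k = 20L,
                          adjacency = c("adjacent", "non_adjacent")) {
  adjacency <- match.arg(adjacency)
  sel <- components[components$adjacent == (adjacency == "adjacent"), ,
                    drop = FALSE]
  ord <- order(-sel$contribution, sel$chain_i, sel$seq_index_i,
               sel$chain_j, sel$seq_index_j)
  out <- sel[utils::head(ord, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Positional contribution counts across a cohort
#'
#' For each antibody, takes its top-\code{k} hydrophobicity
#' components in each adjacency class and counts how often each
#' (chain, IMGT position) appears in those pairs -- the recurrence
#' table used to localise positions that drive extreme patch scores.
#'
#' @param profiles List of \code{\linkS4class{TapProfile}}.
#' @param k Pairs per adjacency class per antibody.
#' @param metric Component set to rank (default \code{"psh"}).
#' @return Data.frame: chain, imgt, count; sorted by decreasing count.
#' @export
positionContributionTable <- function(profiles, k = 20L, metric = "psh") {
  tally <- new.env(parent = emptyenv())
  bump <- function(chain, imgt) {
    key <- paste0(chain, ":", imgt)
    assign(key, (if (exists(key, tally)) get(key, tally) else 0L) + 1L, tally)
  }
  for (p in profiles) {
    comp <- tapComponents(p, metric)
    for (adj in c("adjacent", "non_adjacent")) {
      top <- topComponents(comp, k, adj)
      if (!nrow(top)) next
      for (r in seq_len(nrow(top))) {
        bump(top$chain_i[r], top$imgt_i[r])
        bump(top$chain_j[r], top$imgt_j[r])
      }
    }
  }
  keys <- ls(tally)
  if (!length(keys)) {
    return(data.frame(chain = character(0), imgt = integer(0),
                      count = integer(0)))
  }
  counts <- vapply(keys, get, 0L, envir = tally)
  parts <- strsplit(keys, ":", fixed = TRUE)
  out <- data.frame(chain = vapply(parts, `[`, "", 1),
                    imgt = as.integer(vapply(parts, `[`, "", 2)),
                    count = as.integer(counts), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$chain, out$imgt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
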