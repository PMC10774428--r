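## S4 classes for the profiling pipeline. Atom and residue records are
## kept as plain data.frames inside the objects; accessors below are the
## supported interface.

## Canonical residue key: "chain:resno" plus any insertion code.
resKey <- function(chain, resno, insert = "") {
  ins <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste0(chain, ":", resno, ins)
}

.ATOM_COLS <- c("chain", "resno", "insert", "aa", "seq_index",
                "name", "element", "x", "y", "z", "bfactor", "vdw")

#' FvStructure: an IMGT-numbered antibody Fv
#'
#' Paired heavy (H) and light (L) variable domains with heavy-atom
#' coordinates. Residues are identified by chain, IMGT position and
#' insertion code; the optional per-residue predicted error (Angstrom)
#' is taken from the B-factor column of predictor output at read time.
#'
#' @slot id Character identifier.
#' @slot atoms data.frame with one row per heavy atom: chain, resno
#'   (IMGT number), insert, aa (one-letter), seq_index (0-based file
#'   order within chain), name, element, x, y, z, bfactor, vdw.
#' @slot residues data.frame with one row per residue: chain, resno,
#'   insert, aa, seq_index, pe (predicted error, NA when absent).
#' @slot lightLocus \code{"kappa"}, \code{"lambda"} or \code{"unknown"}.
#' @slot metadata Free-form named list (V gene, group labels, ...).
#' @exportClass FvStructure
setClass("FvStructure",
  representation(id = "character", atoms = "data.frame",
                 residues = "data.frame", lightLocus = "character",
                 metadata = "list"))

setValidity("FvStructure", function(object) {
  at <- object@atoms
  msgs <- character(0)
  if (!all(.ATOM_COLS %in% names(at)))
    return(paste("atoms must have columns:", paste(.ATOM_COLS, collapse = ", ")))
  if (!setequal(unique(at$chain), c("H", "L")))
    msgs <- c(msgs, "structure must contain exactly chains H and L, both non-empty")
  if (any(at$element == "H"))
    msgs <- c(msgs, "hydrogen atoms are not allowed after ingestion")
  if (!all(is.finite(c(at$x, at$y, at$z))))
    msgs <- c(msgs, "coordinates must be finite")
  if (!all(at$vdw > 0))
    msgs <- c(msgs, "van der Waals radii must be positive")
  rs <- object@residues
  if (!all(rs$aa %in% .AA1))
    msgs <- c(msgs, "all residues must be canonical amino acids")
  key <- resKey(rs$chain, rs$resno, rs$insert)
  if (anyDuplicated(key))
    msgs <- c(msgs, "(chain, IMGT number, insertion code) must be unique")
  for (ch in c("H", "L")) {
    si <- rs$seq_index[rs$chain == ch]
    if (length(si) && any(diff(si) <= 0))
      msgs <- c(msgs, paste0("seq_index must be strictly increasing in chain ", ch))
  }
  if (!object@lightLocus %in% c("kappa", "lambda", "unknown"))
    msgs <- c(msgs, "lightLocus must be kappa, lambda or unknown")
  if (length(msgs)) msgs else TRUE
})

## Build the residue table (and backbone-mean predicted error) from an
## atom table.
residuesFromAtoms <- function(atoms, predicted_error = TRUE) {
  key <- resKey(atoms$chain, atoms$resno, atoms$insert)
  first <- !duplicated(key)
  rs <- atoms[first, c("chain", "resno", "insert", "aa", "seq_index")]
  rownames(rs) <- NULL
  pe <- rep(NA_real_, nrow(rs))
  if (predicted_error) {
    bb <- atoms[atoms$name %in% c("N", "CA", "C", "O"), ]
    bkey <- resKey(bb$chain, bb$resno, bb$insert)
    cnt <- table(bkey)
    mean_b <- tapply(bb$bfactor, bkey, mean)
    rkey <- resKey(rs$chain, rs$resno, rs$insert)
    ok <- rkey %in% names(cnt)[cnt == 4L]
    pe[ok] <- as.numeric(mean_b[rkey[ok]])
  }
  rs$pe <- pe
  rs
}

## Internal constructor from a complete atom table.
newFvStructure <- function(id, atoms, lightLocus = "unknown",
                           metadata = list(), predicted_error = TRUE) {
  atoms <- atoms[order(match(atoms$chain, c("H", "L"))), , drop = FALSE]
  rownames(atoms) <- NULL
  methods::new("FvStructure", id = id, atoms = atoms,
               residues = residuesFromAtoms(atoms, predicted_error),
               lightLocus = lightLocus, metadata = metadata)
}

#' SasaResult: solvent-accessible surface areas
#'
#' Per-atom and per-residue solvent-accessible surface area for one
#' structure; residue values are the sums over their atoms.
#'
#' @slot atomSasa Numeric, aligned with the rows of the structure's
#'   atom table, square Angstrom.
#' @slot residueSasa data.frame: chain, resno, insert, aa, seq_index,
#'   sasa.
#' @slot probeRadius Probe radius used, Angstrom.
#' @slot nPoints Quadrature points per atom.
#' @exportClass SasaResult
setClass("SasaResult",
  representation(atomSasa = "numeric", residueSasa = "data.frame",
                 probeRadius = "numeric", nPoints = "integer"))

setValidity("SasaResult", function(object) {
  if (any(object@atomSasa < 0) || any(object@residueSasa$sasa < 0))
    return("SASA values must be non-negative")
  TRUE
})

#' TapProfile: the five developability metrics for one structure
#'
#' Holds the total CDR length, the three patch scores with their full
#' pairwise decompositions, and the Fv charge symmetry parameter.
#'
#' @slot id Character identifier.
#' @slot lTot Total IMGT CDR length, residues.
#' @slot psh,ppc,pnc Patch scores (surface hydrophobicity, positive
#'   charge, negative charge), unitless.
#' @slot sfvcsp Structural Fv charge symmetry parameter, unitless.
#' @slot components Named list (psh, ppc, pnc) of data.frames, one row
#'   per contributing residue pair: chain_i, imgt_i, insert_i, aa_i,
#'   seq_index_i, chain_j, imgt_j, insert_j, aa_j, seq_index_j,
#'   distance, contribution, adjacent.
#' @exportClass TapProfile
setClass("TapProfile",
  representation(id = "character", lTot = "integer",
                 psh = "numeric", ppc = "numeric", pnc = "numeric",
                 sfvcsp = "numeric", components = "list"))

setValidity("TapProfile", function(object) {
  for (m in c("psh", "ppc", "pnc")) {
    s <- methods::slot(object, m)
    comp <- object@components[[m]]
    if (is.null(comp)) return(paste("missing components for", m))
    tot <- sum(comp$contribution)
    if (abs(s - tot) > 1e-9 * max(1, abs(s)))
      return(paste(m, "score must equal the sum of its components"))
    if (nrow(comp) && any(comp$contribution < 0))
      return(paste(m, "components must be non-negative"))
  }
  TRUE
})

#' ThresholdSet: percentile flagging boundaries
#'
#' Amber/red flag boundaries per metric fitted from a reference score
#' collection: 0th percentile (minimum), 5th, 95th and 100th
#' (maximum), populated according to each metric's sidedness
#' (two-sided for total CDR length and surface hydrophobicity, upper
#' tail only for the charge patch metrics, lower tail only for the
#' charge symmetry parameter).
#'
#' @slot table data.frame: metric, sidedness, lower_red, lower_amber,
#'   upper_amber, upper_red (NA on unflagged sides).
#' @slot referenceN Named integer: reference scores per metric.
#' @exportClass ThresholdSet
setClass("ThresholdSet",
  representation(table = "data.frame", referenceN = "integer"))

setValidity("ThresholdSet", function(object) {
  tb <- object@table
  need <- c("metric", "sidedness", "lower_red", "lower_amber",
            "upper_amber", "upper_red")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  for (i in seq_len(nrow(tb))) {
    b <- unlist(tb[i, c("lower_red", "lower_amber", "upper_amber", "upper_red")])
    b <- b[!is.na(b)]
    if (is.unsorted(b))
      return(paste("boundaries out of order for", tb$metric[i]))
  }
  TRUE
})

#' SuperpositionResult: framework-aligned region RMSDs
#'
#' Rigid-body superposition (least squares on framework backbone
#' atoms) and the per-region backbone RMSDs computed in that frame
#' without re-fitting.
#'
#' @slot rotation 3x3 proper rotation matrix.
#' @slot translation Length-3 numeric, Angstrom.
#' @slot perRegionRmsd Named numeric: RMSD per region (FR, CDR1,
#'   CDR2, CDR3), Angstrom.
#' @slot nAtoms Named integer: backbone atoms per region.
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 perRegionRmsd = "numeric", nAtoms = "integer"))

setValidity("SuperpositionResult", function(object) {
  if (!all(dim(object@rotation) == c(3, 3)))
    return("rotation must be 3x3")
  if (abs(det(object@rotation) - 1) > 1e-6)
    return("rotation must be proper (det +1)")
  if (any(object@perRegionRmsd < 0, na.rm = TRUE))
    return("RMSD must be non-negative")
  TRUE
})
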