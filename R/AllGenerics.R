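#' @include AllClasses.R
NULL

#' Accessors for FvStructure
#'
#' @param x An \code{FvStructure}.
#' @return \code{fvId}: the identifier; \code{fvAtoms} /
#'   \code{fvResidues}: the atom / residue tables; \code{lightLocus}:
#'   the light-chain locus; \code{fvMetadata}: the metadata list;
#'   \code{fvSequence}: named character of one-letter sequences per
#'   chain.
#' @name FvStructure-accessors
#' @aliases fvId fvAtoms fvResidues lightLocus fvMetadata fvSequence
NULL

#' @rdname FvStructure-accessors
#' @export
setGeneric("fvId", function(x) standardGeneric("fvId"))
#' @rdname FvStructure-accessors
#' @export
setGeneric("fvAtoms", function(x) standardGeneric("fvAtoms"))
#' @rdname FvStructure-accessors
#' @export
setGeneric("fvResidues", function(x) standardGeneric("fvResidues"))
#' @rdname FvStructure-accessors
#' @export
setGeneric("lightLocus", function(x) standardGeneric("lightLocus"))
#' @rdname FvStructure-accessors
#' @export
setGeneric("fvMetadata", function(x) standardGeneric("fvMetadata"))
#' @rdname FvStructure-accessors
#' @export
setGeneric("fvSequence", function(x) standardGeneric("fvSequence"))

setMethod("fvId", "FvStructure", function(x) x@id)
setMethod("fvId", "TapProfile", function(x) x@id)
setMethod("fvAtoms", "FvStructure", function(x) x@atoms)
setMethod("fvResidues", "FvStructure", function(x) x@residues)
setMethod("lightLocus", "FvStructure", function(x) x@lightLocus)
setMethod("fvMetadata", "FvStructure", function(x) x@metadata)
setMethod("fvSequence", "FvStructure", function(x) {
  rs <- x@residues
  vapply(c(H = "H", L = "L"),
         function(ch) paste(rs$aa[rs$chain == ch], collapse = ""), "")
})

setMethod("show", "FvStructure", function(object) {
  rs <- object@residues
  cat("FvStructure:", object@id, "\n")
  cat("  chain H:", sum(rs$chain == "H"), "residues; chain L:",
      sum(rs$chain == "L"), "residues;", nrow(object@atoms),
      "heavy atoms\n")
  cat("  light locus:", object@lightLocus, "\n")
  if (any(!is.na(rs$pe)))
    cat("  predicted error: present for", sum(!is.na(rs$pe)), "residues\n")
})

#' Accessors for SasaResult
#'
#' @param x A \code{SasaResult}.
#' @return \code{atomSasa}: numeric vector aligned with the atom
#'   table; \code{residueSasa}: per-residue data.frame with a
#'   \code{sasa} column.
#' @name SasaResult-accessors
#' @aliases atomSasa residueSasa
NULL

#' @rdname SasaResult-accessors
#' @export
setGeneric("atomSasa", function(x) standardGeneric("atomSasa"))
#' @rdname SasaResult-accessors
#' @export
setGeneric("residueSasa", function(x) standardGeneric("residueSasa"))

setMethod("atomSasa", "SasaResult", function(x) x@atomSasa)
setMethod("residueSasa", "SasaResult", function(x) x@residueSasa)

setMethod("show", "SasaResult", function(object) {
  cat("SasaResult:", length(object@atomSasa), "atoms,",
      nrow(object@residueSasa), "residues\n")
  cat(sprintf("  total SASA %.1f A^2 (probe %.2f A, %d points/atom)\n",
              sum(object@atomSasa), object@probeRadius, object@nPoints))
})

#' Accessors for TapProfile
#'
#' @param x A \code{TapProfile}.
#' @param metric For \code{tapComponents}: one of \code{"psh"},
#'   \code{"ppc"}, \code{"pnc"}.
#' @return \code{tapMetrics}: named numeric of the five metric values;
#'   \code{tapComponents}: the pairwise component table for one patch
#'   metric.
#' @name TapProfile-accessors
#' @aliases tapMetrics tapComponents
NULL

#' @rdname TapProfile-accessors
#' @export
setGeneric("tapMetrics", function(x) standardGeneric("tapMetrics"))
#' @rdname TapProfile-accessors
#' @export
setGeneric("tapComponents",
           function(x, metric = "psh") standardGeneric("tapComponents"))

setMethod("tapMetrics", "TapProfile", function(x) {
  c(l_tot = as.numeric(x@lTot), psh = x@psh, ppc = x@ppc,
    pnc = x@pnc, sfvcsp = x@sfvcsp)
})
setMethod("tapComponents", "TapProfile", function(x, metric = "psh") {
  metric <- match.arg(metric, c("psh", "ppc", "pnc"))
  x@components[[metric]]
})

setMethod("show", "TapProfile", function(object) {
  cat("TapProfile:", object@id, "\n")
  m <- tapMetrics(object)
  cat(sprintf("  L_tot %d  PSH %.2f  PPC %.2f  PNC %.2f  SFvCSP %.2f\n",
              object@lTot, m["psh"], m["ppc"], m["pnc"], m["sfvcsp"]))
  cat("  components:", paste(vapply(object@components, nrow, 0L),
                             collapse = "/"), "(psh/ppc/pnc pairs)\n")
})

#' Accessors for ThresholdSet
#'
#' @param x A \code{ThresholdSet}.
#' @return \code{thresholdTable}: the per-metric boundary data.frame;
#'   \code{referenceN}: named integer of reference-set sizes.
#' @name ThresholdSet-accessors
#' @aliases thresholdTable referenceN
NULL

#' @rdname ThresholdSet-accessors
#' @export
setGeneric("thresholdTable", function(x) standardGeneric("thresholdTable"))
#' @rdname ThresholdSet-accessors
#' @export
setGeneric("referenceN", function(x) standardGeneric("referenceN"))

setMethod("thresholdTable", "ThresholdSet", function(x) x@table)
setMethod("referenceN", "ThresholdSet", function(x) x@referenceN)

setMethod("show", "ThresholdSet", function(object) {
  cat("ThresholdSet fitted on", max(object@referenceN), "reference scores\n")
  print(object@table, row.names = FALSE)
})

setMethod("show", "SuperpositionResult", function(object) {
  cat("SuperpositionResult (framework-aligned backbone RMSD, A):\n")
  print(round(object@perRegionRmsd, 3))
})
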