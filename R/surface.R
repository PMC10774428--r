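## Solvent-accessible surface area by the Shrake-Rupley method with a
## deterministic golden-spiral point lattice, plus residue exposure
## classification against theoretical per-residue maxima.

## Deterministic golden-spiral lattice of n points on the unit sphere.
goldenSpiralPoints <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a spherical probe over the van der Waals surface by testing,
#' for each atom, a fixed golden-spiral lattice of points on its
#' probe-expanded sphere against all neighbouring expanded spheres.
#' Per-atom SASA is (accessible points / total points) x 4 pi
#' (r_vdw + probe)^2; residue SASA is the sum over the residue's
#' atoms. Entirely deterministic (no random numbers).
#'
#' @param structure An \code{\linkS4class{FvStructure}}, or an atom
#'   data.frame with columns x, y, z, vdw (and, for residue sums,
#'   chain, resno, insert, aa, seq_index).
#' @param probe_radius Probe radius, Angstrom (default 1.4, water).
#' @param n_points Lattice points per atom (>= 16; default 960).
#' @return A \code{\linkS4class{SasaResult}}.
#' @examples
#' fv <- makeMiniFv(miniFvSpec(seed = 1))
#' sr <- shrakeRupley(fv)
#' head(residueSasa(sr))
#' @export
shrakeRupley <- function(structure, probe_radius = 1.4, n_points = 960L) {
  at <- if (methods::is(structure, "FvStructure")) fvAtoms(structure)
        else structure
  n <- nrow(at)
  stopifnot(n >= 1, n_points >= 16)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- at$vdw + probe_radius
  unit <- goldenSpiralPoints(as.integer(n_points))

  sasa <- numeric(n)
  ## neighbour candidates: centre distance below r_i + r_j + 2 probe,
  ## i.e. expanded spheres intersect
  d2full <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    area <- 4 * pi * rad[i]^2
    nb <- which(d2full[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    if (!length(nb)) {
      sasa[i] <- area
      next
    }
    pts <- sweep(unit * rad[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(pts))
    ## test closest neighbours first to shed points quickly
    for (j in nb[order(d2full[i, nb])]) {
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 >= rad[j]^2
      if (!any(acc)) break
    }
    sasa[i] <- mean(acc) * area
  }

  if (all(c("chain", "resno", "insert") %in% names(at))) {
    key <- resKey(at$chain, at$resno, at$insert)
    first <- !duplicated(key)
    res <- at[first, intersect(c("chain", "resno", "insert", "aa", "seq_index"),
                               names(at))]
    rownames(res) <- NULL
    res$sasa <- as.numeric(tapply(sasa, key, sum)[resKey(res$chain, res$resno,
                                                         res$insert)])
  } else {
    res <- data.frame(sasa = sasa)
  }
  methods::new("SasaResult", atomSasa = sasa, residueSasa = res,
               probeRadius = probe_radius, nPoints = as.integer(n_points))
}

#' Theoretical maximum residue SASA table
#'
#' For each amino acid X, computes the solvent-accessible surface
#' area of the central residue in an extended-conformation
#' (phi = -120, psi = +120 degrees) Ala-X-Ala tripeptide built by
#' \code{\link{makePeptide}}, using \code{\link{shrakeRupley}} with
#' the same probe. These open-chain maxima are the denominators for
#' relative exposure. A copy generated with the default parameters is
#' shipped as \code{extdata/max_sasa.csv}; this function regenerates
#' it from code.
#'
#' @param probe_radius Probe radius, Angstrom.
#' @param n_points Lattice points per atom.
#' @return Named numeric vector over the 20 canonical residues
#'   (square Angstrom), with a \code{provenance} attribute.
#' @export
buildMaxSasaTable <- function(probe_radius = 1.4, n_points = 960L) {
  vals <- vapply(.AA1, function(aa) {
    tri <- makePeptide(paste0("A", aa, "A"))
    sr <- shrakeRupley(tri, probe_radius, n_points)
    sr@residueSasa$sasa[2]
  }, numeric(1))
  attr(vals, "provenance") <- sprintf(
    "extended Ala-X-Ala tripeptide (phi=-120, psi=+120), probe %.2f A, %d points",
    probe_radius, n_points)
  vals
}

#' Shipped maximum-SASA table
#'
#' Reads the packaged \code{extdata/max_sasa.csv}, generated by
#' \code{\link{buildMaxSasaTable}} with the default probe and lattice.
#'
#' @return Named numeric vector over the 20 canonical residues.
#' @export
defaultMaxSasaTable <- function() {
  path <- system.file("extdata", "max_sasa.csv", package = "abtap",
                      mustWork = TRUE)
  tb <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(tb$max_sasa, tb$aa)
}

#' Classify residues as exposed or buried
#'
#' A residue is exposed when its SASA is at least \code{fraction}
#' (default 7.5 percent) of the theoretical maximum for its amino
#' acid; the comparison is inclusive.
#'
#' @param sasa A \code{\linkS4class{SasaResult}} computed on the full
#'   Fv (both chains together, so burial at the interface counts).
#' @param table Maximum-SASA table as \code{\link{defaultMaxSasaTable}}.
#' @param fraction Exposure threshold as a fraction of the maximum.
#' @return Named logical vector (TRUE = exposed) keyed by residue
#'   (\code{"chain:resno[insert]"}), in residue order.
#' @export
classifyExposure <- function(sasa, table = defaultMaxSasaTable(),
                             fraction = 0.075) {
  res <- residueSasa(sasa)
  if (!all(res$aa %in% names(table)))
    stop("missing max-SASA table entry for: ",
         paste(setdiff(unique(res$aa), names(table)), collapse = ", "))
  exposed <- res$sasa >= fraction * unname(table[res$aa])
  stats::setNames(exposed, resKey(res$chain, res$resno, res$insert))
}
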