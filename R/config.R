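## Constants and run configuration shared by all stages.

.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

.AA3TO1 <- stats::setNames(names(.AA3), unname(.AA3))

## Kyte-Doolittle hydropathy index (raw scale).
.KD_RAW <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
             Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
             L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
             S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

## Heavy side-chain atoms per residue type, used by the fixture builder
## and as the reference composition for placeholder geometries.
.SIDE_CHAIN_ATOMS <- list(
  A = "CB",
  R = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  N = c("CB", "CG", "OD1", "ND2"),
  D = c("CB", "CG", "OD1", "OD2"),
  C = c("CB", "SG"),
  Q = c("CB", "CG", "CD", "OE1", "NE2"),
  E = c("CB", "CG", "CD", "OE1", "OE2"),
  G = character(0),
  H = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  I = c("CB", "CG1", "CG2", "CD1"),
  L = c("CB", "CG", "CD1", "CD2"),
  K = c("CB", "CG", "CD", "CE", "NZ"),
  M = c("CB", "CG", "SD", "CE"),
  F = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  P = c("CB", "CG", "CD"),
  S = c("CB", "OG"),
  T = c("CB", "OG1", "CG2"),
  W = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  Y = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  V = c("CB", "CG1", "CG2")
)

## IMGT CDR position ranges (inclusive), identical for both chains.
.CDR_BOUNDS <- list(CDR1 = c(27L, 38L), CDR2 = c(56L, 65L), CDR3 = c(105L, 117L))

.TAP_METRICS <- c("l_tot", "psh", "ppc", "pnc", "sfvcsp")

.METRIC_SIDEDNESS <- c(l_tot = "two_sided", psh = "two_sided",
                       ppc = "upper", pnc = "upper", sfvcsp = "lower")

.FLAG_LEVELS <- c("green", "amber", "red")

#' Kyte-Doolittle hydrophobicity scale
#'
#' Returns the raw Kyte-Doolittle hydropathy index together with a
#' strictly positive, order-preserving normalisation used as the
#' residue weight in the surface-hydrophobicity patch score. The
#' normalisation is the affine map of the raw scale onto
#' \code{range} (default \code{[1, 2]}), so the most hydrophilic
#' residue (R, -4.5) maps to the lower bound and the most hydrophobic
#' (I, +4.5) to the upper bound.
#'
#' @param range Numeric length-2: target interval for the normalised
#'   scale. Must be positive and increasing.
#' @return A list with components \code{raw} and \code{normalized},
#'   each a named numeric vector over the 20 canonical residues.
#' @examples
#' kyteDoolittle()$normalized[c("G", "L")]
#' @export
kyteDoolittle <- function(range = c(1, 2)) {
  stopifnot(length(range) == 2, range[1] > 0, range[2] > range[1])
  lo <- min(.KD_RAW)
  hi <- max(.KD_RAW)
  normalized <- range[1] + (.KD_RAW - lo) / (hi - lo) * (range[2] - range[1])
  list(raw = .KD_RAW, normalized = normalized)
}

#' Formal residue charge assignment
#'
#' Side-chain formal charges at physiological pH used by the charge
#' patch scores and the Fv charge symmetry parameter: R and K +1,
#' D and E -1, histidine a configurable fractional charge (default
#' +0.1 reflecting its minority protonation), all other residues 0.
#'
#' @param his Charge assigned to histidine.
#' @return Named numeric vector over the 20 canonical residues.
#' @export
chargeAssignment <- function(his = 0.1) {
  q <- stats::setNames(numeric(20), .AA1)
  q[c("R", "K")] <- 1
  q[c("D", "E")] <- -1
  q["H"] <- his
  q
}

#' Van der Waals radii table
#'
#' Element radii (Angstrom) used for solvent-accessible surface area.
#' Unlisted elements fall back to \code{default}.
#'
#' @return Named numeric vector with elements C, N, O, S and a
#'   \code{default} entry.
#' @export
defaultVdwRadii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, default = 1.70)
}

#' Run configuration for the developability profiling pipeline
#'
#' Collects every tunable parameter with its default. Defaults mirror
#' the published protocol: 1.4 Angstrom solvent probe, exposure at
#' >= 7.5 percent of the theoretical maximum residue SASA, CDR
#' vicinity within 4.5 Angstrom of the anchor residues, and a pairwise
#' patch kernel w_i * w_j / d^2 with a 7.5 Angstrom pair cutoff.
#'
#' @param probe_radius Solvent probe radius, Angstrom.
#' @param n_sphere_points Quadrature points per atom for the
#'   Shrake-Rupley surface lattice.
#' @param exposure_fraction Fraction of the theoretical maximum
#'   residue SASA at or above which a residue is called exposed.
#' @param vicinity_cutoff Distance (Angstrom) from an anchor residue
#'   within which an exposed residue joins the CDR vicinity.
#' @param pair_cutoff Maximum residue-residue distance (Angstrom) for
#'   a pair to contribute to a patch score.
#' @param distance_exponent Exponent on distance in the patch kernel.
#' @param distance_mode Residue-residue distance: minimum over heavy
#'   atom pairs (\code{"min-heavy"}) or C-beta distance (\code{"cb"}).
#' @param hydrophobicity_range Target interval for the normalised
#'   Kyte-Doolittle weights.
#' @param his_charge Histidine formal charge.
#' @param sfvcsp_scope Residues summed for the charge symmetry
#'   parameter: every exposed residue of each variable domain
#'   (\code{"domain"}) or only CDR-vicinity members (\code{"vicinity"}).
#' @param sd_divisor Convention for reported standard deviations:
#'   \code{"n-1"} (sample, default) or \code{"n"} (population).
#' @param noncanonical Reader policy for non-canonical residues:
#'   \code{"error"} (default) or \code{"skip"}.
#' @param read_predicted_error Interpret the PDB B-factor column as
#'   per-residue backbone predicted error.
#' @param vdw_radii Named radii table as \code{\link{defaultVdwRadii}}.
#' @return A list of class \code{"tapConfig"}.
#' @examples
#' cfg <- tapConfig(pair_cutoff = 6.0)
#' cfg$pair_cutoff
#' @export
tapConfig <- function(probe_radius = 1.4,
                      n_sphere_points = 960L,
                      exposure_fraction = 0.075,
                      vicinity_cutoff = 4.5,
                      pair_cutoff = 7.5,
                      distance_exponent = 2,
                      distance_mode = c("min-heavy", "cb"),
                      hydrophobicity_range = c(1, 2),
                      his_charge = 0.1,
                      sfvcsp_scope = c("domain", "vicinity"),
                      sd_divisor = c("n-1", "n"),
                      noncanonical = c("error", "skip"),
                      read_predicted_error = TRUE,
                      vdw_radii = defaultVdwRadii()) {
  stopifnot(probe_radius > 0, n_sphere_points >= 16,
            exposure_fraction >= 0, vicinity_cutoff > 0,
            pair_cutoff > 0, distance_exponent > 0,
            all(vdw_radii > 0), "default" %in% names(vdw_radii))
  cfg <- list(
    probe_radius = probe_radius,
    n_sphere_points = as.integer(n_sphere_points),
    exposure_fraction = exposure_fraction,
    vicinity_cutoff = vicinity_cutoff,
    pair_cutoff = pair_cutoff,
    distance_exponent = distance_exponent,
    distance_mode = match.arg(distance_mode),
    hydrophobicity_range = hydrophobicity_range,
    his_charge = his_charge,
    sfvcsp_scope = match.arg(sfvcsp_scope),
    sd_divisor = match.arg(sd_divisor),
    noncanonical = match.arg(noncanonical),
    read_predicted_error = isTRUE(read_predicted_error),
    vdw_radii = vdw_radii
  )
  class(cfg) <- "tapConfig"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path YAML file with \code{\link{tapConfig}} argument names
#'   as keys.
#' @return A \code{tapConfig} list.
#' @export
readTapConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(tapConfig))
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(vals$vdw_radii)) vals$vdw_radii <- unlist(vals$vdw_radii)
  do.call(tapConfig, vals)
}

## Polynomial rolling hash mod 2^31 - 1 (exact in double precision),
## used to stamp output files with their resolved configuration.
strHash <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

#' Short hash of a resolved configuration
#'
#' @param config A \code{tapConfig} list.
#' @return 8-character hexadecimal string identifying the configuration.
#' @export
configHash <- function(config) {
  flat <- paste(names(unlist(config)), unlist(config),
                sep = "=", collapse = ";")
  strHash(flat)
}
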