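## PDB ingestion and serialisation for IMGT-numbered Fv models.
## Parsing and fixed-width formatting are delegated to bio3d; this
## layer enforces the Fv-specific contract: exactly two mapped chains,
## hydrogens and heteroatoms stripped, a single conformer per atom,
## canonical residues only, and predicted error recovered from the
## B-factor column.

inferElement <- function(elety, elesy) {
  el <- toupper(trimws(as.character(elesy)))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # fall back to the atom name: strip digits, first letter
    nm <- gsub("[0-9']", "", toupper(elety[miss]))
    two <- substr(nm, 1, 2)
    el[miss] <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"),
                       two, substr(nm, 1, 1))
  }
  el
}

#' Read an IMGT-numbered Fv model from a PDB file
#'
#' Reads ATOM records for the two mapped chains, drops hydrogens,
#' waters and all heteroatoms, keeps the highest-precedence alternate
#' location (blank, then 'A'), assigns van der Waals radii from the
#' configuration, and -- when \code{config$read_predicted_error} is
#' TRUE -- stores the mean backbone (N, CA, C, O) B-factor of each
#' residue as its predicted error, the convention used by
#' deep-learning antibody model deposits.
#'
#' @param path PDB file.
#' @param chain_map Named character vector mapping file chain ids to
#'   \code{"H"} / \code{"L"}; default assumes the file already uses H
#'   and L.
#' @param config A \code{\link{tapConfig}}; controls radii, predicted
#'   error, and the non-canonical residue policy (\code{"error"} or
#'   \code{"skip"}).
#' @param id Structure identifier; defaults to the file name.
#' @param light_locus Light-chain locus annotation
#'   (\code{"kappa"}, \code{"lambda"}, \code{"unknown"}).
#' @param metadata Named list of free-form annotations.
#' @return An \code{\linkS4class{FvStructure}}.
#' @examples
#' fv <- makeMiniFv(miniFvSpec(seed = 1))
#' p <- tempfile(fileext = ".pdb")
#' writeFvPdb(fv, p)
#' fv2 <- readFvPdb(p, id = fvId(fv))
#' all.equal(fvResidues(fv)$aa, fvResidues(fv2)$aa)
#' @export
readFvPdb <- function(path, chain_map = c(H = "H", L = "L"),
                      config = tapConfig(), id = NULL,
                      light_locus = "unknown", metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id)) id <- sub("\\.pdb$", "", basename(path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(at) == 0L) stop("empty structure: no ATOM records in ", path)

  # altloc precedence: blank first, then 'A'; other conformers dropped
  alt <- ifelse(is.na(at$alt), "", at$alt)
  at <- at[alt %in% c("", "A"), , drop = FALSE]

  if (is.null(names(chain_map)) || !setequal(unname(chain_map), c("H", "L")))
    stop("chain_map must map two file chain ids onto H and L")
  for (file_ch in names(chain_map)) {
    if (!file_ch %in% at$chain)
      stop("chain not found: ", file_ch)
  }
  at <- at[at$chain %in% names(chain_map), , drop = FALSE]
  at$chain <- unname(chain_map[at$chain])

  element <- inferElement(at$elety, at$elesy)
  at <- at[!element %in% c("H", "D"), , drop = FALSE]
  element <- element[!element %in% c("H", "D")]
  if (nrow(at) == 0L) stop("empty structure: only hydrogens in ", path)

  aa <- unname(.AA3TO1[at$resid])
  if (anyNA(aa)) {
    bad <- unique(at$resid[is.na(aa)])
    if (config$noncanonical == "error")
      stop("non-canonical residue: ", paste(bad, collapse = ", "))
    keep <- !is.na(aa)
    at <- at[keep, , drop = FALSE]
    element <- element[keep]
    aa <- aa[keep]
  }

  insert <- ifelse(is.na(at$insert), "", at$insert)
  radii <- config$vdw_radii
  vdw <- unname(radii[element])
  vdw[is.na(vdw)] <- radii[["default"]]

  atoms <- data.frame(chain = at$chain, resno = as.integer(at$resno),
                      insert = insert, aa = aa,
                      seq_index = NA_integer_, name = at$elety,
                      element = element, x = at$x, y = at$y, z = at$z,
                      bfactor = ifelse(is.na(at$b), 0, at$b), vdw = vdw,
                      stringsAsFactors = FALSE)
  # 0-based residue rank in file order, per chain
  for (ch in c("H", "L")) {
    sel <- atoms$chain == ch
    key <- resKey(atoms$chain[sel], atoms$resno[sel], atoms$insert[sel])
    atoms$seq_index[sel] <- match(key, unique(key)) - 1L
  }
  newFvStructure(id, atoms, lightLocus = light_locus, metadata = metadata,
                 predicted_error = config$read_predicted_error)
}

#' Write an FvStructure to a PDB file
#'
#' Serialises standard ATOM records (coordinates at 3 decimals,
#' insertion codes in column 27, B-factors preserved) such that
#' \code{\link{readFvPdb}} reproduces the residue and atom inventory.
#'
#' @param structure An \code{FvStructure}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
writeFvPdb <- function(structure, path) {
  methods::validObject(structure)
  at <- structure@atoms
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("unwritable path: ", path)
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   type = rep("ATOM", nrow(at)),
                   resno = at$resno,
                   resid = unname(.AA3[at$aa]),
                   eleno = seq_len(nrow(at)),
                   elety = at$name,
                   chain = at$chain,
                   insert = ifelse(at$insert == "", NA, at$insert),
                   o = rep(1, nrow(at)),
                   b = at$bfactor,
                   elesy = at$element,
                   end = TRUE)
  invisible(path)
}
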