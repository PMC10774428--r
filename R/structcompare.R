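## Framework-aligned backbone RMSD between a model and a reference
## structure, reported per IMGT region. The rigid superposition is
## least-squares (Kabsch, via SVD) on the framework backbone atoms
## common to both structures; region RMSDs are then computed in that
## frame without re-fitting, so CDR deviations are measured relative
## to a framework alignment.

## Kabsch: rotation R and translation t minimising ||R X + t - Y||.
## X, Y are n x 3 matrices of paired coordinates.
kabschSuperpose <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 3)
  cx <- colMeans(X)
  cy <- colMeans(Y)
  H <- t(sweep(X, 2, cx)) %*% sweep(Y, 2, cy)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- cy - as.numeric(R %*% cx)
  list(rotation = R, translation = t_vec)
}

## Backbone (N, CA, C, O) coordinates for one chain, keyed by
## residue and atom name; residues missing any backbone atom are
## dropped with a warning.
backboneCoords <- function(structure, chain) {
  at <- fvAtoms(structure)
  at <- at[at$chain == chain & at$name %in% c("N", "CA", "C", "O"), ,
           drop = FALSE]
  key <- resKey(at$chain, at$resno, at$insert)
  complete <- names(which(table(key) == 4L))
  dropped <- setdiff(unique(key), complete)
  if (length(dropped))
    warning("skipping residue(s) with missing backbone atoms in ",
            fvId(structure), ": ", paste(dropped, collapse = ", "))
  at <- at[key %in% complete, , drop = FALSE]
  at <- at[order(at$seq_index, match(at$name, c("N", "CA", "C", "O"))), ,
           drop = FALSE]
  at$akey <- paste(resKey(at$chain, at$resno, at$insert), at$name)
  at
}

#' Framework-aligned per-region backbone RMSD
#'
#' Superposes the model onto the reference using the backbone atoms
#' (N, CA, C, O) of the framework residues of one chain (matched by
#' chain, IMGT number and insertion code), then computes the backbone
#' RMSD of each IMGT region (FR, CDR1, CDR2, CDR3) in that fixed
#' frame.
#'
#' @param model,reference \code{\linkS4class{FvStructure}} objects
#'   sharing residue identities on \code{chain}.
#' @param chain \code{"H"} or \code{"L"}.
#' @return A \code{\linkS4class{SuperpositionResult}}.
#' @examples
#' fv <- makeMiniFv(miniFvSpec(seed = 1))
#' res <- frameworkAlignRegionRmsd(fv, fv, "H")
#' res@perRegionRmsd
#' @export
frameworkAlignRegionRmsd <- function(model, reference, chain = c("H", "L")) {
  chain <- match.arg(chain)
  bm <- backboneCoords(model, chain)
  br <- backboneCoords(reference, chain)
  common <- intersect(bm$akey, br$akey)
  bm <- bm[match(common, bm$akey), , drop = FALSE]
  br <- br[match(common, br$akey), , drop = FALSE]

  regions_ref <- assignRegions(reference)
  regions_ref <- regions_ref[regions_ref$chain == chain, , drop = FALSE]
  reg_by_key <- stats::setNames(regions_ref$region,
                                resKey(regions_ref$chain, regions_ref$resno,
                                       regions_ref$insert))
  reg <- unname(reg_by_key[resKey(br$chain, br$resno, br$insert)])

  fr <- reg == "FR"
  if (sum(fr) < 12L)  # 3 residues x 4 backbone atoms
    stop("fewer than 3 common framework residues on chain ", chain)
  X <- as.matrix(bm[, c("x", "y", "z")])
  Y <- as.matrix(br[, c("x", "y", "z")])
  fit <- kabschSuperpose(X[fr, , drop = FALSE], Y[fr, , drop = FALSE])
  Xs <- sweep(X %*% t(fit$rotation), 2, fit$translation, "+")

  region_names <- c("FR", "CDR1", "CDR2", "CDR3")
  rmsd <- n_at <- stats::setNames(rep(NA_real_, 4), region_names)
  for (rn in region_names) {
    sel <- reg == rn
    n_at[rn] <- sum(sel)
    if (any(sel))
      rmsd[rn] <- sqrt(mean(rowSums((Xs[sel, , drop = FALSE] -
                                       Y[sel, , drop = FALSE])^2)))
  }
  methods::new("SuperpositionResult", rotation = fit$rotation,
               translation = fit$translation, perRegionRmsd = rmsd,
               nAtoms = stats::setNames(as.integer(n_at), region_names))
}
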