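## Deterministic synthetic structures: ideal-geometry peptides and
## two-chain mini-Fv fixtures with valid IMGT numbering, plus a
## Monte-Carlo SASA estimator kept fully independent of the
## deterministic Shrake-Rupley implementation.

## Evaluate expr under a fixed RNG state, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Natural-extension-of-reference-frame placement: position D given
## A, B, C so that |C-D| = bond, angle(B,C,D) = angle and dihedral
## (A,B,C,D) = torsion (degrees).
nerfPlace <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang), bond * cos(tor) * sin(ang),
          bond * sin(tor) * sin(ang))
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

.BOND <- c(N_CA = 1.46, CA_C = 1.52, C_N = 1.33, C_O = 1.23,
           CA_CB = 1.53, SC = 1.45)

#' Build an ideal-geometry peptide fragment
#'
#' Generates backbone coordinates (N, CA, C, O per residue; bond
#' lengths N-CA 1.46, CA-C 1.52, C-N 1.33 Angstrom, standard angles)
#' at the requested backbone dihedrals, with simplified side-chain
#' placeholder atoms: the full heavy-atom complement of each residue
#' type laid out along the CA-CB direction. The result is an atom
#' table suitable for assembly into an \code{FvStructure} or for
#' direct geometric tests. Fully deterministic for a given spec;
#' optional coordinate jitter is driven by \code{seed}.
#'
#' @param sequence One-letter amino-acid string (canonical residues).
#' @param chain Chain identifier, \code{"H"} or \code{"L"}.
#' @param resno Integer IMGT numbers, one per residue (default
#'   sequential from 1).
#' @param insert Insertion codes, one per residue (default none).
#' @param phi,psi,omega Backbone dihedrals in degrees; the defaults
#'   (-120, +120, 180) give an extended strand.
#' @param bfactor Per-residue B-factor value(s) written to every atom
#'   of the residue (recycled); used to encode predicted error.
#' @param jitter Standard deviation (Angstrom) of optional Gaussian
#'   coordinate noise.
#' @param seed RNG seed for the jitter; required when jitter > 0.
#' @param offset Length-3 translation applied to all coordinates.
#' @param vdw_radii Radii table as \code{\link{defaultVdwRadii}}.
#' @return Atom data.frame in the \code{FvStructure} column layout.
#' @examples
#' pep <- makePeptide("ACDEFG")
#' nrow(pep)
#' @export
makePeptide <- function(sequence, chain = "H", resno = NULL, insert = NULL,
                        phi = -120, psi = 120, omega = 180,
                        bfactor = 0, jitter = 0, seed = NULL,
                        offset = c(0, 0, 0), vdw_radii = defaultVdwRadii()) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n == 0L) stop("empty sequence")
  if (!all(aa %in% .AA1))
    stop("invalid amino-acid letter: ",
         paste(unique(aa[!aa %in% .AA1]), collapse = ", "))
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(insert)) insert <- rep("", n)
  stopifnot(length(resno) == n, length(insert) == n)
  bfactor <- rep_len(bfactor, n)
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)

  Nc <- CAc <- Cc <- matrix(NA_real_, n, 3)
  Nc[1, ] <- c(0, 0, 0)
  CAc[1, ] <- c(.BOND["N_CA"], 0, 0)
  a <- 111 * pi / 180
  Cc[1, ] <- CAc[1, ] + .BOND["CA_C"] * c(-cos(a), sin(a), 0)
  if (n > 1) {
    for (i in 2:n) {
      Nc[i, ]  <- nerfPlace(Nc[i - 1, ], CAc[i - 1, ], Cc[i - 1, ],
                            .BOND["C_N"], 116.2, psi[i - 1])
      CAc[i, ] <- nerfPlace(CAc[i - 1, ], Cc[i - 1, ], Nc[i, ],
                            .BOND["N_CA"], 121.7, omega)
      Cc[i, ]  <- nerfPlace(Cc[i - 1, ], Nc[i, ], CAc[i, ],
                            .BOND["CA_C"], 111.0, phi[i])
    }
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    names_i <- c("N", "CA", "C", "O")
    coords <- rbind(Nc[i, ], CAc[i, ], Cc[i, ],
                    nerfPlace(Nc[i, ], CAc[i, ], Cc[i, ],
                              .BOND["C_O"], 120.5, psi[i] + 180))
    sc <- .SIDE_CHAIN_ATOMS[[aa[i]]]
    if (length(sc)) {
      cb <- nerfPlace(Cc[i, ], Nc[i, ], CAc[i, ],
                      .BOND["CA_CB"], 110.5, -122.0)
      coords <- rbind(coords, cb)
      names_i <- c(names_i, sc[1])
      if (length(sc) > 1) {
        u <- cb - CAc[i, ]
        u <- u / sqrt(sum(u^2))
        ref <- CAc[i, ] - Nc[i, ]
        w <- c(u[2] * ref[3] - u[3] * ref[2],
               u[3] * ref[1] - u[1] * ref[3],
               u[1] * ref[2] - u[2] * ref[1])
        w <- w / sqrt(sum(w^2))
        for (k in seq_along(sc[-1])) {
          coords <- rbind(coords,
                          cb + k * .BOND["SC"] * u + 0.5 * (k %% 2) * w)
          names_i <- c(names_i, sc[k + 1])
        }
      }
    }
    rows[[i]] <- data.frame(chain = chain, resno = as.integer(resno[i]),
                            insert = insert[i], aa = aa[i],
                            seq_index = i - 1L, name = names_i,
                            element = substr(names_i, 1, 1),
                            x = coords[, 1], y = coords[, 2], z = coords[, 3],
                            bfactor = bfactor[i], vdw = NA_real_,
                            stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  vdw <- unname(vdw_radii[at$element])
  vdw[is.na(vdw)] <- vdw_radii[["default"]]
  at$vdw <- vdw
  if (jitter > 0) {
    if (is.null(seed)) stop("jitter requires a seed")
    noise <- withSeed(seed, matrix(stats::rnorm(3 * nrow(at), sd = jitter),
                                   ncol = 3))
    at$x <- at$x + noise[, 1]
    at$y <- at$y + noise[, 2]
    at$z <- at$z + noise[, 3]
  }
  at$x <- at$x + offset[1]
  at$y <- at$y + offset[2]
  at$z <- at$z + offset[3]
  rownames(at) <- NULL
  at
}

#' IMGT numbering for a CDR3 of given length
#'
#' Positions 105-117, with insertion codes at position 111 when the
#' loop exceeds the 13 standard positions.
#'
#' @param len Loop length, residues.
#' @return List with integer \code{resno} and character \code{insert}.
#' @export
imgtCdr3Numbers <- function(len) {
  stopifnot(len >= 1)
  if (len <= 13L) {
    list(resno = 105:(104L + len), insert = rep("", len))
  } else {
    n_ins <- len - 13L
    if (n_ins > 26L) stop("CDR3 longer than supported (max 39)")
    list(resno = c(105:111, rep(111L, n_ins), 112:117),
         insert = c(rep("", 7), LETTERS[seq_len(n_ins)], rep("", 6)))
  }
}

## Numbering plan for one chain: framework stubs flanking the three
## CDR ranges, all numbers valid IMGT positions for their region.
chainNumberingPlan <- function(cdr_len, fr_len = c(4L, 4L, 4L, 4L)) {
  stopifnot(length(cdr_len) == 3, length(fr_len) == 4,
            cdr_len[1] >= 1, cdr_len[1] <= 12,
            cdr_len[2] >= 1, cdr_len[2] <= 10,
            cdr_len[3] >= 1,
            fr_len[1] >= 1, fr_len[1] <= 26,
            fr_len[2] >= 1, fr_len[2] <= 17,
            fr_len[3] >= 1, fr_len[3] <= 39,
            fr_len[4] >= 1, fr_len[4] <= 11)
  c3 <- imgtCdr3Numbers(cdr_len[3])
  resno <- c((27L - fr_len[1]):26L,
             27:(26L + cdr_len[1]),
             39:(38L + fr_len[2]),
             56:(55L + cdr_len[2]),
             (105L - fr_len[3]):104L,
             c3$resno,
             118:(117L + fr_len[4]))
  insert <- c(rep("", fr_len[1] + cdr_len[1] + fr_len[2] + cdr_len[2] + fr_len[3]),
              c3$insert,
              rep("", fr_len[4]))
  list(resno = as.integer(resno), insert = insert)
}

#' Specification for a synthetic mini-Fv fixture
#'
#' Describes a small two-chain structure with designed CDR segment
#' lengths, valid IMGT numbering (including insertion codes for long
#' CDR3 loops), deterministic sequences drawn from the seed, and
#' optional coordinate jitter and per-residue predicted error.
#'
#' @param heavy_cdr,light_cdr Integer length-3: designed CDR1/2/3
#'   lengths per chain.
#' @param heavy_fr,light_fr Integer length-4: framework stub lengths.
#' @param seed Integer; fully determines sequences, jitter and
#'   predicted error.
#' @param jitter Coordinate noise standard deviation, Angstrom.
#' @param pe \code{NULL} (no predicted error), \code{"random"}
#'   (uniform 0.3-2.5 Angstrom, seeded), or a numeric vector recycled
#'   over all residues (heavy then light).
#' @param id Structure identifier.
#' @param light_locus Light-chain locus annotation.
#' @param separation Inter-chain translation along y, Angstrom.
#' @return A list of class \code{"miniFvSpec"}.
#' @examples
#' spec <- miniFvSpec(seed = 7)
#' sum(spec$heavy_cdr) + sum(spec$light_cdr)
#' @export
miniFvSpec <- function(heavy_cdr = c(8L, 8L, 10L), light_cdr = c(6L, 3L, 9L),
                       heavy_fr = c(4L, 4L, 4L, 4L), light_fr = c(4L, 4L, 4L, 4L),
                       seed = 1L, jitter = 0, pe = NULL, id = NULL,
                       light_locus = "kappa", separation = 9) {
  if (is.null(id)) id <- sprintf("minifv_s%d", seed)
  spec <- list(heavy_cdr = as.integer(heavy_cdr),
               light_cdr = as.integer(light_cdr),
               heavy_fr = as.integer(heavy_fr),
               light_fr = as.integer(light_fr),
               seed = as.integer(seed), jitter = jitter, pe = pe, id = id,
               light_locus = light_locus, separation = separation)
  # fail early if the plan violates the IMGT ranges
  chainNumberingPlan(spec$heavy_cdr, spec$heavy_fr)
  chainNumberingPlan(spec$light_cdr, spec$light_fr)
  class(spec) <- "miniFvSpec"
  spec
}

#' Build a synthetic two-chain mini-Fv
#'
#' Assembles two extended-strand chains from a \code{\link{miniFvSpec}}:
#' designed CDR lengths, valid IMGT numbers, deterministic seeded
#' sequences, the light chain offset in y so the chains form a loose
#' interface. Suitable for exercising the full profiling pipeline
#' without external data.
#'
#' @param spec A \code{\link{miniFvSpec}}.
#' @return An \code{\linkS4class{FvStructure}}.
#' @examples
#' fv <- makeMiniFv(miniFvSpec(seed = 3))
#' fv
#' @export
makeMiniFv <- function(spec = miniFvSpec()) {
  stopifnot(inherits(spec, "miniFvSpec"))
  planH <- chainNumberingPlan(spec$heavy_cdr, spec$heavy_fr)
  planL <- chainNumberingPlan(spec$light_cdr, spec$light_fr)
  nH <- length(planH$resno)
  nL <- length(planL$resno)
  seqs <- withSeed(spec$seed, {
    list(H = paste(sample(.AA1, nH, replace = TRUE), collapse = ""),
         L = paste(sample(.AA1, nL, replace = TRUE), collapse = ""))
  })
  pe <- spec$pe
  if (identical(pe, "random")) {
    pe <- withSeed(spec$seed + 1L, stats::runif(nH + nL, 0.3, 2.5))
  } else if (is.null(pe)) {
    pe <- 0
  }
  pe <- rep_len(pe, nH + nL)
  atH <- makePeptide(seqs$H, chain = "H", resno = planH$resno,
                     insert = planH$insert, bfactor = pe[seq_len(nH)],
                     jitter = spec$jitter, seed = spec$seed + 2L)
  atL <- makePeptide(seqs$L, chain = "L", resno = planL$resno,
                     insert = planL$insert, bfactor = pe[nH + seq_len(nL)],
                     jitter = spec$jitter, seed = spec$seed + 3L,
                     offset = c(0, spec$separation, 0))
  newFvStructure(spec$id, rbind(atH, atL), lightLocus = spec$light_locus,
                 metadata = list(seed = spec$seed),
                 predicted_error = !is.null(spec$pe))
}

#' Monte-Carlo solvent-accessible surface area estimate
#'
#' Independent stochastic check of the deterministic surface
#' implementation: for each atom, directions are drawn uniformly on
#' the probe-expanded sphere (normalised Gaussian triples) and the
#' accessible fraction estimated by rejection against all
#' neighbouring expanded spheres. Shares no code with
#' \code{\link{shrakeRupley}}.
#'
#' @param x An \code{FvStructure} or an atom data.frame with columns
#'   x, y, z, vdw.
#' @param probe_radius Probe radius, Angstrom.
#' @param n_samples Sample directions per atom (>= 10000).
#' @param seed RNG seed.
#' @return List with numeric vectors \code{sasa} and \code{se}
#'   (standard error), one entry per atom.
#' @export
mcSasaOracle <- function(x, probe_radius = 1.4, n_samples = 20000L,
                         seed = 42L) {
  at <- if (methods::is(x, "FvStructure")) fvAtoms(x) else x
  stopifnot(n_samples >= 1e4)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- at$vdw + probe_radius
  n <- nrow(xyz)
  withSeed(seed, {
    sasa <- se <- numeric(n)
    d2full <- as.matrix(stats::dist(xyz))^2
    for (i in seq_len(n)) {
      nb <- which(d2full[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
      dirs <- matrix(stats::rnorm(3 * n_samples), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      pts <- sweep(dirs * rad[i], 2, xyz[i, ], "+")
      acc <- rep(TRUE, n_samples)
      for (j in nb) {
        dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        acc <- acc & dj2 >= rad[j]^2
        if (!any(acc)) break
      }
      p <- mean(acc)
      area <- 4 * pi * rad[i]^2
      sasa[i] <- p * area
      se[i] <- area * sqrt(p * (1 - p) / n_samples)
    }
    list(sasa = sasa, se = se)
  })
}
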