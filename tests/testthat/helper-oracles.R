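# Independent brute-force oracles and tiny fixture builders shared by
# the tests. These deliberately share no code with the implementations
# they check: distances, percentiles and correlations are computed with
# explicit loops / textbook formulas.

# Minimum inter-atom distance between two residues, nested loops.
naiveMinResidueDistance <- function(atoms, key_a, key_b) {
  keys <- paste0(atoms$chain, ":", atoms$resno,
                 ifelse(atoms$insert == "", "", atoms$insert))
  A <- atoms[keys == key_a, c("x", "y", "z"), drop = FALSE]
  B <- atoms[keys == key_b, c("x", "y", "z"), drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt(sum((as.numeric(A[i, ]) - as.numeric(B[j, ]))^2))
      if (d < best) best <- d
    }
  }
  best
}

# Naive double-loop patch score over a set of residue keys.
naivePatchOracle <- function(atoms, member_keys, weights, cutoff = 7.5,
                             exponent = 2) {
  total <- 0
  n <- length(member_keys)
  if (n < 2) return(total)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      wi <- weights[[member_keys[i]]]
      wj <- weights[[member_keys[j]]]
      if (is.null(wi) || is.null(wj) || wi <= 0 || wj <= 0) next
      d <- naiveMinResidueDistance(atoms, member_keys[i], member_keys[j])
      if (d <= cutoff) total <- total + wi * wj / d^exponent
    }
  }
  total
}

# Sorted linear-interpolation percentile (the "linear" convention),
# written out longhand.
percentileOracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Textbook Pearson correlation.
pearsonOracle <- function(a, b) {
  ma <- sum(a) / length(a)
  mb <- sum(b) / length(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# Fixed-width PDB ATOM/HETATM record.
pdbLine <- function(record, serial, name, resid3, chain, resno, x, y, z,
                    b = 0, element = substr(name, 1, 1), insert = " ",
                    alt = " ") {
  namefmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, namefmt, alt, resid3, chain, resno, insert,
          x, y, z, 1.00, b, element)
}

# A hand-written two-chain PDB with glycine backbones; one residue per
# entry of resnos. Returns the file path.
writeTinyPdb <- function(path, chains, resnos, inserts = NULL,
                         resid3 = "GLY", b = 0, spacing = 4) {
  if (is.null(inserts)) inserts <- rep(" ", length(resnos))
  resid3 <- rep_len(resid3, length(resnos))
  lines <- character(0)
  serial <- 0L
  for (i in seq_along(resnos)) {
    x0 <- i * spacing
    y0 <- ifelse(chains[i] == "H", 0, 30)
    for (at in list(c("N", -1.2, 0), c("CA", 0, 0), c("C", 1.2, 0),
                    c("O", 1.2, 1.2))) {
      serial <- serial + 1L
      lines <- c(lines, pdbLine("ATOM", serial, at[[1]], resid3[i],
                                chains[i], resnos[i],
                                x0 + as.numeric(at[[2]]),
                                y0 + as.numeric(at[[3]]), 0,
                                b = b, insert = inserts[i]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# Small single-atom "residues" at chosen coordinates: a convenient
# synthetic surface for kernel tests (every residue one CA atom).
pointResidueAtoms <- function(coords, chain = "H", aa = "A",
                              resno = NULL) {
  n <- nrow(coords)
  if (is.null(resno)) resno <- seq_len(n)
  aa <- rep_len(aa, n)
  chain <- rep_len(chain, n)
  data.frame(chain = chain, resno = as.integer(resno), insert = "",
             aa = aa, seq_index = seq_len(n) - 1L, name = "CA",
             element = "C", x = coords[, 1], y = coords[, 2],
             z = coords[, 3], bfactor = 0, vdw = 1.7,
             stringsAsFactors = FALSE)
}

keyOf <- function(atoms) {
  paste0(atoms$chain, ":", atoms$resno,
         ifelse(atoms$insert == "", "", atoms$insert))
}

# Uniform random rotation (quaternion construction) and rigid motion
# of a structure, for superposition-invariance tests.
randomRotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

transformFv <- function(fv, R, t) {
  at <- fvAtoms(fv)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- xyz[, 1] + t[1]
  at$y <- xyz[, 2] + t[2]
  at$z <- xyz[, 3] + t[3]
  abtap:::newFvStructure(fvId(fv), at)
}

# Shared small mini-Fv specs (smaller framework stubs keep the SASA
# cost of repeated pipeline tests low).
smallSpec <- function(seed, ...) {
  miniFvSpec(heavy_cdr = c(5L, 4L, 6L), light_cdr = c(4L, 3L, 5L),
             heavy_fr = c(3L, 3L, 3L, 3L), light_fr = c(3L, 3L, 3L, 3L),
             seed = seed, ...)
}
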