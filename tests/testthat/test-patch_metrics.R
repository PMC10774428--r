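# The kernel tests build small synthetic residue clouds and check the
# vectorised implementation against hand sums and naive double loops.

mkVicinity <- function(members) {
  out <- list(anchors = members, members = members, cutoff = 4.5)
  class(out) <- "CdrVicinity"
  out
}

allExposed <- function(fv) {
  keys <- keyOf(fvResidues(fv))
  setNames(rep(TRUE, length(keys)), keys)
}

twoChainCloud <- function(coordsH, coordsL = cbind(c(0, 4), 100, 0),
                          aaH = "A", aaL = "G") {
  atH <- pointResidueAtoms(coordsH, chain = "H", aa = aaH)
  atL <- pointResidueAtoms(coordsL, chain = "L", aa = aaL)
  abtap:::newFvStructure("cloud", rbind(atH, atL))
}

test_that("patch score is a cutoff-limited pairwise inverse-square sum", {
  # triangle with pairwise distances 4, 5, 6 and weights 2, 1.5, 1
  coords <- rbind(c(0, 0, 0), c(4, 0, 0), c(1.125, 4.871, 0) * 6 / 5.0)
  # place third point so d13 = 5 and d23 = 6
  x3 <- (4^2 + 5^2 - 6^2) / (2 * 4)
  coords[3, ] <- c(x3, sqrt(25 - x3^2), 0)
  fv <- twoChainCloud(coords)
  keys <- paste0("H:", 1:3)
  w <- setNames(c(2, 1.5, 1, 0, 0), c(keys, "L:1", "L:2"))
  res <- patchScore(fv, mkVicinity(keys), allExposed(fv), w,
                    pair_cutoff = 7.5, exponent = 2)
  hand <- 2 * 1.5 / 4^2 + 2 * 1 / 5^2 + 1.5 * 1 / 6^2
  expect_equal(res$score, hand, tolerance = 1e-12)
  expect_equal(nrow(res$components), 3L)
  expect_equal(sum(res$components$contribution), res$score)

  # beyond the pair cutoff nothing contributes
  far <- twoChainCloud(rbind(c(0, 0, 0), c(8, 0, 0)))
  res2 <- patchScore(far, mkVicinity(c("H:1", "H:2")), allExposed(far),
                     setNames(c(1, 1), c("H:1", "H:2")))
  expect_equal(res2$score, 0)
  expect_equal(nrow(res2$components), 0L)

  # a single weighted residue has no pairs
  res3 <- patchScore(fv, mkVicinity(keys), allExposed(fv),
                     setNames(c(2, 0, 0, 0, 0), c(keys, "L:1", "L:2")))
  expect_equal(res3$score, 0)
})

test_that("patch scores match the naive double-loop oracle on random clouds", {
  set.seed(1205)
  for (rep in 1:100) {
    n <- sample(3:8, 1)
    coords <- matrix(runif(3 * n, 0, 12), ncol = 3)
    fv <- twoChainCloud(coords)
    keys <- paste0("H:", seq_len(n))
    w <- setNames(c(round(runif(n, 0, 2), 3), 1, 1), c(keys, "L:1", "L:2"))
    # random exposure pattern
    exposure <- allExposed(fv)
    exposure[sample(keys, n %/% 3)] <- FALSE
    res <- patchScore(fv, mkVicinity(keys), exposure, w)
    active <- keys[exposure[keys] & w[keys] > 0]
    oracle <- naivePatchOracle(fvAtoms(fv), active, as.list(w))
    expect_equal(res$score, oracle, tolerance = 1e-10)
    expect_equal(sum(res$components$contribution), res$score)
  }
})

test_that("hydrophobicity weights preserve the Kyte-Doolittle order", {
  coords <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0))
  gly <- twoChainCloud(coords, aaH = "G")
  leu <- twoChainCloud(coords, aaH = "L")
  keys <- paste0("H:", 1:3)
  sg <- pshScore(gly, mkVicinity(keys), allExposed(gly))
  sl <- pshScore(leu, mkVicinity(keys), allExposed(leu))
  expect_gt(sl$score, sg$score)
  expect_equal(sum(sl$components$contribution), sl$score)

  norm <- kyteDoolittle()$normalized
  expect_true(all(norm > 0))
  expect_equal(order(norm), order(kyteDoolittle()$raw))
})

test_that("charge patch scores see only their own sign", {
  coords <- rbind(c(0, 0, 0), c(4, 0, 0))
  kk <- twoChainCloud(coords, aaH = "K")
  keys <- c("H:1", "H:2")
  res <- ppcScore(kk, mkVicinity(keys), allExposed(kk))
  expect_equal(res$score, 1 / 16)          # two lysines at 4 A
  expect_equal(pncScore(kk, mkVicinity(keys), allExposed(kk))$score, 0)

  ss <- twoChainCloud(coords, aaH = "S")   # no charged residues at all
  expect_equal(ppcScore(ss, mkVicinity(keys), allExposed(ss))$score, 0)
  dd <- twoChainCloud(coords, aaH = "D")
  expect_equal(pncScore(dd, mkVicinity(keys), allExposed(dd))$score, 1 / 16)
  expect_equal(ppcScore(dd, mkVicinity(keys), allExposed(dd))$score, 0)
})

test_that("charge symmetry parameter is a product of net domain charges", {
  atH <- pointResidueAtoms(rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)),
                           chain = "H", aa = c("K", "K", "D"))
  atL <- pointResidueAtoms(rbind(c(0, 50, 0), c(4, 50, 0)),
                           chain = "L", aa = c("D", "D"))
  fv <- abtap:::newFvStructure("csp", rbind(atH, atL))
  exposure <- allExposed(fv)
  expect_equal(sfvcspScore(fv, exposure), (1 + 1 - 1) * (-2))

  # swapping the chain labels leaves the product unchanged
  atH2 <- atL; atH2$chain <- "H"
  atL2 <- atH; atL2$chain <- "L"
  fv2 <- abtap:::newFvStructure("csp2", rbind(atH2, atL2))
  expect_equal(sfvcspScore(fv2, allExposed(fv2)),
               sfvcspScore(fv, exposure))

  # zero heavy net charge gives zero regardless of the light chain
  atH0 <- pointResidueAtoms(rbind(c(0, 0, 0), c(4, 0, 0)),
                            chain = "H", aa = c("K", "D"))
  fv0 <- abtap:::newFvStructure("csp0", rbind(atH0, atL))
  expect_equal(sfvcspScore(fv0, allExposed(fv0)), 0)

  # negating every charge preserves the score; negating one chain flips it
  q <- chargeAssignment()
  s <- sfvcspScore(fv, exposure, q)
  expect_equal(sfvcspScore(fv, exposure, -q), s)
  rs <- fvResidues(fv)
  hsum <- sum(q[rs$aa[rs$chain == "H"]])
  lsum <- sum(q[rs$aa[rs$chain == "L"]])
  expect_equal(-hsum * lsum, -s)
})

test_that("patch scores are quadratic in a global weight rescaling", {
  set.seed(42)
  fv <- twoChainCloud(matrix(runif(15, 0, 8), ncol = 3))
  keys <- paste0("H:", 1:5)
  w <- setNames(c(runif(5, 0.5, 2), 0, 0), c(keys, "L:1", "L:2"))
  s1 <- patchScore(fv, mkVicinity(keys), allExposed(fv), w)$score
  s3 <- patchScore(fv, mkVicinity(keys), allExposed(fv), 3 * w)$score
  expect_equal(s3, 9 * s1, tolerance = 1e-10)
})

test_that("profiles are deterministic, internally consistent, and local", {
  fv <- makeMiniFv(smallSpec(seed = 8))
  p1 <- computeTapProfile(fv)
  p2 <- computeTapProfile(fv)
  expect_equal(tapMetrics(p1), tapMetrics(p2))
  expect_identical(tapComponents(p1, "psh"), tapComponents(p2, "psh"))
  expect_equal(p1@lTot, totalCdrLength(assignRegions(fv)))
  for (m in c("psh", "ppc", "pnc")) {
    expect_equal(sum(tapComponents(p1, m)$contribution),
                 unname(tapMetrics(p1)[m]), tolerance = 1e-12)
  }

  # perturbing a residue far from every anchor leaves patch scores alone
  spec <- miniFvSpec(heavy_fr = c(20L, 4L, 4L, 4L), separation = 25,
                     seed = 8)
  fv2 <- makeMiniFv(spec)
  at <- fvAtoms(fv2)
  # FR1 stub start is > pair_cutoff + vicinity cutoff from every anchor
  target <- at$chain == "H" & at$seq_index == 0L
  regions <- assignRegions(fv2)
  anchors <- buildAnchorSet(fv2, regions)
  dmin <- min(vapply(anchors, function(a)
    naiveMinResidueDistance(at, "H:7", a), numeric(1)))
  expect_gt(dmin, 7.5 + 4.5)
  base <- computeTapProfile(fv2)
  at$x[target] <- at$x[target] + 0.9
  fv3 <- abtap:::newFvStructure(fvId(fv2), at)
  moved <- computeTapProfile(fv3)
  expect_equal(tapMetrics(moved)[c("psh", "ppc", "pnc")],
               tapMetrics(base)[c("psh", "ppc", "pnc")])
})

test_that("component ranking filters by adjacency and breaks ties deterministically", {
  fv <- makeMiniFv(smallSpec(seed = 8))
  comp <- tapComponents(computeTapProfile(fv), "psh")
  for (adj in c("adjacent", "non_adjacent")) {
    top <- topComponents(comp, 5, adj)
    expect_true(all(top$adjacent == (adj == "adjacent")))
    expect_true(all(diff(top$contribution) <= 0))
  }
  # adjacency means same chain, consecutive positions
  adj_rows <- comp[comp$adjacent, ]
  expect_true(all(adj_rows$chain_i == adj_rows$chain_j))
  expect_true(all(abs(adj_rows$seq_index_i - adj_rows$seq_index_j) == 1))

  # k larger than the list returns everything, ranking equals a sort oracle
  set.seed(9)
  fake <- comp[sample(nrow(comp)), ]
  top_all <- topComponents(fake, nrow(fake) + 10, "non_adjacent")
  oracle <- fake[!fake$adjacent, ]
  oracle <- oracle[order(-oracle$contribution, oracle$chain_i,
                         oracle$seq_index_i, oracle$chain_j,
                         oracle$seq_index_j), ]
  expect_equal(top_all$contribution, oracle$contribution)
  expect_equal(nrow(top_all), nrow(oracle))
})

test_that("position contribution table equals a hand tally", {
  mkProfile <- function(id, comp) {
    methods::new("TapProfile", id = id, lTot = 10L,
                 psh = sum(comp$contribution), ppc = 0, pnc = 0, sfvcsp = 0,
                 components = list(psh = comp, ppc = abtap:::emptyComponents(),
                                   pnc = abtap:::emptyComponents()))
  }
  row <- function(ci, ii, si, cj, ij, sj, contrib, adj) {
    data.frame(chain_i = ci, imgt_i = ii, insert_i = "", aa_i = "A",
               seq_index_i = si, chain_j = cj, imgt_j = ij, insert_j = "",
               aa_j = "A", seq_index_j = sj, distance = 5,
               contribution = contrib, adjacent = adj,
               stringsAsFactors = FALSE)
  }
  p1 <- mkProfile("a", rbind(row("H", 105, 0, "H", 106, 1, 2.0, TRUE),
                             row("H", 105, 0, "L", 40, 5, 1.0, FALSE)))
  p2 <- mkProfile("b", rbind(row("H", 105, 0, "H", 106, 1, 3.0, TRUE)))
  p3 <- mkProfile("c", abtap:::emptyComponents())
  tab <- positionContributionTable(list(p1, p2, p3), k = 20)
  lookup <- function(ch, no) tab$count[tab$chain == ch & tab$imgt == no]
  expect_equal(lookup("H", 105), 3L)  # both pairs of a, one of b
  expect_equal(lookup("H", 106), 2L)
  expect_equal(lookup("L", 40), 1L)
  # counts never exceed 2 positions x k pairs x 2 classes x antibodies
  expect_lte(sum(tab$count), 2 * 20 * 2 * 3)
})
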