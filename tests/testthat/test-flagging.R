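mkThresholds <- function(metric, sidedness, lr = NA, la = NA, ua = NA,
                         ur = NA, n = 100L) {
  methods::new("ThresholdSet",
               table = data.frame(metric = metric, sidedness = sidedness,
                                  lower_red = lr, lower_amber = la,
                                  upper_amber = ua, upper_red = ur,
                                  stringsAsFactors = FALSE),
               referenceN = setNames(n, metric))
}

test_that("threshold fitting matches the uniform grid and the sort oracle", {
  ts <- fitThresholds(list(l_tot = 0:100))
  tb <- thresholdTable(ts)
  expect_equal(tb$lower_red, 0)
  expect_equal(tb$lower_amber, 5)
  expect_equal(tb$upper_amber, 95)
  expect_equal(tb$upper_red, 100)

  # sidedness: two-sided metrics carry 4 boundaries, one-sided carry 2
  set.seed(77)
  scores <- list(l_tot = sample(30:70, 200, TRUE),
                 psh = rnorm(200, 120, 20), ppc = rexp(200),
                 pnc = rexp(200), sfvcsp = rnorm(200, -5, 8))
  ts2 <- fitThresholds(scores)
  tb2 <- thresholdTable(ts2)
  n_bounds <- rowSums(!is.na(tb2[, c("lower_red", "lower_amber",
                                     "upper_amber", "upper_red")]))
  expect_equal(setNames(n_bounds, tb2$metric),
               c(l_tot = 4, psh = 4, ppc = 2, pnc = 2, sfvcsp = 2))

  # percentiles equal an independent sort-and-interpolate oracle
  for (rep in 1:20) {
    x <- rnorm(sample(20:300, 1), sd = runif(1, 1, 50))
    ts3 <- fitThresholds(list(psh = x))
    tb3 <- thresholdTable(ts3)
    expect_equal(tb3$lower_amber, percentileOracle(x, 0.05))
    expect_equal(tb3$upper_amber, percentileOracle(x, 0.95))
    expect_equal(tb3$lower_red, min(x))
    expect_equal(tb3$upper_red, max(x))
  }
  expect_error(fitThresholds(list(psh = numeric(0))), "empty reference")
})

test_that("flag assignment respects sidedness and inclusive amber bounds", {
  # published charge-symmetry red region: below -30.60
  ts <- mkThresholds("sfvcsp", "lower", lr = -30.60, la = -6.00)
  flag_of <- function(s, t) assignFlags(setNames(s, t@table$metric), t)$flag
  expect_equal(flag_of(-31.0, ts), "red")
  expect_equal(flag_of(-30.60, ts), "amber")   # at the minimum: amber
  expect_equal(flag_of(-6.00, ts), "amber")
  expect_equal(flag_of(-5.99, ts), "green")
  expect_equal(flag_of(100, ts), "green")      # upper side unflagged

  two <- mkThresholds("psh", "two_sided", lr = 80, la = 95, ua = 110,
                      ur = 130)
  expect_equal(flag_of(102, two), "green")     # interior (median-like) point
  expect_equal(flag_of(110, two), "amber")     # exactly p95: amber
  expect_equal(flag_of(95, two), "amber")
  expect_equal(flag_of(130, two), "amber")     # at the maximum: amber
  expect_equal(flag_of(130.01, two), "red")
  expect_equal(flag_of(79.99, two), "red")

  up <- mkThresholds("ppc", "upper", ua = 4.22, ur = 8.0)
  expect_equal(flag_of(0, up), "green")
  expect_equal(flag_of(4.22, up), "amber")
  expect_equal(flag_of(8.01, up), "red")
})

test_that("a reference cohort flagged against itself has no red and ~5% amber per tail", {
  set.seed(664)
  scores <- list(l_tot = as.numeric(sample(30:70, 664, TRUE)),
                 psh = rnorm(664, 120, 20), ppc = rexp(664),
                 pnc = rexp(664), sfvcsp = rnorm(664, -5, 8))
  ts <- fitThresholds(scores)
  tb <- thresholdTable(ts)
  for (m in names(scores)) {
    row <- tb[tb$metric == m, ]
    flags <- vapply(scores[[m]], abtap:::flagOne, "", row = row)
    expect_equal(sum(flags == "red"), 0L)
    n_tails <- sum(row$sidedness == "two_sided") + 1
    amber_rate <- mean(flags == "amber") / n_tails
    if (m == "l_tot") {
      # heavily tied integer scores: amber rate can exceed the nominal
      # tail mass, but min/max can never red-flag
      expect_gte(amber_rate, 0.05 - 0.01)
    } else {
      expect_gt(amber_rate, 0.04)
      expect_lt(amber_rate, 0.065)
    }
  }
})

test_that("monotonicity: raising a surface-hydrophobicity score never improves its flag", {
  ts <- mkThresholds("psh", "two_sided", lr = 80, la = 95, ua = 110, ur = 130)
  sev <- function(f) match(f, c("green", "amber", "red"))
  s <- seq(75, 135, by = 0.5)
  f <- vapply(s, function(x) assignFlags(c(psh = x), ts)$flag, "")
  upper <- s >= 100
  expect_true(all(diff(sev(f[upper])) >= 0))
})

test_that("CDRH3 RMS predicted error follows the quadratic-mean formula", {
  mk <- function(pes) {
    n <- length(pes)
    # heavy chain layout: FR1(4) CDR1(5) FR2(4) CDR2(4) FR3(4) CDR3(n) FR4(4)
    pe <- rep(0.5, 25 + n + 34)
    pe[21 + seq_len(n)] <- pes
    makeMiniFv(miniFvSpec(heavy_cdr = c(5L, 4L, n), seed = 1, pe = pe))
  }
  h3len <- function(fv) sum(assignRegions(fv)$chain == "H" &
                              assignRegions(fv)$region == "CDR3")
  fv3 <- mk(c(1, 1, 1))
  expect_equal(h3len(fv3), 3L)
  expect_equal(cdrh3RmsPredictedError(fv3), 1.0)
  fv_mix <- mk(c(0.5, 1.5, 2.5))
  expect_equal(cdrh3RmsPredictedError(fv_mix), sqrt(8.75 / 3),
               tolerance = 1e-12)
  expect_equal(round(cdrh3RmsPredictedError(fv_mix), 4), 1.7078)
  fv1 <- mk(1.37)
  expect_equal(cdrh3RmsPredictedError(fv1), 1.37)

  # missing predicted error is an error, not a silent zero
  fv_na <- makeMiniFv(miniFvSpec(seed = 1))   # pe = NULL
  expect_error(cdrh3RmsPredictedError(fv_na), "missing predicted error")
})

test_that("confidence filtering retains at or below the threshold", {
  mkfv <- function(id, pe) {
    spec <- smallSpec(seed = 3, pe = pe, id = id)
    makeMiniFv(spec)
  }
  same <- lapply(1:5, function(i) mkfv(paste0("s", i), 1.2))
  # identical RMS values, threshold exactly at them: inclusive, all retained
  res <- confidenceFilter(same,
                          threshold = cdrh3RmsPredictedError(same[[1]]))
  expect_equal(length(res$retained), 5L)
  expect_equal(length(confidenceFilter(same, threshold = 0)$retained), 0L)

  # 100 distinct RMS values, 75th percentile: 75 retained
  cohort <- lapply(1:100, function(i) mkfv(paste0("c", i), i / 10))
  res2 <- confidenceFilter(cohort, percentile = 0.75)
  expect_equal(length(res2$retained), 75L)
  # oracle: count values at or below the interpolated percentile
  rms <- sort(res2$rms)
  expect_equal(sum(res2$rms <= percentileOracle(rms, 0.75)), 75L)

  # exclusion list changes the derivation but not the application
  res3 <- confidenceFilter(cohort, percentile = 0.75,
                           exclude_ids = paste0("c", 76:100))
  expect_lt(res3$threshold, res2$threshold)
  # threshold from c1..c75 only: 5.65 A, retaining c1..c56 of the full set
  expect_equal(length(res3$retained), 56L)
  expect_error(confidenceFilter(cohort), "exactly one")
})

test_that("ensemble consensus is the worst flag over runs, order-invariant", {
  sev <- c(green = 1, amber = 2, red = 3)
  combos <- expand.grid(r1 = names(sev), r2 = names(sev), r3 = names(sev),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    fl <- unlist(combos[i, ])
    expect_equal(worstFlag(fl), names(sev)[max(sev[fl])])
    expect_equal(worstFlag(rev(fl)), worstFlag(fl))
  }
  expect_equal(worstFlag(c("green", "amber", "green")), "amber")
})

test_that("ensemble reports per-metric mean, population variance and consensus", {
  mkp <- function(psh) {
    comp <- abtap:::emptyComponents()
    one <- data.frame(chain_i = "H", imgt_i = 105L, insert_i = "",
                      aa_i = "L", seq_index_i = 20L, chain_j = "H",
                      imgt_j = 106L, insert_j = "", aa_j = "L",
                      seq_index_j = 21L, distance = 4,
                      contribution = psh, adjacent = TRUE,
                      stringsAsFactors = FALSE)
    methods::new("TapProfile", id = "ab1", lTot = 44L, psh = psh, ppc = 0,
                 pnc = 0, sfvcsp = -1,
                 components = list(psh = one, ppc = comp, pnc = comp))
  }
  ts <- fitThresholds(list(l_tot = as.numeric(40:50), psh = seq(90, 130, 2),
                           ppc = seq(0, 2, 0.1), pnc = seq(0, 2, 0.1),
                           sfvcsp = seq(-20, 0, 1)))
  runs <- list(mkp(1), mkp(2), mkp(3))
  rep3 <- ensembleProfile(runs, ts)
  expect_equal(unname(rep3$mean["psh"]), 2)
  expect_equal(unname(rep3$variance["psh"]), 2 / 3)  # divisor n
  expect_equal(rep3$overall, "red")                  # psh 1 << reference min

  same <- ensembleProfile(list(mkp(110), mkp(110)), ts)
  expect_equal(unname(same$variance["psh"]), 0)
  expect_equal(unname(same$consensus["psh"]),
               assignFlags(c(psh = 110), ts)$flag)

  expect_error(ensembleProfile(list(mkp(1)), ts), "length")
  bad <- mkp(1); bad@id <- "other"
  expect_error(ensembleProfile(list(mkp(1), bad), ts), "mismatched ids")
})
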