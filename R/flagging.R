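## Percentile threshold fitting, flag assignment, model-confidence
## filtering, and repeat-run ensemble consensus.
##
## Flag scheme: amber in the extreme 5 percent tail(s) of the
## reference distribution (0th-5th and/or 95th-100th percentile,
## inclusive), red strictly beyond the observed reference minimum or
## maximum on a flagged side. L_tot and PSH are two-sided, PPC and
## PNC upper-tail only, SFvCSP lower-tail only.

#' Fit percentile flagging thresholds from a reference cohort
#'
#' Computes, per metric, the 0th (minimum), 5th, 95th and 100th
#' (maximum) percentiles of the reference scores by sorted linear
#' interpolation, and records each metric's sidedness. Boundaries on
#' unflagged sides are NA.
#'
#' @param reference_scores Named list of numeric vectors, one per
#'   metric (\code{l_tot}, \code{psh}, \code{ppc}, \code{pnc},
#'   \code{sfvcsp}); a subset of metrics is allowed.
#' @return A \code{\linkS4class{ThresholdSet}}.
#' @examples
#' ts <- fitThresholds(list(l_tot = 0:100))
#' thresholdTable(ts)
#' @export
fitThresholds <- function(reference_scores) {
  metrics <- intersect(.TAP_METRICS, names(reference_scores))
  if (!length(metrics)) stop("no recognised metrics in reference_scores")
  rows <- lapply(metrics, function(m) {
    x <- reference_scores[[m]]
    if (!length(x)) stop("empty reference list for ", m)
    side <- .METRIC_SIDEDNESS[[m]]
    q <- stats::quantile(x, c(0, 0.05, 0.95, 1), type = 7, names = FALSE)
    data.frame(
      metric = m, sidedness = side,
      lower_red   = if (side %in% c("two_sided", "lower")) q[1] else NA_real_,
      lower_amber = if (side %in% c("two_sided", "lower")) q[2] else NA_real_,
      upper_amber = if (side %in% c("two_sided", "upper")) q[3] else NA_real_,
      upper_red   = if (side %in% c("two_sided", "upper")) q[4] else NA_real_,
      stringsAsFactors = FALSE)
  })
  methods::new("ThresholdSet", table = do.call(rbind, rows),
               referenceN = stats::setNames(
                 vapply(metrics, function(m) length(reference_scores[[m]]), 0L),
                 metrics))
}

## Flag one score against one threshold row.
flagOne <- function(score, row) {
  lower <- row$sidedness %in% c("two_sided", "lower")
  upper <- row$sidedness %in% c("two_sided", "upper")
  if (lower && score < row$lower_red) return("red")
  if (upper && score > row$upper_red) return("red")
  if (lower && score <= row$lower_amber) return("amber")
  if (upper && score >= row$upper_amber) return("amber")
  "green"
}

#' Worst of a set of flags
#'
#' Severity ordering green < amber < red.
#'
#' @param flags Character vector of flags.
#' @return Single flag, the most severe.
#' @export
worstFlag <- function(flags) {
  .FLAG_LEVELS[max(match(flags, .FLAG_LEVELS))]
}

#' Assign developability flags to a profile
#'
#' Scores strictly inside the 5th-95th percentile band (on flagged
#' sides) are green; scores at or beyond the 5th/95th percentile but
#' within the observed reference range are amber (boundary values
#' inclusive); scores strictly beyond the reference minimum/maximum
#' on a flagged side are red.
#'
#' @param profile A \code{\linkS4class{TapProfile}}, or a named
#'   numeric vector of metric scores.
#' @param thresholds A \code{\linkS4class{ThresholdSet}}.
#' @return Data.frame (metric, score, flag) with attribute
#'   \code{overall} = worst flag.
#' @export
assignFlags <- function(profile, thresholds) {
  scores <- if (methods::is(profile, "TapProfile")) tapMetrics(profile)
            else profile
  tb <- thresholdTable(thresholds)
  tb <- tb[tb$metric %in% names(scores), , drop = FALSE]
  flag <- vapply(seq_len(nrow(tb)), function(i)
    flagOne(unname(scores[tb$metric[i]]), tb[i, ]), "")
  out <- data.frame(metric = tb$metric,
                    score = unname(scores[tb$metric]),
                    flag = flag, stringsAsFactors = FALSE)
  attr(out, "overall") <- worstFlag(flag)
  out
}

#' Root-mean-squared CDRH3 predicted error
#'
#' sqrt(sum over CDRH3 residues of PE^2 / L_CDRH3), the model
#' confidence statistic used to filter out the least reliably
#' modelled structures.
#'
#' @param structure An \code{\linkS4class{FvStructure}} whose CDRH3
#'   residues carry predicted error.
#' @return RMS predicted error, Angstrom.
#' @export
cdrh3RmsPredictedError <- function(structure) {
  regions <- assignRegions(structure)
  h3 <- regions[regions$chain == "H" & regions$region == "CDR3", ,
                drop = FALSE]
  if (!nrow(h3)) stop("empty CDRH3 in ", fvId(structure))
  if (anyNA(h3$pe)) stop("missing predicted error in CDRH3 of ",
                         fvId(structure))
  sqrt(sum(h3$pe^2) / nrow(h3))
}

#' Filter a cohort by model confidence
#'
#' Retains structures whose CDRH3 RMS predicted error is at most a
#' threshold. The threshold is either given directly or derived as a
#' percentile of the cohort's RMS values, optionally after excluding
#' listed ids from the derivation (e.g. entries for which solved
#' structures exist); the filter itself is then applied to the whole
#' cohort. The comparison is inclusive.
#'
#' @param cohort List of \code{\linkS4class{FvStructure}}.
#' @param threshold RMS predicted error cutoff, Angstrom.
#' @param percentile Alternative to \code{threshold}: probability in
#'   (0, 1); the cutoff is this percentile (sorted linear
#'   interpolation) of the cohort's RMS values.
#' @param exclude_ids Ids excluded from the percentile derivation.
#' @return List: \code{retained} (ids), \code{threshold} (Angstrom),
#'   \code{rms} (named numeric over the full cohort).
#' @export
confidenceFilter <- function(cohort, threshold = NULL, percentile = NULL,
                             exclude_ids = character(0)) {
  if (is.null(threshold) == is.null(percentile))
    stop("give exactly one of threshold or percentile")
  ids <- vapply(cohort, fvId, "")
  rms <- stats::setNames(vapply(cohort, cdrh3RmsPredictedError, 0), ids)
  if (is.null(threshold)) {
    stopifnot(percentile > 0, percentile < 1)
    pool <- rms[!ids %in% exclude_ids]
    if (!length(pool)) stop("no structures left to derive the percentile")
    threshold <- stats::quantile(pool, percentile, type = 7, names = FALSE)
  }
  list(retained = ids[rms <= threshold], threshold = threshold, rms = rms)
}

#' Aggregate repeat-run profiles into an ensemble report
#'
#' For repeat calculations on the same antibody (e.g. repeated
#' stochastic side-chain modelling), reports per-metric values, mean
#' and population variance (divisor n) across runs, per-run flags,
#' and the consensus flag: the worst flag raised on any run, the
#' "flagged on any repeat" convention.
#'
#' @param profiles List (>= 2) of \code{\linkS4class{TapProfile}} of
#'   the same antibody.
#' @param thresholds A \code{\linkS4class{ThresholdSet}}.
#' @return List of class \code{"EnsembleReport"}: \code{id},
#'   \code{values} (metric x run matrix), \code{mean},
#'   \code{variance}, \code{flags} (metric x run), \code{consensus}
#'   (named character per metric), \code{overall}.
#' @export
ensembleProfile <- function(profiles, thresholds) {
  stopifnot(length(profiles) >= 2)
  ids <- vapply(profiles, fvId, "")
  if (length(unique(ids)) != 1L)
    stop("mismatched ids across runs: ", paste(unique(ids), collapse = ", "))
  vals <- vapply(profiles, tapMetrics, numeric(5))  # metric x run
  flags <- vapply(profiles, function(p) {
    fr <- assignFlags(p, thresholds)
    stats::setNames(fr$flag, fr$metric)[rownames(vals)]
  }, character(5))
  consensus <- apply(flags, 1, worstFlag)
  out <- list(id = ids[1], values = vals,
              mean = rowMeans(vals),
              variance = apply(vals, 1, function(v) mean((v - mean(v))^2)),
              flags = flags, consensus = consensus,
              overall = worstFlag(consensus))
  class(out) <- "EnsembleReport"
  out
}
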