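## Cohort-level comparisons: flag rates by group, CDR-length
## statistics, gene-usage enrichment among green/red populations,
## and inter-run agreement.

#' Read an antibody metadata table
#'
#' CSV with header \code{id,light_locus,v_gene,group} (extra columns
#' are kept).
#'
#' @param path CSV file.
#' @return Data.frame with at least those columns.
#' @export
readFvMetadata <- function(path) {
  md <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "light_locus", "v_gene", "group")
  missing <- setdiff(need, names(md))
  if (length(missing))
    stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  md
}

#' Gene family from a gene allele label
#'
#' Text before the first hyphen, e.g. \code{IGLV2} from
#' \code{IGLV2-14*01}. Labels are consumed verbatim; no germline
#' calling is performed.
#'
#' @param gene Character vector of gene labels.
#' @return Character vector of family labels.
#' @export
geneFamily <- function(gene) {
  sub("-.*$", "", sub("\\*.*$", "", gene))
}

#' Build a cohort table
#'
#' Joins per-antibody profiles and flag reports to metadata, one row
#' per antibody, against a single declared threshold set.
#'
#' @param profiles List of \code{\linkS4class{TapProfile}}.
#' @param thresholds A \code{\linkS4class{ThresholdSet}}; flags are
#'   (re)computed against it.
#' @param metadata Data.frame as \code{\link{readFvMetadata}};
#'   every profile id must be present.
#' @param lengths Optional data.frame (id, cdrh3_len, cdrl3_len) to
#'   support per-loop length statistics.
#' @return Data.frame of class \code{"CohortTable"}: id, the five
#'   metric scores, per-metric flag columns (\code{flag_psh}, ...),
#'   overall flag, metadata columns, optional loop lengths.
#' @export
buildCohortTable <- function(profiles, thresholds, metadata,
                             lengths = NULL) {
  ids <- vapply(profiles, fvId, "")
  if (anyDuplicated(ids)) stop("duplicate profile ids")
  missing <- setdiff(ids, metadata$id)
  if (length(missing))
    stop("metadata missing id(s): ", paste(missing, collapse = ", "))
  rows <- lapply(profiles, function(p) {
    m <- tapMetrics(p)
    fr <- assignFlags(p, thresholds)
    flags <- stats::setNames(fr$flag, paste0("flag_", fr$metric))
    cbind(data.frame(id = fvId(p), as.list(m), stringsAsFactors = FALSE),
          as.list(flags),
          data.frame(flag_overall = attr(fr, "overall"),
                     stringsAsFactors = FALSE))
  })
  tab <- do.call(rbind, rows)
  tab <- merge(tab, metadata, by = "id", sort = FALSE)
  if (!is.null(lengths)) tab <- merge(tab, lengths, by = "id", sort = FALSE)
  class(tab) <- c("CohortTable", class(tab))
  tab
}

#' Flag rates by group
#'
#' Percentage of each group's members carrying an amber (and red)
#' flag for one metric. \code{mode = "amber_only"} counts exactly
#' amber; \code{"amber_or_worse"} counts amber and red together (both
#' conventions are reported in the literature's figures).
#'
#' @param table A \code{CohortTable}.
#' @param metric One of the five metric names.
#' @param group_key Column of \code{table} defining the groups.
#' @param mode Amber counting convention.
#' @return Data.frame: group, n, amber_pct, red_pct (2 decimals).
#' @export
flagRateByGroup <- function(table, metric, group_key,
                            mode = c("amber_only", "amber_or_worse")) {
  mode <- match.arg(mode)
  if (!group_key %in% names(table)) stop("unknown group_key: ", group_key)
  fcol <- paste0("flag_", metric)
  if (!fcol %in% names(table)) stop("unknown metric: ", metric)
  groups <- split(table[[fcol]], table[[group_key]])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    f <- groups[[g]]
    amber <- if (mode == "amber_only") sum(f == "amber")
             else sum(f %in% c("amber", "red"))
    data.frame(group = g, n = length(f),
               amber_pct = round(100 * amber / length(f), 2),
               red_pct = round(100 * sum(f == "red") / length(f), 2),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' CDR-length statistics by group
#'
#' Mean and standard deviation of a loop length (or total CDR
#' length) per group.
#'
#' @param table A \code{CohortTable} carrying the requested length
#'   column (\code{l_tot}, or \code{cdrh3_len} / \code{cdrl3_len}
#'   supplied via \code{lengths} in \code{\link{buildCohortTable}}).
#' @param region \code{"CDRH3"}, \code{"CDRL3"} or \code{"L_tot"}.
#' @param group_key Grouping column.
#' @param sd_divisor \code{"n-1"} (sample, default) or \code{"n"}.
#' @return Data.frame: group, n, mean, sd.
#' @export
lengthStats <- function(table, region = c("CDRH3", "CDRL3", "L_tot"),
                        group_key, sd_divisor = c("n-1", "n")) {
  region <- match.arg(region)
  sd_divisor <- match.arg(sd_divisor)
  col <- switch(region, CDRH3 = "cdrh3_len", CDRL3 = "cdrl3_len",
                L_tot = "l_tot")
  if (!col %in% names(table)) stop("cohort table lacks column ", col)
  groups <- split(as.numeric(table[[col]]), table[[group_key]])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    n <- length(x)
    v <- if (n > 1) sum((x - mean(x))^2) / (if (sd_divisor == "n-1") n - 1 else n)
         else 0
    data.frame(group = g, n = n, mean = mean(x), sd = sqrt(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Gene usage enrichment between green- and red-flagged antibodies
#'
#' For one metric, splits the cohort into the green- and red-flagged
#' populations and reports, for each gene (or family), the fraction
#' of each population using it and the red:green ratio. A gene absent
#' from the green population has an infinite ratio, encoded as
#' \code{Inf}; a gene absent from both has ratio \code{NA}.
#'
#' @param table A \code{CohortTable}.
#' @param metric Metric whose flags define the populations.
#' @param gene_key Column holding the gene label.
#' @param by_family Collapse labels with \code{\link{geneFamily}}.
#' @return Data.frame: gene, green_fraction, red_fraction, ratio.
#' @export
geneUsageEnrichment <- function(table, metric, gene_key = "v_gene",
                                by_family = FALSE) {
  fcol <- paste0("flag_", metric)
  genes <- table[[gene_key]]
  if (by_family) genes <- geneFamily(genes)
  green <- genes[table[[fcol]] == "green"]
  red <- genes[table[[fcol]] == "red"]
  all_genes <- sort(unique(genes))
  gf <- if (length(green)) as.numeric(table(factor(green, all_genes))) / length(green)
        else numeric(length(all_genes))
  rf <- if (length(red)) as.numeric(table(factor(red, all_genes))) / length(red)
        else numeric(length(all_genes))
  ratio <- ifelse(gf == 0 & rf == 0, NA_real_,
                  ifelse(gf == 0, Inf, rf / gf))
  data.frame(gene = all_genes, green_fraction = gf, red_fraction = rf,
             ratio = ratio, stringsAsFactors = FALSE)
}

#' Inter-run agreement statistics
#'
#' Consistency of a metric across repeat runs of the same cohort:
#' Pearson correlation for every run pair, the mean across
#' antibodies of the per-antibody (population) variance, and the
#' percentage of antibodies whose flag from a designated single run
#' differs from the ensemble consensus (worst flag over runs).
#'
#' @param runs List (>= 2) of named numeric score vectors, aligned
#'   by id (same names, same order after matching).
#' @param thresholds A \code{\linkS4class{ThresholdSet}} covering
#'   \code{metric}.
#' @param metric The metric the scores belong to.
#' @param single_run Index of the run compared against the consensus.
#' @return List: \code{pearson} (data.frame run_i, run_j, r),
#'   \code{mean_variance}, \code{flag_inconsistency_pct}.
#' @export
interrunAgreement <- function(runs, thresholds, metric = "psh",
                              single_run = 1L) {
  stopifnot(length(runs) >= 2)
  ids <- names(runs[[1]])
  if (is.null(ids)) stop("run vectors must be named by antibody id")
  for (r in runs[-1]) {
    if (length(r) != length(ids)) stop("length mismatch across runs")
    if (!setequal(names(r), ids)) stop("id mismatch across runs")
  }
  mat <- vapply(runs, function(r) r[ids], numeric(length(ids)))
  pairs <- utils::combn(length(runs), 2)
  pearson <- data.frame(run_i = pairs[1, ], run_j = pairs[2, ],
                        r = apply(pairs, 2, function(p)
                          stats::cor(mat[, p[1]], mat[, p[2]])))
  mean_variance <- mean(apply(mat, 1, function(v) mean((v - mean(v))^2)))
  tb <- thresholdTable(thresholds)
  row <- tb[tb$metric == metric, , drop = FALSE]
  if (!nrow(row)) stop("thresholds lack metric ", metric)
  flags <- apply(mat, c(1, 2), function(s) flagOne(s, row))
  consensus <- apply(flags, 1, worstFlag)
  inconsistent <- flags[, single_run] != consensus
  list(pearson = pearson, mean_variance = mean_variance,
       flag_inconsistency_pct = 100 * mean(inconsistent))
}
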