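#' Quality-control thresholds for snATAC nuclei
#'
#' Defaults are the standard stringent single-nucleus ATAC filters: between
#' 3,000 and 100,000 fragments in peak regions, more than 15% of reads in
#' peaks, blacklist ratio below 0.025, nucleosome signal below 10 and TSS
#' enrichment above 2. All comparisons are strict inequalities, so a
#' nucleus sitting exactly on a threshold is filtered out.
#'
#' @param min_peak_fragments,max_peak_fragments Bounds on
#'   `peak_region_fragments`.
#' @param min_pct_in_peaks Lower bound on `pct_reads_in_peaks` (percent).
#' @param max_blacklist_ratio Upper bound on `blacklist_ratio` (fraction).
#' @param max_nucleosome_signal Upper bound on `nucleosome_signal`.
#' @param min_tss_enrichment Lower bound on `tss_enrichment`.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_peak_fragments = 3000,
                          max_peak_fragments = 100000,
                          min_pct_in_peaks = 15,
                          max_blacklist_ratio = 0.025,
                          max_nucleosome_signal = 10,
                          min_tss_enrichment = 2) {
  if (min_peak_fragments >= max_peak_fragments)
    stop("min_peak_fragments must be < max_peak_fragments")
  structure(list(min_peak_fragments = min_peak_fragments,
                 max_peak_fragments = max_peak_fragments,
                 min_pct_in_peaks = min_pct_in_peaks,
                 max_blacklist_ratio = max_blacklist_ratio,
                 max_nucleosome_signal = max_nucleosome_signal,
                 min_tss_enrichment = min_tss_enrichment),
            class = "qc_thresholds")
}

#' @noRd
qc_metric_cols <- c("peak_region_fragments", "pct_reads_in_peaks",
                    "blacklist_ratio", "nucleosome_signal",
                    "tss_enrichment")

#' Filter nuclei on QC metrics
#'
#' A nucleus is kept iff all six strict inequalities hold. The failure
#' tally counts each violated rule independently, so one nucleus can
#' contribute to several rules; records with a missing metric are
#' rejected with reason `missing-metric`.
#'
#' @param records `data.frame` with columns `peak_region_fragments`,
#'   `pct_reads_in_peaks`, `blacklist_ratio`, `nucleosome_signal`,
#'   `tss_enrichment` (and typically `barcode`).
#' @param thresholds A [qc_thresholds()].
#' @return List: `kept` (passing rows), `failed` (failing rows with a
#'   `reason` column), `tally` (named integer vector of per-rule failure
#'   counts), `pass` (logical vector over the input order).
#' @export
qc_filter <- function(records, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  missing_cols <- setdiff(qc_metric_cols, names(records))
  if (length(missing_cols))
    stop("records lack QC metric column(s): ",
         paste(missing_cols, collapse = ", "))
  th <- thresholds
  rules <- list(
    min_peak_fragments = records$peak_region_fragments > th$min_peak_fragments,
    max_peak_fragments = records$peak_region_fragments < th$max_peak_fragments,
    min_pct_in_peaks = records$pct_reads_in_peaks > th$min_pct_in_peaks,
    max_blacklist_ratio = records$blacklist_ratio < th$max_blacklist_ratio,
    max_nucleosome_signal =
      records$nucleosome_signal < th$max_nucleosome_signal,
    min_tss_enrichment = records$tss_enrichment > th$min_tss_enrichment)
  has_na <- Reduce(`|`, lapply(records[qc_metric_cols], is.na))
  viol <- vapply(rules, function(ok) !is.na(ok) & !ok,
                 logical(nrow(records)))
  viol <- matrix(viol, nrow = nrow(records),
                 dimnames = list(NULL, names(rules)))
  tally <- c(colSums(viol), `missing-metric` = sum(has_na))
  pass <- !has_na & rowSums(viol) == 0L
  failed <- records[!pass, , drop = FALSE]
  if (nrow(failed)) {
    reason <- apply(viol[!pass, , drop = FALSE], 1L, function(v)
      paste(names(rules)[v], collapse = ";"))
    reason[has_na[!pass]] <- "missing-metric"
    failed$reason <- reason
  }
  list(kept = records[pass, , drop = FALSE], failed = failed,
       tally = tally, pass = pass)
}

#' Per-gene promoter accessibility scores
#'
#' Converts a nucleus-by-gene matrix of fragment counts in promoter (or
#' promoter + gene body) windows into per-nucleus proportions:
#' `score_g = count_g / sum(counts)`. Scores of a nucleus sum to 1
#' whenever it has any window fragment, and are all 0 otherwise (such a
#' nucleus is later labelled `unassigned`). Scores are invariant to
#' uniform rescaling of a nucleus's counts.
#'
#' @param counts Numeric matrix or data.frame, rows nuclei, columns genes.
#' @return Matrix of scores with the same dimnames.
#' @export
score_promoters <- function(counts) {
  m <- as.matrix(counts)
  if (!is.numeric(m)) stop("counts must be numeric")
  if (any(m < 0, na.rm = TRUE)) stop("counts must be >= 0")
  tot <- rowSums(m)
  sc <- m / ifelse(tot > 0, tot, 1)
  sc[tot == 0, ] <- 0
  sc
}

#' Fiber-type call from promoter accessibility scores
#'
#' A nucleus is assigned to the gene with the highest score when that
#' score dominates the runner-up by at least `margin`-fold; a nucleus
#' with accessible promoters but no dominant one is `hybrid`; a nucleus
#' with no window signal is `unassigned`.
#'
#' @param scores Matrix from [score_promoters()] (or one numeric vector).
#' @param margin Dominance ratio, `>= 1`. Default 2: the top promoter must
#'   carry at least twice the accessibility of the second.
#' @return Character vector of labels (gene name, `"hybrid"` or
#'   `"unassigned"`).
#' @export
classify_fiber_type <- function(scores, margin = 2.0) {
  if (is.vector(scores)) scores <- matrix(scores, nrow = 1,
                                          dimnames = list(NULL, names(scores)))
  if (!is.numeric(margin) || margin < 1) stop("margin must be >= 1")
  genes <- colnames(scores)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(scores)))
  apply(scores, 1L, function(s) {
    if (all(s == 0)) return("unassigned")
    top <- which.max(s)
    second <- if (length(s) > 1L) max(s[-top]) else 0
    if (s[top] >= margin * second) genes[top] else "hybrid"
  })
}

#' QC-filter and classify a set of nuclei
#'
#' @param metrics `data.frame` of per-nucleus QC metrics (see
#'   [qc_filter()]), one row per row of `counts`.
#' @param counts Nucleus-by-gene promoter count matrix.
#' @param thresholds A [qc_thresholds()].
#' @param margin Dominance margin for [classify_fiber_type()].
#' @return `data.frame`: barcode (if present), qc_pass, label
#'   (`"filtered"` for QC failures) and the per-gene scores.
#' @export
classify_nuclei <- function(metrics, counts, thresholds = qc_thresholds(),
                            margin = 2.0) {
  if (nrow(metrics) != nrow(counts))
    stop("metrics and counts must have one row per nucleus")
  qc <- qc_filter(metrics, thresholds)
  scores <- score_promoters(counts)
  label <- rep("filtered", nrow(metrics))
  if (any(qc$pass))
    label[qc$pass] <- classify_fiber_type(scores[qc$pass, , drop = FALSE],
                                          margin = margin)
  out <- data.frame(qc_pass = qc$pass, label = label)
  if (!is.null(metrics$barcode)) out <- cbind(barcode = metrics$barcode, out)
  cbind(out, as.data.frame(scores))
}
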