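# Sample QC, RPM normalisation, pseudo-count log2 transform, and
# replicate-outlier flagging.

#' QC thresholds for sample filtering
#'
#' A sample fails QC if any metric is strictly below its threshold; a metric
#' exactly at the threshold passes. Defaults are the standard targeted
#' RNA-seq inclusion criteria: sequencing depth and aligned reads >= 300K,
#' total alignment rate >= 40%, unique alignment rate >= 30%, and >= 50% of
#' probes with at least five reads.
#'
#' @param min_depth,min_total_align,min_unique_align,min_aligned_reads,min_pct_probes_ge5
#'   non-negative thresholds.
#' @return Named numeric vector of thresholds.
#' @export
qcThresholds <- function(min_depth = 3e5, min_total_align = 40,
                         min_unique_align = 30, min_aligned_reads = 3e5,
                         min_pct_probes_ge5 = 50) {
  th <- c(min_depth = min_depth, min_total_align = min_total_align,
          min_unique_align = min_unique_align,
          min_aligned_reads = min_aligned_reads,
          min_pct_probes_ge5 = min_pct_probes_ge5)
  if (any(th < 0)) stopf("QC thresholds must be non-negative")
  th
}

# metric column -> threshold name
.qcRuleMap <- c(sequencing_depth = "min_depth",
                total_alignment_rate = "min_total_align",
                unique_alignment_rate = "min_unique_align",
                aligned_reads = "min_aligned_reads",
                pct_probes_ge5 = "min_pct_probes_ge5")

#' Filter samples on sequencing QC metrics
#'
#' @param metrics data.frame with a `sample_id` column and the five metric
#'   columns `sequencing_depth`, `total_alignment_rate`,
#'   `unique_alignment_rate`, `aligned_reads`, `pct_probes_ge5`.
#' @param thresholds as from [qcThresholds()].
#' @return data.frame with `sample_id`, logical `pass`, and `failed_rules`
#'   (comma-separated names of the violated thresholds, `""` if none).
#' @details Failure is strictly-below: a metric equal to its threshold
#'   passes. Missing metric values are an error naming the sample and
#'   metric.
#' @examples
#' qc <- data.frame(sample_id = "s1", sequencing_depth = 299999,
#'                  total_alignment_rate = 80, unique_alignment_rate = 70,
#'                  aligned_reads = 5e5, pct_probes_ge5 = 90)
#' qcFilter(qc)
#' @export
qcFilter <- function(metrics, thresholds = qcThresholds()) {
  miss <- setdiff(names(.qcRuleMap), names(metrics))
  if (length(miss))
    stopf("QC metrics table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!"sample_id" %in% names(metrics))
    stopf("QC metrics table lacks a sample_id column")
  for (m in names(.qcRuleMap)) {
    bad <- which(is.na(metrics[[m]]))
    if (length(bad))
      stopf("sample '%s' has missing QC metric '%s'",
            metrics$sample_id[bad[1]], m)
  }
  fails <- vapply(seq_len(nrow(metrics)), function(i) {
    f <- names(.qcRuleMap)[vapply(names(.qcRuleMap), function(m)
      metrics[[m]][i] < thresholds[[.qcRuleMap[[m]]]], logical(1))]
    paste(.qcRuleMap[f], collapse = ",")
  }, character(1))
  data.frame(sample_id = metrics$sample_id, pass = fails == "",
             failed_rules = fails, stringsAsFactors = FALSE)
}

#' Reads-per-million normalisation
#'
#' Scales each sample (column) so counts sum to one million.
#'
#' @param counts an [ExprMatrix-class] on the `"counts"` scale.
#' @return An [ExprMatrix-class] on the `"rpm"` scale; every column sums to
#'   1e6 (relative tolerance 1e-9).
#' @export
normalizeRPM <- function(counts) {
  stopifnot(is(counts, "ExprMatrix"))
  if (exprScale(counts) != "counts")
    stopf("normalizeRPM expects a counts-scale matrix, got '%s'",
          exprScale(counts))
  v <- exprValues(counts)
  cs <- colSums(v)
  if (any(cs == 0))
    stopf("zero library size for sample(s): %s",
          paste(colnames(v)[cs == 0], collapse = ", "))
  ExprMatrix(sweep(v, 2L, cs, "/") * 1e6, "rpm")
}

#' Pseudo-count log2 transform
#'
#' Adds a pseudo-count of one to each normalised value and takes log2.
#'
#' @param rpm an [ExprMatrix-class] on the `"rpm"` scale.
#' @return An [ExprMatrix-class] on the `"log2"` scale.
#' @export
logTransform <- function(rpm) {
  stopifnot(is(rpm, "ExprMatrix"))
  if (exprScale(rpm) != "rpm")
    stopf("logTransform expects an rpm-scale matrix, got '%s'", exprScale(rpm))
  v <- exprValues(rpm)
  if (any(v < 0)) stopf("negative values cannot be log-transformed")
  ExprMatrix(log2(v + 1), "log2")
}

#' Flag replicate outliers by inter-replicate correlation
#'
#' Within each replicate group (chemical x dose x sex) of size >= 3, a
#' sample is flagged when the median of its pairwise Spearman correlations
#' with the other group members falls below `minMedianCorr`. Groups of size
#' <= 2 are never flagged (no quorum to decide which member is aberrant).
#'
#' @param logMatrix an [ExprMatrix-class] on the `"log2"` scale, or a plain
#'   log2 matrix.
#' @param metadata data.frame with `sample_id`, `chemical`, `dose_mg_per_kg`,
#'   `sex` covering the matrix columns.
#' @param minMedianCorr flagging threshold (default 0.8).
#' @return data.frame with `sample_id`, `group`, `median_corr`, and logical
#'   `outlier`.
#' @export
flagOutliers <- function(logMatrix, metadata, minMedianCorr = 0.8) {
  v <- if (is(logMatrix, "ExprMatrix")) exprValues(logMatrix) else logMatrix
  stopifnot(all(colnames(v) %in% metadata$sample_id))
  md <- metadata[match(colnames(v), metadata$sample_id), ]
  grp <- paste(md$chemical, md$dose_mg_per_kg, md$sex, sep = "|")
  out <- data.frame(sample_id = colnames(v), group = grp,
                    median_corr = NA_real_, outlier = FALSE,
                    stringsAsFactors = FALSE)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 3L) next
    cm <- stats::cor(v[, idx, drop = FALSE], method = "spearman")
    med <- vapply(seq_along(idx), function(i)
      stats::median(cm[i, -i]), numeric(1))
    out$median_corr[idx] <- med
    out$outlier[idx] <- med < minMedianCorr
  }
  out
}

#' Run the full preprocessing chain on a study bundle
#'
#' Applies [qcFilter()] (dropping failing samples), RPM normalisation and
#' the pseudo-count log2 transform (skipped when the bundle already carries
#' a `"log2"` assay, as log-normal simulations do), then [flagOutliers()]
#' (dropping flagged samples by default).
#'
#' @param study a [ToxStudy-class].
#' @param thresholds QC thresholds, see [qcThresholds()].
#' @param minMedianCorr outlier threshold, see [flagOutliers()].
#' @param dropOutliers drop flagged replicate outliers (default TRUE).
#' @return A [ToxStudy-class] restricted to retained samples, with a
#'   `"log2"` assay, and `metadata(x)$preprocess` recording what was
#'   dropped.
#' @export
preprocessStudy <- function(study, thresholds = qcThresholds(),
                            minMedianCorr = 0.8, dropOutliers = TRUE) {
  stopifnot(is(study, "ToxStudy"))
  qcres <- qcFilter(qcMetrics(study), thresholds)
  keep <- qcres$sample_id[qcres$pass]
  study2 <- study[, keep]
  if ("log2" %in% assayNames(study2)) {
    logm <- assay(study2, "log2")
  } else {
    cm <- ExprMatrix(assay(study2, "counts"), "counts")
    logm <- exprValues(logTransform(normalizeRPM(cm)))
    SummarizedExperiment::assay(study2, "log2") <- logm
  }
  fo <- flagOutliers(logm, sampleInfo(study2), minMedianCorr)
  if (dropOutliers && any(fo$outlier))
    study2 <- study2[, fo$sample_id[!fo$outlier]]
  md <- metadata(study2)
  md$preprocess <- list(qc = qcres, outliers = fo,
                        dropped_qc = qcres$sample_id[!qcres$pass],
                        dropped_outliers = fo$sample_id[fo$outlier &
                                                          dropOutliers])
  se <- as(study2, "SummarizedExperiment")
  S4Vectors::metadata(se) <- md
  new("ToxStudy", se)
}
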