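# Response-pattern classification (consistent / sex-dependent /
# class-dependent), dose-trend detection, and weighted-signature
# concordance.

#' Detect a dose-based trend in a gene's fold changes
#'
#' Operationalises the qualitative "FC moves in one direction as dose
#' increases" rule over the top `window` doses: all fold changes share one
#' sign (an exact 0 counts as neither sign and breaks the run), |fc| is
#' non-decreasing with dose up to a small `tolerance` (noise allowance on
#' replicate-mean fold changes), and the top-dose |fc| reaches `threshold`.
#' Fewer than 3 doses give `"none"`.
#'
#' @param fc numeric log2 fold changes in ascending dose order.
#' @param threshold top-dose |fc| requirement (default 0.6).
#' @param window number of highest doses examined (default 3).
#' @param tolerance maximum allowed dip in |fc| between successive doses
#'   (default 0.3 log2 units; 0 demands strict monotonicity).
#' @return `"up"`, `"down"`, or `"none"`.
#' @examples
#' detectDoseTrend(c(0.1, 0.4, 0.9))   # "up"
#' detectDoseTrend(c(0.9, 0.4, 0.1))   # "none"
#' @export
detectDoseTrend <- function(fc, threshold = 0.6, window = 3L,
                            tolerance = 0.3) {
  if (length(fc) < 3L) return("none")
  x <- utils::tail(fc, window)
  if (all(x > 0)) dir <- "up"
  else if (all(x < 0)) dir <- "down"
  else return("none")
  a <- abs(x)
  if (any(diff(a) < -tolerance)) return("none")
  if (a[length(a)] < threshold) return("none")
  dir
}

#' Classify one gene's response pattern across chemicals and sexes
#'
#' Takes the top-dose fold change of one gene in every (chemical, sex) cell
#' and assigns a single pattern, in precedence order:
#' \enumerate{
#'   \item `consistent_up` / `consistent_down`: all cells share one sign and
#'     at least `minSupport` of them pass `threshold`;
#'   \item `sex_dependent`: within each sex all cells share a sign, the two
#'     sexes disagree, and at least `minSupport` of cells pass;
#'   \item `class_dependent`: within each chemical class all cells (both
#'     sexes) share a sign, the classes disagree, and at least `minSupport`
#'     of cells pass;
#'   \item `none`.
#' }
#' A fold change of exactly 0 carries no sign and breaks any consistency
#' requirement.
#'
#' @param cells data.frame with columns `chemical`, `class`, `sex`, `fc`
#'   (one row per chemical x sex, top dose).
#' @param threshold |fc| pass threshold (default 0.6).
#' @param minSupport minimum fraction of cells passing the threshold
#'   (default 1.0; 0.75 is the relaxed mode).
#' @return list with `pattern` and logical `support` (per-cell pass flags,
#'   named chemical|sex).
#' @export
classifyGeneResponse <- function(cells, threshold = 0.6, minSupport = 1.0) {
  need <- c("chemical", "class", "sex", "fc")
  stopifnot(all(need %in% names(cells)))
  if (!all(c("male", "female") %in% cells$sex))
    stopf("both sexes must be represented")
  if (!all(c("PFAS", "PAH") %in% cells$class))
    stopf("both chemical classes must be represented")
  s <- sign(cells$fc)
  pass <- abs(cells$fc) >= threshold
  support <- stats::setNames(pass, paste(cells$chemical, cells$sex, sep = "|"))
  enough <- mean(pass) >= minSupport
  oneSign <- function(v) length(unique(v)) == 1L && v[1] != 0
  pattern <- "none"
  if (oneSign(s) && enough) {
    pattern <- if (s[1] > 0) "consistent_up" else "consistent_down"
  } else if (enough) {
    bySex <- vapply(c("male", "female"), function(sx) {
      v <- s[cells$sex == sx]
      if (oneSign(v)) v[1] else NA_real_
    }, numeric(1))
    byClass <- vapply(c("PFAS", "PAH"), function(cl) {
      v <- s[cells$class == cl]
      if (oneSign(v)) v[1] else NA_real_
    }, numeric(1))
    if (!anyNA(bySex) && bySex[1] != bySex[2]) pattern <- "sex_dependent"
    else if (!anyNA(byClass) && byClass[1] != byClass[2])
      pattern <- "class_dependent"
  }
  list(pattern = pattern, support = support)
}

#' Classify every gene's response pattern and dose trends
#'
#' Convenience driver over a fold-change table: for each gene, the top-dose
#' fold change per (chemical, sex) feeds [classifyGeneResponse()], and the
#' full dose ladder per (chemical, sex) feeds [detectDoseTrend()].
#'
#' @param fcTable data.frame from [buildFCTable()].
#' @param threshold,minSupport see [classifyGeneResponse()].
#' @param trendThreshold,trendWindow,trendTolerance see
#'   [detectDoseTrend()].
#' @return data.frame with `gene`, `pattern`, and one `trend_<chemical>_<sex>`
#'   column per (chemical, sex).
#' @export
classifyResponses <- function(fcTable, threshold = 0.6, minSupport = 1.0,
                              trendThreshold = 0.6, trendWindow = 3L,
                              trendTolerance = 0.3) {
  cs <- unique(fcTable[, c("chemical", "class", "sex")])
  cs <- cs[order(cs$chemical, cs$sex), ]
  genes <- unique(fcTable$gene)
  trendCols <- sprintf("trend_%s_%s", gsub("[^A-Za-z0-9]", "", cs$chemical),
                       cs$sex)
  out <- data.frame(gene = genes, pattern = NA_character_,
                    stringsAsFactors = FALSE)
  # one gene x dose matrix per (chemical, sex) cell, doses ascending
  topFC <- matrix(NA_real_, length(genes), nrow(cs))
  for (i in seq_len(nrow(cs))) {
    sel <- fcTable$chemical == cs$chemical[i] & fcTable$sex == cs$sex[i]
    sub <- fcTable[sel, ]
    doses <- sort(unique(sub$dose_mg_per_kg))
    m <- matrix(NA_real_, length(genes), length(doses))
    for (j in seq_along(doses)) {
      dj <- sub[sub$dose_mg_per_kg == doses[j], ]
      m[, j] <- dj$log2fc[match(genes, dj$gene)]
    }
    topFC[, i] <- m[, length(doses)]
    out[[trendCols[i]]] <- apply(m, 1L, detectDoseTrend,
                                 threshold = trendThreshold,
                                 window = trendWindow,
                                 tolerance = trendTolerance)
  }
  for (gi in seq_along(genes)) {
    cells <- data.frame(chemical = cs$chemical, class = cs$class,
                        sex = cs$sex, fc = topFC[gi, ],
                        stringsAsFactors = FALSE)
    out$pattern[gi] <- classifyGeneResponse(cells, threshold,
                                            minSupport)$pattern
  }
  out
}

#' Concordance of observed fold changes with a weighted gene signature
#'
#' For each signature gene at one condition: the gene is significant iff
#' q < `qThreshold`; a significant gene whose fold-change sign matches the
#' sign of its signature weight is `concordant`, with opposite sign
#' `discordant`; non-significant genes are `not_significant`; signature
#' genes absent from the table are `absent`.
#'
#' @param fcTable data.frame from [buildFCTable()].
#' @param signature data.frame with columns `gene`, `weight` (non-zero,
#'   signed; positive means upregulated with pathology).
#' @param chemical,dose,sex the condition.
#' @param qThreshold significance cut (default 0.1, strict).
#' @return data.frame: `gene`, `weight`, `log2fc`, `q`, `status`.
#' @export
signatureConcordance <- function(fcTable, signature, chemical, dose, sex,
                                 qThreshold = 0.1) {
  stopifnot(all(c("gene", "weight") %in% names(signature)),
            nrow(signature) > 0)
  if (any(signature$weight == 0)) stopf("signature weights must be non-zero")
  sel <- fcTable$chemical == chemical & fcTable$dose_mg_per_kg == dose &
    fcTable$sex == sex
  sub <- fcTable[sel, ]
  idx <- match(signature$gene, sub$gene)
  fc <- sub$log2fc[idx]
  q <- sub$q[idx]
  status <- ifelse(is.na(idx), "absent",
            ifelse(q >= qThreshold, "not_significant",
            ifelse(sign(fc) == sign(signature$weight), "concordant",
                   "discordant")))
  data.frame(gene = signature$gene, weight = signature$weight,
             log2fc = fc, q = q, status = status, stringsAsFactors = FALSE)
}

#' Read a weighted signature TSV
#'
#' @param path TSV with header columns `gene`, `weight`.
#' @return The signature data.frame.
#' @export
readSignatureTSV <- function(path) {
  df <- readTSV(path)
  if (!all(c("gene", "weight") %in% names(df)))
    stopf("signature needs 'gene' and 'weight' columns")
  df
}

#' Write response calls to TSV
#'
#' @param calls data.frame from [classifyResponses()].
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
writeResponseCalls <- function(calls, path) writeTSV(calls, path)
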