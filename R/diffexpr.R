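# Per-condition log2 fold changes, per-dose one-way ANOVA against pooled
# vehicle controls, and Benjamini-Hochberg FDR.

# Select treated/control column indices for one condition; errors name it.
conditionGroups <- function(metadata, chemical, dose, sex) {
  trt <- which(metadata$chemical == chemical & metadata$sex == sex &
                 metadata$dose_mg_per_kg == dose)
  ctl <- which(metadata$chemical == chemical & metadata$sex == sex &
                 metadata$dose_mg_per_kg == 0)
  lab <- sprintf("%s / %g mg/kg / %s", chemical, dose, sex)
  if (length(trt) < 2L)
    stopf("condition %s has %d treated sample(s); need >= 2", lab, length(trt))
  if (length(ctl) < 2L)
    stopf("condition %s has %d control sample(s); need >= 2", lab, length(ctl))
  list(treated = trt, control = ctl)
}

#' Per-gene log2 fold change for one condition
#'
#' FC is the mean log2 expression of the treated group (one chemical, dose,
#' sex) minus the mean of that chemical's vehicle controls of the same sex
#' (pooled across all of the chemical's dose arms).
#'
#' @param logMatrix an [ExprMatrix-class] on the `"log2"` scale, or a plain
#'   log2 matrix.
#' @param metadata sample metadata data.frame (`sample_id`, `chemical`,
#'   `dose_mg_per_kg`, `sex`).
#' @param chemical,dose,sex the condition.
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
computeLog2FC <- function(logMatrix, metadata, chemical, dose, sex) {
  v <- if (is(logMatrix, "ExprMatrix")) exprValues(logMatrix) else logMatrix
  md <- metadata[match(colnames(v), metadata$sample_id), ]
  g <- conditionGroups(md, chemical, dose, sex)
  rowMeans(v[, g$treated, drop = FALSE]) -
    rowMeans(v[, g$control, drop = FALSE])
}

# Vectorised two-group one-way ANOVA over the rows of x1 (treated) and x2
# (control). Returns F and p; zero between- and within-group variance -> p 1.
twoGroupAnova <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  gm <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  df2 <- n1 + n2 - 2L
  f <- (ssb / 1) / (ssw / df2)
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  degen <- ssw == 0 & ssb == 0
  f[degen] <- 0
  p[degen] <- 1
  sep <- ssw == 0 & ssb > 0
  f[sep] <- Inf
  p[sep] <- 0
  data.frame(F = f, p = p)
}

#' Per-dose one-way ANOVA for one condition
#'
#' One-way ANOVA between a treated group and the pooled vehicle controls,
#' per gene. For two groups the F statistic equals the square of the pooled
#' two-sample t statistic. Genes with zero between- and within-group
#' variance get F = 0, p = 1 and are retained.
#'
#' @inheritParams computeLog2FC
#' @return data.frame with per-gene `F` and `p` (rownames = genes).
#' @export
anovaPerDose <- function(logMatrix, metadata, chemical, dose, sex) {
  v <- if (is(logMatrix, "ExprMatrix")) exprValues(logMatrix) else logMatrix
  md <- metadata[match(colnames(v), metadata$sample_id), ]
  g <- conditionGroups(md, chemical, dose, sex)
  res <- twoGroupAnova(v[, g$treated, drop = FALSE],
                       v[, g$control, drop = FALSE])
  rownames(res) <- rownames(v)
  res
}

#' One-way ANOVA across all dose groups of a chemical and sex
#'
#' Optional global mode: a single one-way ANOVA per gene over all dose
#' groups (including vehicle) of one chemical and sex.
#'
#' @inheritParams computeLog2FC
#' @return data.frame with per-gene `F` and `p`.
#' @export
anovaAcrossDoses <- function(logMatrix, metadata, chemical, sex) {
  v <- if (is(logMatrix, "ExprMatrix")) exprValues(logMatrix) else logMatrix
  md <- metadata[match(colnames(v), metadata$sample_id), ]
  sel <- md$chemical == chemical & md$sex == sex
  if (!any(sel)) stopf("no samples for %s / %s", chemical, sex)
  grp <- factor(md$dose_mg_per_kg[sel])
  if (nlevels(grp) < 2L) stopf("need >= 2 dose groups for %s / %s",
                               chemical, sex)
  x <- v[, sel, drop = FALSE]
  k <- nlevels(grp)
  n <- ncol(x)
  gm <- rowMeans(x)
  ssb <- 0
  ssw <- 0
  for (lv in levels(grp)) {
    xi <- x[, grp == lv, drop = FALSE]
    mi <- rowMeans(xi)
    ssb <- ssb + ncol(xi) * (mi - gm)^2
    ssw <- ssw + rowSums((xi - mi)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  degen <- ssw == 0 & ssb == 0
  f[degen] <- 0; p[degen] <- 1
  sep <- ssw == 0 & ssb > 0
  f[sep] <- Inf; p[sep] <- 0
  data.frame(F = f, p = p, row.names = rownames(v))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values; q >= p elementwise and the adjustment is
#' invariant to input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as `p`.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) stopf("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Build the full fold-change table
#'
#' Applies [computeLog2FC()] and [anovaPerDose()] to every (chemical, dose,
#' sex) condition present in the metadata, then adjusts p-values with
#' [bhAdjust()]. The FDR family is per condition across genes by default;
#' `qFamily = "global"` adjusts across the whole table instead.
#'
#' @inheritParams computeLog2FC
#' @param qFamily `"within_condition"` (default) or `"global"`.
#' @return data.frame with one row per (gene, condition): `gene`,
#'   `chemical`, `class`, `dose_mg_per_kg`, `sex`, `log2fc`, `p`, `q`.
#' @export
buildFCTable <- function(logMatrix, metadata,
                         qFamily = c("within_condition", "global")) {
  qFamily <- match.arg(qFamily)
  v <- if (is(logMatrix, "ExprMatrix")) exprValues(logMatrix) else logMatrix
  md <- metadata[match(colnames(v), metadata$sample_id), ]
  conds <- unique(md[md$dose_mg_per_kg > 0,
                     c("chemical", "class", "dose_mg_per_kg", "sex")])
  if (!nrow(conds)) stopf("metadata contains no treated condition")
  conds <- conds[order(conds$chemical, conds$sex, conds$dose_mg_per_kg), ]
  out <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    cc <- conds[i, ]
    fc <- computeLog2FC(v, md, cc$chemical, cc$dose_mg_per_kg, cc$sex)
    an <- anovaPerDose(v, md, cc$chemical, cc$dose_mg_per_kg, cc$sex)
    q <- if (qFamily == "within_condition") bhAdjust(an$p) else NA_real_
    out[[i]] <- data.frame(
      gene = rownames(v), chemical = cc$chemical, class = cc$class,
      dose_mg_per_kg = cc$dose_mg_per_kg, sex = cc$sex,
      log2fc = unname(fc), p = an$p, q = q, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  if (qFamily == "global") tab$q <- bhAdjust(tab$p)
  rownames(tab) <- NULL
  tab
}

#' Write / read a fold-change table TSV
#'
#' @param fcTable data.frame as returned by [buildFCTable()].
#' @param path file path.
#' @return `writeFCTable` invisibly returns `path`; `readFCTable` returns
#'   the table.
#' @export
writeFCTable <- function(fcTable, path) writeTSV(fcTable, path)

#' @rdname writeFCTable
#' @export
readFCTable <- function(path) readTSV(path)
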