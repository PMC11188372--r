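#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData
NULL

# ---------------------------------------------------------------------------
# ExprMatrix: a genes x samples matrix carrying an explicit scale tag, so the
# normalisation chain (counts -> rpm -> log2) is enforced by type.
# ---------------------------------------------------------------------------

#' Expression matrix with a scale tag
#'
#' A thin S4 wrapper around a numeric genes x samples matrix that records
#' whether its values are raw counts, reads-per-million (RPM), or
#' log2(RPM + 1). Stage functions such as [normalizeRPM()] and
#' [logTransform()] refuse inputs on the wrong scale, which catches the
#' classic mistake of log-transforming twice or normalising log values.
#'
#' @slot values numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers).
#' @slot scale one of `"counts"`, `"rpm"`, `"log2"`.
#' @export
setClass("ExprMatrix",
  representation(values = "matrix", scale = "character"))

setValidity("ExprMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (!object@scale %in% c("counts", "rpm", "log2"))
    msgs <- c(msgs, "scale must be one of 'counts', 'rpm', 'log2'")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must have gene rownames and sample colnames")
  if (anyNA(v))
    msgs <- c(msgs, "values must not contain missing cells")
  else {
    if (object@scale %in% c("counts", "rpm") && any(v < 0))
      msgs <- c(msgs, "counts/rpm values must be non-negative")
    if (object@scale == "log2" && any(!is.finite(v)))
      msgs <- c(msgs, "log2 values must be finite")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an [ExprMatrix-class]
#'
#' @param values numeric matrix with gene rownames and sample colnames.
#' @param scale `"counts"`, `"rpm"`, or `"log2"`.
#' @return An [ExprMatrix-class] object.
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExprMatrix(m, "counts")
#' @export
ExprMatrix <- function(values, scale = c("counts", "rpm", "log2")) {
  scale <- match.arg(scale)
  new("ExprMatrix", values = as.matrix(values), scale = scale)
}

#' @describeIn ExprMatrix-class the underlying matrix.
#' @param x an `ExprMatrix`.
#' @export
exprValues <- function(x) {
  stopifnot(is(x, "ExprMatrix"))
  x@values
}

#' @describeIn ExprMatrix-class the scale tag.
#' @export
exprScale <- function(x) {
  stopifnot(is(x, "ExprMatrix"))
  x@scale
}

setMethod("show", "ExprMatrix", function(object) {
  cat(sprintf("ExprMatrix [%s]: %d genes x %d samples\n",
              object@scale, nrow(object@values), ncol(object@values)))
})

#' @describeIn ExprMatrix-class dimensions of the underlying matrix.
#' @export
setMethod("dim", "ExprMatrix", function(x) dim(x@values))

# ---------------------------------------------------------------------------
# StudyDesign
# ---------------------------------------------------------------------------

#' Dose-response study design
#'
#' Describes a multi-chemical, multi-dose, two-sex in vivo transcriptomics
#' design: each chemical has an ascending dose ladder, each (chemical, dose,
#' sex) group has `nTreated` animals, and each (chemical, sex) pair shares a
#' single pool of `nControl` vehicle controls across all doses.
#'
#' @slot chemicals data.frame with columns `name` and `class`
#'   (`"PFAS"` or `"PAH"`).
#' @slot doses named list, one strictly increasing positive dose ladder
#'   (mg/kg) per chemical.
#' @slot sexes character vector, subset of `c("male", "female")`.
#' @slot nTreated animals per treated group (>= 2).
#' @slot nControl vehicle-control animals per (chemical, sex) (>= 2).
#' @slot nGenes number of genes in the simulated transcriptome.
#' @export
setClass("StudyDesign",
  representation(chemicals = "data.frame", doses = "list",
                 sexes = "character", nTreated = "integer",
                 nControl = "integer", nGenes = "integer"))

setValidity("StudyDesign", function(object) {
  msgs <- character()
  ch <- object@chemicals
  if (!all(c("name", "class") %in% names(ch)))
    msgs <- c(msgs, "chemicals needs 'name' and 'class' columns")
  else {
    if (anyDuplicated(ch$name))
      msgs <- c(msgs, "chemical names must be unique")
    if (!all(ch$class %in% c("PFAS", "PAH")))
      msgs <- c(msgs, "chemical class must be 'PFAS' or 'PAH'")
    if (!setequal(names(object@doses), ch$name))
      msgs <- c(msgs, "doses must be named by chemical name")
  }
  for (nm in names(object@doses)) {
    d <- object@doses[[nm]]
    if (length(d) < 1 || any(d <= 0) || any(diff(d) <= 0))
      msgs <- c(msgs,
        sprintf("dose ladder for '%s' must be strictly increasing and positive", nm))
  }
  if (!all(object@sexes %in% c("male", "female")) || !length(object@sexes))
    msgs <- c(msgs, "sexes must be a non-empty subset of male/female")
  if (object@nTreated < 2L) msgs <- c(msgs, "nTreated must be >= 2")
  if (object@nControl < 2L) msgs <- c(msgs, "nControl must be >= 2")
  if (object@nGenes < 1L) msgs <- c(msgs, "nGenes must be positive")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf(
    "StudyDesign: %d chemicals (%s), %d sexes, n=%d treated / %d controls, %d genes\n",
    nrow(object@chemicals),
    paste(object@chemicals$class, collapse = "/"),
    length(object@sexes), object@nTreated, object@nControl, object@nGenes))
  for (nm in object@chemicals$name)
    cat(sprintf("  %s: %s mg/kg\n", nm,
                paste(object@doses[[nm]], collapse = ", ")))
})

# ---------------------------------------------------------------------------
# ToxStudy: the study bundle (counts/log2 + metadata + QC + planted truth)
# ---------------------------------------------------------------------------

#' Study bundle: expression, sample metadata, QC metrics, and planted truth
#'
#' Extends [SummarizedExperiment::SummarizedExperiment]. Assays hold the
#' `"counts"` matrix (and, after preprocessing or for log-normal simulations,
#' a `"log2"` matrix). `colData` carries the sample metadata columns
#' `chemical`, `class`, `dose_mg_per_kg`, `sex`, `replicate` plus the five
#' per-sample sequencing QC metrics. For synthetic studies,
#' `metadata(x)$truth` records the exact planted mean log2 effect for every
#' (gene, chemical, dose, sex) that was perturbed.
#'
#' @export
setClass("ToxStudy", contains = "SummarizedExperiment")

setValidity("ToxStudy", function(object) {
  msgs <- character()
  cd <- colData(object)
  need <- c("sample_id", "chemical", "class", "dose_mg_per_kg", "sex",
            "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msgs <- c(msgs, paste("missing colData columns:",
                          paste(miss, collapse = ", ")))
  else {
    if (!identical(as.character(cd$sample_id), colnames(object)))
      msgs <- c(msgs, "colData sample_id must match assay column names")
    if (any(cd$dose_mg_per_kg < 0))
      msgs <- c(msgs, "doses must be >= 0 (0 = vehicle)")
    if (!all(cd$sex %in% c("male", "female")))
      msgs <- c(msgs, "sex must be male/female")
  }
  if (!length(assayNames(object)) ||
      !any(assayNames(object) %in% c("counts", "log2")))
    msgs <- c(msgs, "need a 'counts' or 'log2' assay")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ToxStudy-class sample metadata as a plain data.frame.
#' @param study a `ToxStudy`.
#' @export
sampleInfo <- function(study) {
  stopifnot(is(study, "ToxStudy"))
  as.data.frame(colData(study))
}

#' @describeIn ToxStudy-class the five per-sample QC metrics.
#' @export
qcMetrics <- function(study) {
  stopifnot(is(study, "ToxStudy"))
  cols <- c("sample_id", "sequencing_depth", "total_alignment_rate",
            "unique_alignment_rate", "aligned_reads", "pct_probes_ge5")
  as.data.frame(colData(study))[, intersect(cols, colnames(colData(study))),
                                drop = FALSE]
}

#' @describeIn ToxStudy-class planted-effect ground truth (synthetic studies;
#'   NULL for real data). One row per planted (gene, chemical, dose, sex).
#' @export
truthTable <- function(study) {
  stopifnot(is(study, "ToxStudy"))
  metadata(study)$truth
}

#' @describeIn ToxStudy-class the [StudyDesign-class] the bundle was built
#'   from (synthetic studies; NULL otherwise).
#' @export
studyDesignOf <- function(study) {
  stopifnot(is(study, "ToxStudy"))
  metadata(study)$design
}

setMethod("show", "ToxStudy", function(object) {
  cd <- colData(object)
  cat(sprintf("ToxStudy: %d genes x %d samples (assays: %s)\n",
              nrow(object), ncol(object),
              paste(assayNames(object), collapse = ", ")))
  cat(sprintf("  chemicals: %s; sexes: %s; %d vehicle samples\n",
              paste(unique(cd$chemical), collapse = ", "),
              paste(unique(cd$sex), collapse = "/"),
              sum(cd$dose_mg_per_kg == 0)))
  if (!is.null(metadata(object)$truth))
    cat(sprintf("  planted truth: %d (gene, condition) effects\n",
                nrow(metadata(object)$truth)))
})

# ---------------------------------------------------------------------------
# Compendium: reference expression for the PC-regression extrapolator
# ---------------------------------------------------------------------------

#' Reference expression compendium
#'
#' A log2-scale genes x reference-samples matrix used to train the
#' principal-component-regression extrapolator, together with the subset of
#' genes measured by the targeted platform. Synthetic compendia additionally
#' record the latent rank and noise level they were generated with.
#'
#' @slot expr numeric matrix, genes x reference samples, log2 scale.
#' @slot measuredGenes character, subset of rownames(expr).
#' @slot latentRank integer, rank of the generating factor model (synthetic).
#' @slot noiseSd numeric, sd of the additive noise (synthetic).
#' @export
setClass("Compendium",
  representation(expr = "matrix", measuredGenes = "character",
                 latentRank = "integer", noiseSd = "numeric"))

setValidity("Compendium", function(object) {
  msgs <- character()
  if (is.null(rownames(object@expr)))
    msgs <- c(msgs, "expr must have gene rownames")
  if (!all(object@measuredGenes %in% rownames(object@expr)))
    msgs <- c(msgs, "measured genes must be a subset of the compendium genes")
  if (object@latentRank > min(dim(object@expr)))
    msgs <- c(msgs, "latent rank cannot exceed min(genes, samples)")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Compendium-class the log2 expression matrix.
#' @param x a `Compendium`.
#' @export
compendiumExpr <- function(x) {
  stopifnot(is(x, "Compendium"))
  x@expr
}

#' @describeIn Compendium-class the measured (targeted-platform) gene subset.
#' @export
measuredGenes <- function(x) {
  stopifnot(is(x, "Compendium"))
  x@measuredGenes
}

setMethod("show", "Compendium", function(object) {
  cat(sprintf(
    "Compendium: %d genes x %d reference samples; %d measured genes (rank %d, noise sd %g)\n",
    nrow(object@expr), ncol(object@expr), length(object@measuredGenes),
    object@latentRank, object@noiseSd))
})

# ---------------------------------------------------------------------------
# ExtrapolationModel: PC regression from measured panel to full transcriptome
# ---------------------------------------------------------------------------

#' Principal-component-regression extrapolation model
#'
#' Fitted by [fitExtrapolator()]: principal components are computed on the
#' gene-centered measured-gene submatrix of a reference compendium, and every
#' output gene is regressed on the component scores by ordinary least
#' squares. [applyExtrapolator()] projects new samples measured on the panel
#' onto the loadings and predicts the full transcriptome.
#'
#' @slot measuredGenes character, the input panel.
#' @slot centers named numeric, per-measured-gene centering offsets.
#' @slot loadings matrix (measured genes x components), orthonormal.
#' @slot coefficients matrix (components x output genes).
#' @slot intercepts named numeric, per-output-gene intercepts (compendium
#'   means).
#' @slot nComponents number of retained components.
#' @slot passthrough logical; if TRUE, measured genes are passed through
#'   verbatim on prediction rather than re-predicted.
#' @export
setClass("ExtrapolationModel",
  representation(measuredGenes = "character", centers = "numeric",
                 loadings = "matrix", coefficients = "matrix",
                 intercepts = "numeric", nComponents = "integer",
                 passthrough = "logical"))

setValidity("ExtrapolationModel", function(object) {
  msgs <- character()
  out <- names(object@intercepts)
  if (object@nComponents < 1L) msgs <- c(msgs, "nComponents must be >= 1")
  if (!all(object@measuredGenes %in% out))
    msgs <- c(msgs, "output gene set must contain the measured gene set")
  if (!identical(dim(object@loadings),
                 c(length(object@measuredGenes), as.integer(object@nComponents))))
    msgs <- c(msgs, "loadings must be measured genes x nComponents")
  if (!identical(dim(object@coefficients),
                 c(as.integer(object@nComponents), length(out))))
    msgs <- c(msgs, "coefficients must be nComponents x output genes")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ExtrapolationModel", function(object) {
  cat(sprintf(
    "ExtrapolationModel: %d measured genes -> %d output genes, %d components%s\n",
    length(object@measuredGenes), length(object@intercepts),
    object@nComponents,
    if (object@passthrough) " (measured genes passed through)" else ""))
})

# ---------------------------------------------------------------------------
# MIENetwork
# ---------------------------------------------------------------------------

#' MIE-to-target regulatory network
#'
#' Regulatory edges restricted to transcription factors that match a
#' molecular initiating event (MIE) list, with per-MIE counts of distinct
#' targets and of targets mapped to the expression gene set.
#'
#' @slot mies data.frame with columns `name`, `sources`.
#' @slot edges data.frame with columns `mie`, `target`, `mode`.
#' @slot counts data.frame with columns `mie`, `n_targets`, `n_mapped`.
#' @export
setClass("MIENetwork",
  representation(mies = "data.frame", edges = "data.frame",
                 counts = "data.frame"))

setValidity("MIENetwork", function(object) {
  msgs <- character()
  if (!all(object@edges$mie %in% object@mies$name))
    msgs <- c(msgs, "every edge's MIE must appear in the MIE list")
  if (!all(object@counts$n_mapped <= object@counts$n_targets))
    msgs <- c(msgs, "n_mapped cannot exceed n_targets")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn MIENetwork-class MIE names.
#' @param x an `MIENetwork`.
#' @export
mieNames <- function(x) {
  stopifnot(is(x, "MIENetwork"))
  x@mies$name
}

#' @describeIn MIENetwork-class edge table (mie, target, mode).
#' @export
mieEdges <- function(x) {
  stopifnot(is(x, "MIENetwork"))
  x@edges
}

#' @describeIn MIENetwork-class per-MIE target counts (n_targets, n_mapped).
#' @export
mieCounts <- function(x) {
  stopifnot(is(x, "MIENetwork"))
  x@counts
}

setMethod("show", "MIENetwork", function(object) {
  cat(sprintf("MIENetwork: %d MIEs, %d edges, %d with no TRRUST match\n",
              nrow(object@mies), nrow(object@edges),
              sum(object@counts$n_targets == 0)))
})
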