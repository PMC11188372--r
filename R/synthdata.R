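# Synthetic-data generators: regulon tables, study-design-faithful expression
# bundles with planted regulon/sex/class effects, and reference compendia.

#' Construct a dose-response study design
#'
#' @param chemicals data.frame with columns `name` and `class`
#'   (`"PFAS"`/`"PAH"`).
#' @param doses named list of strictly increasing positive dose ladders
#'   (mg/kg), one per chemical.
#' @param sexes subset of `c("male", "female")`.
#' @param nTreated animals per (chemical, dose, sex) group.
#' @param nControl vehicle controls per (chemical, sex); shared across all
#'   doses of that chemical.
#' @param nGenes genes in the simulated transcriptome.
#' @return A [StudyDesign-class].
#' @seealso [defaultStudyDesign()] for the four-chemical rat study layout.
#' @export
studyDesign <- function(chemicals, doses, sexes = c("male", "female"),
                        nTreated = 5L, nControl = 10L, nGenes = 17000L) {
  new("StudyDesign", chemicals = chemicals, doses = doses,
      sexes = sexes, nTreated = as.integer(nTreated),
      nControl = as.integer(nControl), nGenes = as.integer(nGenes))
}

#' The default four-chemical rat exposure design
#'
#' One PAH (2,3-Benzofluorene) and three PFAS (6:1 FTOH, 10:2 FTOH,
#' PFHxSAm), each with a nine-point dose ladder plus vehicle; both sexes;
#' n = 5 treated per group and n = 10 shared vehicle controls per
#' (chemical, sex); a ~17K-gene transcriptome. 10:2 FTOH uses its own,
#' lower, ladder.
#'
#' @param nGenes transcriptome size (default 17000).
#' @param nTreated,nControl group sizes (defaults 5 and 10).
#' @return A [StudyDesign-class].
#' @export
defaultStudyDesign <- function(nGenes = 17000L, nTreated = 5L,
                               nControl = 10L) {
  chems <- data.frame(
    name = c("2,3-Benzofluorene", "6:1 FTOH", "10:2 FTOH", "PFHxSAm"),
    class = c("PAH", "PFAS", "PFAS", "PFAS"),
    stringsAsFactors = FALSE)
  ladder <- c(0.15, 0.50, 1.40, 4, 12, 37, 111, 333, 1000)
  ladder102 <- c(0.07, 0.20, 0.70, 2, 6, 18, 55, 160, 475)
  studyDesign(chems,
              doses = list("2,3-Benzofluorene" = ladder,
                           "6:1 FTOH" = ladder,
                           "10:2 FTOH" = ladder102,
                           "PFHxSAm" = ladder),
              nTreated = nTreated, nControl = nControl, nGenes = nGenes)
}

#' Simulate a TRRUST-dialect regulon table
#'
#' Draws a target-set size for each transcription factor from
#' `targetsPerTF`, fills the sets from a synthetic gene pool (reusing an
#' already-used target with probability `overlapProb`, so regulons can
#' share genes), and assigns each edge a regulation mode from `modeProbs`.
#'
#' @param nTFs number of transcription factors (>= 1).
#' @param targetsPerTF integer range `c(lo, hi)`; target counts are drawn
#'   uniformly from it. A length-1 value fixes the count.
#' @param modeProbs probabilities for `Activation`, `Repression`, `Unknown`;
#'   must sum to 1.
#' @param overlapProb probability that a drawn target reuses a gene already
#'   targeted by another TF.
#' @param tfNames optional TF symbols (default `TF01`, `TF02`, ...).
#' @param seed integer seed; fixed seed reproduces the table exactly.
#' @return data.frame with columns `tf`, `target`, `mode`, `references`
#'   (the TRRUST four-column dialect).
#' @examples
#' reg <- simulateRegulons(3, c(4, 8), seed = 1)
#' table(reg$mode)
#' @export
simulateRegulons <- function(nTFs, targetsPerTF = c(5L, 300L),
                             modeProbs = c(Activation = 0.5,
                                           Repression = 0.3,
                                           Unknown = 0.2),
                             overlapProb = 0.1, tfNames = NULL,
                             seed = NULL) {
  if (nTFs < 1L) stopf("nTFs must be >= 1")
  if (abs(sum(modeProbs) - 1) > 1e-8 || any(modeProbs < 0))
    stopf("modeProbs must be a probability vector summing to 1")
  rng <- range(as.integer(targetsPerTF))
  if (rng[1] < 1L) stopf("targetsPerTF must be positive")
  if (is.null(tfNames)) tfNames <- sprintf("TF%02d", seq_len(nTFs))
  stopifnot(length(tfNames) == nTFs)
  withSeed(seed, {
    sizes <- if (rng[1] == rng[2]) rep(rng[1], nTFs) else
      sample(rng[1]:rng[2], nTFs, replace = TRUE)
    fresh <- 0L
    used <- character()
    rows <- vector("list", nTFs)
    for (i in seq_len(nTFs)) {
      tgt <- character(sizes[i])
      for (j in seq_len(sizes[i])) {
        reuse <- length(used) > 0L && stats::runif(1) < overlapProb
        g <- if (reuse) sample(used, 1L) else {
          fresh <- fresh + 1L
          sprintf("Gene%05d", fresh)
        }
        # keep targets distinct within a TF
        while (g %in% tgt[seq_len(j - 1L)]) {
          fresh <- fresh + 1L
          g <- sprintf("Gene%05d", fresh)
        }
        tgt[j] <- g
      }
      used <- union(used, tgt)
      rows[[i]] <- data.frame(
        tf = tfNames[i], target = tgt,
        mode = sample(names(modeProbs), sizes[i], replace = TRUE,
                      prob = modeProbs),
        references = "SYNTH", stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Describe a planted expression effect
#'
#' One entry of the planted-effect specification consumed by
#' [simulateStudy()]. The effect applies to either the targets of a named
#' TF in the supplied regulon table, or an explicit gene list; it ramps up
#' the dose ladder according to `doseShape`, reaching `maxLog2FC` at the top
#' dose, and is restricted to the given sexes and chemical classes.
#'
#' A gene may be covered by several entries only if their (sex x class)
#' scopes are disjoint; overlapping scopes are rejected by
#' [simulateStudy()]. Sex-dependent genes (opposite direction in males and
#' females) are planted with `sexDirections`.
#'
#' @param tf TF symbol whose regulon receives the effect (alternative to
#'   `genes`).
#' @param genes explicit gene identifiers (alternative to `tf`).
#' @param direction `"up"` or `"down"`.
#' @param maxLog2FC positive effect size (log2 units) at the top dose.
#' @param doseShape `"linear_in_log_dose"` (effect proportional to
#'   log(d/dmin + 1), normalised to 1 at the top dose) or `"hill"`
#'   (d / (d + EC50) with EC50 the geometric mid-dose of the ladder).
#' @param sexes sexes the effect applies to.
#' @param classes chemical classes the effect applies to.
#' @param sexDirections optional named vector like
#'   `c(male = "down", female = "up")` overriding `direction` per sex.
#' @return A `plantedEffect` list usable in the `effects` argument of
#'   [simulateStudy()].
#' @export
plantedEffect <- function(tf = NULL, genes = NULL,
                          direction = c("up", "down"), maxLog2FC,
                          doseShape = c("linear_in_log_dose", "hill"),
                          sexes = c("male", "female"),
                          classes = c("PFAS", "PAH"),
                          sexDirections = NULL) {
  direction <- match.arg(direction)
  doseShape <- match.arg(doseShape)
  if (is.null(tf) == is.null(genes))
    stopf("exactly one of 'tf' or 'genes' must be given")
  if (maxLog2FC <= 0) stopf("maxLog2FC must be > 0")
  stopifnot(all(sexes %in% c("male", "female")),
            all(classes %in% c("PFAS", "PAH")))
  if (!is.null(sexDirections))
    stopifnot(all(names(sexDirections) %in% c("male", "female")),
              all(sexDirections %in% c("up", "down")))
  structure(list(tf = tf, genes = genes, direction = direction,
                 maxLog2FC = maxLog2FC, doseShape = doseShape,
                 sexes = sexes, classes = classes,
                 sexDirections = sexDirections),
            class = "plantedEffect")
}

# Effect magnitude (unsigned, as a fraction of maxLog2FC) at dose d.
doseShapeScale <- function(dose, ladder, shape) {
  if (shape == "linear_in_log_dose") {
    log(dose / min(ladder) + 1) / log(max(ladder) / min(ladder) + 1)
  } else {
    ec50 <- exp(mean(log(ladder)))  # geometric mid-dose
    dose / (dose + ec50)
  }
}

# Resolve a plantedEffect against the regulon table; errors name unknown TFs.
resolveEffectGenes <- function(effect, regulons) {
  if (!is.null(effect$tf)) {
    if (is.null(regulons) || !effect$tf %in% regulons$tf)
      stopf("planted effect refers to unknown TF '%s'", effect$tf)
    unique(regulons$target[regulons$tf == effect$tf])
  } else effect$genes
}

#' Simulate a dose-response study bundle
#'
#' Generates per-sample latent log2 expression as gene baseline + planted
#' effect (scaled along the dose ladder, applied only to samples matching the
#' effect's sex and chemical-class scope) + Normal(0, `noiseSd`) noise. In
#' `mode = "counts"` the latent values are converted to library-scale
#' intensities and Poisson-thinned to a library size drawn uniformly from
#' `libsizeRange`, exercising the full RPM/log2 preprocessing path; in
#' `mode = "lognormal"` the latent log2 matrix is returned directly, for
#' stages that only need log2 values.
#'
#' Per-sample QC metrics are generated alongside, with an optional fraction
#' of deliberately failing samples for boundary-testing the QC filter. The
#' exact planted mean log2 effects are recorded in the bundle's truth table
#' (one row per planted gene x chemical x dose x sex; unplanted
#' combinations are implicitly zero).
#'
#' @param design a [StudyDesign-class].
#' @param regulons regulon table (as from [simulateRegulons()]) whose TF and
#'   target symbols become the leading gene identifiers of the transcriptome;
#'   optional if all effects use explicit gene lists.
#' @param effects list of [plantedEffect()] entries (may be empty).
#' @param noiseSd sd of the per-sample log2 noise.
#' @param libsizeRange library-size range for Poisson thinning.
#' @param mode `"counts"` or `"lognormal"`.
#' @param qcFailFraction fraction of samples given one QC metric drawn below
#'   its threshold (default 0).
#' @param baselineMean,baselineSd distribution of per-gene baseline log2 RPM
#'   levels before rescaling.
#' @param seed integer seed; a fixed seed reproduces the bundle exactly.
#' @return A [ToxStudy-class] with assay `"counts"` (plus metadata) or
#'   `"log2"`.
#' @examples
#' des <- studyDesign(data.frame(name = "A", class = "PFAS"),
#'                    list(A = c(1, 10, 100)), nGenes = 200)
#' st <- simulateStudy(des, mode = "lognormal", seed = 7)
#' dim(st)
#' @export
simulateStudy <- function(design, regulons = NULL, effects = list(),
                          noiseSd = 0.5, libsizeRange = c(2e6, 4e6),
                          mode = c("counts", "lognormal"),
                          qcFailFraction = 0, baselineMean = 5,
                          baselineSd = 2, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(design, "StudyDesign"), noiseSd >= 0)
  if (inherits(effects, "plantedEffect")) effects <- list(effects)

  # gene universe: regulon symbols first, then filler genes
  regSymbols <- if (is.null(regulons)) character() else
    unique(c(regulons$tf, regulons$target))
  if (length(regSymbols) > design@nGenes)
    stopf("design nGenes (%d) smaller than the %d regulon symbols",
          design@nGenes, length(regSymbols))
  filler <- sprintf("Filler%05d", seq_len(design@nGenes - length(regSymbols)))
  genes <- c(regSymbols, filler)

  # resolve + scope-check effects
  effGenes <- lapply(effects, resolveEffectGenes, regulons = regulons)
  for (i in seq_along(effects)) {
    bad <- setdiff(effGenes[[i]], genes)
    if (length(bad))
      stopf("planted effect genes not in the transcriptome: %s",
            paste(utils::head(bad, 3), collapse = ", "))
  }
  if (length(effects) > 1L) {
    scope <- function(e) as.vector(outer(e$sexes, e$classes, paste))
    for (i in seq_len(length(effects) - 1L))
      for (j in seq(i + 1L, length(effects))) {
        shared <- intersect(effGenes[[i]], effGenes[[j]])
        if (length(shared) &&
            length(intersect(scope(effects[[i]]), scope(effects[[j]]))))
          stopf("gene '%s' planted twice with overlapping sex/class scope",
                shared[1])
      }
  }

  # sample sheet
  sheet <- do.call(rbind, lapply(seq_len(nrow(design@chemicals)), function(ci) {
    nm <- design@chemicals$name[ci]
    cls <- design@chemicals$class[ci]
    ab <- gsub("[^A-Za-z0-9]", "", nm)
    do.call(rbind, lapply(design@sexes, function(sx) {
      ctrl <- data.frame(chemical = nm, class = cls, dose_mg_per_kg = 0,
                         sex = sx, replicate = seq_len(design@nControl),
                         stringsAsFactors = FALSE)
      trt <- do.call(rbind, lapply(design@doses[[nm]], function(d)
        data.frame(chemical = nm, class = cls, dose_mg_per_kg = d,
                   sex = sx, replicate = seq_len(design@nTreated),
                   stringsAsFactors = FALSE)))
      rbind(ctrl, trt)
    }))
  }))
  sheet$sample_id <- sprintf("%s_%s_d%s_r%02d",
                             gsub("[^A-Za-z0-9]", "", sheet$chemical),
                             ifelse(sheet$sex == "male", "M", "F"),
                             gsub("\\.", "p", as.character(sheet$dose_mg_per_kg)),
                             sheet$replicate)
  sheet <- sheet[, c("sample_id", "chemical", "class", "dose_mg_per_kg",
                     "sex", "replicate")]
  nS <- nrow(sheet)

  withSeed(seed, {
    # baseline log2-RPM levels, rescaled so intensities sum to 1e6
    b <- pmax(stats::rnorm(design@nGenes, baselineMean, baselineSd), 0)
    intensity0 <- 2^b - 1
    intensity0 <- intensity0 / sum(intensity0) * 1e6
    baseline <- log2(intensity0 + 1)
    names(baseline) <- genes

    # planted signal matrix and truth table
    signal <- matrix(0, design@nGenes, nS, dimnames = list(genes, sheet$sample_id))
    truthRows <- list()
    for (k in seq_along(effects)) {
      e <- effects[[k]]
      gl <- effGenes[[k]]
      for (ci in seq_len(nrow(design@chemicals))) {
        nm <- design@chemicals$name[ci]
        if (!design@chemicals$class[ci] %in% e$classes) next
        ladder <- design@doses[[nm]]
        for (sx in intersect(design@sexes, e$sexes)) {
          dir <- if (!is.null(e$sexDirections) && sx %in% names(e$sexDirections))
            e$sexDirections[[sx]] else e$direction
          sgn <- if (dir == "up") 1 else -1
          for (d in ladder) {
            eff <- sgn * e$maxLog2FC * doseShapeScale(d, ladder, e$doseShape)
            sel <- sheet$chemical == nm & sheet$sex == sx &
              sheet$dose_mg_per_kg == d
            signal[gl, sel] <- signal[gl, sel] + eff
            truthRows[[length(truthRows) + 1L]] <- data.frame(
              gene = gl, chemical = nm, dose_mg_per_kg = d, sex = sx,
              effect = eff, stringsAsFactors = FALSE)
          }
        }
      }
    }
    truth <- if (length(truthRows)) do.call(rbind, truthRows) else
      data.frame(gene = character(), chemical = character(),
                 dose_mg_per_kg = numeric(), sex = character(),
                 effect = numeric(), stringsAsFactors = FALSE)

    latent <- baseline + signal +
      matrix(stats::rnorm(design@nGenes * nS, 0, noiseSd), design@nGenes, nS)
    dimnames(latent) <- list(genes, sheet$sample_id)

    qc <- data.frame(
      sample_id = sheet$sample_id,
      sequencing_depth = NA_real_,
      total_alignment_rate = round(stats::runif(nS, 70, 95), 2),
      unique_alignment_rate = NA_real_,
      aligned_reads = NA_real_,
      pct_probes_ge5 = NA_real_, stringsAsFactors = FALSE)
    qc$unique_alignment_rate <-
      round(qc$total_alignment_rate * stats::runif(nS, 0.75, 0.95), 2)

    if (mode == "counts") {
      libsize <- round(stats::runif(nS, libsizeRange[1], libsizeRange[2]))
      counts <- matrix(0L, design@nGenes, nS,
                       dimnames = list(genes, sheet$sample_id))
      for (s in seq_len(nS)) {
        lam <- pmax(2^latent[, s] - 1, 0)
        counts[, s] <- stats::rpois(design@nGenes, libsize[s] * lam / sum(lam))
      }
      qc$sequencing_depth <- libsize
      qc$pct_probes_ge5 <- round(100 * colMeans(counts >= 5), 2)
      assays <- list(counts = counts)
    } else {
      qc$sequencing_depth <- round(stats::runif(nS, libsizeRange[1],
                                                libsizeRange[2]))
      qc$pct_probes_ge5 <- round(stats::runif(nS, 70, 95), 2)
      assays <- list(log2 = latent)
    }
    qc$aligned_reads <- round(qc$sequencing_depth *
                                qc$total_alignment_rate / 100)

    # deliberately failing samples for QC boundary testing
    nFail <- round(qcFailFraction * nS)
    if (nFail > 0L) {
      fs <- sample(nS, nFail)
      for (s in fs) {
        m <- sample(5L, 1L)
        if (m == 1L) qc$sequencing_depth[s] <- round(stats::runif(1, 5e4, 299999))
        if (m == 2L) qc$total_alignment_rate[s] <- round(stats::runif(1, 10, 39.9), 2)
        if (m == 3L) qc$unique_alignment_rate[s] <- round(stats::runif(1, 5, 29.9), 2)
        if (m == 4L) qc$aligned_reads[s] <- round(stats::runif(1, 5e4, 299999))
        if (m == 5L) qc$pct_probes_ge5[s] <- round(stats::runif(1, 10, 49.9), 2)
      }
    }

    cd <- S4Vectors::DataFrame(cbind(sheet, qc[, -1, drop = FALSE]))
    rownames(cd) <- sheet$sample_id
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = assays, colData = cd,
      metadata = list(design = design, truth = truth,
                      params = list(noiseSd = noiseSd, mode = mode,
                                    libsizeRange = libsizeRange,
                                    seed = seed)))
    new("ToxStudy", se)
  })
}

#' Simulate a reference compendium with known latent rank
#'
#' Expression is a rank-`latentRank` factor model (gene loadings times sample
#' scores) plus a gene-level mean and Normal(0, `noiseSd`) noise; a uniform
#' random subset of genes at `measuredFraction` plays the role of the
#' targeted measurement panel.
#'
#' @param nRefSamples reference samples.
#' @param nGenes compendium genes.
#' @param latentRank rank of the generating model; must not exceed
#'   `min(nRefSamples, nGenes)`.
#' @param measuredFraction fraction of genes in the measured panel.
#' @param noiseSd additive noise sd (0 gives an exactly low-rank matrix).
#' @param seed integer seed.
#' @return A [Compendium-class].
#' @export
simulateCompendium <- function(nRefSamples, nGenes, latentRank,
                               measuredFraction = 0.1, noiseSd = 0.1,
                               seed = NULL) {
  if (latentRank > min(nRefSamples, nGenes))
    stopf("latentRank (%d) exceeds min(genes, samples)", latentRank)
  stopifnot(measuredFraction > 0, measuredFraction <= 1, noiseSd >= 0)
  withSeed(seed, {
    genes <- sprintf("Gene%05d", seq_len(nGenes))
    L <- matrix(stats::rnorm(nGenes * latentRank), nGenes, latentRank)
    S <- matrix(stats::rnorm(latentRank * nRefSamples), latentRank,
                nRefSamples)
    mu <- stats::rnorm(nGenes, 6, 1.5)
    X <- mu + L %*% S
    if (noiseSd > 0)
      X <- X + matrix(stats::rnorm(length(X), 0, noiseSd), nrow(X))
    dimnames(X) <- list(genes, sprintf("Ref%04d", seq_len(nRefSamples)))
    nm <- max(1L, round(measuredFraction * nGenes))
    measured <- if (measuredFraction >= 1) genes else sort(sample(genes, nm))
    new("Compendium", expr = X, measuredGenes = measured,
        latentRank = as.integer(latentRank), noiseSd = noiseSd)
  })
}

#' Write a study bundle to plain-text TSV files
#'
#' Emits `counts.tsv` (or `log2.tsv`), `metadata.tsv`, `qc.tsv` and, when
#' planted truth is present, `truth.tsv` under `dir`.
#'
#' @param study a [ToxStudy-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
writeStudyTSVs <- function(study, dir) {
  stopifnot(is(study, "ToxStudy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  an <- assayNames(study)[1]
  m <- as.data.frame(assay(study, an))
  m <- cbind(gene_id = rownames(m), m)
  p <- file.path(dir, paste0(an, ".tsv"))
  writeTSV(m, p)
  paths <- c(paths, p)
  meta <- sampleInfo(study)[, c("sample_id", "chemical", "class",
                                "dose_mg_per_kg", "sex", "replicate")]
  paths <- c(paths, writeTSV(meta, file.path(dir, "metadata.tsv")))
  paths <- c(paths, writeTSV(qcMetrics(study), file.path(dir, "qc.tsv")))
  tr <- truthTable(study)
  if (!is.null(tr) && nrow(tr))
    paths <- c(paths, writeTSV(tr, file.path(dir, "truth.tsv")))
  invisible(paths)
}

#' Write a regulon table in the TRRUST four-column dialect
#'
#' @param regulons data.frame with columns `tf`, `target`, `mode`,
#'   `references`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeRegulonTSV <- function(regulons, path) {
  stopifnot(all(c("tf", "target", "mode", "references") %in% names(regulons)))
  write.table(regulons[, c("tf", "target", "mode", "references")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
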