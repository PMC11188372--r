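# Pipeline orchestration from a single config, heatmap matrix rendering,
# and run manifests.

#' Read / write an expression TSV with a scale sidecar line
#'
#' The first line is a comment of the form `# scale: counts|rpm|log2`;
#' the rest is a header row (`gene_id` plus sample identifiers) and one row
#' per gene.
#'
#' @param path file path.
#' @param x an [ExprMatrix-class] (writer).
#' @return `readExpressionTSV` returns an [ExprMatrix-class];
#'   `writeExpressionTSV` invisibly returns `path`.
#' @export
readExpressionTSV <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*scale:\\s*(counts|rpm|log2)\\s*$",
                                 first))[[1]]
  if (length(m) < 2L)
    stopf("expression TSV must start with a '# scale: <tag>' line")
  df <- utils::read.delim(path, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  ExprMatrix(mat, m[2])
}

#' @rdname readExpressionTSV
#' @export
writeExpressionTSV <- function(x, path) {
  stopifnot(is(x, "ExprMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scale: %s", exprScale(x)), con)
  v <- exprValues(x)
  df <- data.frame(gene_id = rownames(v), round(v, 6), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render an ordered fold-change heatmap matrix
#'
#' Builds a genes x conditions matrix of log2 fold changes with columns
#' ordered by chemical, then sex, then ascending dose (so each chemical
#' block reads left to right with increasing concentration), and rows
#' ordered by average-linkage hierarchical clustering of the genes on
#' Euclidean distance. Genes absent from the table (or with missing cells)
#' are skipped and reported.
#'
#' @param fcTable data.frame from [buildFCTable()].
#' @param genes genes to include (non-empty).
#' @param conditions optional data.frame (`chemical`, `sex`,
#'   `dose_mg_per_kg`) restricting the columns.
#' @param linkage hierarchical clustering linkage (default "average").
#' @return list with `matrix` (row-ordered, columns `chemical|sex|dose`)
#'   and `skipped` (genes left out).
#' @export
renderHeatmapMatrix <- function(fcTable, genes, conditions = NULL,
                                linkage = "average") {
  if (!length(genes)) stopf("empty gene set")
  if (is.null(conditions))
    conditions <- unique(fcTable[, c("chemical", "sex", "dose_mg_per_kg")])
  conditions <- conditions[order(conditions$chemical, conditions$sex,
                                 conditions$dose_mg_per_kg), ]
  cols <- sprintf("%s|%s|%g", conditions$chemical, conditions$sex,
                  conditions$dose_mg_per_kg)
  m <- matrix(NA_real_, length(genes), nrow(conditions),
              dimnames = list(genes, cols))
  for (i in seq_len(nrow(conditions))) {
    sel <- fcTable$chemical == conditions$chemical[i] &
      fcTable$sex == conditions$sex[i] &
      fcTable$dose_mg_per_kg == conditions$dose_mg_per_kg[i]
    sub <- fcTable[sel, ]
    m[, i] <- sub$log2fc[match(genes, sub$gene)]
  }
  complete <- rowSums(is.na(m)) == 0
  skipped <- genes[!complete]
  m <- m[complete, , drop = FALSE]
  if (nrow(m) > 2L) {
    hc <- stats::hclust(stats::dist(m), method = linkage)
    m <- m[hc$order, , drop = FALSE]
  }
  list(matrix = m, skipped = skipped)
}

# ---------------------------------------------------------------------------
# Pipeline config + orchestration
# ---------------------------------------------------------------------------

#' Read and validate a pipeline config
#'
#' @param path YAML config file; see the packaged demo config
#'   (`system.file("extdata", "demo_config.yaml", package = "MIEprofiler")`)
#'   for the schema.
#' @return The validated config list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  validatePipelineConfig(yaml::read_yaml(path))
}

validatePipelineConfig <- function(config) {
  if (is.null(config$output_dir))
    stopf("config is missing required field 'output_dir'")
  if (is.null(config$simulate)) {
    if (is.null(config$inputs))
      stopf("config needs either a 'simulate' block or an 'inputs' block")
    for (k in c("expression", "metadata", "qc", "regulons")) {
      if (is.null(config$inputs[[k]]))
        stopf("config is missing required field 'inputs.%s'", k)
      if (!file.exists(config$inputs[[k]]))
        stopf("config input path does not exist: %s", config$inputs[[k]])
    }
    if (is.null(config$mie_list))
      stopf("config is missing required field 'mie_list'")
  }
  th <- config$thresholds
  up <- th$up %||% 0.6
  down <- th$down %||% -0.6
  if (up <= down) stopf("thresholds: up (%g) must exceed down (%g)", up, down)
  q <- th$q %||% 0.1
  if (q <= 0 || q >= 1) stopf("thresholds: q must lie in (0, 1)")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build planted effects from the config's simulate.effects block.
configEffects <- function(entries) {
  lapply(entries, function(e)
    plantedEffect(tf = e$tf, genes = unlist(e$genes),
                  direction = e$direction %||% "up",
                  maxLog2FC = e$max_log2fc,
                  doseShape = e$dose_shape %||% "linear_in_log_dose",
                  sexes = unlist(e$sexes) %||% c("male", "female"),
                  classes = unlist(e$classes) %||% c("PFAS", "PAH"),
                  sexDirections = unlist(e$sex_directions)))
}

configDesign <- function(sim) {
  if (is.null(sim$chemicals)) {
    defaultStudyDesign(nGenes = sim$n_genes %||% 17000L,
                       nTreated = sim$n_treated %||% 5L,
                       nControl = sim$n_control %||% 10L)
  } else {
    chems <- do.call(rbind, lapply(sim$chemicals, function(ch)
      data.frame(name = ch$name, class = ch$class, stringsAsFactors = FALSE)))
    doses <- stats::setNames(lapply(sim$chemicals, function(ch)
      as.numeric(unlist(ch$doses))), chems$name)
    studyDesign(chems, doses, nTreated = sim$n_treated %||% 5L,
                nControl = sim$n_control %||% 10L,
                nGenes = sim$n_genes %||% 17000L)
  }
}

#' Run the full pipeline from a config
#'
#' Executes the stages in order — simulate (or load inputs), QC +
#' normalisation + outlier removal, fold-change table, regulon network,
#' dysregulation profile, response classification, optional signature
#' concordance, and renderers (Table-1 layout, heatmap matrix, SIF/GraphML
#' network exports at the top dose of each chemical and sex) — writing all
#' artifacts plus a run manifest under the config's `output_dir`. The run is
#' deterministic for a fixed config and seed.
#'
#' @param config a config list or the path to a YAML config
#'   (see [readPipelineConfig()]).
#' @param seed overrides the config's `seed` if given.
#' @return Invisibly, a list with the principal in-memory artifacts
#'   (`study`, `fcTable`, `network`, `profile`, `calls`, `manifest`) and
#'   the written `paths`.
#' @export
runPipeline <- function(config, seed = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  config <- validatePipelineConfig(config)
  seed <- seed %||% config$seed %||% 1L
  outDir <- config$output_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  warnings <- character()
  noteWarning <- function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  th <- config$thresholds
  upThr <- th$up %||% 0.6
  downThr <- th$down %||% -0.6
  qThr <- th$q %||% 0.1
  topK <- config$top_k_doses %||% 3L

  withCallingHandlers({
    # --- stage: inputs ------------------------------------------------------
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      design <- configDesign(sim)
      reg <- sim$regulons %||% list()
      regulons <- simulateRegulons(
        nTFs = reg$n_tfs %||% 19L,
        targetsPerTF = unlist(reg$targets_per_tf) %||% c(5L, 100L),
        overlapProb = reg$overlap_prob %||% 0.05,
        seed = seed)
      effects <- configEffects(sim$effects %||% list())
      study <- simulateStudy(design, regulons, effects,
                             noiseSd = sim$noise_sd %||% 0.5,
                             mode = sim$mode %||% "counts",
                             qcFailFraction = sim$qc_fail_fraction %||% 0,
                             seed = seed + 1L)
      inDir <- file.path(outDir, "inputs")
      writeStudyTSVs(study, inDir)
      writeRegulonTSV(regulons, file.path(inDir, "regulons.tsv"))
      mies <- if (is.null(config$mie_list))
        data.frame(name = unique(regulons$tf), sources = "target_prediction",
                   stringsAsFactors = FALSE)
      else readMIEList(config$mie_list)
      inputPaths <- list.files(inDir, full.names = TRUE)
    } else {
      em <- readExpressionTSV(config$inputs$expression)
      meta <- readTSV(config$inputs$metadata)
      qc <- readTSV(config$inputs$qc)
      cd <- S4Vectors::DataFrame(cbind(meta, qc[match(meta$sample_id,
                                                      qc$sample_id), -1]))
      rownames(cd) <- meta$sample_id
      assays <- stats::setNames(list(exprValues(em)[, meta$sample_id]),
                                if (exprScale(em) == "log2") "log2" else "counts")
      study <- new("ToxStudy", SummarizedExperiment::SummarizedExperiment(
        assays = assays, colData = cd))
      regulons <- readRegulatoryTable(config$inputs$regulons)
      mies <- readMIEList(config$mie_list)
      inputPaths <- unlist(config$inputs, use.names = FALSE)
    }
    if (!is.null(config$mapping)) {
      mapped <- mapSymbols(regulons, readMappingTable(config$mapping))
      regulons <- mapped$edges
      writeTSV(mapped$report, file.path(outDir, "symbol_mapping_report.tsv"))
    }

    # --- stage: preprocess --------------------------------------------------
    qcth <- do.call(qcThresholds, config$qc_thresholds %||% list())
    proc <- preprocessStudy(study, qcth,
                            minMedianCorr = th$min_median_corr %||% 0.8)
    logm <- assay(proc, "log2")
    meta <- sampleInfo(proc)

    # --- stage: differential expression ------------------------------------
    fcTable <- buildFCTable(logm, meta)
    writeFCTable(fcTable, file.path(outDir, "fc_table.tsv"))

    # --- stage: regulon network --------------------------------------------
    network <- buildMIENetwork(regulons, mies, rownames(logm))
    writeTSV(mieCounts(network), file.path(outDir, "mie_counts.tsv"))

    # --- stage: profiling ---------------------------------------------------
    profile <- profileConditions(fcTable, network, upThr = upThr,
                                 downThr = downThr)
    writeProfileTSV(directionSplit(profile),
                    file.path(outDir, "profile_long.tsv"))
    writeProfileTableTSV(profile, file.path(outDir, "profile_table1.tsv"),
                         k = topK)

    # --- stage: classification ---------------------------------------------
    calls <- classifyResponses(fcTable, threshold = upThr,
                               minSupport = th$min_support %||% 1.0,
                               trendThreshold = upThr,
                               trendWindow = th$trend_window %||% 3L,
                               trendTolerance = th$trend_tolerance %||% 0.3)
    writeResponseCalls(calls, file.path(outDir, "response_calls.tsv"))

    # --- stage: signature concordance --------------------------------------
    concord <- NULL
    if (!is.null(config$signature)) {
      sig <- readSignatureTSV(config$signature)
      cs <- unique(fcTable[, c("chemical", "sex")])
      concord <- do.call(rbind, lapply(seq_len(nrow(cs)), function(i) {
        d <- max(fcTable$dose_mg_per_kg[fcTable$chemical == cs$chemical[i]])
        cbind(chemical = cs$chemical[i], sex = cs$sex[i],
              dose_mg_per_kg = d,
              signatureConcordance(fcTable, sig, cs$chemical[i], d,
                                   cs$sex[i], qThr))
      }))
      writeTSV(concord, file.path(outDir, "concordance.tsv"))
    }

    # --- stage: renderers ---------------------------------------------------
    netDir <- file.path(outDir, "networks")
    dir.create(netDir, showWarnings = FALSE)
    cs <- unique(fcTable[, c("chemical", "sex")])
    for (i in seq_len(nrow(cs))) {
      d <- max(fcTable$dose_mg_per_kg[fcTable$chemical == cs$chemical[i]])
      sel <- fcTable$chemical == cs$chemical[i] & fcTable$sex == cs$sex[i] &
        fcTable$dose_mg_per_kg == d
      fc <- stats::setNames(fcTable$log2fc[sel], fcTable$gene[sel])
      stem <- sprintf("%s_%s_top", gsub("[^A-Za-z0-9]", "", cs$chemical[i]),
                      cs$sex[i])
      exportNetwork(network, fc, "sif", file.path(netDir, paste0(stem, ".sif")),
                    attrFile = file.path(netDir, paste0(stem, "_nodes.tsv")),
                    upThr = upThr, downThr = downThr)
      exportNetwork(network, fc, "graphml",
                    file.path(netDir, paste0(stem, ".graphml")),
                    upThr = upThr, downThr = downThr)
    }
    hmGenes <- unlist(config$heatmap$genes) %||% {
      dys <- unique(fcTable$gene[abs(fcTable$log2fc) >= upThr &
                                   fcTable$gene %in% mieEdges(network)$target])
      utils::head(sort(dys), 50L)
    }
    hm <- NULL
    if (length(hmGenes)) {
      hm <- renderHeatmapMatrix(fcTable, hmGenes)
      hdf <- data.frame(gene = rownames(hm$matrix), hm$matrix,
                        check.names = FALSE)
      writeTSV(hdf, file.path(outDir, "heatmap_matrix.tsv"))
      if (length(hm$skipped))
        writeLines(hm$skipped, file.path(outDir, "heatmap_skipped_genes.txt"))
    }

    # --- manifest -----------------------------------------------------------
    configEcho <- config
    configEcho$output_dir <- NULL  # keep the manifest path-independent
    hashes <- tools::md5sum(inputPaths)
    names(hashes) <- basename(inputPaths)
    manifest <- list(
      config = configEcho, seed = seed,
      input_hashes = as.list(hashes),
      stage_counts = list(
        samples_in = ncol(study), samples_retained = ncol(proc),
        fc_rows = nrow(fcTable), network_edges = nrow(mieEdges(network)),
        profile_rows = nrow(profile), call_rows = nrow(calls),
        concordance_rows = if (is.null(concord)) 0L else nrow(concord),
        heatmap_genes = if (is.null(hm)) 0L else nrow(hm$matrix)),
      warnings = warnings)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    invisible(list(study = proc, fcTable = fcTable, network = network,
                   profile = profile, calls = calls, concordance = concord,
                   manifest = manifest,
                   paths = list.files(outDir, recursive = TRUE,
                                      full.names = TRUE)))
  }, warning = noteWarning)
}
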