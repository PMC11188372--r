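# Synthetic-data generator: regulon tables, study bundles, compendia.

test_that("simulateRegulons honours forced parameters and mode simplex", {
  # 2 TFs x exactly 3 targets, no overlap -> 6 edges, disjoint target sets
  reg <- simulateRegulons(2, c(3, 3), overlapProb = 0, seed = 1)
  expect_equal(nrow(reg), 6L)
  expect_length(intersect(reg$target[reg$tf == "TF01"],
                          reg$target[reg$tf == "TF02"]), 0L)

  # degenerate simplex forces a single mode
  reg2 <- simulateRegulons(3, c(2, 5),
                           modeProbs = c(Activation = 1, Repression = 0,
                                         Unknown = 0), seed = 2)
  expect_true(all(reg2$mode == "Activation"))

  expect_error(simulateRegulons(2, c(2, 4),
                                modeProbs = c(Activation = 0.9,
                                              Repression = 0.9,
                                              Unknown = 0.2)),
               "simplex|summing to 1")
  # determinism
  expect_identical(simulateRegulons(4, c(2, 9), seed = 7),
                   simulateRegulons(4, c(2, 9), seed = 7))
})

test_that("realized regulon mode fractions fall in exact 99% binomial bands", {
  probs <- c(Activation = 0.5, Repression = 0.3, Unknown = 0.2)
  reg <- simulateRegulons(19, c(5, 300), modeProbs = probs, seed = 11)
  n <- nrow(reg)
  for (m in names(probs)) {
    k <- sum(reg$mode == m)
    # oracle: exact binomial 99% interval computed independently
    lo <- qbinom(0.005, n, probs[[m]])
    hi <- qbinom(0.995, n, probs[[m]])
    expect_gte(k, lo)
    expect_lte(k, hi)
  }
})

test_that("simulateStudy sample arithmetic and determinism", {
  des <- studyDesign(data.frame(name = "X", class = "PFAS"),
                     list(X = c(1, 10)), nTreated = 5, nControl = 10,
                     nGenes = 100)
  st <- simulateStudy(des, seed = 3)
  # 2 doses x 5 x 2 sexes + 10 controls x 2 sexes = 40
  expect_equal(ncol(st), 40L)
  expect_identical(colnames(st), sampleInfo(st)$sample_id)
  st2 <- simulateStudy(des, seed = 3)
  expect_identical(SummarizedExperiment::assay(st, "counts"),
                   SummarizedExperiment::assay(st2, "counts"))
  expect_identical(sampleInfo(st), sampleInfo(st2))
})

test_that("null study realized fold changes match the closed-form tail", {
  des <- tinyDesign(nGenes = 2000, doses = c(1, 10))
  st <- simulateStudy(des, noiseSd = 0.5, mode = "lognormal", seed = 5)
  logm <- SummarizedExperiment::assay(st, "log2")
  md <- sampleInfo(st)
  fcs <- unlist(lapply(c(1, 10), function(d)
    c(computeLog2FC(logm, md, "PFAS-A", d, "male"),
      computeLog2FC(logm, md, "PFAS-A", d, "female"))))
  sd0 <- 0.5 * sqrt(1 / 5 + 1 / 10)
  pTail <- 2 * pnorm(-0.6 / sd0)
  obs <- mean(abs(fcs) >= 0.6)
  se <- sqrt(pTail * (1 - pTail) / length(fcs))
  expect_lt(abs(obs - pTail), 3 * se)
  # grand mean of realized log2FC within 3 SE of 0
  expect_lt(abs(mean(fcs)), 3 * sd0 / sqrt(length(fcs)))
})

test_that("planted sex-scoped effect lands on the right sex and magnitude", {
  tgts <- sprintf("PT%02d", 1:20)
  reg <- data.frame(tf = "PPARA", target = tgts, mode = "Activation",
                    references = "SYNTH")
  des <- studyDesign(data.frame(name = "X", class = "PFAS"),
                     list(X = c(1, 10, 100)), nGenes = 500)
  eff <- plantedEffect(tf = "PPARA", maxLog2FC = 2, sexes = "male")
  st <- simulateStudy(des, reg, list(eff), noiseSd = 0.5,
                      mode = "lognormal", seed = 6)
  logm <- SummarizedExperiment::assay(st, "log2")
  md <- sampleInfo(st)
  fcM <- computeLog2FC(logm, md, "X", 100, "male")[tgts]
  fcF <- computeLog2FC(logm, md, "X", 100, "female")[tgts]
  se <- 0.5 * sqrt(1 / 5 + 1 / 10) / sqrt(20)
  expect_lt(abs(mean(fcM) - 2), 3 * se)
  expect_lt(abs(mean(fcF) - 0), 3 * se)
  # truth table is exhaustive and unique over planted combinations
  tr <- truthTable(st)
  expect_equal(nrow(tr), 20 * 3 * 1)  # genes x doses x sexes in scope
  expect_false(anyDuplicated(tr[, c("gene", "chemical", "dose_mg_per_kg",
                                    "sex")]) > 0)
  expect_equal(max(tr$effect), 2)
})

test_that("unknown TF in an effect errors naming the TF", {
  des <- tinyDesign(nGenes = 50)
  reg <- simulateRegulons(2, c(3, 3), seed = 1)
  expect_error(
    simulateStudy(des, reg, list(plantedEffect(tf = "NOPE", maxLog2FC = 1)),
                  seed = 1),
    "NOPE")
})

test_that("overlapping-scope double planting is rejected", {
  des <- tinyDesign(nGenes = 50)
  e1 <- plantedEffect(genes = "Filler00001", maxLog2FC = 1, sexes = "male")
  e2 <- plantedEffect(genes = "Filler00001", direction = "down",
                      maxLog2FC = 1, sexes = "male")
  expect_error(simulateStudy(des, NULL, list(e1, e2), seed = 1),
               "overlapping")
  # disjoint scopes are fine
  e3 <- plantedEffect(genes = "Filler00001", direction = "down",
                      maxLog2FC = 1, sexes = "female")
  expect_s4_class(simulateStudy(des, NULL, list(e1, e3),
                                mode = "lognormal", seed = 1), "ToxStudy")
})

test_that("count-mode column sums track the drawn library sizes", {
  des <- studyDesign(data.frame(name = "X", class = "PFAS"),
                     list(X = 1), nTreated = 2, nControl = 2, nGenes = 400)
  st <- simulateStudy(des, libsizeRange = c(5e5, 8e5), seed = 9)
  cs <- colSums(SummarizedExperiment::assay(st, "counts"))
  # Poisson thinning tolerance: 4 sd around the drawn library size
  expect_true(all(cs > 5e5 - 4 * sqrt(5e5) & cs < 8e5 + 4 * sqrt(8e5)))
})

test_that("simulateCompendium construction invariants hold", {
  cp <- simulateCompendium(40, 200, 3, measuredFraction = 0.25,
                           noiseSd = 0, seed = 4)
  expect_equal(qr(sweep(compendiumExpr(cp), 1,
                        rowMeans(compendiumExpr(cp))))$rank, 3L)
  expect_length(measuredGenes(cp), 50L)
  cpAll <- simulateCompendium(10, 30, 2, measuredFraction = 1, seed = 4)
  expect_setequal(measuredGenes(cpAll), rownames(compendiumExpr(cpAll)))
  expect_error(simulateCompendium(5, 30, 6, seed = 1), "latentRank")
})

test_that("study TSV writers round-trip the sample sheet", {
  des <- tinyDesign(nGenes = 30, doses = c(1, 10), nTreated = 2,
                    nControl = 2)
  st <- simulateStudy(des, mode = "lognormal", seed = 8)
  dir <- withr::local_tempdir()
  writeStudyTSVs(st, dir)
  meta <- read.delim(file.path(dir, "metadata.tsv"))
  expect_equal(meta$sample_id, sampleInfo(st)$sample_id)
  qc <- read.delim(file.path(dir, "qc.tsv"))
  expect_named(qc, c("sample_id", "sequencing_depth", "total_alignment_rate",
                     "unique_alignment_rate", "aligned_reads",
                     "pct_probes_ge5"))
})
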