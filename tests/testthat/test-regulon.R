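# TRRUST-dialect ingestion, symbol mapping, network construction, export.

writeLinesTmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("readRegulatoryTable parses, collapses and validates", {
  f <- writeLinesTmp(c("TP53\tCDKN1A\tActivation\t123",
                       "MYC\tTERT\tActivation\t456",
                       "STAT3\tBCL2\tRepression\t789"))
  ed <- readRegulatoryTable(f)
  expect_equal(nrow(ed), 3)
  expect_setequal(ed$mode, c("Activation", "Repression"))

  # conflicting modes collapse to one Unknown edge with a warning
  f2 <- writeLinesTmp(c("A\tB\tActivation\t1", "A\tB\tRepression\t2"))
  expect_warning(ed2 <- readRegulatoryTable(f2), "conflicting")
  expect_equal(nrow(ed2), 1)
  expect_identical(ed2$mode, "Unknown")

  # exact duplicates collapse silently
  f3 <- writeLinesTmp(c("A\tB\tActivation\t1", "A\tB\tActivation\t1"))
  expect_equal(nrow(readRegulatoryTable(f3)), 1)

  # unknown mode cites the line
  f4 <- writeLinesTmp(c("A\tB\tActivation\t1", "A\tC\tUp\t2"))
  expect_error(readRegulatoryTable(f4), "line 2.*Up")
  # malformed field count cites the line
  f5 <- writeLinesTmp(c("A\tB\tActivation"))
  expect_error(readRegulatoryTable(f5), "line 1")
})

test_that("mapSymbols applies table, fallback and one-to-many rules", {
  ed <- data.frame(tf = c("TP53", "X"), target = c("CDKN1A", "ABCC3"),
                   mode = "Activation", references = "r",
                   stringsAsFactors = FALSE)
  mapping <- data.frame(source_symbol = c("TP53", "X", "X"),
                        destination_symbol = c("Tp53", "Y", "Z"))
  res <- mapSymbols(ed, mapping)
  expect_true("Tp53" %in% res$edges$tf)
  # fallback title-case conversion, recorded in the report
  expect_true("Abcc3" %in% res$edges$target)
  expect_identical(res$report$status[res$report$symbol == "ABCC3"],
                   "fallback")
  expect_identical(res$report$status[res$report$symbol == "CDKN1A"],
                   "fallback")
  # one-to-many produces one edge per destination
  expect_identical(res$report$status[res$report$symbol == "X"],
                   "one_to_many")
  expect_setequal(res$edges$tf[res$edges$target == "Abcc3"], c("Y", "Z"))
})

test_that("mapSymbols with empty mapping is idempotent on converted symbols", {
  ed <- data.frame(tf = "Tp53", target = "Abcc3", mode = "Unknown",
                   references = "r", stringsAsFactors = FALSE)
  once <- mapSymbols(ed)$edges
  twice <- mapSymbols(once)$edges
  expect_identical(once, twice)
  expect_identical(once$tf, "Tp53")
})

test_that("buildMIENetwork matches case-insensitively and keeps unmatched MIEs", {
  ed <- data.frame(tf = c("Ppara", "Ppara", "Nr3c1"),
                   target = c("T1", "T2", "T1"), mode = "Activation",
                   references = "r", stringsAsFactors = FALSE)
  mies <- data.frame(name = c("PPARA", "NR3C1", "ESR1"),
                     sources = "aop_database", stringsAsFactors = FALSE)
  expect_warning(net <- buildMIENetwork(ed, mies, c("T1")), "ESR1")
  cnt <- mieCounts(net)
  expect_equal(cnt$n_targets[cnt$mie == "PPARA"], 2)
  expect_equal(cnt$n_mapped[cnt$mie == "PPARA"], 1)
  expect_equal(cnt$n_targets[cnt$mie == "ESR1"], 0)
  # a target regulated by two MIEs counts once for each
  expect_equal(cnt$n_targets[cnt$mie == "NR3C1"], 1)
})

test_that("per-MIE counts equal brute-force set sizes on random fixtures", {
  set.seed(40)
  for (i in 1:10) {
    nTF <- sample(3:8, 1)
    reg <- simulateRegulons(nTF, c(2, 30), overlapProb = 0.3, seed = i)
    mies <- data.frame(name = sample(unique(reg$tf)), sources = "x")
    genes <- unique(reg$target)
    exprGenes <- sample(genes, ceiling(length(genes) / 2))
    net <- buildMIENetwork(reg, mies, exprGenes)
    cnt <- mieCounts(net)
    for (m in mies$name) {
      tg <- unique(reg$target[reg$tf == m])
      expect_equal(cnt$n_targets[cnt$mie == m], length(tg))
      expect_equal(cnt$n_mapped[cnt$mie == m],
                   length(intersect(tg, exprGenes)))
    }
    # row-order invariance
    cnt2 <- mieCounts(buildMIENetwork(reg[sample(nrow(reg)), ], mies,
                                      exprGenes))
    expect_equal(cnt2[order(cnt2$mie), ], cnt[order(cnt$mie), ],
                 ignore_attr = TRUE)
  }
})

test_that("exportNetwork writes SIF lines and classed node attributes", {
  ed <- data.frame(tf = "M1", target = c("A", "B"), mode = "Activation",
                   references = "r", stringsAsFactors = FALSE)
  net <- buildMIENetwork(ed, data.frame(name = "M1", sources = "x"),
                         c("A", "B"))
  sif <- withr::local_tempfile(fileext = ".sif")
  attrs <- exportNetwork(net, c(A = -0.2, B = 0), "sif", sif,
                         attrFile = NULL)
  expect_identical(readLines(sif),
                   c("M1\tregulates\tA", "M1\tregulates\tB"))
  expect_identical(attrs$sign_class[attrs$node == "A"], "down")
  expect_identical(attrs$dysreg_class[attrs$node == "A"], "none")
  expect_identical(attrs$sign_class[attrs$node == "B"], "neutral")
  # MIE node has no fc -> neutral
  expect_identical(attrs$sign_class[attrs$node == "M1"], "neutral")
  expect_error(exportNetwork(net, c(A = 1), "dot", sif), "unknown")
})

test_that("GraphML round-trip preserves edges and attributes", {
  reg <- simulateRegulons(3, c(3, 6), seed = 41)
  mies <- data.frame(name = unique(reg$tf), sources = "x")
  net <- buildMIENetwork(reg, mies, unique(reg$target))
  fc <- setNames(round(runif(length(unique(reg$target)), -2, 2), 3),
                 unique(reg$target))
  gml <- withr::local_tempfile(fileext = ".graphml")
  attrs <- exportNetwork(net, fc, "graphml", gml)
  back <- importGraphML(gml)
  expect_setequal(paste(back$edges$from, back$edges$to),
                  paste(mieEdges(net)$mie, mieEdges(net)$target))
  idx <- match(attrs$node, back$nodes$name)
  expect_equal(back$nodes$sign_class[idx], attrs$sign_class)
  expect_equal(back$nodes$dysreg_class[idx], attrs$dysreg_class)
  fcExp <- ifelse(is.na(attrs$log2fc), 0, attrs$log2fc)
  expect_equal(back$nodes$log2fc[idx], fcExp, tolerance = 1e-9)
})
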