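# Dysregulated-target counting and Table-1-style profiles.

simpleNet <- function(targets, mie = "M1") {
  buildMIENetwork(
    data.frame(tf = mie, target = targets, mode = "Unknown",
               references = "r", stringsAsFactors = FALSE),
    data.frame(name = mie, sources = "x", stringsAsFactors = FALSE),
    targets)
}

test_that("countDysregulated uses inclusive +/-0.6 boundaries", {
  net <- simpleNet(c("A", "B", "C"))
  cnt <- countDysregulated(c(A = 0.6, B = -0.6, C = 0.59), net)
  expect_equal(cnt$n_up, 1)
  expect_equal(cnt$n_down, 1)
  expect_equal(cnt$genes_up[[1]], "A")
  expect_equal(cnt$genes_down[[1]], "B")

  expect_equal(countDysregulated(c(A = 0, B = 0, C = 0), net)$n_total, 0)
  expect_error(countDysregulated(c(A = 1), net, upThr = -0.6,
                                 downThr = 0.6), "greater")
  # targets missing from fc contribute nothing
  expect_equal(countDysregulated(c(A = 2), net)$n_total, 1)
})

test_that("counts equal an exhaustive brute-force scan on random fixtures", {
  set.seed(50)
  for (i in 1:20) {
    nTF <- sample(2:10, 1)
    reg <- simulateRegulons(nTF, c(2, 40), overlapProb = 0.25, seed = i + 100)
    mies <- data.frame(name = unique(reg$tf), sources = "x")
    genes <- unique(reg$target)
    net <- buildMIENetwork(reg, mies, genes)
    fc <- setNames(round(runif(length(genes), -1.5, 1.5), 2), genes)
    # randomly drop some genes from fc
    fc <- fc[runif(length(fc)) > 0.2]
    cnt <- countDysregulated(fc, net)
    oracle <- bruteCountDysregulated(fc, mieEdges(net), mies$name, 0.6, -0.6)
    expect_equal(cnt[, c("mie", "n_up", "n_down", "n_total")], oracle,
                 ignore_attr = TRUE)
  }
})

test_that("counts are monotone in thresholds", {
  set.seed(51)
  reg <- simulateRegulons(4, c(10, 30), seed = 52)
  net <- buildMIENetwork(reg, data.frame(name = unique(reg$tf),
                                         sources = "x"),
                         unique(reg$target))
  fc <- setNames(rnorm(length(unique(reg$target))), unique(reg$target))
  base <- countDysregulated(fc, net)
  higher <- countDysregulated(fc, net, upThr = 0.9)
  lower <- countDysregulated(fc, net, downThr = -0.9)
  expect_true(all(higher$n_up <= base$n_up))
  expect_true(all(lower$n_down <= base$n_down))
})

test_that("mode-aware counting restricts to concordant directions", {
  reg <- data.frame(tf = "M1", target = c("A", "B", "C"),
                    mode = c("Activation", "Repression", "Unknown"),
                    references = "r", stringsAsFactors = FALSE)
  net <- buildMIENetwork(reg, data.frame(name = "M1", sources = "x"),
                         c("A", "B", "C"))
  fc <- c(A = 1, B = 1, C = 1)
  cnt <- countDysregulated(fc, net, modeAware = TRUE)
  # B (Repression) upregulated -> not concordant
  expect_equal(cnt$n_up, 2)
  expect_equal(countDysregulated(fc, net)$n_up, 3)
})

test_that("profileConditions covers conditions and the top-dose view pivots", {
  des <- tinyDesign(nGenes = 150, doses = c(1, 5, 25, 125), nTreated = 3,
                    nControl = 4)
  reg <- simulateRegulons(3, c(5, 15), seed = 60)
  st <- simulateStudy(des, reg, mode = "lognormal", seed = 61)
  tab <- buildFCTable(SummarizedExperiment::assay(st, "log2"),
                      sampleInfo(st))
  net <- buildMIENetwork(reg, data.frame(name = unique(reg$tf),
                                         sources = "x"), rownames(st))
  prof <- profileConditions(tab, net)
  expect_equal(nrow(prof), 3 * 2 * 4 * 2)  # MIEs x chems x doses x sexes
  expect_true(all(prof$n_total == prof$n_up + prof$n_down))

  wide <- profileTopDoses(prof, k = 3)
  expect_equal(nrow(wide), 3)
  expect_equal(ncol(wide), 1 + 2 * 2 * 3)  # mie + chem x sex x top-3 doses
  expect_false(any(grepl("\\|1$", names(wide))))  # lowest dose dropped

  expect_error(
    profileConditions(tab, net,
                      conditions = data.frame(chemical = "PFAS-A",
                                              dose_mg_per_kg = 999,
                                              sex = "male")),
    "999")
})

test_that("profile is invariant to gene and MIE order", {
  reg <- simulateRegulons(4, c(5, 10), seed = 62)
  genes <- unique(reg$target)
  net1 <- buildMIENetwork(reg, data.frame(name = unique(reg$tf),
                                          sources = "x"), genes)
  net2 <- buildMIENetwork(reg[rev(seq_len(nrow(reg))), ],
                          data.frame(name = rev(unique(reg$tf)),
                                     sources = "x"), rev(genes))
  fc <- setNames(rnorm(length(genes)), genes)
  c1 <- countDysregulated(fc, net1)
  c2 <- countDysregulated(sample(fc), net2)
  expect_equal(c1[order(c1$mie), c("mie", "n_up", "n_down")],
               c2[order(c2$mie), c("mie", "n_up", "n_down")],
               ignore_attr = TRUE)
})

test_that("directionSplit reports fractions and flags empty cells", {
  prof <- data.frame(mie = c("a", "b"), chemical = "X", class = "PFAS",
                     sex = "male", dose_mg_per_kg = 1,
                     n_up = c(3, 0), n_down = c(1, 0), n_total = c(4, 0))
  sp <- directionSplit(prof)
  expect_equal(sp$frac_up, c(0.75, NA))
  expect_equal(sp$frac_down, c(0.25, NA))
  expect_equal(sp$undefined, c(FALSE, TRUE))
})

test_that("a planted regulon tops the profile at its condition", {
  tgts <- sprintf("PL%02d", 1:15)
  regPlanted <- data.frame(tf = "MIEP", target = tgts, mode = "Activation",
                           references = "r", stringsAsFactors = FALSE)
  regOther <- simulateRegulons(5, c(10, 25), seed = 63)
  reg <- rbind(regPlanted, regOther)
  des <- studyDesign(data.frame(name = "X", class = "PFAS"),
                     list(X = c(1, 10, 100)), nGenes = 600)
  st <- simulateStudy(des, reg,
                      list(plantedEffect(tf = "MIEP", maxLog2FC = 2)),
                      noiseSd = 0.4, mode = "lognormal", seed = 64)
  tab <- buildFCTable(SummarizedExperiment::assay(st, "log2"),
                      sampleInfo(st))
  net <- buildMIENetwork(reg, data.frame(name = unique(reg$tf),
                                         sources = "x"), rownames(st))
  prof <- profileConditions(tab, net)
  top <- prof[prof$dose_mg_per_kg == 100 & prof$sex == "male", ]
  expect_identical(top$mie[which.max(top$n_total)], "MIEP")
  # planted all-up effect -> up fraction 1 at the planted condition
  sp <- directionSplit(top)
  expect_equal(sp$frac_up[sp$mie == "MIEP"], 1)
})
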