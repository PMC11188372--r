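# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by the most naive route available so
# they stay independent of the package implementation.

# Hand-coded Benjamini-Hochberg step-up (oracle for bhAdjust / p.adjust).
bhStepUp <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  # step-up: enforce monotonicity from the largest rank down
  for (i in rev(seq_len(n - 1L)))
    ranked[i] <- min(ranked[i], ranked[i + 1L])
  q <- numeric(n)
  q[o] <- pmin(ranked, 1)
  q
}

# Exhaustive brute-force dysregulation scan (oracle for countDysregulated).
bruteCountDysregulated <- function(fc, edges, mieNamesVec, upThr, downThr) {
  res <- NULL
  for (m in mieNamesVec) {
    tg <- character()
    for (i in seq_len(nrow(edges)))
      if (edges$mie[i] == m && !edges$target[i] %in% tg)
        tg <- c(tg, edges$target[i])
    nu <- 0L; nd <- 0L
    for (t in tg) {
      if (!t %in% names(fc)) next
      if (fc[[t]] >= upThr) nu <- nu + 1L
      if (fc[[t]] <= downThr) nd <- nd + 1L
    }
    res <- rbind(res, data.frame(mie = m, n_up = nu, n_down = nd,
                                 n_total = nu + nd))
  }
  res
}

# Naive average-linkage (UPGMA) agglomeration on Euclidean distance.
# Returns the list of merged clusters (as sets of row indices), in merge
# order: an oracle for the *tree*, independent of leaf-ordering conventions.
naiveUpgmaClusters <- function(m) {
  d <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  merged <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(clusters) - 1L))
      for (j in seq(i + 1L, length(clusters))) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < bestd) { bestd <- dij; best <- c(i, j) }
      }
    newc <- c(clusters[[best[1]]], clusters[[best[2]]])
    merged[[length(merged) + 1L]] <- sort(newc)
    clusters[[best[1]]] <- newc
    clusters[[best[2]]] <- NULL
  }
  merged
}

# A small two-class, two-sex design for fast end-to-end fixtures.
tinyDesign <- function(nGenes = 300L, doses = c(1, 10, 100),
                       nTreated = 5L, nControl = 10L) {
  studyDesign(
    data.frame(name = c("PFAS-A", "PAH-B"), class = c("PFAS", "PAH"),
               stringsAsFactors = FALSE),
    list("PFAS-A" = doses, "PAH-B" = doses),
    nTreated = nTreated, nControl = nControl, nGenes = nGenes)
}

# QC metrics row with comfortable values, for boundary perturbation.
goodQCRow <- function(sample_id = "s1") {
  data.frame(sample_id = sample_id, sequencing_depth = 1e6,
             total_alignment_rate = 85, unique_alignment_rate = 70,
             aligned_reads = 8e5, pct_probes_ge5 = 90,
             stringsAsFactors = FALSE)
}
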