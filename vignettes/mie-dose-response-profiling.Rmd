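---
title: "Methods: MIE target-gene dose-response profiling"
author: "MIEprofiler authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MIE target-gene dose-response profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MIEprofiler)
```

# The analysis in one paragraph

A chemical that initiates an adverse outcome pathway for hepatic steatosis
typically does so by engaging a molecular initiating event (MIE): binding
and (de)activating a transcription factor such as PPARα, HNF4α, NR3C1 or
AHR. The downstream fingerprint of an activated MIE is a coordinated shift
in its regulon. This package quantifies that fingerprint in a
dose-response design: per condition (chemical × dose × sex) it computes a
log2 fold change per gene against pooled vehicle controls, counts each
MIE's targets beyond a ±0.6 log2FC threshold, classifies each gene's
cross-chemical response pattern, flags dose-based trends, and scores
concordance with a weighted pathology signature.

# Preprocessing model and assumptions

**QC filtering.** A sample is excluded when any of five sequencing metrics
falls *strictly below* its threshold: sequencing depth and aligned reads
(300,000 reads), total alignment rate (40%), unique alignment rate (30%),
and percentage of probes with at least five reads (50%). The
strictly-below rule means a metric exactly at its threshold passes; the
boundary behaviour is pinned by tests on every metric. Thresholds are
exposed via `qcThresholds()`.

**Normalisation.** Counts are scaled to reads per million per sample, a
pseudo-count of one is added, and values are log2-transformed. The RPM
denominator is the sum over the genes present in the matrix — no external
total-read denominator is available at the gene level, so the library size
is defined by the analysed gene set. The `ExprMatrix` class carries a
scale tag (`counts` → `rpm` → `log2`) and each stage refuses input on the
wrong scale, which rules out double transformation by construction.

**Outlier flagging.** Replicate diagnostics (PCA, clustering, correlation
heatmaps) are traditionally inspected by eye; this package fixes one
reproducible rule instead: within each replicate group (chemical × dose ×
sex) of size ≥ 3, a sample is flagged when the *median* of its pairwise
Spearman correlations with its co-replicates falls below
`minMedianCorr = 0.8`. Groups of one or two samples are never flagged —
with two anticorrelated samples there is no quorum to decide which one is
aberrant. Spearman (rank) correlation makes the rule insensitive to
monotone distortions; the median makes it robust to one bad co-replicate.
The threshold is a config knob, 0.8 being a conservative default for
log-scale liver expression replicates.

**Extrapolation.** Targeted platforms measure a sentinel panel
(~1–3K genes); the whole transcriptome is predicted by principal-component
regression trained on a reference compendium. `fitExtrapolator()` centres
each measured gene across the compendium samples, computes the panel's
principal components (no scaling), and regresses every output gene on the
component scores by ordinary least squares — because scores are centred
and orthogonal this is one cross-product per gene. Defaults: the smallest
number of components explaining ≥ 95% of panel variance, capped at 100;
measured genes are passed through verbatim rather than re-predicted (the
observation is better than its projection). These defaults are this
package's own choices; they are not a reproduction of any external
extrapolation tool's internals, which are not publicly specified. The
linear factor model is exactly right for data generated by
`simulateCompendium()` and only an approximation for real compendia;
recovery guarantees (exact at the latent rank in the noiseless case,
held-out R² under noise) are verified by the acceptance suite at rank 5,
2,000 genes, 200 measured, 300 training samples.

# Differential expression

"Differentially expressed genes per dose" is implemented as a two-group
one-way ANOVA per dose: the treated group (n = 5) against that chemical's
vehicle controls of the same sex pooled across arms (n = 10). For two
groups the ANOVA F equals the square of the pooled-variance t statistic —
the suite asserts this equivalence to 1e-9 against `t.test()` on a
thousand random datasets. A global all-dose one-way ANOVA
(`anovaAcrossDoses()`) is available as an optional mode. Genes with zero
within- and between-group variance get p = 1 and are retained, so table
cardinality is stable at genes × conditions.

FDR uses Benjamini–Hochberg, adjusted **within condition across genes**
(`qFamily = "within_condition"`). The family choice is genuinely open —
adjusting across the whole study is defensible too and available via
`qFamily = "global"` — but the within-condition family matches how
per-dose fold-change tables are consumed downstream: each condition's
calls stand alone.

# Regulon ingestion and the MIE network

The TRRUST dialect is four tab-separated columns: TF, target, mode
(`Activation` / `Repression` / `Unknown`), references. Exact duplicate
rows collapse silently; a (TF, target) pair with *conflicting* modes
collapses to a single `Unknown` edge with a warning — dropping such edges
would shrink regulons for what is usually a curation artefact.

Cross-species symbol mapping applies a user-supplied table (one row per
source→destination pair; one-to-many entries fan out into one edge per
destination). Symbols absent from the table fall back to title-case
conversion (`ABCC3` → `Abcc3`), the standard human→rodent orthography; all
fallback and one-to-many events are itemised in a report. With an empty
mapping the operation is idempotent on already-converted symbols.

MIE-to-TF matching is case-insensitive exact symbol match. Receptor
aliases (GR vs NR3C1, SREBF vs SREBF1) are *not* resolved here: the MIE
list is expected to carry the TF symbol to match, because alias resolution
is a curation decision, not a string operation. MIEs with no edge in the
regulon table are retained with zero counts and a warning — in real
ingestions a substantial fraction of candidate MIEs has no TF annotation,
and silently dropping them would misrepresent the network's coverage.

# Profiling, classification, trends

**Counting.** Per MIE and condition, targets with log2FC ≥ 0.6 count as
up, ≤ −0.6 as down; both boundaries inclusive. Counting ignores regulation
mode by default (published per-MIE tables count both directions together);
`modeAware = TRUE` restricts to mode-concordant dysregulation. Each MIE
counts its own distinct targets — a gene regulated by two MIEs contributes
to both, since each row of the profile answers "how disturbed is *this*
regulon".

**Pattern classification.** For each gene, the top-dose fold change in
every (chemical, sex) cell is reduced to a sign and a pass flag
(|FC| ≥ 0.6). Patterns are evaluated in precedence order consistent >
sex-dependent > class-dependent: a gene responding identically everywhere
is *also* sex-consistent within each sex, so without precedence the
categories overlap. `minSupport` is the fraction of cells that must pass
the threshold: the default 1.0 demands every cell pass; 0.75 is a relaxed
mode for screening, since verbal descriptions of "consistent" responses
tolerate an occasional sub-threshold cell. A fold change of exactly zero
carries no sign and breaks any consistency requirement (a deterministic
tie rule is needed; zero is the only defensible neutral point).

**Dose trends.** The qualitative rule "fold change moves in one direction
as dose increases" is operationalised over the top `window = 3` doses:
one sign throughout, |FC| non-decreasing with dose up to a tolerance, and
top-dose |FC| ≥ 0.6. The tolerance (default 0.3 log2 units) is the one
genuinely numerical choice: fold-change estimates at n = 5 vs 10 with
per-sample noise sd 0.3 have a standard error of
`0.3·√(1/5 + 1/10) ≈ 0.16`, while the planted dose-shape increments
between the top three doses of a nine-point ladder are ≈ 0.125 — strict
monotonicity of noisy estimates would reject roughly half of genuinely
monotone genes, so a tolerance of about two standard errors is required
for the detector to have useful power, while the top-dose threshold keeps
the null flag rate negligible (a null gene must still reach |FC| ≥ 0.6,
a > 3.6σ event, with a consistent sign). Window, tolerance and threshold
are all exposed.

**Signature concordance.** At a condition, a signature gene is significant
iff q < 0.1 (strict); significant genes are `concordant` when
sign(FC) = sign(weight), `discordant` otherwise; non-significant genes and
genes absent from the table are reported as such rather than silently
dropped.

# The synthetic-data generator

`simulateStudy()` emulates the design of a five-day repeat-dose rat study:
four chemicals (three PFAS, one PAH) with nine-point dose ladders in mg/kg
(0.15–1,000; one chemical on a lower 0.07–475 ladder), both sexes, n = 5
treated per group, and n = 10 vehicle controls per (chemical, sex) shared
across that chemical's arms — `defaultStudyDesign()` encodes exactly this.
Latent per-sample log2 expression is gene baseline + planted effect +
Gaussian noise (`noiseSd`, default 0.5 log2 units, a typical
inter-animal spread for liver transcriptomics). Planted effects scale
along the ladder by either `linear_in_log_dose`
(effect ∝ log(d/dmin + 1), normalised to the maximum at the top dose) or a
`hill` curve with EC50 at the geometric mid-dose; both are monotone, so
trend detection has clean ground truth. Sex-dependent genes use per-sex
direction overrides; class-dependent genes use two entries with disjoint
class scopes (entries covering the same gene must have disjoint
sex × class scopes — overlapping scopes would make the planted truth
ambiguous).

Counts are produced by Poisson thinning: latent log2 values are mapped to
intensities on a million-read scale and sampled at a library size drawn
from `libsizeRange`. Poisson is a deliberate stand-in — the real
platform's dispersion model is not published — so a `lognormal` mode also
returns the latent log2 matrix directly for stages that only consume log2
values; all calibration claims against closed-form normal tails use that
mode. The truth table records the exact planted mean effect for every
(gene, chemical, dose, sex); unplanted combinations are implicitly zero.

What the generator does **not** emulate: batch effects, probe-level
ambiguity, count overdispersion, correlated gene modules beyond the
planted regulons, and realistic library-size/QC-metric joint
distributions. Passing tests therefore demonstrate correctness of the
machinery and calibration under the stated noise model, not performance on
real platform data.

# Problem sizes and determinism

The test and acceptance suites run at deliberately scaled sizes chosen to
give the statistical checks adequate resolution: 2,000-gene null studies
for tail calibration, 100 simulated studies for planted-MIE recovery,
five replicate 1,300-gene studies (100 genes per planted pattern, 1,000
null genes) for pattern recovery — a single study estimates a ~94%
recovery rate with ±2.5 points of Monte Carlo error, so rates are averaged
over replicates — and a 2,000 × 300 rank-5 compendium for extrapolation.
All generators take an explicit seed and fixed seeds reproduce study
bundles byte-identically; the pipeline writes TSV floats rounded to six
decimals so that golden-file comparison is exact, and the run manifest
records config echo, seed, input hashes and per-stage counts without
timestamps or absolute paths, keeping reruns byte-identical.

# Known limitations

- The per-dose two-group ANOVA ignores the shared-control correlation
  between doses of the same chemical and sex; condition-level q-values are
  therefore not independent across doses.
- The extrapolator is strictly linear; non-linear structure in a real
  compendium ends up in the residual.
- Pattern classification consumes only top-dose fold changes; a gene with
  a strong mid-dose response and a flat top dose is called `none`.
- A response present in one chemical class and absent (rather than
  opposite) in the other is deliberately *not* `class_dependent`; the
  class contrast requires opposite signs.
- No enrichment statistics are computed on the per-MIE counts; the counts
  are descriptive, and their null level must be judged against the
  calibration quantities the acceptance script reports.
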