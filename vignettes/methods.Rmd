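---
title: "Methods: models, parameters and design choices in regconverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in regconverge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Skeletogenic mesenchyme arises three times in the vertebrate embryo — from
the cranial neural crest, the somites and the lateral plate mesoderm — and
in each case precursor cells (PC) differentiate into early chondrogenic
cells (EC) that express one shared gene programme. `regconverge`
implements the quantitative machinery for dissecting this convergence in
paired single-cell RNA and ATAC data: whether transcriptomes converge
(pseudobulk co-clustering), which *trans* inputs stay lineage-specific
(TF-restricted correlation, motif deviations, motif-variant similarity),
which *cis* inputs do (differential peak categories, promoter-versus-distal
similarity, peak-to-gene links), and how the programmes unfold in time
(pseudotime binning and cross-lineage trajectory alignment).

# The synthetic cohort model

Every analysis stage is verified against a generator
(`sim_config()` / `simulate_cohort()`) that plants the convergence
structure with a recorded ground truth. Its model, per cell with latent
pseudotime $t \sim U(0,1)$:

* **RNA counts** are negative binomial with
  $\log \mu_{gc} = \beta_g + e_{gc} + \log d_c$, dispersion (`size`)
  `nb_dispersion = 2` and a per-cell log-normal depth factor $d_c$
  (`depth_lognormal_params = c(0, 0.35)`).
* **Shared chondrogenic module** (17 + 41 genes, plus `n_shared_tfs = 6`
  convergent TF genes): $e_{gc} = a_g \,\sigma(t_c)$ in *every* lineage,
  where $\sigma$ is a logistic rise with midpoint `chondro_midpoint = 0.65`
  (pseudotime units) and slope scale 0.1.
* **Lineage TF programmes** (8 genes per lineage): a Gaussian bump centred
  at `tf_bump_center = 0.35` (SD 0.25) plus a persistent offset, active
  only in the TF's own lineage — the TF wave precedes the module's rise,
  and the offset keeps the TF a lineage marker across the whole
  trajectory. The constructor rejects configurations with
  `tf_bump_center >= chondro_midpoint`.
* **Amplitude heterogeneity.** Every planted amplitude is
  $a_g = \texttt{effect\_size\_logfc} \times U(0.6, 1.4)$ (natural-log
  units, default 2.5). Heterogeneity is essential, not cosmetic: Spearman
  correlation between pseudobulks is driven by the *ordering* of feature
  values, and a module whose genes all rose by the same factor would not
  change that ordering — shared gene-specific amplitudes are what make EC
  pseudobulks recognisably similar. The default of 2.5 makes the planted
  module recoverable through the logFC > 0.5 marker gate, whose
  `ln((mean+1)/(mean+1))` convention compresses measured fold changes well
  below the planted ones.
* **Composition balance.** Planted-up genes rest at low expression, and a
  progenitor programme (`n_pc_genes = 45` highly expressed genes,
  `n_pc_daps = 150` open distal peaks) declines along $t$ in every
  lineage. This mirrors real differentiation (progenitor programmes shut
  down) and keeps per-cell totals roughly constant: in a 500-gene
  simulation, an unbalanced rising module would drag the depth-normalised
  values of *all* flat features downward together and manufacture
  spurious peak–gene correlations — an artifact that is negligible
  genome-wide but dominant at this scale.
* **ATAC counts** are Poisson with the analogous structure: module/shared
  promoters and shared CREs open with $\sigma(t)$ everywhere;
  lineage-specific distal DAP blocks and link CREs open only in their
  lineage; progenitor peaks close; `atac_depth = 3` puts ~3,000 in-peak
  fragments per cell, typical of real scATAC and inside the 1,000–100,000
  QC range. Fragments are materialised with a bimodal length mixture
  (nucleosome-free ≈ N(90, 20) clipped to 50–140 bp, mono-nucleosome
  ≈ N(210, 25) clipped to 160–280 bp) plus ~20 % off-peak background.
* **Genome layout.** One shared chromosome plus one per lineage; genes sit
  in 600-kb slots so the ±250-kb link windows of neighbouring genes never
  overlap, which makes the planted link truth exact. Ground truth records
  every co-driven peak–gene pair inside a window (distal CREs *and* the
  promoters of module, TF and progenitor genes).
* **Motifs.** Each TF gets a sharp random core (length 8–14 within the
  8–22 bp de-novo range); "de-novo-like" variants add uniform flanks, and
  the convergent TFs additionally get lineage-specific 5′ heterodimeric
  extensions in mesenchymal contexts but exact copies in non-mesenchymal
  contexts — planting the expectation that mesenchymal same-TF motif pairs
  are *less* similar across lineages.
* **Conservation.** A 10-bp piecewise-constant track over the peak set,
  drawn around `shared_mean = 0.65` on shared elements and
  `specific_mean = 0.25` elsewhere (SD 0.08, clipped to (0, 1)), encoding
  the common-elements-are-more-conserved ordering as plantable truth.

What the generator does **not** emulate: doublets, ambient RNA, batch
effects beyond depth, read-level sequence context (motif occupancy is a
planted hit matrix unless toy sequences are scanned), isoforms/exon
structure (the gene-body category is "intronic"), and cell-type
heterogeneity beyond the PC → EC axis. Tests passing on this cohort show
the *algorithms* behave as specified under the planted model; they do not
certify performance on the full messiness of real tissue data.

# Stage-by-stage notes and numerical choices

## Quality control

Sample-level statistics (mean, median, unscaled MAD, max genes detected)
are computed once on the input population and reported; re-filtering a
kept subset with the frozen statistics is exactly idempotent. The MAD
carries no 1.4826 consistency factor. The genes-per-UMI rule reads the
"count-to-genes ratio" as genes detected / total UMI (the literal inverse
could never fall below 0.15); the exception spares cells detecting at
least 2/3 of the sample maximum of genes — the alternative literal reading
(spare cells *below* 2/3 of the maximum, which disables the rule for
nearly all cells) is selectable via `ratio_exception = "low_detected"`.
TSS enrichment uses a ±50 bp core against 1901–2000 bp flanks with
pseudocount 0.1 — the score is named but not defined in common usage, so
the conventional window sizes are adopted. All boundary comparisons are
strict except the closed 1,000–100,000 fragments-in-peaks range.

## Normalisation, variable features, module scores

`normalize_log()` is `ln(1 + 1e4 * count / total)`; the scale factor and
natural log are conventions (config-exposed). `select_hvg()` standardises
each feature by a loess trend (span 0.3, degree 2) of log10 variance on
log10 mean, clips standardised values at $\sqrt{n}$, and keeps features
whose standardised variance exceeds median + MAD; the rule is applied per
input matrix. Module scores are Tirosh-style: module mean minus the mean
of `n_ctrl = 100` controls per gene drawn from the same
average-expression bin (24 equal-frequency bins), seed-controlled.

## Marker testing

The likelihood-ratio test fits the covariates-only null once per contrast
and one penalised-free logistic fit per feature (`stats::glm.fit`).
(Quasi-)separated fits — non-convergence, |coefficient| > 15, or
near-zero deviance — fall back to a ridge-penalised Newton solver
(λ = 0.01 on non-intercept terms) and are flagged. Bonferroni is the
default adjustment with BH selectable, since only "adjusted p-value" is
specified. Stage labels enter as latent covariates; the generator draws
stages as overlapping collection batches precisely so that a latent batch
term does not absorb the biological contrast, as a deterministic
pseudotime tertile would.

## Peaks

Fixed-width finalisation requires an odd width (501 default) so the summit
is an integer centre; windows spilling past chromosome ends are dropped,
not truncated, preserving the width invariant. Iterative overlap removal
keeps, repeatedly, the most significant remaining peak and discards
everything overlapping it (ties by chromosome then start); tests verify
equality with an $O(n^2)$ greedy oracle. The promoter window is
strand-aware TSS −2000/+100 (a common convention; configurable), with
category precedence promoter > intronic > intergenic. The
promoter-versus-distal comparison draws `n_resamples = 80` equal-size
distal samples per lineage pair; nothing in the package assumes a
particular decomposition of that figure count.

## Trajectory alignment

Bins are equal-width over the observed pseudotime range
(`cut(..., include.lowest = TRUE)` conventions); empty bins are dropped
with a warning, and interpolation runs between bin *centres*. The
dissimilarity between interpolated positions is 1 − Spearman ρ across
shared features. Open-ended DTW uses steps {(1,0), (0,1), (1,1)} with free
start and end anywhere on the boundary rows/columns; among all boundary
cut pairs the path minimising the *mean* dissimilarity along the path is
found exactly by Dinkelbach fractional programming (iterating
λ ← cost/length of the path minimising cost − λ·length; each iteration is
one dynamic-programming pass). Ties are broken toward the diagonal
continuation and a path never restarts at equal cost — without this,
rank-degenerate grids (exact zeros off the diagonal) would admit
non-diagonal zero-cost paths and the self-alignment identity would be
ill-posed. Cut-off terminal indices are reported as unmatched, never
hard-coded. Pseudotime transfer is a correlation-kNN simplification of
anchor-based label transfer: features z-scored jointly across both cell
sets, Spearman similarity, weights (ρ+1)/2 over the k nearest RNA cells
(k = 10 in the function signature; the pipeline uses k = 50, which
averages away more of the per-cell gene-activity noise).

## Motifs

Column information content is $2 + \sum_b p_b \log_2 p_b$ bits against a
uniform background; trimming strips terminal runs below
`min_ic = 0.25` bits (no threshold is standard, so it is configurable)
and refuses to shorten a matrix below 4 columns. Similarity is the mean
column-wise Pearson correlation maximised over all ungapped offsets with
overlap ≥ max(5, ⌈0.75 · min(L)⌉) and over the reverse complement;
zero-variance columns contribute 1 when identical and 0 otherwise.
Deduplication applies the > 0.8 rule to *trimmed* matrices by default
(flanks carry no evidence of shared binding). Deviation z-scores follow
the bias-corrected scheme: expected counts proportional to the motif's
share of total accessibility times cell depth, raw deviation
(obs − exp)/exp, and `n_background = 50` matched peak sets built by
replacing each member peak with one of its 50 nearest neighbours in
z-scored (GC, log mean accessibility) space. Annotation aggregates are
k = 50 cells × n = 400 draws (k cells *per aggregate*, n aggregates — the
reverse reading of "k, n" is honoured by swapping the arguments), sampled
uniformly with replacement; candidates need similarity ≥ 0.6 and
detection in ≥ 5 % of cells, and are ranked by Spearman ρ between
aggregate mean deviation and aggregate mean expression, ties broken by
similarity then name.

## Peak-to-gene links

Candidates are peaks whose centre lies within ±250 kb of a TSS; Pearson r
over aggregate means, p from the t distribution with
(n aggregates − 2) df, BH per lineage, retained at r ≥ 0.45 and
FDR < 1e-4. The correlation and FDR cutoffs are package defaults — the
source analyses state that cutoffs exist without printing values — and are
fully configurable. The pipeline builds aggregates in kNN mode seeded
along pseudotime (each aggregate pools developmentally similar cells, so
aggregate means span the trajectory instead of averaging it away) and
applies a redundancy filter dropping aggregates that share more than 80 %
of their members with an already-kept one. The filter matters
statistically: 500 overlapping aggregates of 100 cells drawn from 1,500
contain roughly 15 effectively independent windows, and the nominal
t-test is then wildly anticonservative for features whose
between-aggregate variation is smoothed sampling noise; filtering restores
an honest degrees-of-freedom count. `hkmeans_links()` initialises k-means
with a Ward (ward.D2) cut and refines by Lloyd iterations
(tolerance 1e-6, ≤ 100 iterations), making the clustering deterministic;
k is a config choice and the objective trace serves as an elbow
diagnostic. Conservation means are per-base weighted averages; bases
missing from the track score 0 and are flagged.

## Pipeline and problem sizes

`run_pipeline()` chains sim → qc → pseudobulk/differential → peaks →
trajectory → motifs → links and emits a JSON-serialisable report. The
default cohort is 3 lineages × 1,500 cells, 500 genes and 1,200 peaks —
deliberately compact: the simulations behind the test suite use 300–1,500
cells per lineage and the motif-deviation stage subsamples 500 cells per
lineage, sizes at which every planted pattern is comfortably detectable
while a full run stays in the minutes range on a single CPU. All
stochastic steps take explicit seeds; no function consults global RNG
state without restoring it.

# Known limitations

* The logistic-regression marker test treats cells as independent;
  pseudobulk replicate testing across lineages is approximated by running
  the same test on aggregate profiles rather than a dedicated
  pseudobulk-DE model.
* The pseudotime transfer is a deliberate simplification of anchor-based
  transfer; its accuracy is bounded by the information in a single cell's
  gene-activity profile.
* `scan_motifs()` scores toy sequences with a 0-order uniform background;
  it is a verification tool, not a genome-scale scanner.
* The conservation track is piecewise-constant synthetic ground truth;
  real per-base tracks (e.g. phastCons bedGraphs) are read by the same
  interface but carry their own biases.
* Trajectory *inference* is out of scope: pseudotime is an input column,
  either synthetic truth or user-provided.
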