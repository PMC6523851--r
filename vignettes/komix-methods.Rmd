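---
title: "Methods: joint functional analysis of microbiome and host in KO space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint functional analysis of microbiome and host in KO space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(komix)
```

# The problem

A treatment study that profiles both the gut microbiome (16S rRNA OTU
counts) and host blood transcriptomes (log-scale mRNA) produces two feature
spaces with no common identifiers. `komix` moves both into KEGG Orthology
(KO) space — cross-species functional gene families — so that a single
enrichment question can be asked of the microbiome, the host, and their
union: *which KEGG pathways are differentially active under treatment, and
which transcripts and taxa drive them?*

This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the synthetic validation demonstrates.

# KO inference from 16S profiles

Microbial KO abundances are inferred with the classic gene-content
projection. Each OTU's read count is first divided by its genome's 16S
rRNA gene copy number (read abundance over-represents taxa with many 16S
operons; division approximates organism abundance). The normalized table is
then projected through a per-genome gene-content matrix:

$$\mathrm{ko}(k, s) \;=\; \sum_{o} \frac{\mathrm{otu}(o, s)}{\mathrm{copies}(o)}\,
\mathrm{content}(o, k).$$

The summands are kept as a long-format *contribution table* `(otu, ko,
sample, contribution)` with zeros omitted; by construction the per-(KO,
sample) sums reconstruct the prediction exactly (tested to 1e-9 relative),
which is what later allows an enriched pathway to be attributed to specific
taxa. Pathway abundances are plain sums of member-KO abundances; a KO in
several pathways contributes its full abundance to each. Predictions are
kept as reals; `round_predictions = TRUE` restores legacy integer rounding
for parity with older inference tools, at the cost of feeding quantized
values into the differential stage. No prediction-confidence score (NSTI)
is computed — the pipeline does not consume one.

Genus aggregation follows the 7-rank Greengenes taxonomy convention: OTUs
sum over the `g__` field; an OTU with an empty genus is pooled into
`unclassified_<lowest named rank>` (e.g. `unclassified_S24-7` for an OTU
classified only to that family), so column sums are conserved.

# The uniform differential engine

All feature tables — OTU, genus, KO (counts) and expression (log2) — pass
through one engine, so that gate semantics and moderation are identical
across omics.

**Count transform.** Counts are converted to
$y = \log_2\!\big((c + 0.5)/(L + 1)\cdot 10^6\big)$ with $L$ the library
size. A group-means model is fitted per feature; the LOWESS curve (span
0.5, 3 robustness iterations) of $\sqrt{s_g}$ (square root of the residual
SD) on average log2 count forms the mean–variance trend, and every
observation's fitted log2 count is mapped through the trend into a
precision weight $\mathrm{trend}(\cdot)^{-4}$. The trend is clamped to its
boundary values outside the fitted range, and floored at $10^{-6}$ so
weights stay finite. Fewer than 10 features triggers a warning (the trend
is then unstable); if every feature is identical the trend degenerates to a
constant and all weights are equal.

**Moderated statistics.** Per feature, a weighted group-means fit over
*all* design groups gives the contrast coefficient
$\beta = \bar{y}_A - \bar{y}_B$, its unscaled standard error
$u_g = (W_A^{-1} + W_B^{-1})^{1/2}$ (group weight totals $W$), and the
residual variance $s_g^2$ on $d_g$ df. The empirical-Bayes prior
$(d_0, s_0^2)$ is estimated by moment matching on $\log s_g^2$: the excess
variance of $e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$ over
$\psi'(d_g/2)$ determines $d_0$ through Newton inversion of the trigamma
function (tolerance 1e-10); when the observed spread does not exceed what
$d_g$ df alone produce, $d_0 = \infty$. The posterior variance
$\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ yields
$t = \beta/(u_g \tilde{s}_g)$ on $d_0 + d_g$ df, two-sided p, and the 95%
CI $\beta \pm t_{0.975,\,d_0+d_g}\, u_g \tilde{s}_g$.

Numerical guards, chosen for degenerate synthetic inputs rather than tuned
to any outcome: exact-zero residual variances (identical replicates) are
floored at the 1st percentile of the positive variances (1e-8 if none
exist); p-values are clamped into (0, 1] against underflow. With
`prior_df = 0` the engine reproduces the ordinary equal-variance t-test
exactly; with `prior_df = Inf` it reproduces the pooled-prior closed form
$t = \beta/(u_g s_0)$. A subtlety documented here because it is easy to
mistake for a bug: when all $s_g^2$ are *equal*, the log-scale moment
estimator returns $d_0 = \infty$ with
$s_0^2 = s^2 \exp(\log(d/2) - \psi(d/2)) \neq s^2$, so the moderated t
differs from the ordinary t by the deterministic factor
$\exp\!\big((\log(d/2)-\psi(d/2))/2\big)$, which tends to 1 as $d$ grows.
The test suite asserts this exact relationship.

**Gate.** A feature is called up if $\log_2\mathrm{FC} \ge 1$ (fold change
≥ 2) and raw $p \le 0.05$, down symmetrically. The p gate is inclusive by
default and configurable to strict. Deliberately, *no* multiple-testing
correction enters the gate — the design philosophy is to retain potentially
meaningful features in small-n studies for downstream enrichment, where
significance is re-assessed at the pathway level; a BH-FDR column is
emitted for information only. The log2FC for count tables is the model
coefficient on the log2-cpm scale, not a ratio of raw means.

Samples are internally ordered by (group, sample id) before any row-wise
accumulation, which makes results bit-identical under sample permutations.

# KO sets, enrichment, and the background universe

Host differential genes map to KOs through a static two-column file
(offline by design: a live database lookup would make runs irreproducible;
a helper outside the tested core can regenerate the file). Direction
conflicts — a KO reached from both an up and a down source, within one omic
or across the two — are kept in the ALL set, flagged, and excluded from
UP/DOWN.

Enrichment uses the EASE score: the one-sided Fisher exact p computed after
removing one hit, i.e. the upper hypergeometric tail of
$(k-1,\; n-k,\; K-k,\; N-K-n+k)$ where all margins shrink by one. The
penalty makes single-hit pathways unrankable ($p = 1$ for $k \le 1$) and is
always conservative relative to the unpenalized Fisher test. The
penalization variant (margins reduced with the hit) is isolated in
`ease_score()`; `variant = "fisher"` gives the unpenalized test.

The single most consequential declared choice is the background universe
$N$: the KOs *measured* in the relevant omic (predicted KO table for the
microbiome; KOs reachable from measured genes for the host) *and* annotated
to at least one pathway. Joint runs use the union of the two universes.
Pathways with fewer than `min_size = 3` measured KOs are skipped. Raw EASE
p-values are reported with star annotations (≤ 0.05 / ≤ 0.01 / ≤ 0.001); no
multiple-testing correction is applied at the pathway level either, which
is why the null-calibration and planted-truth validation below matter.

Deconvolution resolves each significant joint pathway into (i) host genes,
from the provenance of its hit KOs, annotated with their own direction
calls; and (ii) genera, by summing the contribution table over the hit KOs
and all samples, annotating each genus with its genus-level differential
direction, and ordering by contribution share (shares sum to 1 per
pathway). A gene that failed the differential gate is absent from
provenance and therefore cannot be attributed, even if its KO was detected
through the microbiome — attribution never outruns detection.

# The synthetic study generator

The generator's defaults define the study conditions used throughout the
validation: four arms (healthy control, disease model, and two therapy
arms: NOCIA / CIA / MS / MTXMS) of 5 samples each, with the four pairwise
contrasts CIA-NOCIA, MS-CIA, MTXMS-CIA, MS-MTXMS (a contrast `A-B` means
log2FC = mean(A) − mean(B)); 300 OTUs sequenced at 15,000 reads/sample;
negative-binomial counts with variance $\mu + \alpha\mu^2$, $\alpha = 0.1$;
log-normal baseline relative abundances (sdlog 1.5); 400 microbial KOs with
90% gene-content sparsity and 16S copy numbers uniform on 1–5; 600 host
genes with gaussian log2 expression (residual SD 0.5); 40 pathways of 12
KOs. Planted effects are |log2FC| = 2 — chosen so planted features clear
the fold-change gate with the study's power, which is the regime the
pipeline is built for. The arm count, per-arm n, depth and effect size
mirror a small animal cohort; dispersion 0.1 and the content sparsity are
ordinary values for 16S data and microbial pangenomes.

Planted enriched pathways are realized as *cassettes*: a planted pathway's
12 KOs receive gene content only from 6 dedicated OTUs, themselves planted
differential in the pathway's contrast and direction, and 4 planted host
genes are wired to the same KOs through the map. Construction therefore
guarantees the ground truth for deconvolution: the cassette OTUs are the
sole contributors of the cassette KOs. Extra planted OTUs and genes outside
any cassette provide background differential signal. A single master seed
derives per-stage substreams, so bundles are byte-identical across runs;
`effect_log2 = 0` plants nothing and yields a global-null study.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: phylogenetic correlation between OTUs,
compositional coupling beyond the shared sequencing depth, gene-content
error (real 16S-based inference mispredicts content for taxa far from
reference genomes), overlap structure of real KEGG pathways, and
batch/covariate effects. Recovery rates on cassettes are an upper bound on
real-data behavior, not an estimate of it; the published p-values of any
specific real study are additionally unrecoverable without its exact
database versions and background universe.

# Validation design and problem sizes

The acceptance suite (also re-runnable via `scripts/acceptance.R`) checks:

- **EASE oracle equivalence** — exhaustive enumeration over all margins
  $N \le 40$ (~260k instances) plus 1,000 random instances up to
  $N = 10{,}000$, agreement to 1e-12.
- **Prediction conservation** — 200 random instances against a triple-loop
  oracle (1e-12) and contribution sums (1e-9 relative).
- **Null calibration** — 20 global-null studies at 2,000 OTUs and 2,000
  genes: pooled fraction of raw $p \le 0.05$ within 0.05 ± 0.01 per table;
  no enrichment at $p \le 0.001$ in ≥ 19/20 seeds. (Per-seed
  Kolmogorov–Smirnov uniformity is asserted on the expression table, whose
  gaussian model is exact; the count transform is an approximation whose
  small systematic deviation a 2,000-feature KS test detects even when the
  gate calibration is inside the band.)
- **Planted recovery** — 100 studies at the default conditions: a seed
  passes if all 3 planted pathways reach EASE $p \le 0.05$ in the planted
  comparison and direction *and* every recovered pathway's deconvolution
  lists ≥ 80% of its cassette genera and planted genes; ≥ 90% of seeds must
  pass.
- **Moderated-statistic correctness** — 95% CI coverage within ± 1.5% over
  10,000 feature replicates; exact d₀ = 0 and d₀ → ∞ limits.
- **Gate semantics and determinism** — threshold boundary cases, and
  byte-identical output trees for identical config + seed.

These sizes were chosen as the smallest that give the Monte-Carlo
assertions comfortable margins (binomial SE well below each band).

# Known limitations

- The engine fits group-means models only: no covariates, batch terms,
  random effects or time-course structure.
- Copy-number and gene-content tables are taken as ground truth; no
  uncertainty propagates from the 16S inference into the differential
  stage.
- The uncorrected gate is liberal by construction; interpretation should
  rest on the pathway-level results and their deconvolution, not on
  individual feature calls.
- EASE p-values are reported raw; with ~40 pathways × several conditions,
  isolated `*` entries are expected under the null (the validation bounds
  only `***`).
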