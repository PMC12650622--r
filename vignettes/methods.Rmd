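---
title: "Methods: concordant DEGs, summary-data MR, diagnostic panels and reporter metabolites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concordant DEGs, summary-data MR, diagnostic panels and reporter metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdmr)
```

# The problem this package addresses

Biallelic loss of *GBA1* causes Gaucher disease; heterozygous *GBA1*
variants are the strongest common genetic risk factor for Parkinson's
disease (PD). If the two disorders share a transcriptional programme,
some of the shared genes may sit on the causal path to PD rather than
merely reacting to it. `pdmr` implements the full analytic chain for
that question: find genes that are differentially expressed in the same
direction across independent datasets of Gaucher disease,
*GBA1*-associated PD and sporadic PD; test the shared genes for causal
effects on PD risk with cis-eQTL-instrumented two-sample Mendelian
randomisation (MR); evaluate the prioritised genes as diagnostic
classifiers; and project the expression changes onto a genome-scale
metabolic model to find metabolic "hotspots". Each stage is usable on
real externally derived inputs (differential-expression tables, eQTL and
GWAS summary statistics, GMT collections, COBRA-JSON/SBML models) and on
synthetic inputs with known ground truth.

# Concordant differential expression

Per-dataset DEG calling is a pure threshold filter: FDR < 0.05 and
|log2FC| ≥ 1 (`call_degs`), both configurable. Cross-dataset
harmonisation deliberately avoids merged expression matrices and
meta-analytic effect pooling — only the identity and direction of
significant genes travel across datasets. A gene enters a condition's
shared set when it qualifies in at least `min_datasets` (default 2)
datasets of that condition with one direction; a direction conflict in
*any* qualifying dataset of the condition excludes the gene (the strict
reading of "consistently"). Pairwise and three-way concordant sets then
intersect the per-condition sets requiring identical direction.
Magnitude plays no role beyond the calling threshold: direction is sign
of log2FC only. Gene identity is whatever identifier the input tables
use; no symbol remapping is attempted. A "subset" analysis (e.g.
restricting to neuronal datasets) is expressed by re-running
`shared_degs` on the subset with the same rule, not by a special mode.

The internal DE test (`differential_expression`) exists so synthetic
data can flow end to end: Welch's t per gene on log2(CPM+1) with BH
adjustment, zero-variance genes forced to p = 1. Real-data users are
expected to supply tables from dedicated DE tools.

# Two-sample Mendelian randomisation

## Instruments

`select_instruments` filters exposure records in the order p-value →
MAF → F-statistic → LD pruning. The order is not dictated by the
method (the first three filters commute); it was chosen so the LD
pruner only sees eligible SNPs, and every exclusion is written to a
provenance log so alternative orders can be audited. Defaults:
p < 5×10⁻⁶, MAF > 0.01, F = β²/SE² > 10, pairwise r² < 0.3. Note that
the defaults make the p filter subsume the F filter (p < 5×10⁻⁶ implies
F > 20.8); the F rule still matters whenever either threshold is
changed. LD pruning is greedy by ascending p — the de-facto standard:
keep a SNP iff its declared r² with every already-kept SNP is below
threshold; pairs absent from the LD table count as independent. Genes
with fewer than two surviving SNPs are flagged
`insufficient_instruments` and reported, never silently dropped.

## Harmonisation

`harmonise` aligns outcome records to the exposure's effect allele:
exact match, swapped alleles (sign and EAF flipped), or
complementary-strand variants of either. Palindromic (A/T, C/G) SNPs
cannot be strand-resolved from alleles; they are dropped when the
exposure MAF exceeds 0.42 and otherwise oriented by comparing which
allele is minor in each study. When exposure and outcome EAF disagree
for a retained palindrome, the exposure EAF governs. The
reverse-causation screen excludes a SNP iff its outcome association is
both genome-wide suggestive (p < 5×10⁻⁶) *and* stronger than its
exposure association — the conjunctive reading of "more strongly
associated with the outcome than with expression"; each sub-rule can be
toggled independently, which matters for estimator-stress experiments
(see the acceptance section). Harmonisation is idempotent on its
retained records.

## Estimators

All estimators consume the per-SNP Wald ratios rⱼ = β_out,j/β_exp,j
with first-order delta SE se_out,j/|β_exp,j| (exposure-side error is
ignored, the NOME approximation — adequate here because instruments are
required to be strong).

* **IVW** (primary): precision-weighted mean; fixed-effect SE
  (Σwⱼ)^(−1/2). If Cochran's Q (df = n−1) has p < 0.05 the SE is
  inflated by √(Q/df) floored at 1 — the multiplicative random-effects
  convention of summary-data MR; additive random effects are out of
  scope.
* **MR-Egger**: WLS of β_out on β_exp with intercept, weights 1/se_out²,
  after orienting all β_exp ≥ 0. Slope = causal estimate; the intercept
  and its p-value form the directional-pleiotropy test. Inference uses
  the regression t distribution (df = n−2). A design in which all
  oriented exposure effects coincide is flagged degenerate.
* **Weighted median**: order the ratios; the estimate sits where the
  normalised cumulative weight crosses 0.5, linearly interpolated
  between bracketing ratios. SE by seeded parametric bootstrap
  (resampling β_exp and β_out from their reported normals;
  `n_boot = 1000` default).
* **Simple mode**: argmax of an unweighted normal-kernel density over
  the ratios. The bandwidth is `bandwidth_factor` × 0.9·s·n^(−1/5) with
  s = min(sd, MAD) of the ratios (falling back to the SD when the MAD
  degenerates to zero); the factor defaults to 1 and is exposed because
  no canonical value exists.

`run_mr_panel` composes the stages per gene, computes OR = exp(β̂) with
normal 95% CIs on the per-SD-of-expression scale, and applies BH FDR to
the IVW p-values across the genes of one tissue; blood and brain panels
are run (and corrected) separately by passing separate inputs, matching
the separate-reporting convention. α = 0.05 throughout.

## Scale assumption

Exposure effects are treated as per SD of expression, so β̂ and the OR
read "per one-SD increase in genetically proxied expression". eQTL
sources do not always print their scale; if an input is on another
scale the estimates rescale accordingly (all four estimators are
exposure-scale-equivariant, a tested property).

# Diagnostics

AUCs use the Mann–Whitney identity with midranks; variances, CIs and
paired tests use DeLong structural components (V10/V01), with CIs
clipped to [0,1] and degenerate zero-variance cases flagged rather than
papered over. Single-gene evaluation fits one-predictor logistic
models and reports the AUC of the fitted case-probability — AUC is
invariant to the monotone link, so this equals the oriented
raw-expression AUC; scores are never silently reoriented by
max(AUC, 1−AUC). Single-gene AUCs are in-sample by default (the
cross-validated alternative is the panel path), a deliberate choice
where the field's practice is ambiguous.

The multi-gene panel is an L1-penalised logistic regression evaluated
by nested stratified cross-validation, `k_outer = k_inner = 5` by
default (a common choice; the fold counts are exposed because no value
is canonical). Within each outer-training part, features are
standardised (training statistics only — no leakage), a 100-point
log-spaced λ grid is built from that part's λ_max down four decades,
and inner CV selects λ by the one-standard-error rule on binomial
deviance (the loss the rule originates from; AUC-based selection is
available by flag). Out-of-fold probabilities are pooled — each sample
predicted exactly once — into a single ROC/AUC with DeLong CI.
Gene-vs-panel comparisons are DeLong paired tests BH-corrected across
genes. Path fitting is delegated to `glmnet`; fold construction, the
inner loss, the 1-SE selection and the pooling are this package's own.

# Reporter metabolites

Gene p-values become one-sided Z-scores, Z_g = Φ⁻¹(1−p_g), computed in
the upper-tail form so extremely small p survive floating point.
Scoring is direction-agnostic (evidence, not sign): the package ranks
metabolic neighbourhoods by how extreme their enzymes' expression
changes are, without asserting up- or down-regulation. For each
metabolite the neighbour set is the union of genes in the GPR rules of
reactions producing or consuming it, each gene counted once however
many adjacent reactions contain it (prevents hub-gene double
counting). The raw score Σ Z_g/√k is centred and scaled by a background
(μ_k, σ_k) estimated per distinct k from `n_background` (default
10000) seeded draws of k genes from the scored model genes — the
algorithm's own convention, not a genome-wide pool. A degenerate
zero-variance background (all evidence identical) maps to a corrected
score of 0 or ±Inf instead of NaN. `p = 1 − Φ(z_corrected)` with BH
across metabolites; whether a one-tailed-on-up variant was used in the
inspiring analyses is not stated anywhere authoritative, so the
direction-agnostic default is recorded here rather than asserted as a
reproduction. A currency-metabolite exclusion list is accepted and
empty by default.

Reaction-level DE linkage collapses the GPR with OR: a reaction is
linked iff any gene in its rule is differentially expressed. The full
AND/OR parse is kept (and a strict boolean evaluation mode exists) but
the subsystem test uses the OR-collapse, matching the plain meaning of
"reactions linked to DE genes". Subsystem enrichment is the upper-tail
hypergeometric over the universe of GPR-bearing reactions. The
two-contrast driver runs both PD subtypes with one seed policy and
labels findings shared / subtype-specific / neither at the configured
FDR.

Model I/O: the community COBRA JSON dialect, and SBML Level 3 with
`fbc` gene-product associations (plus `GENE_ASSOCIATION:`/`SUBSYSTEM:`
notes fallbacks). The SBML writer emits the same dialect the reader
consumes; GPRs may gain redundant parentheses in a round trip, so
equality is semantic, not textual.

# The synthetic world

The generators state one fixed world; their defaults were chosen once,
to be realistic for this field, and are not tuned against test
outcomes.

* **Expression** (`gen_expression_datasets`): negative-binomial counts,
  gene means log-normal (meanlog = log 100, sdlog = 1), one dispersion
  (0.1, a typical bulk RNA-seq scale), 2000 genes, 10 + 10 samples per
  dataset, 3 datasets per condition. Planted DEGs (5% of genes,
  |log2FC| = 2) are either shared by all three conditions with one
  direction (half) or specific to one condition. Not emulated: batch
  effects, library-size imbalance, read-level error, cross-platform
  probe differences — a green concordance test establishes the set
  logic and power at the stated effect size, not robustness to those
  artefacts.
* **Summary statistics** (`gen_summary_stats`): per-SNP EAF uniform on
  [0.1, 0.5]; exposure SE 1/√(2·EAF(1−EAF)·n) with n = 31,684
  (a whole-blood eQTL-meta scale); outcome SE with the effective n of a
  33,674-case / 482,730-control GWAS. True exposure effects are uniform
  on [0.05, 0.2] SD per allele so that instruments are genuinely strong
  (F ≈ 30–500). For valid SNP j, β_out = θ·b_j + N(0, se_out²); invalid
  SNPs add a direct effect (`pleiotropy_intercept`/`pleiotropy_sd`,
  the InSIDE-compatible construction Egger detects) and/or a constant
  Wald-ratio shift (`pleiotropy_shift`, the weighted-median breakdown
  construction). Effect alleles are coded as the expression-increasing
  allele by default ("increasing"): that is how cis-eQTL instruments
  are extracted in practice, and with random sign coding the Egger
  orientation step would cancel any directional intercept by
  construction, making directional pleiotropy undetectable for *any*
  implementation; a "random" option remains for orientation-invariance
  checks. LD is declared, not emergent: the generator emits the r²
  table the pruner consumes; no haplotypes are simulated. About 30% of
  outcome records are stored allele-swapped to keep harmonisation
  honest.
* **Case/control expression** (`gen_case_control_expression`): Gaussian
  with unit noise; a gene with case-shift Δ has closed-form
  univariable AUC Φ(Δ/(σ√2)), the oracle used in tests.
* **Toy metabolic model** (`gen_toy_metabolic_model`): a connected
  chain plus random edges, unique genes per reaction, one planted
  metabolite whose adjacent reactions' genes draw p from
  Uniform(0, 1/contrast) (contrast 1 ⇒ no signal); hotspot reactions
  share a `planted_pathway` subsystem so the subsystem test has a
  planted truth too.

All randomness descends from one integer master seed through a
deterministic splitter (`seed × stage-key` hashing), so stages re-run
independently yet reproducibly, and any derived seed stays below 2³¹.

# Numerical choices and degenerate inputs

* p-values are floored at the smallest positive double before Z
  transformation; Z uses the upper-tail `qnorm` form.
* Zero-variance genes: p = 1 (DE test), AUC 0.5 with a `constant` flag
  (univariable), intercept-only model with AUC 0.5 (panel).
* β_exp = 0 SNPs are excluded from ratios with a logged reason;
  identical score vectors give Δ AUC = 0 with p = 1.
* The random-effects inflation is floored at 1 so homogeneous panels
  can never be anti-conservative relative to fixed effects.
* BH is used for every multiplicity correction, NA-tolerant.

# What the acceptance tests establish — and what they cannot

The acceptance suite (in `tests/testthat/test-acceptance.R`) checks:
IVW type-I error and CI coverage at nominal levels under the null;
recovery of planted θ by IVW (bias < 0.01), by the weighted median
under 40% invalid weight, and of a directional pleiotropy intercept by
the Egger test (power ≥ 0.8); exact agreement of IVW/Q/AUC/
hypergeometric values with closed-form or brute-force oracles;
harmonisation rules at their exact thresholds; exact set algebra and
planted-truth recovery for concordant DEGs; nested-CV null calibration
and signal recovery; and planted-hotspot recovery with k-independent
null reporter scores. Two estimator-stress experiments disable the
reverse-causation screen via its config toggle, because with the
screen on the strongly pleiotropic instruments are (correctly) removed
before the estimators see them — the experiments target the estimators,
not the filters. Headline numbers of any real-data analysis (specific
gene lists, specific ORs and AUCs, named pathways) depend on external
GEO/eQTL/GWAS inputs and are therefore outside what a green suite can
establish.

# Known limitations

No colocalisation, multivariable MR or full Steiger directionality
testing; no GO DAG handling or term redundancy trimming; no
flux-balance analysis — the metabolic model is used only as a
gene–reaction–metabolite graph with subsystem labels; no cross-platform
gene-identifier harmonisation. The Welch-on-log-CPM DE test is a
convenience for synthetic data, not a substitute for dedicated DE
frameworks on real counts.
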