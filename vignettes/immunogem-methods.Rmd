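---
title: "Methods: differential PBMC metabolomics and context-specific metabolic modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential PBMC metabolomics and context-specific metabolic modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`immunogem` implements an analysis chain for longitudinal metabolomics of
peripheral blood mononuclear cells (PBMCs) in cohorts progressing to type 1
diabetes, together with the genome-scale-modelling arm that interprets those
data on a metabolic network. The chain is: cohort simulation (or ingestion)
→ quality control → group/age differential statistics → pathway
over-representation → expression-based reaction scoring → INIT-style
context-specific model extraction → reporter-metabolite analysis → flux
balance analysis of glycosphingolipid production. Every stage is exercised
end-to-end on a toy sphingolipid network and a simulated cohort with planted
ground truth.

# Statistical model of the omics data

Intensities are analysed on the log2 scale throughout: `log2_normalize()`
maps raw intensity `x` to `log2(x + offset)` with `offset = 1` so zeros stay
finite (the offset is irrelevant at the simulator's intensity scale of
`2^6`–`2^12` but protects real data with missing-value zeros).

**Age binning.** Samples are assigned to the nearest of the target ages (12,
24, 36 months) within a ±6-month window; when one child contributes several
samples to a bin, the closest (ties: earlier) is kept. Note the ±6-month
windows tile the whole 6–42-month range, so only very early or very late
samples are dropped.

**Homogeneity check.** PCA on the column-centered matrix; samples outside
the Hotelling T² ellipse of the first two components at 95% confidence are
flagged. With `confidence = 1` the ellipse is infinite and nothing is
flagged. Under a pure-noise model about 5% of samples exceed the ellipse by
construction; the check is a screen, not a test.

**Explained variation.** Per feature, a linear model on age, sex, clinical
group and their pairwise interactions; each term's sequential (type I) sum
of squares over the total defines its EV%. The cohort-level summary is the
median EV% per term. Sequential sums of squares make the decomposition sum
to at most 100% per feature; the term order (age, sex, group, interactions)
is fixed and documented rather than data-dependent.

**Contrasts.** Unpaired comparisons use Welch's t per feature (a pooled
variance Student option exists; Welch is the default because group sizes of
10 vs 34 with unequal variances are the realistic regime). The log2 fold
change is mean(first-named group) − mean(second). Benjamini–Hochberg
q-values are computed within each contrast-by-age feature family; both raw p
and q are reported. Degenerate features (all values equal) get `p = 1` and a
flag rather than NaN. The paired before/after-seroconversion contrast
averages each subject's samples before (`age < seroconversion age`) and at
or after seroconversion and applies a paired t test; subjects lacking either
side are excluded and counted.

**Sparse PLS-DA.** `plsda_fit()` is NIPALS PLS1 against the centered 0/1
class indicator with autoscaled columns. Sparsity is the keep-k convention:
each component's weight vector keeps the `keep_per_component` largest
absolute weights, zeroes the rest, and is renormalized; keeping everything
recovers dense PLS-DA. Defaults are 2 components and keep 20 — the component
count and sparsity of the original analysis are not published, so both are
exposed in the configuration. The reported per-feature coefficient (RC) is
the regression coefficient of the final linear predictor,
`B = W (PᵀW)⁻¹ C`; VIP scores use
`VIP_j = sqrt(p · Σ_a ssy_a (w_{ja}/‖w_a‖)² / Σ_a ssy_a)`, which satisfies
`Σ_j VIP_j² = p` exactly. Model quality is a stratified 5-fold
cross-validated AUC, 10 repeats; AUC is computed per test fold and averaged
so fold-specific score offsets cannot distort the ranking. A feature is
called altered by both analyses ("multi+uni") when AUC ≥ 0.65, |RC| > 0.05,
VIP > 1 and p < 0.05, and "uni-only" on p < 0.05 alone; these thresholds
follow the published selection rule and are configurable.

**Correlation maps.** Spearman's ρ with average ranks on ties for every
feature pair of two subject-and-age-paired matrices; two-sided p from the
t approximation `t = ρ√((n−2)/(1−ρ²))`; the default significance mask is
ρ > 0.70 and p < 0.05.

# Pathway over-representation and impact

Hits (features selected in a contrast) are tested per pathway with the
one-sided hypergeometric upper tail after intersecting each pathway with the
measured, pathway-mappable universe — the universe is what was measured, not
the whole database, which is standard ORA practice. BH control across
pathways at FDR < 0.05. The pathway impact score (PIS) is the sum of
relative betweenness centralities of hit members over that of all members,
computed on the pathway's own graph (the MetaboAnalyst convention); a
pathway without a graph has undefined (NA) impact rather than 0. Pathways
are read from GMT plus an optional edge-list TSV; the synthetic pipeline
derives chemical-class pathways with path-graph topology from the feature
panel (`synthetic_pathways()`).

# Genome-scale modelling arm

**Network container.** `metabolic_model` stores metabolites (with
single-letter compartments c/g/r/l/m/e), reactions (bounds, reversibility,
subsystem, GPR rule) and stoichiometries; the sparse stoichiometric matrix S
is reconstructed losslessly by `model_S()`. SBML L3v1 with FBC v2 is read
and written in a documented minimal dialect (species, per-reaction
flux-bound parameters, gene-product associations, subsystems in
cobra-style `SUBSYSTEM:` notes); unknown SBML packages are ignored with a
warning.

**GPR evaluation.** AND nodes combine by `min`, OR nodes by `max` (the
standard constraint-based convention; both rules are arguments because the
original analysis did not publish its aggregation rule). Genes absent from
the expression data contribute *no evidence* — they are dropped from their
node, not set to zero, because a missing probe is not absence of expression.
An all-missing or empty rule evaluates to NA.

**Reaction confidence scores.** Per group, gene expression is averaged on
the linear scale, aggregated through the GPR, and converted to a weight
`w = log2(e/τ)` clipped to ±5, with τ defaulting to the median of the
gene-by-group mean matrix. The weight is zero exactly at the evidence
threshold, symmetric in up/down evidence, and bounded; reactions without
gene evidence score 0. The original reaction-confidence formula is in
unpublished supplementary material, so this form is a declared substitute,
not a reconstruction, and every piece (τ, clip, rules) is configurable.

**Metabolite evidence and exchange constraints.** A metabolite is evidenced
for a group when a feature mapping to it is detected at the modelling age
(36 months, the post-seroconversion endpoint): the one-sided 95% lower
confidence bound of the group-mean log2 intensity must exceed the detection
limit (default 6). The confidence margin, rather than the plain mean, is
what "consistently quantified above the platform limit" means in a group of
half a dozen samples — without it, single high samples call borderline
species present. Hexosylceramide features are chemically
ambiguous between glucosyl- and galactosylceramide and map to both. Uptake
is opened (lower bound −10 flux units) only for exchanges of evidenced or
basal-medium metabolites (serine, palmitate, glucose, galactose, choline
donor); all other uptakes are closed, secretion stays open; the overlay is
idempotent.

**INIT extraction.** On the irreversibility-split network we solve

max Σᵢ wᵢ yᵢ + κ Σⱼ xⱼ  s.t. S v = b, bⱼ ∈ [0, b_max] for evidenced j
(0 otherwise), ε yᵢ ≤ vᵢ ≤ Mᵢ yᵢ, ε xⱼ ≤ bⱼ ≤ b_max xⱼ, y, x ∈ {0,1},

with ε = 10⁻³, M = 1000, b_max = 100, κ = 20 (so producing an evidenced
metabolite outweighs any single low-confidence reaction, |w| ≤ 5). Defaults
are declared substitutes for unpublished tuning and all sit in the
configuration. Numerical design choices: (i) per-reaction M is tightened by
an FVA pass before the solve, which both sharpens the LP relaxation and
fixes never-active reactions to zero; the coupling bound is further capped
near twice the total uptake capacity — indicator constraints only ever
force ε-scale flux and internal loops deflate below any cap, so the cap
cannot change the optimum, while a loose big-M on loop reactions makes the
relaxation nearly blind to negative-weight loop members and the
branch-and-bound intractable; (ii) reactions with zero weight carry
no binary — their inclusion neither helps nor hurts the objective, so after
the solve their inclusion is decided by an "ε-spreading" LP (with the scored
decisions and evidence indicators fixed, maximize Σ min(vᵢ, ε) over the
unscored reactions, linearized with auxiliaries), which concentrates flux
onto routes that carry at least ε; a final feasibility re-solve then
verifies that the whole included set sustains ≥ ε flux jointly; (iii) the extraction is
exactly reproducible — the branch-and-bound is deterministic (largest
|objective coefficient|, then lowest index; nearest-branch-first).

**Solver.** No mixed-integer (or even linear) programming solver exists in
the package's dependency environment, so the package carries its own: a
dense two-phase primal simplex and a deterministic depth-first
branch-and-bound over the binaries (largest-coefficient branching, up-child
first, root rounding heuristic). Indicator-coupled flux LPs are both highly
degenerate and badly scaled (ε = 10⁻³ against bounds of 10³), so the
simplex takes the numerical precautions real solvers take: a Harris
two-pass ratio test so well-conditioned pivots win over tiny ones, periodic
refactorization (the compiled kernel runs a bounded number of pivots, then
the basic solution and tableau are recomputed exactly from the original
data and optimality is verified on clean reduced costs before a solution is
accepted), stall-triggered switching to Bland's rule, and a retry ladder
with shorter refactorization intervals; irrecoverable numerical failure
raises an error rather than returning an unverified optimum. This is
adequate for the toy-network scale the package targets (tens of
metabolites, ~100 columns); it is not intended for genome-scale
reconstructions. Exactness is tested against exhaustive subset enumeration
on random small networks and against analytic optima.

**Reporter metabolites.** Gene-level two-sided p-values are converted to
Z = Φ⁻¹(1−p) (directional modes halve the p-value in the stated direction
first; p floored at 10⁻¹⁵). A metabolite's score aggregates its
neighborhood genes — the union of genes in the GPRs of all reactions it
participates in — as `z_raw = Σ Z_g/√k`, and is corrected by the mean and sd
of the same statistic over 10,000 random size-k draws (with replacement)
from the scored-gene pool: `z_corr = (z_raw − μ_k)/σ_k`,
`p = 1 − Φ(z_corr)`, BH across metabolites. Compartment instances are
scored separately (glucosylceramide in cytosol vs Golgi), matching
per-compartment reporter reporting. Currency species are excluded from
neighborhoods; in the toy model the free sugar pools stand in for
UDP-glucose/UDP-galactose donors and are treated as currency, since donor
metabolites connect every glycosylation step and would destroy locality.
Directional (up/down) reporters are the default figure-style output; the
combined mode exists because the original choice is not stated.

**Flux analysis.** FBA is `max/min c·v` under `S v = 0` and bounds; optimal
states must satisfy mass balance to 10⁻⁹. Because FBA vertices are not
unique, reported flux vectors come from a parsimonious second stage
(minimize Σ|v| at the fixed optimum), which also silences futile cycles
(e.g. the kinase/phosphatase pairs). The two production objectives are the
cytosolic demands `glcCer_demand` (glucosylceramide from ceramide and
glucose) and `digalCer_demand` (digalactosylceramide from ceramide and
galactose). Extraction routinely prunes inactive demand reactions, so the
production question is answered by re-adding the demand to a context model
*when its metabolite survived extraction*; a context model lacking the
metabolite reports flux 0 with a pruned flag, because pruning is
informative, not an error. Subsystem summaries compare Σ|v| per subsystem
between two optimal states; the pipeline contrasts the quiescent
(zero-demand parsimonious) state with maximal glucosylceramide production.

# The toy sphingolipid network

35–60 reactions over compartments c/g/r/l/e covering de novo synthesis in
the ER (SPT → KSR → CerS → DES), sphingomyelin synthesis and breakdown (SMS,
SMase), the ceramide salvage route (CDase, CerS), the glycosphingolipid
branch (GCS, LacCer synthase, GalCS, the glycosidases, digalactosylceramide
synthase), the signalling branch (SK, S1P lyase/phosphatase, CK, C1PP),
phosphatidylcholine supply, and uptake of serine, palmitate, glucose,
galactose and a choline head-group donor. Stoichiometries are unit
coefficients; no elemental formulas are tracked (the fatty-acid leaving
group of ceramidase, for example, is not mass-balanced — only the
sphingoid backbone is). Every enzyme step has a distinct single-gene GPR;
transport, exchange and demand steps are unannotated, as vesicular or
spontaneous lipid movement commonly is in metabolic reconstructions. The
default model is flux-consistent (every reaction can carry flux), checked
by per-reaction FVA; topology edits that block reactions error out when the
consistency check is requested.

# What the simulators emulate — and what they do not

**Cohort.** Three groups (10 controls CTRL, 27 seroconverted non-progressors
P1Ab, 34 progressors PT1D), samples at 12/24/36 months, 35% of
subject-by-age samples missing (matching a cohort in which 137 of 213
possible samples existed). Seroconversion ages are log-normal with medians
≈24 months (P1Ab) and ≈14 months (PT1D), enabling before/after paired
contrasts. Intensities: feature baseline + linear age trend + subject random
intercept (sd 0.3 log2) + planted effects + residual (sd 0.5 log2),
exponentiated. The intercept/residual sds make a planted |log2FC| = 0.8
detectable at these group sizes but not trivially.

**Planted truth.** A long-chain ceramide-like feature down 0.8 log2 in PT1D
at all ages; hexosyl- and lactosylceramide-like features up 1.0 log2 in
PT1D at 36 months; a broad decrease (−0.4) of 60% of features in both
seroconverted groups at 12 months with a transient +0.3 at 24 months; small
post-seroconversion decreases of glutamate (P1Ab) and serine (PT1D).
Glycoceramide features sit 0.6 log2 *below* the detection limit at baseline,
so only the PT1D group at 36 months lifts them into the detected range —
this detection difference, plus the planted expression pattern, is what
differentiates the three context models. The planted registry is returned
with the data (and written as ground-truth JSON), so downstream
sensitivity/specificity can be scored without reading generator code.

**Expression.** One array per subject; 15/15/51 CTRL/P1Ab/PT1D (the
transcriptomics cohorts provide 15 non-progressors and 51 progressors;
their control count is not stated, set to 15). Gene baselines are
log-normal, log2 mean 7 sd 0.6 — the modest spread keeps housekeeping
reaction weights near zero so that context differences are driven by the
planted biology rather than random baselines. The generic generator default
plants a 2-fold GCS increase in PT1D; the pipeline's default configuration
plants a 2.8-fold increase of all four glycosylation genes (GCS, GalCS,
LacCer synthase, digalactosylceramide synthase) on a 0.35× baseline,
encoding "glycosylation quiescent in health, induced in progression".

**Not emulated:** chromatographic/spectral artifacts, batch effects,
feature-wise variance heterogeneity fitted to a real dataset, censoring
below the detection limit (values are generated, detection is an evidence
rule), and intensity-dependent missingness. Passing tests therefore show
correctness of the statistics and of direction recovery under this
generative model — they do not certify performance on real cohort data.

# Problem sizes and budgets

The acceptance checks run the solver-versus-enumeration comparison on 25
random networks of 5–12 reactions, reporter recovery over 25–50 seeded
replicates with 10,000 background draws, reporter calibration on a
2000-metabolite chain network, calibration of the univariate selection on a
cohort-sized null dataset with 2000 noise features, and 10–20 full pipeline
runs; a full synthetic pipeline run takes well under a minute on one CPU.

# Known limitations

* The LP/MILP kernel is dense and single-threaded; genome-scale models are
  out of scope.
* The INIT weight formula, κ, ε and the exchange-constraint rule are
  declared substitutes for unpublished parameters; conclusions about real
  data should be checked for sensitivity to them.
* Reporter background correction is Monte-Carlo; scores carry O(1/√n)
  sampling error (stability under doubling the background is tested).
* The univariate/multivariate selection rule treats the cross-validated AUC
  as a per-model gate shared by all features of a contrast.
* No loess interpolation or bean-plot graphics: figures of that kind are
  presentation, not inference, and are left to the user.
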