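# immunogem

Differential metabolomics and context-specific metabolic modelling of immune
cells during progression to type 1 diabetes.

## The problem

Children who later develop type 1 diabetes show metabolic changes in their
immune cells (peripheral blood mononuclear cells, PBMCs) before and after
seroconversion to islet autoimmunity. Analysing such cohorts takes two
coupled toolchains that this package provides in one place:

1. **Longitudinal differential metabolomics.** Lipid and polar-metabolite
   intensities from three clinical groups — autoantibody-negative controls
   (CTRL), seroconverted non-progressors (P1Ab) and progressors (PT1D) —
   sampled at 12, 24 and 36 months of age, are log2-transformed, binned by
   age, screened by PCA (Hotelling T², 95%), and compared per feature with
   Welch t tests (log2FC = mean(A) − mean(B), BH FDR) and sparse PLS-DA.
   A feature is altered by both analyses when the model's cross-validated
   AUC ≥ 0.65, its VIP > 1 and |RC| > 0.05, and p < 0.05; paired
   before/after-seroconversion t tests, total-signal ANOVA, Spearman
   correlation maps (ρ > 0.70, p < 0.05) and explained-variation
   decomposition complete the statistics. Altered metabolites feed a
   hypergeometric pathway over-representation analysis (FDR < 0.05) with
   betweenness-centrality pathway impact scores (PIS).

2. **Genome-scale modelling of sphingolipid metabolism.** Group-wise gene
   expression scores every reaction of a metabolic network,
   `w = log2(e/τ)` clipped to ±5 with GPR aggregation (AND → min,
   OR → max); detected metabolites constrain exchanges and contribute
   evidence. An INIT-style mixed-integer program extracts a context-specific
   model per group:

   ```
   max  Σᵢ wᵢ yᵢ + κ Σⱼ xⱼ
   s.t. S v = b,  bⱼ ∈ [0, b_max] (evidenced j, else 0)
        ε yᵢ ≤ vᵢ ≤ M yᵢ,   ε xⱼ ≤ bⱼ ≤ b_max xⱼ,   y, x ∈ {0,1}
   ```

   Reporter-metabolite analysis aggregates gene-level differential
   expression onto network metabolites (`z = Σ Z_g/√k`, Monte-Carlo
   background correction per neighborhood size), and flux balance analysis
   compares maximal glucosyl- and digalactosylceramide production across the
   extracted group models (parsimonious FBA, mass balance to 1e-9).

Because the package ships a flux-consistent toy sphingolipid network
(SPT → KSR → CerS → DES core, sphingomyelin, salvage, glycosphingolipid and
signalling branches over cytosol/Golgi/ER/lysosome) and cohort simulators
with planted ground truth, the whole chain runs end-to-end without any
external data. The LP/MILP kernel (dense two-phase simplex plus
deterministic branch and bound) is built in and verified against exhaustive
enumeration.

## Worked example

```r
library(immunogem)

model <- build_toy_sphingolipid_model()
model
#> <metabolic_model> toy_sphingolipid
#>   metabolites: 41  reactions: 52  genes: 20
#>   compartments: c e g l r

# maximal glucosylceramide production of the full network
fba(model, "glcCer_demand")
#> <flux_state> objective glcCer_demand (optimal)
#>   optimum: 5
#>   active reactions: 15 of 52
# (palmitate uptake 10 caps de novo ceramide at 5: SPT and CerS each
#  consume one palmitate per backbone)

# the full synthetic pipeline: simulate -> qc -> contrasts -> ORA ->
# scoring -> INIT extraction -> reporters -> flux
dir <- run_pipeline(default_config(seed = 1, output_dir = "run1"))
read.delim(file.path(dir, "flux_objectives.tsv"))
#>   group       objective optimum pruned ratio_vs_reference
#> 1  CTRL   glcCer_demand       0   TRUE                 NA
#> 2  CTRL digalCer_demand       0   TRUE                 NA
#> 3  P1Ab   glcCer_demand       0   TRUE                 NA
#> 4  P1Ab digalCer_demand       0   TRUE                 NA
#> 5  PT1D   glcCer_demand       5  FALSE                 NA
#> 6  PT1D digalCer_demand       0   TRUE                 NA
```

Only the progressor (PT1D) context model retains the glucosylceramide
synthesis route — its expression data carry the planted up-regulation of the
glycosylation genes and its 36-month lipidome lifts the glycoceramide
features above the detection limit — so its maximal glucosylceramide
production flux (5 flux units, the palmitate-limited optimum) exceeds the
control model's 0. The top up-regulated reporter metabolites for
PT1D vs P1Ab in the same run are exactly the glycoceramide species, per
compartment:

```r
rep <- read.delim(file.path(dir, "reporters.tsv"))
head(subset(rep, contrast == "PT1D_vs_P1Ab" & mode == "up",
            c(metabolite, k, z_corrected, p)), 5)
#>      metabolite k z_corrected          p
#> 117 digalCer[c] 1    2.143271 0.01604566
#> 118   glcCer[c] 1    2.006225 0.02241610
#> 119   glcCer[g] 1    1.871776 0.03061882
#> 120   lacCer[g] 1    1.871776 0.03061882
#> 121   galCer[r] 1    1.542604 0.06146345
```

`contrasts.tsv` carries per-feature log2FC/t/p/q/VIP/RC and the selection
basis per contrast and age; `ora.tsv` the pathway table with PIS;
`inclusion_report.tsv` the INIT decisions; `manifest.json` the MD5 hashes
that make reruns checkable.

A thin command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/immunogem.R", package="immunogem"))')" run --seed 1 --out run1
```

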