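# pathmod

Pathology-seeded co-expression modules and prognostic biomarkers for
amyotrophic lateral sclerosis (ALS).

ALS lacks a predictive biomarker: progression rate varies from under two
years to well over a decade, and most candidate markers are downstream
phenomenology. `pathmod` implements a data-driven workflow that starts from
the one near-universal feature of the disease — p62/TDP-43-positive
cytoplasmic inclusions in motor neurons — and works outward to
peripherally measurable prognostic signals:

1. **Pathology screen.** Spearman rank correlation of every transcript's
   expression (laser-captured motor neurons, microarray) against the count
   of inclusion-bearing neurons per unit area; transcripts with unadjusted
   p < 0.01 become network seeds.
2. **Seeded co-expression network.** Each seed recruits its top 1 % of
   transcripts by Pearson correlation; the union is soft-thresholded
   (`a_ij = |cor_ij|^beta`, beta chosen by scale-free topology fit),
   converted to topological overlap
   `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
   and clustered into modules by average-linkage hierarchical clustering
   with a static cut. Modules without a seed are discarded.
3. **Prioritisation.** Every seeded module is scored by one-sided Fisher
   exact enrichment against three independently curated assessment sets —
   duration-correlated motor-neuron transcripts, rapid-vs-slow
   lymphoblastoid transcripts, and genome-wide-significant ALS
   susceptibility genes — against the measured-gene universe. Modules
   enriched with all three (raw p < 0.05) are the biomarker candidates; a
   motor-neuron cell-identity module serves as negative control.
4. **Module expansion.** The candidate module is extended with globally
   co-expressed and protein-interaction partner genes supplied as a
   weighted edge table (at least two supporting edges each), improving its
   detectability outside the CNS.
5. **Blood assessment.** Cox proportional hazards (Efron ties) of survival
   on the module's top principal components beyond onset age and sex;
   per-gene binomial logistic screens for rapid (< 2 y) versus slow
   (> 4 y) progression; and a leave-one-out cross-validated gene panel with
   an exact binomial test against chance.
6. **CSF assessment.** Soluble TREM2 (the shed microglial receptor
   ectodomain, in ng/ml) from a packaged 46-patient/20-control clinical
   table: rank-based group comparison, staging of patients into
   early/middle/late quartiles of their disease course at sampling, and
   stage-stratified Spearman association with disease duration.

Every stage is testable against ground truth through the built-in
synthetic-study generator (`simulate_study()`), which plants
latent-factor co-expression modules, couples one of them to Poisson
pathology counts and to progression labels, and records the truth.

## Worked example

Discovery on a synthetic study with a planted disease module:

```r
library(pathmod)

study <- simulate_study(sim_config(seed = 1))
disc  <- run_discovery(study)
disc$priority
#> <pm_priority> 1 modules x 3 sets; 1 triple-enriched at raw p < 0.05
#>   triple-enriched: M1
```

The detected module `M1` captures the planted pathology-linked module and
is enriched with all three assessment sets. The CSF phase runs on the
packaged clinical table:

```r
tab <- load_csf_table()
compare_strem2_groups(tab)
#>   mean_als mean_control u_statistic p_value p_two_sided method        ...
#> 1     17.7         7.16         592  0.0333      0.0665 normal_approx ...

stage_summary(tab)
#>   stage      n mean_strem2 se_strem2
#> 1 early     11        36.4     27.4
#> 2 middle    23        11.5      1.91
#> 3 late      11        12.7      2.92

stage_stratified_association(tab)
#>   stage      n    rho p_value p_two_sided method
#> 1 early     11 -0.864 1.000      0.000612 t_approx
#> 2 middle    23  0.104 0.319      0.638    t_approx
#> 3 late      11  0.726 0.00571    0.0114   t_approx
```

Read: mean CSF sTREM2 is 17.7 ng/ml in ALS versus 7.2 ng/ml in controls
(rank test for elevation, p = 0.03); concentrations are about three-fold
higher in patients sampled early in their disease course (36 ng/ml) than
late (13 ng/ml); and within late-stage patients, higher sTREM2 goes with
longer survival (rho = 0.73, two-sided p = 0.011) — consistent with a
sustained neuroprotective microglial response. `p_value` is the one-sided
test of the directional biomarker hypothesis; the two-sided value is
always reported alongside.

Plots: `autoplot()` on screens, priority reports and stage summaries;
`plot_csf_groups()` for the group comparison. Fits expose broom-style
`tidy()`/`glance()` methods.

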