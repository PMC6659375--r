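# epimr

Epigenetic Mendelian randomization from summary statistics.

EWAS report CpG sites where DNA methylation tracks a lifestyle exposure, but
cannot say whether those methylation differences matter downstream. `epimr`
treats methylation at an exposure-associated CpG as an exposure in its own
right and asks, using only per-variant summary statistics plus a VCF
reference panel for LD:

1. **Instruments** — select conditionally independent cis-mQTLs per CpG
   (p < 1e-7, < 1 Mb) by stepwise approximate conditional-and-joint selection
   from summary statistics and panel LD; find r² > 0.8 proxies when an
   instrument is missing from an outcome dataset; harmonize effect alleles.
2. **Two-sample MR** — Wald ratio for one instrument,
   β̂ = Γ̂/γ̂ with se = σ_Y/|γ̂|; fixed-effect IVW for several,
   β̂ = Σ wⱼ β̂ⱼ / Σ wⱼ with wⱼ = γ̂ⱼ² σ_Yⱼ⁻²; phenome-wide scan flagged at
   the Bonferroni threshold α/(n_CpG × n_traits).
3. **Colocalization** — three-trait (methylation, expression, complex trait)
   Bayesian colocalization from Wakefield approximate Bayes factors over all
   15 configuration classes; `ppa_abc` is the posterior that one variant
   drives all three. Scanned for every gene within 100 kb of the CpG, on
   ≥ 50 common variants with panel MAF ≥ 5%.
4. **Orientation** — Steiger directionality tests
   (r² = z²/(z²+n−2), two-sample Fisher-z comparison) applied to each trait
   pair, reverse MR with genome-wide trait instruments, and sign chaining of
   the EWAS exposure→methylation effect with the MR methylation→trait effect.

A coupled-region simulator (`simulate_region()`, `simulate_study()`)
generates LD-structured genotype panels and regression-derived summary
statistics under shared / distinct / null causal architectures, so the whole
pipeline is testable without cohort access.

## Worked example

```r
library(epimr)

# a study of 4 CpGs x 3 traits with one planted shared-causal pair:
# methylation -> expression -> trait, all driven by one variant
cfg <- sim_config(n_panel = 400, n_mqtl = 800, n_eqtl = 400, n_gwas = 4000,
                  n_variants = 60, causal_r2 = 0.2, beta_me = 0.6,
                  beta_mt = 0.3, seed = 901)
study <- simulate_study(n_cpgs = 4, n_traits = 3, planted_cpg = 2,
                        planted_trait = 3, config = cfg)
report <- run_pipeline(study)
report
#> <epimr_report> 4 CpG(s) x 3 trait(s); threshold 0.00417; 1 significant; 1 oriented
#>       cpg_id trait_id gene_id   ppa_abc implied_exposure_effect
#> 1 cg00000002  trait_3   GENE2 0.9999958                  lowers
```

The planted pair — and only it — survives the scan at the Bonferroni
threshold 0.05/(4×3) = 0.00417, colocalizes with the planted gene at
`ppa_abc = 0.9999958` (posterior that methylation, expression and trait share
one causal variant), and is oriented: its MR estimate is near the true effect
0.3 SD/SD, and because the simulated EWAS effect on methylation is negative
(−0.008) while the MR methylation→trait effect is positive, the upstream
exposure putatively *lowers* the trait.

```r
report$mr[report$mr$significant, c("cpg_id", "trait_id", "beta", "se", "p")]
#>       cpg_id trait_id      beta         se            p
#> 6 cg00000002  trait_3 0.2896163 0.03276708 9.689509e-19
```

Individual stages are exported (`select_cis_mqtl`, `cojo_slct`, `find_proxy`,
`harmonize`, `wald_ratio`, `ivw`, `moloc_posteriors`, `gene_window_scan`,
`steiger_direction`, `reverse_mr`, `orient_chain`, `compare_estimates`), as
are the readers/writers for tab-delimited summary tables, CpG/gene
annotations and VCF panels (`read_summary_table`, `read_reference_panel`,
`write_study`, `load_study`). See the methods vignette
(`vignettes/epimr-methods.Rmd`) for the models, priors, tunable parameters
and the simulator's scope.

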