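# firetraits

Fire restructures boreal soil bacterial communities through two different
pressures: the short heat pulse of the burn itself, and the years-long press
of altered post-fire soil chemistry. `firetraits` implements an
experimentally anchored pipeline for telling these apart at the level of
individual 16S amplicon taxa, for microbial ecologists working with paired
burned/unburned soil-core experiments and post-fire field surveys. It
assigns three traits from three lab contrasts —

* **fire survivor**: enriched in burned vs unburned soil 24 h post-burn,
  with an RNA:DNA ratio ≥ 1 (alive, not relic DNA);
* **fast grower**: enriched in burned soil at 5 weeks vs 24 h post-burn;
* **post-fire environment affinity**: enriched in burned vs unburned soil
  after a 6-month incubation of autoclaved, re-inoculated soils —

then quantifies how prevalent each trait is in field communities across a
burn-severity gradient 1 and 5 years post-fire, and fits two-pool
exponential decay models to soil CO₂ flux to ask whether the reshaped
communities constrain carbon mineralization.

## The models at the core

**Differential relative abundance** is a beta-binomial regression, written
and fitted in this package: counts *yᵢ* of a taxon out of library totals
*nᵢ* with

&nbsp;&nbsp;μᵢ = logit⁻¹(xᵢᵀβ), aᵢ = μᵢ(1−φ)/φ, bᵢ = (1−μᵢ)(1−φ)/φ,

where *xᵢ* holds the contrast arm and a centred pH covariate and φ is a
single overdispersion parameter. Effects are reported as
log₂FC = log₂ μ₁/μ₀ at mean covariates with delta-method standard errors;
significance is a Wald *t* test on the group coefficient with
Benjamini–Hochberg control at FDR 0.05, followed by the trait filters
(burn-temperature > 50 °C sample selection, RNA:DNA viability, an
effect-size floor at mean − sd of the significant responders).

**Carbon kinetics** follow the two-pool model *M(t) = M₁e^(−k₁t) +
M₂e^(−k₂t)* (fractions of initial total C; rates d⁻¹), fitted by
Levenberg–Marquardt least squares under a parameterization that enforces
M₁ + M₂ = 1 and k₁ > k₂ ≥ 0, with treatment comparisons by site-paired
Wilcoxon signed-rank tests.

A seeded synthetic-data generator (`sim_config()`, `generate_lab_dataset()`,
`generate_flux_dataset()`, `generate_field_dataset()`) produces complete
studies with known ground truth — Dirichlet-multinomial communities with
spiked trait taxa, paired DNA/RNA libraries, treatment-specific decay
curves, and a field severity gradient — so the whole pipeline is testable
without sequencing data.

## Worked example

Simulate the default 19-site study, run the three trait contrasts, and fit
a decay curve:

```r
library(firetraits)

cfg <- sim_config(seed = 1)
lab <- generate_lab_dataset(cfg)
lab$dna_t24h
#> count_table [DNA]: 120 taxa x 114 samples, total reads 3,421,764

tables <- lab[c("dna_t24h", "rna_t24h", "dna_t5wk", "dna_t6mo")]
surv <- call_trait("survivor", tables, lab$samples)
fast <- call_trait("fast_grower", tables, lab$samples)
aff  <- call_trait("postfire_affinity", tables, lab$samples)
catalogue <- build_catalogue(surv, fast, aff)
catalogue
#> Trait catalogue: 24 taxa
#>   fast_grower        10
#>   postfire_affinity  8
#>   survivor           6
head(catalogue$provenance, 3)
#>   taxon_id    trait horizon   log2fc      q_value
#> 1   asv039 survivor organic 1.960539 1.928563e-04
#> 2   asv043 survivor organic 2.171056 1.467860e-04
#> 3   asv068 survivor organic 2.713976 2.629050e-06

flux <- generate_flux_dataset(cfg)
fit_two_pool(flux$series[["S01_dry_burn_incub"]], sample_id = "S01_dry_burn_incub")
#> Two-pool exponential decay fit [S01_dry_burn_incub]
#>   M1 = 0.0299  M2 = 0.9701  k1 = 0.1278 /d  k2 = 0.001063 /d
#>   R^2 = 0.9999 on 36 obs | converged: TRUE
```

The catalogue recovers 24 of the 28 spiked trait taxa with no false
positives (the generator's 4 relic-DNA decoys are DNA-enriched in burned
soil but removed by the viability filter), and the decay fit lands within a
few percent of the generating coefficients (M₁ = 0.0299, k₁ = 0.138,
k₂ = 0.00108 for this core) despite 5% flux noise. The whole analysis can
also be driven from a YAML config — `run_simulate()`, `run_traits()`,
`run_decay()`, `run_field()`, `run_all()` write every table to disk, and
`inst/cli/firetraits.R` wraps them for shell use.

Field projection works on any catalogue: `match_taxa()` merges lab and
field ASVs by exact sequence, `trait_total_abundance()` sums per-trait
relative, copy-number-normalized and absolute abundances, and
`severity_regression()` fits the severity × years-post-fire models with
automatic interaction dropping.

See `vignettes/firetraits-methods.Rmd` for the models, their assumptions,
the filters, and the identifiability limits of the decay fit.

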