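# traitsets

Species-level functional-trait datasets can be assembled in many ways:
measure plants in the study region (on-site records), pull records from a
global database such as TRY (off-site records), gap-fill the species the
database misses, or combine both sources. Each choice yields a different
dataset — and possibly different ecological conclusions. `traitsets`
implements six construction strategies as one tested pipeline and
quantifies how sensitive downstream trait–invasiveness regressions are to
the choice, using synthetic trait worlds with known ground truth so that
every step can be validated without any external data download.

The package is aimed at trait-based ecologists (in particular invasion
ecologists) who need to decide how to build a species × trait table when
local sampling is incomplete and database coverage is uneven.

## The six strategies

Given a pool of on-site and off-site trait records for a target species
roster:

| | Strategy | Gap handling |
|---|---|---|
| I | On-site data | none (field records only) |
| II | Off-site + taxonomic imputation | taxonomy-nested hierarchical model |
| III | Off-site + phylogenetic stand-ins | nearest data-bearing relatives, resampled |
| IV | Off-site + matrix factorization | hierarchical PMF across correlated traits |
| V | On- & off-site fusion | Bayesian update of off-site priors with on-site records |
| VI | All off-site data | none (roster = whatever the database covers) |

## Models

All traits are analysed on a standardized natural-log scale. The taxonomic
imputer (II, and the prior stage of V) is the four-level normal hierarchy

    y_r        ~ Normal(mu_sp[s(r)], sd_obs)
    mu_sp[s]   ~ Normal(mu_g[g(s)],  sd_sp[g]),   sd_sp[g]^2 ~ InvGamma(a0, b0)
    mu_g[g]    ~ Normal(mu_f[f(g)],  sd_g)
    mu_f[f]    ~ Normal(mu_global,   sd_f)

with `sd_obs`, `sd_g`, `sd_f` fixed and the species-level sd varying among
genera. It is fit by a blocked Gibbs sampler written for this package (all
full conditionals are conjugate), so marginals can be checked exactly
against closed-form multilevel posteriors. Strategy V updates each
species' prior `Normal(prior_mu, prior_sd)` — the hierarchy's posterior on
a capped off-site pool (max 5 records per species, for equal source
weight) — with the on-site records:

    posterior precision = 1/prior_sd^2 + n/sd_t^2.

Strategy IV is a hierarchical probabilistic matrix factorization
`X[s,t] ≈ U_s · V_t` with species factors shrunk toward genus and family
factors, fit by blocked Gibbs; it borrows strength across correlated
traits (e.g. seed mass supporting leaf-trait imputation). The case-study
regressions are conjugate Bayesian normal linear models
`invasiveness ~ Normal(alpha + sum_t beta_t * trait_t, sd)` with
logit-transformed local abundance or log-transformed spread rate as the
response, reporting 95% credible intervals, deviance explained (R²) and
variance inflation factors.

## Worked example

```r
library(traitsets)

cfg <- run_config(
  world = world_config(n_families = 12, genera_per_family = 3,
                       species_per_genus = 3, p_onsite_found = 0.5,
                       p_offsite_covered = 0.65, seed = 1),
  engines = engines_config(mcmc = mcmc_config(chains = 2, iter = 1500),
                           pmf = pmf_config(iter = 500)),
  seed = 1)
res <- run_pipeline(cfg)
res
#> Pipeline run
#>   traits: sla, height; strategies: I, II, III, IV, V, VI
#>   59 target species; 3083 records after filtering
#>   local_abundance models: 6 fitted
#>   spread_rate models: 6 fitted

res$datasets$sla$II
#> Trait dataset II_taxonomic / sla: 59 species (imputed_taxonomic 21, measured 38)

head(res$comparisons$sla, 4)
#>   trait d1  d2 pearson_r spearman_rho n_common
#> 1   sla  I  II 0.7714891    0.7759790       59
#> 2   sla  I III 0.7112865    0.7196808       59
#> 3   sla  I  IV 0.7235570    0.7157765       57
#> 4   sla  I   V 0.9998874    0.9991818       59

sapply(res$evaluations$sla, function(e) round(e$r2, 3))
#> taxonomic     phylo       pmf
#>     0.163     0.110     0.019

res$regressions$local_abundance$I
#> Invasiveness model: local_abundance ~ traits [I_onsite], n = 59, R^2 = 0.151
#>                term estimate lower95 upper95 significant
#>         (Intercept)   -0.001  -0.253   0.247       FALSE
#>                 sla   -0.247  -0.489  -0.003        TRUE
#>           seed_mass    0.143  -0.096   0.394       FALSE
#>  min_residence_time    0.286   0.040   0.541        TRUE
#>   max VIF 1.01

res$consistency$local_abundance
#> Effect consistency (local_abundance): 30 pairwise differences, 0 significant
```

Reading the output: the fused dataset (V) is nearly identical to the
on-site one (ρ ≈ 0.999) because equal-weight fusion with comparable
record counts stays close to the field data; the imputation strategies
(II–IV) agree with each other more than with I; under this default world
(no cross-trait correlation) no imputer has much leave-out skill; and
although datasets disagree, none of the 30 pairwise effect differences is
significant — dataset construction shifts trait values more than it
shifts inference.

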