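# allotrait

Tools for asking how tree architecture is coordinated with plant
functional strategy. Forest ecologists routinely measure two allometries
on co-occurring tree species — total height against stem diameter (DBH,
measured 130 cm above the ground) and crown radius against stem diameter
— and ask whether the species-level parameters of those allometries are
predicted by functional traits such as wood density, seed mass or leaf
nutrient concentrations, while controlling for the shared evolutionary
history of the species. `allotrait` implements that analysis end to end
as a tested, reusable pipeline, together with a synthetic-data generator
that emulates the statistical structure of such a field campaign so the
whole pipeline can be exercised and calibrated without any field data.

## The model

For individual *i* of species *j*, each dimension (height or crown
radius, m) is modelled on the log10 scale,

```
log10(y_ij) ~ Normal(alpha_j + beta_j * log10(DBH_ij), sigma)
(alpha_j, beta_j) ~ BivariateNormal((mu_alpha, mu_beta),
                                    sd_alpha, sd_beta, rho)
```

a hierarchical (partial-pooling) Bayesian regression in which `alpha_j`
is the log10 dimension at DBH = 1 cm, `beta_j` the scaling exponent, and
the species pairs share a bivariate normal hyperdistribution with an
explicit intercept–slope covariance. Slope priors centre on the global
angiosperm exponents (0.75 for height, 0.70 for crown radius) with a
deliberately large SD. A saturating alternative,
`log10(y) = a_j (1 - exp(-b_j * DBH))`, is fit with the same hierarchy
and the two functional forms are compared by WAIC. Sampling is by Gibbs
(JAGS via rjags), with split R-hat and effective-sample-size reporting.

Downstream, species parameters (or expected dimensions at reference
diameters of 1–19 cm) are repeatedly drawn from the posterior; each draw
is converted to phylogenetically independent contrasts on a user-supplied
(or simulated) phylogeny and rank-correlated (Kendall tau-b) with the
contrasts of six functional traits, yielding a median and equal-tailed
95% interval for every trait–parameter and trait–diameter pair, plus the
height–crown coupling across diameters.

## Worked example

```r
library(allotrait)

ds <- generate_dataset(synthetic_config(seed = 42))   # 14 species x 15 trees
head(ds$observations, 3)
#>   species   dbh_cm height_m crown_radius_m
#> 1    SP01 3.849278 5.221636       1.470242
#> 2    SP01 9.424230 9.457480       2.952718
#> 3    SP01 4.415638 6.985055       1.682911

fit <- fit_allometry(ds$observations, model_spec("height"),
                     mcmc_settings(n_chains = 4, n_iter = 4000,
                                   n_warmup = 2000, seed = 1))
head(subset(summarize_parameters(fit), parameter == "slope"), 3)
#>    species parameter response    median      lo95      hi95
#> 15    SP01     slope   height 0.7416935 0.6941174 0.7892194
#> 16    SP02     slope   height 0.7537727 0.7036175 0.8323301
#> 17    SP03     slope   height 0.7604452 0.7165327 0.8176066

tab <- sample_parameter_correlations(fit, ds$traits, ds$phylogeny,
                                     n_samples = 10000, seed = 2)
subset(tab, trait == "wood_density")
#>          trait    target response  median_tau       lo95      hi95 excludes_zero
#> 3 wood_density intercept   height -0.07692308 -0.2820513 0.1025641         FALSE
#> 9 wood_density     slope   height -0.07692308 -0.3333333 0.2820513         FALSE
```

The slope summaries cluster tightly around the generating hyper-slope of
0.75 — the "near-common slopes" regime — while the intercepts (not
shown) spread widely; the correlation table reports, for each trait, the
posterior median and 95% interval of the phylogenetic Kendall
correlation with the species intercepts and slopes, and whether that
interval excludes zero.

The full pipeline (simulate → fit both forms → WAIC-select → correlate)
runs from one seed and writes every table as CSV:

```r
run_pipeline(pipeline_config(seed = 1, out_dir = "out"))
```

or from a shell via `inst/exec/allotrait.R`
(`Rscript allotrait.R pipeline --seed 1 --out out`).

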