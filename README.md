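# domdfe

Co-estimation of the **distribution of fitness effects (DFE)** and the
**dominance–selection relationship** of new nonsynonymous mutations,
from the site frequency spectra (SFS) of an outcrossing and a highly
selfing population.

## The problem and the approach

In a diploid, a mutation's fitness effect has two coordinates: the
selection coefficient *s* (genotype fitnesses 1, 1 + *hs*, 1 + *s*)
and the dominance coefficient *h*. A single outcrossing population is
nearly uninformative about them separately — deleterious alleles are
rare and almost always heterozygous, so its SFS constrains only the
product *hs*. In a highly selfing population (inbreeding coefficient
*F* ≈ 1) genotypes are homozygous, the spectrum responds to *s* alone,
and the confounding breaks: fitting both populations jointly separates
*h* from *s*.

`domdfe` implements this as a composite Poisson random-field
likelihood. Folded SFS counts *X<sub>i</sub>* are independent Poisson
variables with means E[*X<sub>i</sub>*] computed by a finite-volume
diffusion solver under mutation, drift, selection, dominance,
inbreeding and up to three demographic epochs (fitted first to the
synonymous SFS). The DFE is a gamma distribution over deleterious *s*
(optionally with a neutral point mass), and dominance follows one of
three nested models:

* additive: *h* = 0.5;
* constant: *h* = *h*<sub>const</sub>;
* h–s relationship:
  *h* = 1 / (1/θ<sub>intercept</sub> − θ<sub>rate</sub> · *s*),
  so more deleterious mutations can be more recessive
  (a logistic form is also available).

Nested models are compared with likelihood-ratio statistics
Λ = 2(LL₁ − LL₀) against chi-square references (df 1 or 2). For the
selfing population the diffusion reduces exactly to a scaled additive
model — the mean frequency change at *F* = 1 is twice the additive
outcrossing term — so its expected spectra are computed with the
additive engine at *s*<sub>e</sub> = 2*s* and the drift-matched
effective size. Expected spectra under arbitrary DFEs come from a
spline-refined lookup grid over (*N*<sub>e</sub>*s*, *h*), built coarse
(50 × 20) and refined to 1000 × 1000 by two-pass cubic splines.

The package also includes the mechanistic **expression-cost model of
dominance**: fitness as a diminishing-returns function of expression
level minus a linear cost,
*f*(*x*) = (*x* + intercept·scale)(1 − *c·x*)/(*x* + scale), whose
loss-of-function mutations have *s* and *h* determined by fitness at
optimal, half and zero expression — predicting that mutations are
recessive and that more deleterious mutations are more recessive.

## Worked example

Simulate a two-species dataset at the package's study conditions
(additive truth, one tenth of genome-wide mutation-rate magnitudes),
write it as dadi-style `.fs` files, and run the full pipeline:

```r
library(domdfe)

paths <- generate_fixtures("fixtures", profile = "small_category", seed = 1)
cfg <- run_config(
  spectra = list(out_syn = paths[["outcrossing_syn.fs"]],
                 out_nonsyn = paths[["outcrossing_nonsyn.fs"]],
                 self_syn = paths[["selfing_syn.fs"]],
                 self_nonsyn = paths[["selfing_nonsyn.fs"]]),
  L_syn = c(out = 1.88e7, self = 2.99e7),
  demography_family = "constant", n_starts = 8, seed = 1)
report <- run_full_inference(cfg)
report
#> <inference_report>
#>   out: theta_syn = 13146.3, N_e = 24974, F = 0
#>   self: theta_syn = 4092.85, N_e = 4895.76, F = 1
#> <dominance_model_menu>
#>   additive  logLik = -90.108
#>   constant  logLik = -87.794
#>   hs        logLik = -87.794
#> # A tibble: 3 x 5
#>   null     alternative        lambda    df p_value
#>   <chr>    <chr>               <dbl> <int>   <dbl>
#> 1 additive constant    4.63              1  0.0314
#> 2 additive inverse     4.63              2  0.0988
#> 3 constant inverse     0.00000000948     1  1.000
```

Reading the output: the synonymous mutation rates (θ ≈ 13,146 and
4,093) and ancestral sizes are re-estimated from the simulated spectra
(truth: 13,160 / 4,180; *N*<sub>e</sub> 25,000 / 5,000). Because the
data were simulated additive, the h–s relationship buys essentially no
log-likelihood over a constant *h* (Λ ≈ 0, p ≈ 1), and the constant-*h*
improvement over strict additivity (Λ = 4.6, p = 0.03) is the size of
fluctuation expected under the null — the 100-replicate calibration in
`lrt_calibration()` quantifies exactly this. When the truth contains a
real h–s relationship, `power_recovery()` shows Λ in the tens with the
fitted *h*(−0.001) recovered within a factor of two.

Uncertainty comes from Poisson-resampling bootstrap
(`bootstrap_fit()`, 20 replicates, normal-approximation 95% CIs), and
`z_compare()` tests parameter differences between gene categories with
Bonferroni correction.

A thin command-line driver wraps these functions:

```sh
Rscript inst/cli/domfit.R simulate      --config sim.yaml --out fixtures/
Rscript inst/cli/domfit.R fit           --config run.yaml --out results/
Rscript inst/cli/domfit.R calibrate-lrt --config cal.yaml --out results/
```

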