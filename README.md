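# coexipm

Demographic coexistence analysis along environmental gradients with
integral projection models (IPMs).

## The problem

Where along an environmental gradient can a species persist with its
competitors, and why does that ability change? Transplant competition
experiments answer this demographically: focal plants are grown without
neighbours and inside resident monocultures at several sites, and their
survival, growth, flowering and fecundity are followed over annual
censuses. `coexipm` turns such individual-level records into
population-level and pair-level predictions:

* **Intrinsic growth rates** λ<sub>i</sub> — the dominant eigenvalue of a
  size-structured projection kernel built from vital rates estimated
  without competition (N<sub>t+1</sub> = λN<sub>t</sub>; ln λ > 0 means
  the population persists).
* **Invasion growth rates** λ<sub>ij</sub> — the same, for a focal species
  invading a resident monoculture assumed to be at equilibrium.
* **Sensitivities to competition**
  S<sub>ij</sub> = 1 − ln λ<sub>ij</sub> / ln λ<sub>i</sub>,
  from which a pair's niche difference ND = 1 − √(S<sub>ij</sub>S<sub>ji</sub>),
  relative fitness difference RFD = √(S<sub>ji</sub>/S<sub>ij</sub>), and
  coexistence metric 1/(RFD′(1−ND)) = 1/max(S<sub>ij</sub>, S<sub>ji</sub>)
  follow (RFD′ is the orientation with RFD ≥ 1).
* **Competitive outcomes** by mutual invasibility: both species invade →
  stable coexistence; neither → priority effect; one → exclusion.
* **Uncertainty** by a multivariate-normal parametric bootstrap of the
  vital-rate coefficients, propagated through every kernel and every
  downstream quantity.
* **Gradient trends** via mixed-effects models with likelihood-ratio tests,
  both on bootstrap means and replicate by replicate.

Vital-rate regressions (binomial GLMs for survival and flowering, Gaussian
models for growth and log fecundity) are selected by AICc over all nested
submodels of `size + site + background + size:site + size:background`.

A first-class synthetic-data generator emulates the transplant experiment —
two origin groups of species whose vital rates decline beyond their
elevational range edges, competition penalties with stronger intraspecific
effects, replacement of dead transplants, recruitment sowing trials — with
known true parameter surfaces, so every stage of the pipeline can be
validated against exact ground truth. See the methods vignette
(`vignettes/coexipm-methods.Rmd`) for the model, assumptions, and design
choices.

## Worked example

```r
library(coexipm)

# a small synthetic community: 2 lowland + 2 highland species, vital rates
# declining beyond their range edges, 3 sites at 890/1400/1900 m
pool    <- species_pool(2, 2, scenario = "range_limited", seed = 1)
design  <- experiment_design(species_ids = names(pool),
                             n_individuals = 60, n_transitions = 3, seed = 2)
dataset <- simulate_individuals(pool, design)

fits   <- fit_all_species(dataset)                      # GLMs + AICc selection
lambda <- estimate_lambda_table(fits, contexts_from_design(design))
head(subset(lambda, background == "none"), 6)
#>    species background site_elevation_m    lambda   ln_lambda
#> 1   low_01       none              890 1.4278676  0.35618213
#> 2   low_02       none              890 1.8902626  0.63671574
#> 3  high_01       none              890 0.8492285 -0.16342698
#> 4  high_02       none              890 0.9815981 -0.01857329
#> 21  low_01       none             1400 1.2155305  0.19518063
#> 22  low_02       none             1400 1.3803083  0.32230687
```

Both lowland species persist alone at 890 m (ln λ > 0) while the highland
species are below replacement beyond their lower range edge. Pair-level
quantities at the low site:

```r
pairs <- pair_table(lambda, pool_origins(pool))
pairs[pairs$site_elevation_m == 890,
      c("species_i", "species_j", "pair_type", "S_ij", "S_ji", "ND", "metric", "outcome")]
#>    species_i species_j         pair_type        S_ij        S_ji        ND   metric               outcome
#> 1     low_01    low_02   lowland-lowland   0.9702857   0.6547625 0.2029387 1.030624    stable_coexistence
#> 4    high_01    low_01  lowland-highland  -3.6149215   0.8148508        NA       NA competitive_exclusion
#> 16   high_01   high_02 highland-highland  -2.6637865 -11.2613859        NA       NA       priority_effect
```

The two lowland species coexist at their home site (both sensitivities
below 1; the metric barely exceeds 1, so coexistence is weak). The
highland species cannot persist there even alone, so their sensitivities
take flagged negative values, ND/RFD are withheld, and outcomes come from
the invasion growth-rate signs directly.

Uncertainty and trends:

```r
ens <- run_bootstrap(fits, contexts_from_design(design), B = 100, seed = 3,
                     origins = pool_origins(pool))
x <- subset(ens$lambda, species == "low_01" & background == "none" &
                        site_elevation_m == 1900)
summarize_ensemble(x$ln_lambda)
#>      median        lo95        hi95
#> -0.03028778 -0.11465816  0.03578937

intr <- subset(ens$lambda, background == "none")
intr$origin <- factor(pool_origins(pool)[intr$species],
                      c("lowland", "highland"))
per_replicate_test(intr, "ln_lambda", group = "origin",
                   random = "species")[c("median", "lo95", "hi95", "significant")]
#> $median
#> [1] 0.0008683321
#> $lo95
#> [1] 0.0008184767
#> $hi95
#> [1] 0.0009317722
#> $significant
#> [1] TRUE
```

The elevation × origin interaction in intrinsic ln λ is ~0.00087 per metre
(95% bootstrap interval 0.00082–0.00093, excluding zero): lowland and
highland growth rates diverge along the gradient, each group declining
beyond its own range edge — the generator's built-in truth, recovered from
the simulated field data.

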