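# disperseIPM

Microhabitat-structured integral projection models (IPMs) for quantifying
how individual frugivore species affect the population growth of a
fleshy-fruited tree.

## The problem

Fleshy-fruited plants trade pulp for transport: birds and mammals swallow
fruits, carry the seeds, and deposit them — often under different canopy
cover than the parent tree, and with a germination advantage because gut
passage frees the seed from the fruit. Whether a particular disperser
species matters for the *plant's* long-term growth rate is hard to judge
from interaction counts alone: it depends on how often the animal handles
fruits (quantity), on what it does with them (swallow, drop, or crush),
where along the light gradient it deposits the seeds, and on how seedlings
recruited in those microhabitats survive, grow, break, re-sprout and
eventually reproduce. `disperseIPM` assembles all of these pieces into one
demographic model and asks the full-life-cycle questions: how much does
animal dispersal add to the population growth rate λ, which species'
loss would hurt most (interaction deficit), and can the remaining
community buffer such a loss (interaction compensation)?

## The model

Individuals are characterized by standardized log10 stem diameter `z` and
the standardized canopy cover `c` at their location. One projection step
applies

    n'(z', c') = ∫ [ P(z', z, c) + Σ_x F_x(z', c', z, c) + F_grav(z', z, c) ] n(z, c) dz dc

* `P = S(z,c) (1 − B(z)) G(z'|z,c) + S(z,c) B(z) R(z'|z)` — survival,
  growth, breakage and re-sprouting; never moves a plant along the canopy
  axis.
* `F_x` routes each fruit through species `x`:
  consumed seeds (weight `a·q_x·f_nocrush,x·f_consumed,x`) are transported
  to a canopy segment drawn from the species' deposition distribution and
  recruit at the full per-seed rate; dropped fruits stay beneath the
  parent and pay the within-fruit germination penalty (`f_recfruit =
  0.30`, i.e. a −70% effect relative to gut-passed seeds).
* `F_grav` (weight `1 − a`) keeps seeds under the parent with the same
  penalty. `a` is the proportion of fruits removed by animals.

The kernel is discretized on 100 size bins × 10 canopy segments with
cumulative-kernel (bin-to-bin) integration and eviction folded into the
boundary bins, so transition columns sum to one exactly. λ is the dominant
eigenvalue (power iteration); per-species effectiveness is quantity
(relative interaction frequency) × quality (probability that a handled
seed produces a reproductive adult, via an absorbing Markov chain), and
species-loss scenarios are evaluated against the baseline stable stage
structure and reproductive values (see the methods vignette,
`vignettes/methods.Rmd`, for why and for every numerical convention).

A synthetic-data module generates all five input record types — census
transitions, fruit-removal observations, scat records, sowing-experiment
counts, canopy availability — from a frozen, fully known ground truth, so
the entire pipeline is testable without any field download and parameter
recovery can be asserted against truth.

## Worked example

The one-call pipeline simulates a full dataset at the default study
dimensions (1002 census transitions, 1006 frugivore visits, 1729 scats,
100 sowing subplots × 25 seeds), fits the vital rates with AICc selection,
estimates disperser profiles with the 30-scat pooling rule, and runs every
demographic analysis:

```r
library(disperseIPM)
res <- run_pipeline(list(seed = 1L))

round(res$local_lambdas, 3)
#>  [1] 1.163 1.134 1.106 1.080 1.056 1.035 1.015 0.998 0.982 0.968
round(res$lambda_gravity, 3)
#> [1] 1.001
```

Local growth rates decline monotonically from bright gaps (λ = 1.16) to
closed forest (λ = 0.97); weighting them by microhabitat availability
(only ~7% of the forest is in the brighter half of the canopy range) gives
the gravity-dispersal summary λ = 1.001. Increasing the animal-dispersed
fraction raises λ in both scenarios:

```r
est <- subset(res$sweeps, scenario == "fully_established")
gap <- subset(res$sweeps, scenario == "gap_colonization")
est$lambda[11] - est$lambda[1]   # benefit, fully established:  0.0499
gap$lambda[11] - gap$lambda[1]   # benefit, gap colonization:   0.0561
```

The per-species effectiveness table decomposes this benefit:

```r
res$sde[order(-res$sde$quantity), ]
#>     species   quantity  quality delta_lambda_deficit relative_reduction_pct
#>   blackcap  0.483      0.01418             0.013200                  26.40
#>   blackbird 0.218      0.01360             0.004990                  10.00
#>   songthrush 0.103     0.01294             0.002100                   4.20
#>   marten    0.076      0.01306             0.002590                   5.20
#>   robin     0.060      0.01195             0.000783                   1.57
#>   other     0.038      0.01454             0.001700                   3.40
#>   hawfinch  0.022      0.00018            -0.000876                  -1.76
```

Losing the dominant disperser (blackcap, 48% of interactions) costs the
most growth; the seed predator (hawfinch, which crushes 80% of the fruits
it handles) has a *negative* deficit — its loss helps the tree. Quality
varies ~80-fold across species but effectiveness tracks quantity:

```r
res$correlations
#>  component   rho  p_value n
#>   quantity 0.929   0.0025 7
#>    quality 0.643   0.1194 7
```

`sde_compensation()` shows the community can largely buffer the loss of
any single common disperser by scaling up its remaining interactions
(`lambda_compensation` ≈ 1.05 versus the deficit values above). Bootstrap
prediction intervals for every quantity come from
`bootstrap_pipeline()` (stratified within species/sites so every disperser
is present in each of the 500 replicates), or set
`bootstrap = list(enabled = TRUE)` in the config.

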