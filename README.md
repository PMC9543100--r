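# fishestab

Does ecological similarity to the resident community help or hinder an
introduced species? For freshwater fishes the two classic answers point
in opposite directions: relatedness to natives can signal shared
pre-adaptation to the local environment (success), or shared niches and
enemies (failure). `fishestab` is an R package for separating these
forces in records of *intentional fish introductions with known
outcomes*: it measures exotic–native similarity on two axes at once —
phylogenetic distance from a dated tree and functional distance from a
morphological trait space — and models binary establishment outcomes
against both, alongside native diversity and lake geography.

It is aimed at invasion ecologists and community phylogeneticists with
an introduction-events table (lake, species, outcome), a lake × species
native presence matrix, lake attributes, a Newick phylogeny and a
continuous trait table.

## What it computes

For each introduction event, with D either the cophenetic
(phylogenetic) or trait-space (functional) distance matrix:

* similarity of the introduced species *i* to the natives N of the
  target lake: I-N MPD = mean over j in N of d(i, j), and I-N MNTD =
  min over j in N of d(i, j) (functional analogues: I-N MFD, I-N MNFD);
* diversity of the natives themselves: MPD = mean of d(j, k) over pairs
  in N, and MNTD = mean nearest-neighbour distance (MFD, MNFD);

and fits three complementary models of the outcome y ∈ {0, 1}:

1. a **Bayesian phylogenetic hierarchical model**
   (logit P(y=1) = β₀ + Xβ + u_lake + v_species + w_species, with
   w ~ N(0, σ²_P Σ) and Σ the Brownian covariance of the introduced
   species; JAGS MCMC, WAIC model comparison, relative-importance
   partition |β_i| / Σ|β_j|);
2. an **all-subsets GLMM comparison** (lme4; AICc ranking of all 2^8
   fixed-effect subsets, Akaike-weight averaging of models with
   ΔAICc < 2);
3. a **piecewise structural equation model** (per-node mixed
   regressions, Shipley's d-separation basis set, Fisher's
   C = −2 Σ ln p, d-sep AIC = C + 2K model selection, latent-scale
   standardized paths, direct/indirect/total effect decomposition).

A synthetic-data generator (Yule tree, Brownian traits with tunable
signal, gradient-structured lake communities, forward-simulated
outcomes) makes the whole pipeline testable without any survey data.

## Worked example

```r
library(fishestab)

d <- synth_dataset(synth_config(n_lakes = 40, n_events = 300, seed = 7))

m <- mantel_test(d$Dphy, d$Dfun, n_perm = 999, seed = 1)
#> Mantel r = 0.337, p = 0.001

Sig <- phylo_covariance(d$tree, unique(d$covariates$species_id))
fit <- fit_hier(d$covariates, Sig, n_chains = 2, n_iter = 1000,
                n_adapt = 500, seed = 1)
fit
#> Bayesian phylogenetic hierarchical establishment model
#> events: 300   WAIC: 393.3
#>
#>                mean median    sd   q2.5  q97.5    q15    q85
#> (Intercept)  -0.234 -0.230 0.212 -0.649  0.183 -0.456 -0.020
#> in_mpd_z     -0.662 -0.667 0.197 -1.056 -0.294 -0.861 -0.456
#> in_mfd_z      0.432  0.437 0.200  0.030  0.814  0.224  0.638
#> native_mpd_z  0.437  0.447 0.208  0.033  0.842  0.217  0.644
#> native_mfd_z -0.110 -0.112 0.196 -0.494  0.269 -0.308  0.092
#> richness_z   -0.344 -0.342 0.265 -0.869  0.210 -0.598 -0.097
#> area_z       -0.289 -0.288 0.169 -0.625  0.054 -0.460 -0.127
#> elevation_z  -0.099 -0.102 0.200 -0.488  0.319 -0.295  0.096
#> latitude_z   -0.449 -0.443 0.272 -1.003  0.116 -0.717 -0.193
#>
#> random-effect variances:
#>    lake species   phylo
#>   0.321   0.412   0.007
```

The Mantel correlation confirms phylogenetic signal in the trait space
(related species have similar traits) while leaving most functional
variation unexplained — which is what lets the two similarity axes act
independently. The fit recovers the generator's truth (β = −0.6 on
I-N MPD, +0.5 on I-N MFD): establishment probability *falls* with
phylogenetic distance to the natives and *rises* with functional
distance — introductions succeed when the exotic is a close relative
that does something functionally different. The 95% intervals of both
focal effects exclude zero on the correct side.

```r
relative_importance(fit, groups = list(
  similarity = c("in_mpd_z", "in_mfd_z"),
  diversity  = c("native_mpd_z", "native_mfd_z", "richness_z"),
  geography  = c("area_z", "elevation_z", "latitude_z")))
#> similarity  diversity  geography
#>       38.8       31.6       29.6   (percent of summed |effect|)
```

`run_pipeline()` chains everything — generation or file input,
distances, covariates, both metric families with their WAIC comparison,
the GLMM sweep and the SEM — into one seeded, logged run with hashed
artifacts.

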