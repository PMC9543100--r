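---
title: "Modeling establishment of introduced fishes from phylogenetic and functional similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling establishment of introduced fishes from phylogenetic and functional similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the data structure

Whether an introduced species establishes in a recipient community has
long been argued to depend on its ecological similarity to the resident
species, in two opposing ways. Under the pre-adaptation view, exotics
closely related to natives share their adaptations to the local
environment and should succeed more often; under the naturalization
(competition) view, exotics too similar to residents face stronger
competition and shared enemies and should fail more often.
`fishestab` implements an analysis that separates these forces by
measuring similarity on two axes at once — phylogenetic distance from a
dated tree, and functional distance from a morphological trait space —
and regressing binary establishment outcomes of intentional fish
introductions on both, together with the recipient lake's native
diversity and geography.

The unit of analysis is an *introduction event*: one species introduced
into one lake, with outcome 1 (established) or 0 (failed). Events are
cross-classified by lake and by species — many introductions share a
lake, and popular species are introduced many times — so every model in
the package carries lake and species random intercepts.

## Covariates

For each event the `metrics` layer computes, on each distance matrix
(phylogenetic and functional):

* **I-N MPD / I-N MFD** — the mean distance between the introduced
  species and all natives of the target lake (the similarity measures;
  larger = less similar);
* **I-N MNTD / I-N MNFD** — the distance to the single nearest native;
* **native MPD / MFD, MNTD / MNFD** — the mean pairwise and mean
  nearest-neighbour distances among the natives themselves (diversity
  measures);

plus native richness and the lake's area, elevation and latitude. An
introduced species accidentally coded as native to its own target lake
is excluded from that lake's native set and the event is flagged.
Events whose lake retains fewer than two usable natives are dropped
with a log entry, because the native pairwise metrics are undefined
there. Covariates are z-score standardized over the retained event set,
so all coefficients are comparable effect sizes per SD.

The phylogenetic matrix is the cophenetic distance (sum of branch
lengths on the tip-to-tip path). The functional matrix is the Euclidean
distance over the first five principal components of ten continuous
morphological traits. The PCA standardizes traits first
(correlation-matrix PCA): the traits arrive on incommensurate scales
(body length in mm next to dimensionless shape ratios), so a
covariance-matrix PCA would let one trait dominate; a covariance option
is kept for pre-scaled tables. Component signs follow a fixed
convention (largest-magnitude loading positive) so scores are
reproducible across platforms. The Mantel test (Pearson correlation of
distance triangles, one-sided upper-tail permutation p, 9999
permutations by default, seeded; exact enumeration below 8 species)
quantifies the phylogenetic signal in the trait space.

## The hierarchical establishment model

The core model is a Bernoulli regression on the logit scale,

logit P(y = 1) = beta0 + X beta + u_lake + v_species + w_species,

with u ~ N(0, sigma2_L I), v ~ N(0, sigma2_S I) and a phylogenetically
correlated species effect w ~ N(0, sigma2_P Sigma), where Sigma is the
Brownian-motion covariance of the introduced species (shared
root-to-ancestor path lengths, extracted from the full-tree covariance
and rescaled to unit maximum diagonal). Priors are weakly informative:
N(0, 10^2) on all fixed effects and Gamma(0.01, 0.01) on the three
random-effect precisions. The posterior is sampled with JAGS (four
chains by default, seeded per chain), with a convergence gate of R-hat
below 1.01 on the fixed effects; only the product sigma2_P * Sigma is
identified, which is why Sigma is normalized, and with Sigma close to
the identity the split between v and w is not identifiable — only their
sum is, which the reported variances should be read as.

Model families are compared with WAIC computed from the pointwise
posterior log-likelihood; the analysis is run once with the mean-metric
family (I-N MPD, I-N MFD, native MPD, native MFD) and once with the
nearest-metric family, and the family with the lower WAIC is reported.
The *relative importance* of each predictor is the ratio of the
absolute posterior-mean coefficient to the sum of absolute values over
the eight predictors, expressed in percent. The denominator is the sum
of absolute values: a signed sum could be arbitrarily close to zero and
the shares would not partition. Grouped shares (similarity = the two
I-N metrics, diversity = richness + native metrics, geography = area +
latitude + elevation) sum to 100 by construction.

A frequentist check runs the matching GLMM (lme4, Laplace
approximation, no phylogenetic term) through an all-subsets AICc sweep
over the 2^8 fixed-effect subsets — the random-effect structure is
never subset — followed by Akaike-weight averaging of the models within
2 AICc of the best. Averaging uses the full-average (zero-substitution)
convention with Burnham–Anderson unconditional standard errors; the
conditional average is a one-line change but full averaging is the
conservative default when the goal is effect direction and magnitude.
AICc counts the two random-effect variances in k; the alternative
(fixed-effect count only) shifts every candidate equally and cannot
change the ranking within this design.

## Piecewise structural equation model

Direct and indirect pathways are separated with a piecewise SEM: one
regression per endogenous variable (Gaussian for the continuous
diversity/similarity nodes, Bernoulli for establishment), each with the
lake and species random intercepts where identifiable. The default
initial graph routes geography into richness, richness into the native
diversity metrics, diversity into the two I-N similarity metrics, and
similarity (plus lake area) directly into establishment; the
temperature variant swaps the geographic drivers for accumulated and
maximum water temperature. Model fit is evaluated with Shipley's
d-separation test: one independence claim per non-adjacent ordered
pair, conditioned on the union of both parents' sets, tested by adding
the earlier variable to the later variable's component regression and
reading its two-sided Wald p; Fisher's C = -2 sum log p is chi-squared
with twice the number of claims under the model, and candidate graphs
are compared with the d-sep information criterion C + 2K, K counting
all coefficients plus variance components across component models.

Selection starts from the initial graph and adds one edge at a time for
a violated claim (earlier node into later node, so the graph stays
acyclic). Violated claims are tried in order of significance and the
first candidate that lowers C + 2K is kept; adding an edge changes the
conditioning sets of the remaining claims, so the most significant
violation is not always the best repair, which is why the step examines
up to five candidates before giving up. Correlated-error links are not
supported; a dependence between two exogenous variables can therefore
only be absorbed by a directed edge between them, which should be read
as statistical, not causal.

Standardized coefficients for Gaussian components are the usual
beta * sd(x) / sd(y). For the Bernoulli component the observed outcome
has no usable residual SD, so standardization uses the latent-scale
convention: the denominator is the square root of the fixed-effect
variance plus the random-effect variances plus the logistic residual
variance pi^2/3. The same latent variance enters the conditional R2
(Nakagawa partition: explained = fixed + random over total). Total
effects are direct plus the sum over all directed paths of products of
standardized coefficients; relative totals normalize absolute totals to
100 percent. By default the decomposition uses all retained paths; a
`significant_only` switch restricts it to paths with p < 0.05, which is
how such path diagrams are usually displayed — the two conventions give
different totals and the choice is deliberately exposed.

Two degeneracies are handled explicitly. A component whose response is
constant within a grouping (every lake-level response with a lake
intercept) makes that random effect unidentifiable from the residual;
the fit falls back to the fixed-effects-only regression and is flagged.
And claim p-values from such components are computed at the event
level, which over-weights lakes with many introductions; together with
the strictly log-linear richness gradient of the synthetic generator
(linear claim regressions then detect genuine residual curvature at
n = 965), this keeps the global Fisher's C large on synthetic data even
for the selected graph. The selected path structure, the standardized
coefficients and the effect decomposition are the stable outputs; the
global C should be read as a misspecification alarm, not a fit index to
optimize.

## The synthetic generator

The generator exists so that every stage can be verified against known
truth. It emulates the structure of the motivating survey of
intentional introductions into Swedish lakes at its published scale: 38
species on a Yule (pure-birth) tree, an introduced pool of 23 species
drawn with unequal (geometric) frequencies, 100 lakes, 965 introduction
events, native richness between 2 and 27 with median near 6 declining
toward high latitude and elevation. Traits are a blend
sqrt(lambda) * BM + sqrt(1 - lambda) * noise of a Brownian-motion
realization and independent Gaussian noise scaled to the Brownian tip
variance, so lambda tunes the phylogenetic signal without changing
marginal trait variance; the default lambda = 0.7 produces the clearly
significant but imperfect Mantel correlation (r around 0.3) that
morphological traits typically show. Native assemblages are sampled
with mild phylogenetic clustering (sampling weight decaying with
cophenetic distance to a random anchor species). Outcomes are the
hierarchical model run forward: standardized covariates, true focal
coefficients -0.6 on I-N MPD and +0.5 on I-N MFD, the six remaining
coefficients drawn once from N(0, 0.15^2), random-effect SDs 0.5, and
the phylogenetic effect drawn from the scaled tree covariance.
Covariates are standardized *before* the coefficients are applied, so
recovery checks compare like with like. Water temperatures are
generated from an air-temperature gradient plus depth and area and
observed for 30 percent of lakes, leaving the rest for the two-stage
imputation (air temperature regressed on latitude and elevation, water
temperature on depth, area and predicted air temperature; without an
air column the reduced form regresses water temperature on the four
lake attributes directly — the survey protocol does not state the
transform, and both temperature regressions use raw scales by default).

What the generator does *not* emulate: propagule pressure (number and
size of introductions per event), temporal structure beyond a cosmetic
year column, spatial autocorrelation among lakes, observation error in
the outcome, and trait measurement error. Passing tests therefore show
that the machinery recovers what it assumes, not that those assumptions
hold in any real survey.

## Numerical conventions and problem sizes

All randomness flows from a single root seed split per stage.
Distance-matrix validation tolerates asymmetry up to 1e-8; the
phylogenetic covariance receives a 1e-8 diagonal jitter before
inversion and Cholesky. Hierarchical clustering sorts species
lexicographically first so merge ties resolve deterministically; the
all-subsets ranking breaks AICc ties by parameter count, then subset
name. The test suite exercises the full study scale (965 events) for
the sign-recovery and three-family agreement checks, and reduced sizes
(40 lakes, 250 events; 2 MCMC chains with a few hundred kept draws)
for module-level checks, which keeps a complete run of the suite within
a coffee break on one CPU while leaving the generator's scientific
defaults untouched.
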