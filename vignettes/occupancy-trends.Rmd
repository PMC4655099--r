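---
title: "Occupancy trends from opportunistic records and their trait correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy trends from opportunistic records and their trait correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Volunteer recording schemes accumulate large numbers of species occurrence
records without any sampling design. Recording effort grows over time,
varies between sites, and varies between visits, so the raw number of
occupied grid cells per year is a biased measure of how a species is really
doing. occutrend implements a two-stage analysis for such data:

1. **Occupancy stage.** Per species, a Bayesian occupancy-detection model
   separates where the species truly is from how likely it was to be
   recorded when present, using the *list length* of each visit (the number
   of species recorded on it) as a proxy for effort. The posterior yields
   annual occupancy and, within each MCMC draw, the ordinary least-squares
   slope of occupancy on year — the species trend, with full posterior
   uncertainty.
2. **Comparative stage.** Trends are regressed on species traits with
   phylogenetic generalized least squares (PGLS), using a taxonomy-based
   tree. Per-species trend uncertainty is propagated by resampling: each of
   many iterations draws one slope per species from its posterior, refits
   the PGLS (re-estimating Pagel's lambda by maximum likelihood), and the
   trait coefficients are summarised across iterations by their mean and
   2.5/97.5 percentiles.

## Data model

A **record** is (species, date, 1 km grid cell). A **visit** is a unique
(site, date) pair; its detection history codes each species as recorded or
not, and its list length `L` is the number of species on the list. Only
full-precision dates are accepted: a visit is defined by an exact date, so
year- or year-month-only records are rejected (with counts in the ingest
log). Records are detection/non-detection only; duplicates are collapsed
silently with a logged count. Sites are opaque identifiers — no grid
geometry is used anywhere in the model.

Sites with fewer than three distinct years with at least one visit are
discarded ("well-sampled sites" filter). We read "years of data" as
distinct calendar years with a visit; the threshold is the `min_years`
argument of `filter_sites()` and the filter is idempotent.

## The occupancy-detection model

For a focal species, with sites $i$, years $t$ (closure period = one year)
and visits $v$:

State model (true presence):

$$z_{i,t} \sim \mathrm{Bernoulli}(\psi_{i,t}), \qquad
  \operatorname{logit}\psi_{i,t} = a_t + b_i$$

Observation model, conditional on the state:

$$y_v \sim \mathrm{Bernoulli}(z_{i(v),t(v)} \cdot p_v), \qquad
  \operatorname{logit} p_v = c_{t(v)} + d\,\log L_v$$

Priors: year effects $a_t \sim N(0, 10^2)$ independently (vague on the
logit scale); site effects $b_i \sim N(0, \sigma_b^2)$ with
$\sigma_b \sim U(0, 5)$; detection intercepts $c_t \sim N(0, 10^2)$;
$d \sim N(0, 10^2)$. A categorical list-length form — separate effects for
lists of 2–3 and of 4+ species, single-species lists as the reference — is
available via `occu_config(list_length = "categorical")`; the continuous
$\log L$ form is the default for parsimony (one parameter instead of two).

The model is fitted by MCMC through JAGS (rjags). Each chain carries its
own fixed RNG seed derived from the configuration seed, so identical
configuration and data give bit-identical draws. Latent states are
initialised occupied everywhere, which is always consistent with the data
(a detection forces presence). Convergence is monitored by the potential
scale reduction factor on all scalar parameters; values above the
configured threshold (default 1.1) raise a warning naming the parameters,
not an error — short exploratory chains are legitimate, and the warning
keeps the decision with the analyst.

Derived quantities, computed per retained draw:

* annual occupancy $\bar\psi_t = \tfrac{1}{n}\sum_i z_{i,t}$, over **all**
  modelled sites, visited in year $t$ or not;
* the trend $s$ = unweighted OLS slope of $\bar\psi_t$ on calendar year.
  We deliberately use the simplest reading of "a linear trend"; a
  precision-weighted variant would down-weight poorly observed years but
  also couple the trend to the detection model in less transparent ways.

Years inside the study span with no visits anywhere still receive year
effects (drawn from their prior) so that occupancy is defined for every
year; such years are flagged in the fitted object.

A species' trend is classified **increasing** when the 2.5 percentile of
$s$ exceeds zero, **declining** when the 97.5 percentile is below zero,
and **uncertain** otherwise (the interval bridges zero).

## Phylogeny and PGLS

With no molecular phylogeny assumed, the tree is built from taxonomy: one
node per suborder, family and genus, species as tips, all branch lengths 1,
and a single root above the suborders. Every tip sits at depth 4;
cross-suborder pairs share no branches below the root, so their covariance
is zero. Monotypic chains are kept as distinct unit branches. The
covariance matrix $V$ has $V_{jk}$ = shared root-to-MRCA path length
(computed via ape), and Pagel's lambda scales its off-diagonals:
$V(\lambda) = \lambda V + (1-\lambda)\,\mathrm{diag}(V)$.

`pgls_fit()` solves the GLS problem
$\hat\beta = (X^\top V(\lambda)^{-1} X)^{-1} X^\top V(\lambda)^{-1} y$ via
Cholesky (or an eigendecomposition fast path when all tip depths are
equal, as they are for taxonomy trees). $\lambda$ is estimated by profile
maximum likelihood — ML, not REML, as the literal reading of "maximum
likelihood", noting REML as the obvious sensitivity variant — with a
101-point grid scan on $[0,1]$ followed by bounded local refinement
(tolerance $10^{-6}$), ties broken toward smaller $\lambda$. The grid scan
makes the optimizer deterministic and immune to local optima at this
resolution; at $\lambda = 0$ and equal tip depths the estimator reduces
exactly to OLS (with unequal tip depths, $\lambda = 0$ is a weighted
regression — the diagonal of $V$ is never rescaled).

## Trait design

Seven traits enter as fixed effects. Distribution status is ordinal,
coded symmetrically (very rare $= -1.5$ … very widespread $= +1.5$) and
treated as continuous. Thorax length (mm), flight period (months) and
habitat breadth (count of habitats, 1–6) are continuous; all continuous
traits (status included) are centred on zero. The categorical traits use
treatment contrasts with fixed reference levels: region vs "southern",
breeding habitat vs "lentic", overwintering stage vs "eggs" — reference
species carry zeros across their contrast columns, so categorical
coefficients read as contrasts to the reference. With every trait present
the design has 12 columns including the intercept. Zero-variance
non-intercept columns (a level absent from the data) are dropped with a
warning rather than an error, keeping reduced synthetic designs usable.

## The resampling loop

`resample_pgls()` runs `n_iter` iterations (default 10,000). Each
iteration draws one slope per species — independently across species,
since the occupancy models are fitted per species and no joint posterior
exists — uniformly from that species' stored posterior draws, then fits
the PGLS with $\lambda$ re-estimated by ML in every iteration (the
distribution of $\hat\lambda$ across iterations is part of the output).
Coefficients are summarised by their mean and empirical 2.5/97.5
percentiles across iterations; "95% confidence intervals" here are those
percentiles, not Wald intervals. Singular fits are retried with fresh
draws; more than 1% failures aborts. One master seed drives the loop, so
results are exactly reproducible.

Because the design, covariance matrix and $\lambda$ grid are fixed across
iterations, the per-grid-point Cholesky factors of the normal equations
are precomputed once; each iteration then costs a set of triangular
solves. This is an implementation detail — it produces identical results
to the plain per-iteration fit, which the tests verify.

## The synthetic-data generator

`simulate_records()` emulates the structure of a recording-scheme extract:

* per-species annual occupancy trajectories (any species-by-year
  probability matrix; linear trajectories as a convenience), optional
  logit-scale site heterogeneity, independent states across years;
* visits per site-year from a Poisson (or fixed) effort model;
* a visit list length $L \ge 1$ from a zero-truncated Poisson whose mean
  can drift linearly across the window, emulating the growth of recording
  effort; zero-truncation because a visit only exists if something was
  recorded;
* focal detection with probability $\operatorname{logit}^{-1}(c + d\log L)$
  (or a constant $p$); a detected focal occupies one of the $L$ list
  slots and background-pool species fill the rest, so the list length of
  the emitted records equals the generative covariate — the focal counts
  toward its own list, and the detection model sees exactly the effort
  variable that generated the data.

`simulate_trait_system()` plants trait effects on true slopes with
phylogenetically correlated residual noise (covariance
$\sigma^2 C(\lambda_{true})$, $C$ the unit-diagonal tree correlation) and
emits Gaussian pseudo-posterior draws per species.

What the generator does **not** emulate: spatial autocorrelation of
occupancy, observer identity and skill, misidentification (false
positives), within-season phenology of detectability, and
colonization/persistence dynamics between years. Passing tests therefore
demonstrate correctness of the inference machinery under the stated model
family, not robustness to every bias in real scheme data.

## Validation strategy and problem sizes

The test suite checks each stage against an independent oracle or known
truth: visit construction and site filtering against brute-force
re-implementations; the perfect-detection limit (posterior occupancy must
match the observed occupied proportion when $p = 1$ and sites are visited
repeatedly every year — repeat visits matter, because with a single visit
per closure period occupancy and detection are not separately
identifiable); recovery of a simulated decline (0.6 to 0.3 over 15 years,
10 replicates: sign always right, nominal interval coverage); an
effort-confound scenario (constant occupancy, mean list length doubling
over 20 years: the naive reporting-rate slope is positive while the
model's interval covers zero); PGLS against the explicit matrix formula
and against `nlme::gls` with `ape::corPagel`; $\lambda$ recovery on
Brownian vs independent traits on a 64-tip balanced tree; and recovery of
a planted trait effect through the resampling loop, including the
zero-variance degenerate case where all iterations must coincide exactly.

Simulation sizes in the suite (50–150 sites, 10–20 years, chains of a few
thousand iterations; 10,000 resampling iterations where the loop itself is
under test, 1,000–2,000 where it is incidental) are the package's chosen
compromise between Monte-Carlo resolution and a test suite that runs in
minutes; the full-scale defaults (3 chains × 20,000 iterations, 10,000
burn-in, thinning 5) remain the recommended analysis settings in
`occu_config()`.

With vague year-effect priors, years carrying little information (few
visits, low detection) have posterior annual occupancy pulled toward
diffuse values rather than toward the truth; at small numbers of sites
this can lean the trend slightly. This is a property of the model family
with independent year effects, visible in the confound scenario's
replicate spread, and is the price of not smoothing year effects (a
random-walk prior on $a_t$ is the standard extension when it matters).

## Known limitations

* Single-species models: no shared detection information across species
  beyond the list length.
* Taxonomy is a coarse proxy for phylogeny; with unit branch lengths,
  $\lambda$ absorbs both true signal and tree misspecification.
* The trend is a linear summary; strongly non-monotonic occupancy series
  are poorly described by a single slope.
* Pseudo-posterior inputs to the comparative stage (normal draws around a
  mean) are an approximation supported for convenience; use the MCMC
  draws when available.
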