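---
title: "Adaptive introgression with deleterious load: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive introgression with deleterious load: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introsweep)
```

## The question

A single hybridization event places one haploid individual carrying a
beneficial allele into a resident population of `N` wildtype individuals.
The hybrid haplotype also carries `I` deleterious alleles linked to the left
of the beneficial locus, `J` to the right, and `F` unlinked ones. Two
questions drive everything in this package:

1. **Introgression**: with what probability does the beneficial allele
   escape stochastic loss and establish, given the deleterious load it must
   first shed by recombination?
2. **Hitchhiking**: conditioned on establishment, which linked deleterious
   alleles are dragged along to fixation?

## The model

The population follows a Moran model with recombination. At rate `N`, two
uniformly chosen parents produce one offspring; a single crossover falls in
at most one interval of the linked block (per-interval probabilities are
the model's recombination parameters); each unlinked allele is transmitted
with probability 1/2; the offspring replaces a victim chosen with
probability proportional to `1 - sigma`, where `sigma` is the Malthusian
fitness of a class relative to wildtype (`sigma = 0`). All fitness effects
are independent of the genetic background, so a carrier class is fully
described by `(i, j; f)`: the counts of left-linked, right-linked and
unlinked deleterious alleles accompanying the beneficial allele. Only
single crossover is modelled; this restricts the scope to tight linkage,
where double crossovers (probability of order `r^2`) are negligible, and it
means a class can only lose a contiguous outer run of alleles on one side
per birth.

### Early phase: a reducible multitype branching process

While carriers are rare they interact only with wildtype, so recombination
can only *remove* alleles and carrier lineages are independent: a reducible
multitype branching process. Its extinction probabilities satisfy, class by
class, a quadratic equation whose other unknowns belong to classes with
strictly fewer alleles. `extinction_table()` therefore solves scalar
quadratics in order of increasing `i + j`, then increasing `f`, always
taking the smaller root (the minimal fixed point of the offspring
generating system). The introgression probability is `1 - Q` at the founder
class.

Numerics: the smaller root is computed with the cancellation-free quadratic
formula, because under tight linkage the discriminant can be several orders
of magnitude below `b^2` and the naive formula loses most significant
digits. Solved roots are checked against their residual (default
`1e-12`, configurable) and must lie in `[0, 1]` up to a bracket slack of
`1e-9`. A class with `sigma` exactly 0 is valid: its own-type survival is
zero but it can still pass the beneficial allele onward via recombinants,
and the quadratic needs no special casing.

### Stochastic phase: which haplotype rescues the process

`rescue_distribution()` computes which class founds the permanent lineage,
conditioned on survival. A supercritical class (`sigma - r > 0`) can
establish an own-type lineage; the probability that a *subcritical* founder
is rescued through a given recombination pathway is proportional to the
pathway's rate times the survival probability of its target, which turns
into a recursion over classes in increasing `(i + j, f)` order. The
approximation behind this (exactly one rescue lineage; supercritical
classes establish themselves rather than recombining onward first) is
accurate for tight linkage and classes not too close to criticality; the
Moran simulator is the check on both counts.

Two deliberate choices:

* **Critical classes** (`sigma - r = 0` exactly) are treated as
  subcritical — they cannot found an infinite own-type lineage.
* **The founder refinement.** For a supercritical founder the crude
  approximation is a point mass on the founder class itself. The refined
  treatment (default) assigns the founder's own type the probability
  `((sigma - r)/(1 - r)) / (1 - Q)` and routes the complementary mass
  through the recombination pathways. Both agree as `r -> 0`; the refined
  split is what the concatenated single-hitchhiker probability is built
  from, and it matters whenever `r` is comparable to
  `sigma_(0,1)^2 / sigma_(0,0)` — exactly the regime of the `N = 500`
  worked example below. `refine_founder = FALSE` restores the crude form.
  The refinement is implemented for founders without unlinked load; with
  `F > 0` the crude form is used for a supercritical founder (unlinked
  alleles are shed quickly relative to establishment, so the error is of
  the same order as the approximation itself).

Unlinked alleles never establish: rescue types are reported with `f = 0`,
and the recursion accounts for unlinked load through the binomial
transmission weights and the births that shed unlinked alleles only.

### Deterministic phase: surviving the sweep

Once a class establishes it sweeps logistically. Conditioned on
establishment it grows faster than the deterministic path early on, which
is absorbed by starting the path at the *effective initial size*
`nu_bar = 1/p_est` individuals (the mean of the exponential effective-size
law; `det_phase_monte_carlo(sample_nu = TRUE)` samples it instead, off by
default because the mean is the leading-order treatment everything else
uses). During the sweep, recombination with the remaining wildtype keeps
generating fitter escape classes; each escape born at time `T` establishes
with the probability of a time-inhomogeneous birth-death process whose
death rate tracks the sweeping class's frequency. With a single escape
target the expected number of successful escapes integrates in closed form
over the frequency window `[nu_bar/N, 1 - nu_bar/N]`, giving the retention
probability of `retention_probability_single()`. The window matters: the
logistic path is only trusted away from its ends, and at `N = 500` the
difference between the `nu_bar`-corrected form (~0.80) and its
`nu_bar/N -> 0` limit (~0.52) is the package's standing example that the
conditioned early growth cannot be ignored in small populations. For
several linked hitchhikers the retention probability multiplies over the
one-step escape targets (`retention_probability_full()`); the product form
is stated in its `nu_bar/N -> 0` limit, which is the default, with the
corrected variant exposed as an option.

### The Monte-Carlo deterministic phase

Configurations with several *competing* escape types (for example an
established double-hitchhiker whose sweep can be overtaken by either a
single-hitchhiker or the clean haplotype, which may itself later be
overtaken) have no closed form here. `det_phase_monte_carlo()` generalizes
the semi-deterministic construction:

* between establishment events, established classes follow multi-type
  replicator dynamics with constant Malthusian fitnesses, which has the
  closed form `x_k(t) ∝ x_k(0) exp(sigma_k t)` — no ODE solver is needed;
* candidate escapes fitter than every currently established class arrive
  as an inhomogeneous Poisson stream with intensity
  `N * r * x_source * (1 - x_total) * p_est(t)`;
* the time-dependent establishment probability `p_est(t)` solves a scalar
  Riccati equation backwards along the deterministic path. In `u = 1/p`
  the equation is linear and is integrated on a time grid (default 400
  points per segment; trapezoidal, with exact exponential weighting of the
  terminal value). The death rate of a candidate uses the *mean population
  fitness*, the natural multi-type generalization of the single-sweeper
  construction — a modelling extrapolation, stated as such;
* an accepted candidate joins the deterministic system at its own
  effective initial size `1/p_est(T)` and the process repeats; each
  segment ends when the leading class reaches `1 - nu_bar_lead/N`, the
  same frequency window the closed form integrates over. Candidates not
  fitter than the current leader are ignored: they would be displaced by
  the ongoing sweep.

With a single escape target this machinery reproduces the closed form to
Monte-Carlo accuracy, which is one of the standing tests. Replicates that
exceed the event cap (default 12 establishment events) are reported as
non-converged, never silently truncated.

### Concatenation

`fixation_distribution()` multiplies the rescue distribution with the
per-established-class deterministic-phase rows:
`P(type (i,j) fixes) = sum_kl P_rescue(k,l) * P_det((k,l) -> (i,j))`. Rows
are computed in closed form when the established class has at most one
fitter escape target and that target is terminal; otherwise by Monte
Carlo (`verify_mc = TRUE` forces Monte Carlo everywhere, as a check).
Closed-form single-target rows use the `nu_bar`-corrected retention
whenever `nu_bar < N/2`.

## The simulator as ground truth

`moran_estimate()` runs the full model exactly — no branching or
deterministic approximation — and is the oracle for every analytic module.
Implementation choices that matter for fidelity:

* all three individuals of an event are drawn with replacement, so a parent
  (even the reproducing individual itself) can be the victim; the offspring
  enters only after the victim is removed, keeping `N` constant;
* deleterious-only haplotypes (beneficial allele lost by crossover) remain
  in the population as real individuals; they matter once hybrids are
  common, which is precisely what the branching process ignores;
* unlinked loci are independent presence bits per individual —
  exchangeability is an assumption of the analytics, not of the simulator;
* fixation (for hitchhiking estimands) means monomorphism at the beneficial
  and linked loci; unlinked loci are ignored for absorption;
* genotypes outside the contiguous class system can arise from
  hybrid-by-hybrid recombination. Under an additive fitness builder their
  fitness follows from the allele identities; under an explicit fitness
  table it is looked up by per-side allele counts (and non-carriers use the
  class value minus the beneficial effect). These genotypes are rare at the
  parameter scales of interest;
* the event loop skips no-ops: an event whose two parents and victim all
  belong to the current majority class cannot change the state, and the
  conditional distribution of the remaining event types is sampled
  directly. This makes a failed introgression attempt cost proportional to
  the hybrid lineage's size rather than to `N`, and a sweep cost
  proportional to the minority side of the population. It is an exact
  reformulation, not an approximation.

For establishment probabilities, `establishment_threshold` stops a
replicate once the beneficial count reaches a fraction of `N` (default off;
tests use 5%, i.e. 500 copies at `N = 10^4`, where the residual loss
probability `Q^500` is negligible for the effect sizes studied).
Reproducibility: one R RNG stream is seeded per `moran_estimate()` call
(the implementation is single-threaded), and the seed is recorded in the
result.

## Parameters that matter

| Parameter | Meaning | Typical values here |
|---|---|---|
| `sigma_ben` | Malthusian advantage of the beneficial allele | 0.012–0.08 |
| per-allele costs | fitness costs of linked/unlinked deleterious alleles | 0.002–0.1 |
| `r` (per interval) | per-birth crossover probability between adjacent loci | 1e-5–1e-2 |
| `N` | population size | 500–10^4 |

The scales that organize the results: a linked deleterious allele depresses
*introgression* over distances `r ~ s_del`; the *stochastic* phase of
hitchhiking changes over `r ~ sigma_(0,1)^2 / sigma_(0,0)`; the
*deterministic* phase over `r ~ 1/N` (times a ratio of selection
coefficients). With `N * s_del >> 1` the deterministic phase dominates
hitchhiking; at `N * s_del ~ 1` both phases matter.

## Worked example

```{r worked}
w <- scenario_fixture("worked_example_10_2")   # N = 500, 0.012 / 0.01, r = 0.003
introgression_probability(w)
conditional_establishment_supercritical(w)
retention_probability_single(sweep_model(500, 0.01, 0.012, 0.003))
hitchhiking_probability(w, c(0, 1))
```

## What the fixtures emulate — and what they do not

The built-in fixtures (`scenario_fixtures()`) are parameter sets for the
standard study configurations: unlinked load only, a single linked
hitchhiker at large and small `N`, a second linked allele on the same or
the opposite flank, and many-allele architectures. They are *conditions*,
not data: all probabilities in this package are exact functionals of the
scenario, and the simulator generates its own realizations at run time.
Passing tests therefore demonstrate internal consistency of the analytic
machinery with the exact model — they do not validate the biological
assumptions themselves (haploidy or co-dominant diploidy, background-
independent selection, panmixia, a single hybridization event, single
crossover). Small populations are a known limit: branching-process
establishment probabilities ignore drift fixation of deleterious
haplotypes, and the analytic machinery underestimates introgression when
`N * sigma` is not large.

## Problem sizes used by the test suite

Analytic quantities are exact and instant; Monte-Carlo checks are sized to
make 3-standard-error comparisons meaningful while keeping the default
suite at desk scale: simulator-versus-theory establishment checks use
`10^5` attempts at `N = 10^4` (with the 5% establishment threshold);
conditioned fixation-distribution checks use 200–2000 successful sweeps
(at `N = 2000` for the routine unit tests, `N = 10^4` for the oracle
agreement check); deterministic-phase Monte-Carlo rows use `3*10^3`–`10^4`
replicates. The many-allele recursion is evaluated on the full 11x11
class grid.

## Known limitations

* Only equal unlinked effects are supported; per-allele unlinked effects
  are rejected with a clear error rather than silently averaged.
* The rescue recursion assumes a single rescue lineage; for loose linkage
  or nearly critical haplotypes the simulator shows the expected small
  deviations, and the deterministic-phase engine caps at a finite number
  of establishment events per replicate.
* The closed-form deterministic phase requires every escape target to be
  fitter than the established class; mixed cases fall back to Monte Carlo.
* Source-class-dependent recombination matrices (possible in the `matrix`
  config mode) have no single-crossover physical realization and are
  rejected by the simulator, though the analytic recursions accept them.
* Diploid dominance, spatial structure, gene conversion and multiple
  crossover are out of scope.
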