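---
title: "Estimating first coalescent times from maximum shared haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating first coalescent times from maximum shared haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mshtc)
```

## The quantity being estimated

Pick one chromosome from a phased population sample and one base on it (for
a variant, the carrying chromosome and the variant's position). At that base
the chromosome is the tip of a pendant branch of the local gene tree. The
**first coalescent time** `t_c` is the number of generations back to the
point where that branch joins the rest of the tree — for a variant copy,
where its lineage first meets a lineage *not* carrying the variant. A
derived allele observed on the branch must have arisen on it, so `t_c`
upper-bounds the allele's age; a neutral singleton arises uniformly along
the branch and has expected age `t_c / 2`. Unlike frequency-based
reasoning, `t_c` is defined per *copy*, exists for singletons, and is not a
function of allele frequency — which is what lets it reveal, for example,
that functional singletons are systematically younger than neutral ones at
the same frequency.

## From shared haplotypes to a likelihood

The observable is the **maximum shared haplotype (msh)**: looking 5' and 3'
from the focal base, the longest run of sequence identity between the focal
chromosome and any other chromosome in the panel (each direction maximized
independently; for a k-copy variant, against non-carriers only). Mutation
and recombination each occur per base per generation, so along the branch
pair separating the focal chromosome from its closest relative — the focal
branch of length `t_c` plus the sister branch of length `phi <= t_c` — the
distance to the first tract-ending event is approximately exponential with
per-base rate `(mu + rho)(t_c + phi)`.

With an arbitrary recombination map the two directions combine into the
composite event statistic

```
chi  = mu * (msh5 + msh3) + c5 + c3        (c = tract length in Morgans)
beta = (mu + rho5) * (mu + rho3)           (rates at the tract terminators)
```

and the likelihood of a two-sided observation is

```
p(chi | t_c) = Int_0^tc p(phi) beta (t_c + phi)^2 exp(-chi (t_c + phi)) dphi
             + p(phi = t_c) beta (2 t_c)^2 exp(-2 chi t_c).
```

A tract that runs into the end of the assayed region without meeting a
mismatch contributes a censored, single-event kernel (`(t_c + phi)^1`, with
`beta = mu + rho` at the complete side's terminator); if both sides are
censored the observation is a pure no-event term (`(t_c+phi)^0`), retained
but flagged low-information. For a singleton the probability
`1 - exp(-mu t_c)` that its branch actually carries a mutation multiplies
the likelihood. The k copies of an allele contribute a composite
(product) likelihood maximized over a single `t_c`.

The sister-branch length `phi` is integrated out against a coalescent
prior. For a constant diploid size `N` the prior is uniform,
`n / (4N + n t_c)` on `[0, t_c)`, with a point mass
`4N / (4N + n t_c)` at `phi = t_c` (exactly one sister). For an arbitrary
`N(t)` the package builds the prior from the hazard
`lambda(phi) = n(t) / (4 N(t))` with `n(t) = n / (1 + (n/2) tau(t))`
ancestral branches and `tau` the coalescent intensity; the cumulative
hazard has the closed form
`log[(1 + (n/2) tau(t_c)) / (1 + (n/2) tau(t_c - phi))]`, so no quadrature
is nested inside the likelihood.

### Numerical form of the integrated likelihood

Substituting the constant-N prior and integrating gives closed forms, which
we evaluate in the stable reparameterization `a = chi * t_c`,
`u = t_c (1 + v)`:

```
p(chi | t_c) = n/(4N + n t_c) * beta * t_c^(m+1) * exp(-a) * J_m(a)
             + 4N/(4N + n t_c) * beta * (2 t_c)^m * exp(-2a)
```

with kernel power `m` in {2, 1, 0} and
`J_m(a) = Int_0^1 (1+v)^m exp(-a v) dv`. The textbook antiderivative of
`J_m` cancels catastrophically for `a << 1`, so the building blocks
`Int_0^1 v^j e^(-a v) dv` switch to power series below `a = 0.01`
(`expm1` below `1e-12`); everything is assembled in log space. The closed
form is validated against adaptive quadrature of the integral form to
`1e-6` relative error over `t_c` in `10..1e5` and `chi` spanning six
decades — the quadrature path also remains available
(`method = "quadrature"`) and is the production path for non-constant
demographies.

Maximization is bounded scalar optimization over `log10(t_c)` in `[0, 7]`
(1 to 10 million generations, absolute tolerance `1e-4`), after a 61-point
grid pass that brackets the optimum and flags boundary solutions. The
batch path (`estimate_tc_batch()`) runs the same bracketing followed by
vectorized golden-section refinement across thousands of alleles at once;
a test pins it to the scalar optimizer.

The prior is the only place the demography enters, and its effect is
deliberately weak: estimates computed with `N = 1e4` versus `N = 1e5`
correlate above 0.99 on the log scale (asserted in the test suite), which
is what makes cross-population comparisons with unknown histories
defensible.

## Tract extraction

`msh` values come from the positional Burrows–Wheeler transform (prefix
arrays `a` and divergence arrays `d`, built in C++ in a single streaming
pass per direction; the reverse pass supplies the 3' tracts). The focal
column itself is ignored during comparison — the variant being dated
mismatches every non-carrier by construction and is not a terminator.
Conventions that required a decision:

* **Tract length** is the distance from the focal base to the first
  *mismatching* site (the mutation that reveals the tract end), matching
  the model's "distance to the first non-identical base". Measuring to the
  last matching site instead shortens typical common-allele tracts to zero
  sites and was measurably worse in calibration runs.
* **Ties** among equally long matches report the lowest chromosome row, so
  outputs are deterministic.
* **Censoring**: when no contig length is declared, the assayed region is
  the span from the first to the last variant, and tracts reaching those
  bounds are censored there.
* A zero-margin tract (immediately adjacent mismatch) is a legitimate
  realization and keeps its direction's contribution to `chi`.

Every extraction path is checked for exact equality against an independent
brute-force scan over hundreds of random panels.

## Singleton phasing

A heterozygous singleton in a diploid individual belongs to one of two
chromosomes. Masking all singleton columns, the package measures both
chromosomes' tracts at the focal position, dates each, and assigns the
variant to the chromosome with the larger `t_c` — the longer branch is
proportionally more likely to carry the mutation, so the assignment is
correct with probability `t_c / (t_c + t_c*)`. Decisions are made
independently against the masked alignment and committed together, so the
result is order-invariant; ties within `1e-3` on the log10 scale go to the
individual's first chromosome and are flagged (for those, the estimate is
nearly the same under either assignment, so the mis-assignment is
harmless for dating). Re-extraction of tracts after committing assignments
is possible simply by running the estimator on the returned matrix; it is
not done implicitly.

## CpG masking and site filters

Transitions in CpG context (C>T with 3' G, G>A with 5' C) mutate at
elevated, variable rates and would violate the constant-`mu` model, so
they are masked when reference context is supplied. The default removes
masked columns entirely — they neither receive estimates nor terminate
tracts, consistent with pretending the hypermutable positions were never
assayed; `action = "flag"` keeps them as terminators only, for users who
prefer to treat their mutations as real mismatches. Missing genotypes are
a hard error by default; the alternative drops the individual's both
chromosomes for the whole chromosome, because per-site dropping would
fabricate artificially long tracts.

## The simulation harness

`simulate_sample()` generates study conditions with the standard coalescent
simulator (msprime, driven through a bundled Python helper) and reads
per-copy truth directly off the recorded tree sequence: `t_c` is the time
of the first node on the copy's root path whose subtree contains a
non-carrier, `phi` the sister branch length there, and, for singletons
simulated without recombination, `x_A`/`x_AS` the distances to the nearest
retained mutation on the focal (and sister) branches. Three demographies
are built in: constant `N = 1e4`; exponential growth from `1e4` to `5e5`
over the 200 generations before sampling; and a three-population
out-of-Africa history with bottleneck, migration and recent growth
(sampled from the European deme). An independent R-side tree reader
(`true_tc_phi()`, over `ape` trees) cross-checks the helper's traversal on
exported marginal trees.

Simulated data differ from real cohort data in ways that bound what
passing tests show: phase is perfect unless deliberately scrambled, there
are no genotyping errors or coverage-dependent drop-outs (which lengthen
tracts by deleting terminating singletons), mutation rate is uniform with
no CpG hypermutability, and the recombination map is flat. Performance on
real data inherits all of those additional error sources.

### Scoring

Accuracy is summarized as RMSE, mean signed error (bias) and Pearson
correlation of log10-transformed times, overall and within frequency
strata (<=10%, <=1%, singletons). The scoring unit is the **variant**: the
estimator reports one composite estimate per allele, and at the focal
position the carriers form a clade of the marginal tree, so all k copies
share a single true `t_c`. (Per-copy scoring is available and simply
reweights variants by k; it overweights common alleles, whose tracts are
inflated by maximizing over many equally related non-carriers — the main
approximation error of the method, and the source of its typically
negative bias.) The idealized frequency-based comparator `tau_k` — the
class mean of true log10 times, the least-squares value any
frequency-only estimator could reach — is computed alongside: within a
frequency class it explains nothing, which is the contrast the tract-based
estimator wins for rare alleles.

### Problem sizes

The shipped validation runs use 2 Mb windows with n = 100 chromosomes
(three seeds) for recovery and bias, n = 1000 with `rho = mu/10` for the
favorable-regime correlation, and n = 100 over 1 Mb with scrambled
singletons for phasing. These sizes give a few thousand variants per
replicate, enough that the summary statistics are stable to within a few
hundredths while a full validation cycle completes on a laptop in minutes;
larger windows change the numbers only through sampling noise, since
per-variant difficulty is set by rates and sample size, not window length.

## Known limitations

* The exponential tract model treats a recombination event as an
  immediate tract end; in truth the recombined-in lineage may match for a
  short further stretch, so observed tracts run slightly long and
  estimates slightly young (negative bias, typically about −0.2 on the
  log10 scale).
* For alleles at high frequency, maximizing over many equally related
  non-carriers inflates tracts beyond the single-comparison model;
  estimates of old, common alleles are noisier and more biased than rare
  ones.
* When recombination outpaces mutation (`rho >> mu`), typical tracts fall
  below the inter-SNP spacing and the discrete-site measurement degrades —
  bias turns positive and error grows.
* Composite likelihoods across copies assume independence; copies share
  genealogy, so pooled uncertainties are understated (point estimates are
  unaffected in the unimodal regime).
* `x_AS` upper-bounds the tract only with high probability: a mutation on
  the sister branch stops comparisons with the sisters but not with more
  distant relatives. The strict bound, asserted in tests, is the distance
  to the nearest focal-branch mutation.
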