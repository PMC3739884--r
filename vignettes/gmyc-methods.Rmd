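---
title: "The generalized mixed Yule-coalescent model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The generalized mixed Yule-coalescent model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmyc)
```

## The problem

Single-locus surveys — DNA barcoding projects, environmental 16S samples —
deliver an ultrametric gene tree over many individuals spanning many putative
species, and no independent information about species limits. If the sampled
clade has diversified into independently evolving species, gene copies
coalesce quickly *within* species and much more anciently *between* them, so
the tree shows tight clusters separated by long internal branches. The GMYC
(generalized mixed Yule coalescent) model turns that qualitative signature
into a likelihood-based delimitation: it asks where on the tree the branching
process switches from between-species diversification to within-species
coalescence, and whether that switch is supported at all against the null
hypothesis that the whole sample is one population.

## The model

The data reduce to the waiting times $x_i$ between successive branching
events anywhere on the tree (all node ages, sorted). A *delimitation* is a
set of MRCA nodes plus singleton tips that partitions the tips into
monophyletic species. Given a delimitation, every branch is either a
within-species **coalescent** branch (tipward of a cluster's MRCA) or a
**diversification** branch (cluster stems, singleton terminal branches, and
everything deeper).

During interval $i$ the diversification process runs on $n_{\mathrm{spec},i}$
lineages and each species $j$ contributes $n_{ij}$ coalescing lineages. Both
processes are generalized constant-rate branching processes with a
rate-scaling exponent $p$:

* diversification rate $\lambda_{\mathrm{spec}}\, n_{\mathrm{spec},i}^{\,p_{\mathrm{spec}}}$,
* coalescent rate $\lambda\, \big(n_{ij}(n_{ij}-1)\big)^{p}$ within species $j$
  (one shared $\lambda, p$ across species — the *minimum* parameterization).

$p = 1$ is the constant-rate case; $p < 1$ an apparent slowdown toward the
present (niche filling, incomplete sampling for the diversification part;
population growth or a sweep for the coalescent part); $p > 1$ an apparent
acceleration (background extinction; population decline or subdivision). The
superposition of independent branching processes is itself a branching
process whose rate is the sum of the component rates, so interval $i$
contributes

$$\log b_i - b_i x_i, \qquad
b_i = \lambda_{\mathrm{spec}}\, n_{\mathrm{spec},i}^{\,p_{\mathrm{spec}}}
    + \lambda \sum_j \big(n_{ij}(n_{ij}-1)\big)^{p_{\mathrm{coal}}} .$$

The null model treats the whole tree as one population: a single process
with rate $\lambda\,(n_i(n_i-1))^p$ and two free parameters. The
diversification part is handled in reverse time (from the stems toward the
root) so the mixed model has the same number of events ($M-1$ for $M$ tips)
as the null and the two are directly comparable. Stem branches are
approximated as diversification branches throughout.

## Fitting: Moran plug-in rates, Nelder-Mead exponents

For fixed exponents the rates are set by the *modified Moran estimators*:
the number of events of a class divided by the exponent-scaled,
lineage-weighted branch time of that class, e.g.
$\hat\lambda_{\mathrm{spec}} = E_{\mathrm{spec}} / \sum_i
n_{\mathrm{spec},i}^{\,p_{\mathrm{spec}}} x_i$. Only the two exponents are
then optimized, by Nelder-Mead on the log scale (start $(1,1)$, one restart
from $(0.5, 2)$ on non-convergence, relative tolerance $10^{-8}$ on the
log-likelihood, box $(0, p_{\max}]$).

Two deliberate choices deserve emphasis, because both are part of the
method's operating characteristics rather than numerical conveniences:

* **The Moran plug-in is not the exact two-class rate MLE.** With a single
  branching class (the null model, or a delimitation with an empty class) it
  *is* exact. With both classes present the exact profile MLE — available as
  `profile_lambdas()`, computed by damped Newton on the concave rate
  likelihood and verified against numeric optimization in the test suite —
  extracts slightly more likelihood from every mixed model while leaving the
  null untouched. Fitting with the exact profiler therefore makes the
  likelihood-ratio test anti-conservative (measured rejection ~0.17 at
  nominal 0.05 on null simulations) where the plug-in keeps it near or below
  nominal. The fits use the plug-in; the exact profiler is exported for
  estimator diagnostics.
* **The exponent box default is $p_{\max} = 2$.** The exponent's job is to
  bend branching rates smoothly; left unbounded it lets degenerate
  near-all-singleton delimitations impersonate the null coalescent
  ($n^{3.4} \approx (n(n-1))^{1.7}$), which inflates false positives
  severalfold. The box is configurable through the internal fitting
  controls, and every fitted exponent reported in the evaluation scenarios
  sits comfortably inside it.

Waiting intervals of zero length (tied node ages, impossible under the
continuous-time simulator but possible in rate-smoothed empirical trees)
contribute nothing to the likelihood and are excluded from both the event
counts and the branch-time sums, so the plug-in estimators remain the
truncated likelihood's own estimators.

## Single threshold, multiple thresholds

The *single-threshold* model constrains all diversification nodes to be
older than a threshold age $T$ and all coalescent nodes younger. $T$ is a
constraint on the search space, not a parameter: the mixed model has exactly
two more free parameters than the null, the scan evaluates every distinct
node age as a candidate $T$ (duplicate delimitations from tied ages are
removed), and the maximum-likelihood threshold is kept. The likelihood-ratio
statistic $D = 2(\ln L_{\mathrm{best}} - \ln L_0)$, clipped at zero, is
referred to $\chi^2_2$; the legacy 3-df p-value (from the formulation that
counted the threshold as a parameter) is reported alongside, never used for
decisions — at the revised 5% critical value it equals 0.112. For an exact
test, `simulate_null_pvalue()` re-simulates single-population coalescent
trees and ranks the observed statistic.

The *multiple-threshold* search relaxes the single-cut assumption by greedy
hill-climbing over delimitations: SPLIT replaces a cluster MRCA by its two
children, FUSE replaces a sister pair of delimited units by their parent.
Each round fits every neighbor of the incumbent and accepts the best if it
improves the log-likelihood by more than $10^{-9}$; the search stops when a
round finds no improvement. It is seeded from the single-threshold optimum —
the seeding the evaluation found far more reliable than arbitrary multi-starts,
which are attracted to local optima. The move set is deliberately minimal and
reversible, and fuses are restricted to sister units so every candidate stays
monophyletic by construction.

## Uncertainty

Candidate models are compared by Akaike weights
$w_i = e^{-\Delta_i/2} / \sum_r e^{-\Delta_r/2}$. The 95% confidence set is
the smallest AIC-ascending prefix with cumulative weight at least 0.95; the
*GMYC support* of a node is the summed weight of candidate models in which
it appears as a species-defining MRCA; model-averaged parameters use
$\bar\theta = \sum w_i \theta_i$ with unconditional standard errors
$\sum_i w_i \sqrt{\widehat{\mathrm{var}}(\theta_i) + (\theta_i - \bar\theta)^2}$
(per-model variances from the observed information; models with negligible
weight contribute their point estimate). Identical delimitations reached by
different routes are deduplicated before weighting, otherwise pooled sets
would double-count.

For the multiple-threshold method the confidence set pools the
single-threshold candidates with the models the heuristic *found* — its
accepted trajectory. Pooling every evaluated neighbor (hundreds of rejected
trial models per search) dilutes the weights and misstates the evidence
against the null: on null simulations it pushed the false-positive rate from
0.04 to above 0.2. `heuristic_search()` still returns all visited models for
diagnostic use.

Degenerate candidates keep `n_params = 4` with the absent class's rate fixed
at 0 and exponent at 1, so AIC is comparable across every candidate; the
single-cluster delimitation (MRCA = root) is likelihood-equivalent to the
null and the null fit represents that corner of the space in every
comparison.

## The simulation suite

The evaluation scenarios are generated by a multispecies coalescent built
into the package:

* **Species trees** are constant-rate pure-birth (or birth-death,
  conditioned on the number of surviving species via `ape::rphylo`) trees
  rescaled to a root age of $10^7$ generations — with 30 species this
  implies a net speciation rate of $(\log 30 - \log 2)/10^7$ per lineage per
  generation, typical of recent radiations. Because every gene tree is
  rescaled to root age 1 before analysis, only relative rates matter, so any
  exact conditioning scheme is acceptable. Incomplete sampling (scenario C1)
  prunes 30 of 50 species *without* rescaling, preserving the recent deficit
  of speciation events it is meant to create.
* **Population sizes** are constant and equal (B), log-normally distributed
  across species with natural-scale mean equal to the nominal $N_e$ (E, F2;
  log-scale $\sigma = 1$ by default — the spread is a free choice, stated
  here once, as only the mean is pinned by the study design), inherited by
  ancestral branches from the lowest-indexed descendant species.
* **Demography** (D1/D2): an instantaneous bottleneck (growth) $T_b$
  generations ago — half the age of the second most recent speciation node;
  the reading of "penultimate" is configurable — followed by exponential
  10-fold growth (decline) to the present, with the severity chosen so the
  harmonic mean size over the changing phase equals $N_e$ exactly
  ($N_0 = 9N_e/\ln 10$ for growth). The constraint is verified by numeric
  quadrature in the tests.
* **Gene trees**: within each species-tree branch, lineages coalesce
  pairwise at rate $1/(2N(t))$ per generation (diploid convention, so a
  pair's expected coalescence time is $2N_e$ and
  $E[T_{\mathrm{MRCA}}] = 4N_e(1-1/n)$); time-varying rates are handled by
  inverting the accumulated coalescent intensity piecewise. Survivors pass
  to the parent branch; above the root the ancestral population is constant.
  All times are continuous, so tied node ages never arise.
* **Sampling**: five copies per species (B-E), or 150 copies in total
  assigned uniformly (F1) or proportionally to population size (F2) —
  under uniform sampling about 3.2% of species are represented by a single
  copy, which the delimiter must classify as singleton species.

What the simulator does *not* emulate: geographic structure within species,
migration, recombination, selection, sequence evolution and tree
re-estimation. Passing the evaluation therefore demonstrates correctness of
the method under its own assumptions plus the listed violations
(non-constant diversification, varying sizes, demography, random sampling) —
not robustness to reconstruction error or gene flow.

## Study conditions and problem sizes

The replication harness (`run_study()`, and the acceptance script in
`scripts/`) uses: 100 replicates for the null false-positive rates and 500
species trees for the shape summaries; the scenario grids
($N_e \in \{10^4, 10^5, 5\times10^5, 10^6\}$) run at 30 replicates per cell
in the packaged checks, with the full 100 available through `--reps`. At 30
replicates the per-cell Monte-Carlo standard error of an accuracy mean is
about 0.02-0.04, which is the tolerance the directional checks are read
against.

Reference values these conditions reproduce (single threshold unless noted):
false-positive rate 0.02 (multiple threshold 0.07); mean exact-match
accuracy above 90% at $N_e = 10^4$ falling below 20% at $10^6$; mean GMYC
support 0.96 at $N_e = 10^4$; scaling-exponent medians 0.77 (C1), 1.12 (C2),
0.53 (D1), 1.16 (D2) at $N_e = 10^4$; mean Colless imbalance 71 and mean
$\gamma \approx 0$ for the 30-species pure-birth trees.

## Numerical notes and limitations

* Ultrametricity is enforced at a relative tolerance of $10^{-6}$ of the
  root age (configurable); failing trees are rejected, never silently
  corrected, because corrections would perturb the waiting intervals that
  carry all the information. Terminal branches of exactly zero length
  (identical haplotypes) are rejected with advice to prune duplicates — they
  make the coalescent rate estimator infinite.
* Node enumeration is deterministic (age-sorted, ties by node id), so scans
  and searches are bit-reproducible under a fixed seed.
* The delimitation-model count uses exact big-integer arithmetic (the space
  grows doubly exponentially: a balanced 128-tip tree admits
  $4.4128\times10^{22}$ models), which is why exhaustive search is limited
  to oracle checks on small trees.
* The method assumes species are monophyletic on the gene tree and shares
  one $(\lambda, p)$ across species; per-species parameterizations and
  Bayesian searches are out of scope. When $N_e$ is large relative to
  divergence times, species are not reciprocally monophyletic and no
  single-locus method of this family can recover them — the confidence set
  and support values are designed to flag exactly that regime.
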