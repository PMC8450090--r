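---
title: "The deconvolution model behind methdecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The deconvolution model behind methdecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdecon)
```

`methdecon` infers, per user-defined genomic region, the number of major
allelic subpopulations present in a bulk bisulfite-sequencing sample, each
subpopulation's binary methylation profile, their prevalences, and the
intervals where the profiles differ (i-DMRs). This vignette is the
package's own account of the model, its assumptions, the parameters that
matter, and its limits.

## Why binary profiles and per-region smoothing

Per-allele methylation at a CpG is binary; fractional values in bulk data
arise from mixing alleles, from binomial sampling at finite coverage, and
from measurement noise. Observed methylation distributions in sorted cell
populations are not clean point masses at 0, 50 and 100 %: they carry
shoulders near the edges and a small mode near 50 % from imprinting and
allele-specific methylation. Two modelling commitments follow:

* solved profiles are **binary per subpopulation** — the deconvolution
  smooths over single-CpG fluctuations rather than enumerating every read
  pattern, because a read-pattern-level enumeration explodes with coverage
  and is dominated by noise;
* observed methylated read counts are modelled with **beta-binomial
  mixtures**, not a plain binomial, so the extra dispersion seen in real
  data does not get misread as additional subpopulations.

## The hidden Markov model

For a region with $g$ CpGs and a candidate number of subpopulations $d$
with prevalences $p_1 \ge \dots \ge p_d$, $\sum_k p_k = 1$:

**States.** A state at CpG $t$ is $x^{(t)} \in \{0,1\}^d$, the binary
methylation of each subpopulation. The chain has $2^d$ states; the default
cap $d \le 3$ reflects that promoter-scale windows essentially never
support four or more mutually distinct methylation patterns, and keeps the
state space at 8.

**Transitions** factorize over subpopulations: each subpopulation evolves
by the same distance-dependent 2×2 matrix, with no cell-type-specific
transition model. Matrices are trained by binarizing a (homogeneous)
training dataset at 0.5 and counting adjacent-CpG transitions into
distance bins; bins are $(0,50], (50,100], (100,200], (200,500],
(500,1000]$ and $(1000,\infty)$ bp. Only the $>1$ kb grouping is
substantive — beyond that distance methylation correlation has largely
decayed — and the sub-kilobase edges were chosen once to track the decay
with a handful of matrices; they are configurable in
`train_transitions()`. A pseudocount of 1 per cell keeps every transition
strictly positive: Viterbi runs in log space and cannot tolerate $-\infty$
transitions. A bin with no observed transitions falls back to the uniform
matrix with a warning.

**Initial distribution.** The training procedure pins down transitions but
not the state distribution at the first CpG. We use the product over
subpopulations of the stationary distribution of the open-ended ($>1$ kb)
matrix: it is the marginal methylation frequency implied by the trained
long-range matrix, i.e. what one expects for a CpG with no usable left
neighbour.

**Emissions.** At a CpG with coverage $n$ and methylated count $b$, let
$p = \sum_{k: x_k = 1} p_k$. Reads draw their subpopulation of origin
i.i.d. with the prevalence weights, so the methylated-origin count $i$ is
$\mathrm{Bin}(n, p)$. Measurement error is described by two mixtures of
beta-binomials with positive integer shapes: $m(i, j)$, the probability
that $j$ of $i$ methylated-origin reads are measured methylated, and
$u(n-i, b-j)$, the probability that $b-j$ of the $n-i$
unmethylated-origin reads are measured methylated. The emission is the
mixture of convolutions

$$P(b, n) = \sum_{i=0}^{n} \binom{n}{i} p^i (1-p)^{n-i}
  \sum_{j} m(i, j)\, u(n-i, b-j),$$

which sums to exactly 1 over $b$. The package also implements a variant
(`form = "printed"` in `emission_table()`) that inserts the apportionment
factor $\binom{i}{j}\binom{n-i}{b-j} / \binom{n}{b}$ into the inner sum.
Because $m$ is already the complete measurement probability for the
methylated-origin reads, that factor double-counts the apportionment: the
variant loses probability mass over $b$ (it is renormalized when the
deviation exceeds $10^{-6}$) and, at realistic coverage, its renormalized
shape is driven by the combinatorial factor rather than by $p$ — at
$n = 55$, $p = 0.25$ it peaks at $b = 1$ instead of near $np$. Both forms
are verified against an exact-rational direct summation in the test suite;
the solver uses the convolution form. At $p \in \{0, 1\}$ both forms
reduce to a single mixture beta-binomial (the pure-state shortcut, which
also covers degenerate prevalences).

**Decoding and termination.** Each region is decoded by the standard
max-product Viterbi recursion over the $2^d$ states. Regions are solved
for $d = 1, 2, \dots$: candidate $d+1$ is accepted only if its Viterbi log
probability strictly exceeds that of $d$; the first non-improvement (or
the cap `d_max`) stops the search, and the comparison is made directly on
the conditional sequence probabilities, which corresponds to a uniform
prior over candidate $d$. Equal log probabilities terminate. The scheme
always halts: duplicating an existing profile leaves every emission
unchanged while multiplying in additional transition factors, so the
score cannot improve indefinitely.

## Prevalence estimation

A mixture of $d$ binary states can only produce $2^d$ expected fractional
levels — the subset sums of the prevalence vector (`expected_levels()`;
prevalences $(0.3, 0.7)$ give $\{0, 0.3, 0.7, 1\}$). `estimate_prevalence()`
searches all descending prevalence vectors on a grid and minimises the
mean absolute distance of each observed methylation value to its nearest
expected level. This nearest-atom form of the L1 objective is bin-free,
deterministic, and exactly zero whenever the mixture explains every
observed level. Ties are broken toward the smallest minor component, so a
tie never invents a large spurious subpopulation. Grid resolution defaults
to 0.01 for $d \le 2$ and 0.02 for $d = 3$ (the $d = 3$ search space grows
quickly); the minimum component is one grid step.

Design choices made here, where the procedure was genuinely open:

* prevalence is estimated **once per candidate $d$** over the pooled CpGs
  of the sample (optionally restricted to a user-supplied signature region
  list), then held fixed during region solving — regions share the
  sample's composition, while re-estimating per region would let binomial
  jitter in a single region masquerade as composition;
* CpGs are **weighted uniformly**, not by coverage: coverage already
  enters the emission model, and double-weighting deep CpGs would bias the
  estimate toward high-coverage segments of the genome;
* on data whose levels sit only at 0 and 1, every grid vector attains
  objective zero and the tie rule returns the most skewed vector — a
  deliberate statement that such data carry no evidence about composition.

A caution that the package's tests make explicit: in a region whose CpGs
all sit near one intermediate level (e.g. a 50:50 mixture, everything near
0.5), the nearest-atom objective prefers to straddle the noise cloud with
two atoms (e.g. 0.55/0.45 rather than 0.50/0.50). Prevalence should
therefore be estimated from many regions, or from a signature list with
diverse levels, not from a single balanced region.

## i-DMR calling and ranking

With $d \ge 2$ solved, a CpG is *differential* when any two profiles
disagree. Seeds of consecutive differential CpGs are merged greedily left
to right, absorbing interior non-differential CpGs while the differential
fraction of the merged interval stays at or above `min_frac`; intervals
then must span at least `min_len` bp (first CpG start to last CpG end,
half-open) and contain at least `min_cpgs` CpGs. Defaults (50 bp, 3 CpGs,
90 %) follow common DMR-caller practice. The greedy run-merging
construction is the package's own; only the three filters are fixed by the
method. Intervals always start and end at differential CpGs, surviving
intervals are disjoint, and calls are invariant under profile relabelling.
i-DMRs are never merged across user-region boundaries — regions are solved
independently, and a CpG lying in two overlapping regions is simply used
in both.

Ranking uses the parent region's improvement
$\log P(x_2 \mid 2) - \log P(x_1 \mid 1)$: regions whose data genuinely
need a second profile rank above regions with marginal evidence, which
gives downstream enrichment analyses a usable ordering.

## The synthetic-data generators

The package is fully testable offline; its generators emulate the
statistical structure of the data the method targets.

* `synthetic_cpg_positions()` draws CpG spacings from a two-component
  mixture (short island-like gaps of tens of bp; exponential open-sea gaps
  of hundreds of bp), so transition bins up and below 1 kb all get
  exercised.
* `simulate_reference_profiles()` draws binary profiles with
  distance-dependent persistence (copy the previous state with probability
  $e^{-\mathrm{dist}/500\,\mathrm{bp}}$, else redraw), mimicking the
  decay of methylation correlation with distance.
* `simulate_methylation_mixture()` is the idealized mixture: expected
  level = prevalence · states, observed count binomial at fixed coverage.
* `simulate_read_mixture()` emulates read subsampling: the total read
  count is `round(coverage × region size / read length)` (read length
  100 bp by default), read starts are uniform, each read's source
  subpopulation is drawn independently with prevalence probabilities (so
  realized per-region proportions fluctuate, as in resampled sequencing
  data), and per-CpG calls flip with probability `meas_error`
  (default 0.01) to emulate the intermediate-methylation shoulders of real
  data. Reads are single-end.
* `simulate_training_corpus()` produces the genome-scale homogeneous
  corpus (50 000 CpGs by default, two synthetic chromosomes, Poisson
  coverage around 30 floored at 4) from which the shipped defaults were
  built: per-CpG read-level methylation probabilities are drawn from a
  mixture of betas around the underlying state — a sharp edge component,
  a broader shoulder and a small mid component standing in for imprinted
  and allele-specifically methylated CpGs.

What the generators do **not** emulate: bisulfite-conversion chemistry,
paired-end reads, mapping artefacts, copy-number variation, strand
asymmetry, and the long-range coverage waves of real libraries. Passing
tests on this synthetic data therefore demonstrate the correctness of the
algorithms and their behaviour under the modelled noise, not performance
on any particular real dataset.

The shipped defaults in `inst/extdata/` are a transition model trained on
a 200 000-CpG corpus draw and a measurement prior fitted to the same
corpus (`fit_beta_prior()` recovers edge-concentrated mixtures for both
states). Users with real data should retrain both.

## Measurement-model fitting

`fit_beta_prior()` follows a deliberately discrete procedure: methylation
values are rounded to the nearest 0.5 %, CpGs at 0–40 % feed the
unmethylated model and 60–100 % the methylated model, candidate beta
densities with integer shapes in 1..100 are evaluated on the same grid and
renormalized, and the L1 distance to the empirical distribution is
minimised. The first component is found exhaustively; up to two further
components are added by greedy forward selection over a 0.05 weight grid,
each kept only on a ≥ 1 % relative L1 improvement, which stops the mixture
from chasing sampling noise. Integer shapes and grid weights keep the
search exhaustive and reproducible. Fitting refuses to run on fewer than
10 000 training CpGs and points at the shipped default instead.

## Numerical choices

* All probabilities are natural logs; accumulations use log-sum-exp, and
  the per-$i$ convolutions are computed with per-term scaling so nothing
  underflows for coverage up to 1000 (the read-time coverage ceiling).
* The methylated read count is recovered from a fractional level as
  $\lfloor \mathrm{level} \times \mathrm{coverage} + 0.5 \rfloor$ —
  deterministic half-up rounding, unlike `round()`'s half-to-even. (An
  exact complement $b \to n-b$ therefore only commutes with rounding when
  counts are integral; the symmetry tests construct them so.)
* Binarization ties at 0.5 round up to methylated, everywhere.
* Viterbi ties break toward the lexicographically smallest state vector;
  profile rows are ordered by descending prevalence, lexicographically
  within equal prevalence, which resolves label switching
  deterministically.
* Emission tables are memoized per (coverage, $p$) pair within a fit —
  $p$ takes at most $2^d$ values per candidate, so a region batch reuses
  a small set of tables.
* Distance bins are half-open $(\mathrm{lo}, \mathrm{hi}]$: a distance
  exactly at an edge belongs to the lower bin.
* Degenerate inputs: an empty region yields a null solution with a
  warning rather than an error; coverage-0 CpGs contribute no emission;
  duplicate CpG positions within a region are an error, surfacing
  upstream strand-collapsing ambiguity rather than silently merging.

## Identifiability at balanced mixtures

At exactly 50:50, the states $(1,0)$ and $(0,1)$ have identical emissions,
and because all subpopulations share one transition matrix, a state
sequence's transition score depends only on its own change count. A
non-constant pair of complementary profiles is then *not identifiable*:
the constant complementary pair scores at least as well on the same data.
The package's exact-recovery tests for balanced mixtures therefore use
constant complementary profiles (the imprinted-locus analog: one allele
fully methylated, one fully unmethylated), which is precisely the
configuration where a balanced two-population call is scientifically
meaningful. Away from 50:50 the emission asymmetry breaks the degeneracy
and block profiles are recoverable.

## Problem sizes used by the checks

The test suite exercises the solver at the scale the method targets while
staying quick to run: decoder-versus-enumeration equivalence on 500 random
instances with $g \le 5$, $d \le 2$; emission agreement with an
exact-rational oracle for all $n \le 6$, $b \le n$ on a prevalence grid;
recovery on 200 read-level two-population regions ($g = 20$, coverage 55,
minor prevalence 0.20–0.45, flip 0.01); termination behaviour on 200
pure and 200 balanced complementary regions at coverage 60; and
measurement-model recovery from 150 000 discretized Beta(2, 10) draws per
state. These sizes are the package's choice of a thorough-but-fast
default; all generators scale up by argument.

## Known limitations

* Prevalences are shared across regions; focal events (e.g. copy-number
  change under a subclonal profile) violate this and are not modelled.
* Subpopulations beyond `d_max = 3` are not searched by default; raising
  the cap grows the state space as $2^d$.
* Minor subpopulations are limited by reads: at coverage $n$ a prevalence
  $q$ contributes about $nq$ reads per CpG, and below roughly $q = 0.15$
  at mid coverage the evidence for a second profile fades.
* The termination rule is greedy in $d$; a non-improving $d+1$ stops the
  search even if some $d+2$ would improve (not observed in practice, but
  not excluded by construction).
* 5-hydroxymethylation, bisulfite-conversion failure and mapping bias are
  outside the measurement model except insofar as the fitted beta
  mixtures absorb them.
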