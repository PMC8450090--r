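# methdecon

Reference-free deconvolution of subpopulation methylation profiles from
bisulfite sequencing data of heterogeneous samples.

## The problem

Bulk bisulfite sequencing of a heterogeneous sample — a tumor biopsy, a
mixed cell population, or any tissue with allele-specific methylation —
reports one fractional methylation value per CpG that averages over the
alleles present. Yet each individual allele is essentially binary at a CpG:
methylated or not. `methdecon` takes the per-CpG table of fractional
methylation and coverage and, for each user-defined region (promoter
window, CpG island, enhancer, imprinted locus), infers

* how many major **allelic subpopulations** the region supports,
* each subpopulation's **binary methylation profile** across the region's
  CpGs,
* the subpopulations' **prevalences** in the sample, and
* **intrasample differentially methylated regions (i-DMRs)** — intervals
  where the inferred profiles disagree.

No reference methylomes are required. The intended users are genomics
researchers analysing WGBS / RRBS / capture bisulfite data from samples
that cannot be sorted to purity.

## The model

Let a region have *g* CpGs and suppose *d* subpopulations with prevalences
*p₁ ≥ … ≥ p_d* (∑ p_k = 1). The method is a modified hidden Markov model
decoded by the Viterbi algorithm:

* **States.** A hidden state at a CpG is the length-*d* binary vector
  *x = (x₁, …, x_d)* of the subpopulations' methylation values, so there
  are 2^*d* states per CpG.
* **Transitions.** Methylation is locally correlated along the genome, and
  the correlation decays with distance. A single set of distance-binned
  2×2 row-stochastic matrices (bins up to 50 / 100 / 200 / 500 / 1000 bp
  and one open-ended bin beyond 1 kb) is trained by binarizing a
  methylation dataset (≥ 0.5 → methylated) and counting transitions
  between adjacent CpGs. Subpopulations transition independently and
  identically, so the joint transition probability is a product of *d*
  entries of the matrix selected by the CpG spacing.
* **Emissions.** At a CpG with coverage *n* and *b* methylated reads, let
  *p* = ∑ {p_k : x_k = 1} be the prevalence of the methylated underlying
  state. Each read draws its subpopulation of origin independently, so the
  count *i* of methylated-origin reads is Binomial(*n*, *p*); measurement
  noise around the pure states is captured by two mixtures of
  beta-binomials with integer shape parameters, *m* for methylated and *u*
  for unmethylated origin, fitted to training data on a 0.5 % methylation
  grid by L1 minimization. The emission probability is

  P(b, n) = Σᵢ C(n, i) pⁱ (1 − p)ⁿ⁻ⁱ Σⱼ m(i, j) · u(n − i, b − j),

  the convolution of the two measurement models mixed over read origin.
* **Number of subpopulations.** Regions are solved iteratively with d = 1,
  2, …: candidate d + 1 is kept only when its Viterbi log probability
  strictly exceeds that of d (an Occam's-razor rule; with a uniform prior
  on d this is the posterior comparison). The default cap is d ≤ 3.
* **Prevalence.** Before region solving, prevalences are estimated once
  per candidate d from the sample-wide distribution of fractional
  methylation values: a grid search minimises the mean absolute distance
  of each observed level to the nearest *expected mixture level* (the
  subset sums of the prevalence vector — e.g. prevalences (0.3, 0.7) give
  levels {0, 0.3, 0.7, 1}).
* **i-DMRs.** With d ≥ 2, CpGs where any two profiles disagree are
  differential; maximal intervals with ≥ 50 bp span, ≥ 3 CpGs and ≥ 90 %
  differential CpGs are reported and ranked by the region's
  two-versus-one log-probability improvement.

See `vignettes/deconvolution-model.Rmd` for the full account including
numerical choices and limitations.

## Worked example

Simulate a 70:30 mixture of two allelic profiles over 20 CpGs at 60×
coverage, then deconvolve it:

```r
library(methdecon)
pos <- synthetic_cpg_positions(20, seed = 7)
profiles <- rbind(c(rep(1, 12), rep(0, 8)),   # subpopulation A
                  rep(0, 20))                 # subpopulation B
tab <- simulate_methylation_mixture(profiles, pos, prevalence = c(0.7, 0.3),
                                    coverage = 60, seed = 8,
                                    region_id = "promoterX")
fit <- methdecon(tab, d_max = 2)
summary(fit)
```

```
Regions: 1 (20 CpGs)
Subpopulation counts:

0 1 2
0 0 1

Estimated prevalences by candidate d:
  d = 1: 1.00
  d = 2: 0.70, 0.30

i-DMRs called: 1
Top ranked:
  chrom start  end region_id rank_score n_cpgs fraction_differential
1  chrS  1000 3406 promoterX   35.51372     12                     1
```

The fit recovers the planted structure: the region needs two
subpopulations, their prevalences are estimated as 0.70 / 0.30 (the truth),
and the 12 CpGs where the profiles disagree form one i-DMR whose rank score
(35.5) is the gain in Viterbi log probability from modelling the region
with two subpopulations instead of one. `coef(fit, d = 2)` returns the
prevalence vector; `fit$solutions[[1]]$profiles` holds the two binary
profiles; `plot(fit)` draws the observed levels with the fitted mixture and
profile tracks; `fitted()`, `residuals()` and `simulate()` behave as for
other R model objects.

A command-line interface with subcommands (`simulate`,
`train-transitions`, `fit-prior`, `estimate-prevalence`, `deconvolve`,
`call-idmrs`, `evaluate`) is shipped at `inst/cli/methdecon`.

## Input format

A 6-column tab-separated table, one row per CpG: chromosome, start
(0-based), end (exclusive), fractional methylation (mCG/CG), coverage,
region id. Records with coverage outside [4, 1000] are dropped at read
time (configurable). Output files are BED-like TSVs: a profile file
(chrom, start, end, state, subpopulation, prevalence, region id), a
per-region summary (region id, number of subpopulations, log probabilities
per candidate) and the ranked i-DMR BED (chrom, start, end, region id,
rank score, CpG count, differential fraction).
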