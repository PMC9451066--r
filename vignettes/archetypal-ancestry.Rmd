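---
title: "Archetypal analysis of genotype data: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Archetypal analysis of genotype data: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aamix)
```

## The model

`aamix` treats unsupervised ancestry estimation as a constrained matrix
factorization. Genotypes enter as average alternate-allele dosages
(0, ½, 1 for a diploid), giving an N × M matrix with samples in rows.
Archetypal Analysis seeks K archetypes `Z` and fractions `alpha` such that

```
X ≈ alpha %*% Z,        alpha[i, ] in the K-simplex,
Z  = t(X) %*% beta (transposed),  beta[, k] in the N-simplex,
```

minimizing the residual sum of squares `||X - alpha %*% Z||_F^2`. Both
factors being simplex-constrained is the defining feature: every
individual is a mixture of archetypes, and every archetype is a mixture of
observed individuals, so cluster centroids stay inside the convex hull of
the data and can be read as attainable populations. The free-parameter
count is `2NK - N - K` — independent of the number of SNPs — split as
`N(K-1)` for the fractions and `K(N-1)` for the archetype weights; the fit
object carries these in `fit$df`.

Dropping the convexity constraint on the archetypes while restricting each
`alpha` row to one-hot yields Lloyd K-means; restricting both factors to
one-hot yields K-medoids. Both reductions ship as
`kmeans_binary_alpha()` and `kmedoids_binary()` and are tested against an
independent Lloyd implementation and brute-force medoid search. For the
K-medoids descent we chose the alternating assignment/medoid-update scheme
(rather than PAM swaps) because it mirrors the structure of the archetypal
solver it specializes; it is a local method, so tests compare its
best-of-seeds cost with the exhaustive optimum on small instances.

## Why fit on SVD scores

Centered genotype vectors of N samples span at most N − 1 dimensions.
`fit_projection()` centers each variant column and computes the thin SVD
`Xc = U S t(V)`; the scores `X' = U S` are an orthonormal rotation of the
data onto that span. Distances — and hence the AA objective — are
preserved, so fitting on the N × (N − 1) score matrix gives the same RSS
as fitting on the N × M centered dosages while the per-iteration cost
drops from O(M) to O(N) per inner product. The equivalence is asserted to
relative 1e-6 in the tests. The default pipeline retains all non-null
components; `truncate_projection()` supports deliberate dimension
reduction, at the cost of the invariance.

Numerical choices in the projection:

- Components with singular value ≤ 1e-12 × the largest are treated as
  numerically null and dropped, so the invariance checks are not polluted
  by noise dimensions.
- Singular-vector signs are fixed (largest-magnitude element of each right
  singular vector non-negative) so identical inputs give bit-identical
  models across platforms.
- Back-projection of fit-space points re-adds the column means,
  `z %*% t(V) + mu`, so SNP-space archetypes are dosage-like vectors
  comparable with the input encoding. Re-adding the mean is our
  interpretation; the alternative (centered archetypes) differs only by a
  constant shift.

## The alternating solver

Each `alpha` row and each `beta` column is an exact simplex-constrained
least-squares subproblem. We solve them by non-negative least squares on
an augmented system: the design is stacked on a row of ones carrying
weight `1/C`, the target on the value `1/C`, so the sum-to-one constraint
is enforced softly with strength increasing as C decreases. The default
`C = 0.001` makes the constraint row dominate (relative squared weight
about 1e6), after which an exact renormalization projects the weights onto
the simplex. The augmentation could also be read with the *data* divided
by C; that reading would weaken the constraint as C shrinks, contradicting
the intended behavior of C, so we implement the constraint-row weighting.

The NNLS engine is an in-package Lawson–Hanson active-set solver
(`nnls_fit()`). We wrote it rather than wrapping an existing one because
the degenerate systems this package routinely produces — exact-fit
instances where the target lies in the span of few columns, with the huge
constraint row attached — can cycle in off-the-shelf active-set codes that
abort with an error in that situation. `nnls_fit()` detects the
zero-progress step, caps inner iterations, and returns the best feasible
iterate; it is unit-tested against an independent active-set
implementation on random well-posed systems.

One sweep updates all N `alpha` rows against the current archetypes, then
each `beta` column in turn by exact coordinate descent (for fixed `alpha`
and the other columns, the column objective reduces to a least-squares
problem in `t(X) %*% beta_k`). Two safeguards keep the RSS trace exactly
non-increasing, which the tests assert across random configurations:

- every subproblem update is accepted only if it does not increase its own
  residual (the soft constraint plus renormalization can otherwise cause
  sub-1e-6 upticks near convergence);
- an archetype whose `alpha` column loses all mass is re-seeded to the
  sample with the largest current reconstruction residual.

Iteration stops when the relative RSS change `|RSS_c - RSS_p| / RSS_p`
falls to the tolerance `T` (default 0.001), or after `max_iter = 50`
sweeps. We read the stopping rule as a relative first-power change: a
squared scalar difference would make the tolerance scale-dependent and
meaningless across datasets.

### Initialization

Three strategies, all seeded:

- `furthest_sum` (default): first sample uniform at random, each
  subsequent pick maximizing the summed Euclidean distance to all previous
  picks, ties to the lowest index. A `reselect_first` flag additionally
  discards and greedily re-selects the random first pick — a refinement of
  the original scheme that is off by default to keep the default behavior
  the plain greedy rule.
- `random_sample`: K distinct data rows.
- `random_uniform`: coordinates uniform within the per-dimension data
  range.

A `restarts` parameter refits from shifted seeds and returns the best-RSS
fit; explained-variance curves over K are computed with `restarts = 3` in
our tests to smooth out local optima. All randomness flows from the single
integer seed; identical seed and input give identical fits.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | — | number of archetypes; treated as an input, no model selection |
| `C` | 0.001 | sum-to-one constraint weight (dimensionless); smaller = harder constraint |
| `tol` | 0.001 | relative RSS change at which alternation stops |
| `max_iter` | 50 | sweep cap; fits on realistic panels converge in < 10 |
| `init` | furthest_sum | see above |
| `maf_threshold` | 0.1 | variants with minor-allele frequency strictly below are removed |

The MAF filter is strict (`< threshold` removed, `= threshold` kept),
matching the convention of removing "rare variants with MAF < 0.1";
`compute_maf()` treats the dosage column mean as the alternate-allele
frequency, which is exact for the 0/½/1 encoding, and folds at 0.5.
Missing genotypes are mean-imputed per variant before centering — this
keeps the centered column means at zero, the least-structured choice —
with the pre-imputation mask kept for provenance.

## What the simulator does and does not emulate

`simulate_panel()` draws K × M population allele frequencies independently
per SNP, uniform in 0.5 ± `freq_spread` (default 0.4); ancestry rows from
a symmetric Dirichlet (default concentration 0.3, giving realistic skewed
mixtures with some near-pure individuals); and allele counts
`Binomial(2, p_ij)` with `p_ij = sum_k q_ik f_kj`. That is exactly the
generative admixture model underlying likelihood-based ancestry methods,
so parameter-recovery tests measure the right target.

It deliberately omits: linkage disequilibrium (sites independent), shared
ancestral frequencies and drift between populations (each population's
frequencies are independent), mutation/genotyping error, and relatedness.
Passing recovery tests on these panels therefore shows the solver inverts
the admixture model it assumes; it does not show robustness to LD pruning
choices, cohort imbalance, or model misspecification in real data.
`add_vertex_individuals()` appends pure-ancestry individuals, giving the
archetypes attainable extremes — without any near-pure individuals the
archetype of a cluster is pulled inside the point cloud and fractions are
compressed, a known property of convex-hull methods rather than a defect.

## Problem sizes and test design

Test and acceptance runs use simulated panels of roughly N = 20–306
samples and M = 30–500 SNPs — large enough that binomial noise and
Dirichlet skew resemble small real panels, small enough that the entire
suite completes in well under a minute. Recovery is measured after optimal
column matching (`match_columns()`, exhaustive over K! permutations for
K ≤ 8) as the mean absolute difference between fitted and true fractions;
the headline check asks for matched MAE < 0.1 on vertex-enriched panels of
306 samples in at least 4 of 5 seeds, and typical values are ≈ 0.04.

## Known limitations

- K is an input; the package offers no cross-validation or model
  selection over K (the explained-variance curve is the intended aid).
- The solver finds local optima; `restarts` mitigates but does not
  guarantee the global minimum.
- Diploid biallelic SNPs only; haploid or mixed-ploidy GT fields are
  rejected rather than coerced.
- Exhaustive column matching stops at K = 8.
- `read_vcf()` loads the full genotype matrix into memory; the intended
  regime is cohort-scale N with pre-filtered M, not whole-genome site
  counts.
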