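---
title: "Monte Carlo approximation of SNP-BLUP reliabilities"
author: "mcsnpblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo approximation of SNP-BLUP reliabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcsnpblup)
```

## The problem

Routine genomic evaluations in livestock report, next to each estimated
breeding value (EBV), its *reliability* $r^2$ — the squared accuracy of the
prediction. Reliabilities require diagonal (or quadratic-form) elements of
the inverse of the mixed model equations (MME). For the genomic BLUP
(GBLUP) model the MME involve the inverse of a dense genomic relationship
matrix of order $n$, the number of genotyped animals, so the cost grows as
$O(n^3)$ and becomes untenable for modern populations with hundreds of
thousands of genotyped animals. The equivalent SNP-BLUP formulation bounds
the system by the marker count $m$, but once a residual polygenic (RPG)
effect is added — the pedigree-based component capturing genetic variance
the markers miss — the system grows to order $m + n$ again.

This package implements a fully Monte Carlo sampled SNP-BLUP in which *all*
genetic effects are represented by $n_{MC}$ simulated regression columns,
so the MME order is $1 + n_{MC}$ regardless of $m$ and $n$, together with
the exact models needed to measure the quality of the approximation.

## Models

**Exact SNP-BLUP with an RPG effect.** With one record per genotyped
animal,
$$ \mathbf{y} = \mathbf{1}_n \mu + \mathbf{Z}\mathbf{g}_R + \mathbf{e},
\qquad
\mathbf{Z} = \big[\sqrt{1-w}\,\mathbf{Z}_c \;\; \sqrt{w}\,\mathbf{L}\big],
$$
where $\mathbf{Z}_c$ is the centered and scaled marker matrix,
$\mathbf{L}$ the lower Cholesky factor of the pedigree relationship matrix
of the genotyped animals ($\mathbf{A}_{22} = \mathbf{L}\mathbf{L}'$), $w$
the RPG proportion, $\mathbf{g}_R \sim N(0, \mathbf{I}\sigma_u^2)$ and
$\mathbf{e} \sim N(0, \mathbf{R}\sigma_e^2)$ with
$\mathbf{R} = \mathrm{diag}(1/w_i)$ for record weights $w_i$. The
square-root blend coefficients are forced by the variance identity
$\mathrm{Var}(\mathbf{Z}\mathbf{g}_R) = \mathbf{G}_w \sigma_u^2$ with
$$ \mathbf{G}_w = (1-w)\,\mathbf{Z}_c\mathbf{Z}_c' + w\,\mathbf{A}_{22}; $$
linear blend coefficients would instead give
$(1-w)^2 \mathbf{Z}_c\mathbf{Z}_c' + w^2\mathbf{A}_{22}$, which is not a
variance partition. `snpblup_exact_reliability()` implements this model;
`gblup_reliability()` implements the equivalent animal-level model with
covariance $\mathbf{G}_w\sigma_u^2$ directly. The two yield identical
prediction error variances (PEV), which the test suite asserts to
$10^{-8}$, and both serve as exactness oracles for the approximation.

**Marker scalings.** `center_scale()` supports the two standard VanRaden
scalings: a single global scale $S = \sum_l 2p_l(1-p_l)$ (method 1) or the
per-marker scale $S_k = m\,2p_k(1-p_k)$ (method 2). Observed allele
frequencies are the default; base-population frequencies can be supplied
when known. Monomorphic markers center to zero and are retained under
method 1 but must be dropped (with a warning) under method 2, where their
scale would be zero.

**Full Monte Carlo SNP-BLUP.** The approximation replaces all genetic
effects with $n_{MC}$ pseudo-effects:
$\mathbf{y} = \mathbf{1}_n\mu + \mathbf{U}\mathbf{s} + \mathbf{e}$,
$\mathbf{s} \sim N(0, \mathbf{I}\sigma_u^2)$, where column $i$ of
$\mathbf{U}$ is
$$ \mathbf{u}_i = \big(\mathbf{Z}_c\,\mathbf{g}_i + \sqrt{w}\,\mathbf{L}
\mathbf{z}_i\big) / \sqrt{n_{MC}}, \qquad
\mathbf{g}_i \sim N(0, (1-w)\mathbf{I}_m),\;
\mathbf{z}_i \sim N(0, \mathbf{I}_n), $$
so each unscaled column is a draw from $N(0, \mathbf{G}_w)$ and
$E[\mathbf{U}\mathbf{U}'] = \mathbf{G}_w$. The $1/\sqrt{n_{MC}}$ column
scaling is essential: without it $\mathbf{U}\mathbf{U}'$ grows linearly in
$n_{MC}$ and neither the PEV nor the variance formulas below are
consistent. The MME are
$$ \begin{bmatrix}
\mathbf{1}'\mathbf{R}^{-1}\mathbf{1} & \mathbf{1}'\mathbf{R}^{-1}\mathbf{U}\\
\mathbf{U}'\mathbf{R}^{-1}\mathbf{1} &
\mathbf{U}'\mathbf{R}^{-1}\mathbf{U} + \mathbf{I}\lambda
\end{bmatrix}, \qquad \lambda = \sigma_e^2/\sigma_u^2, $$
of order $1 + n_{MC}$. With $\mathbf{C}^{uss}$ the genetic block of the MME
inverse and $\mathbf{t}_j$ row $j$ of $\mathbf{U}$,
$$ \mathrm{PEV}_j = \mathbf{t}_j \mathbf{C}^{uss} \mathbf{t}_j', \qquad
r_j^2 = 1 - \lambda\,\mathrm{PEV}_j / \sigma_j^2 . $$

**The reliability denominator $\sigma_j^2$.** Two modes are provided.
`"mc"` (default) uses the Monte Carlo diagonal
$(\mathbf{U}\mathbf{U}')_{jj}$, computed as row norms; `"exact"` uses
$(1-w)(\mathbf{Z}_c\mathbf{Z}_c')_{jj} + w(1 + F_j)$ with $F_j$ the
animal's inbreeding coefficient, which equals $(\mathbf{G}_w)_{jj}$
exactly. The mc mode is the default because the Monte Carlo errors of the
PEV quadratic form and of the diagonal partially cancel: for an animal
contributing little information, $\mathbf{C}^{uss} \approx
\mathbf{I}/\lambda$ and the ratio $\lambda\,\mathrm{PEV}_j/\sigma_j^2
\to 1$ regardless of the sampling noise in $\mathbf{t}_j$, pinning $r_j^2$
near its exact value of 0; with the exact denominator that cancellation is
lost and accuracy degrades. An alternative `"one-minus-f"` convention
substituting $1 - F_j$ for the polygenic diagonal is kept behind a flag
for cross-checks against implementations that use that sign, although
$1 + F_j$ is the actual $\mathbf{A}_{22}$ diagonal; the two coincide for
non-inbred animals.

## Numerical design

**Two solution paths.** `full_mc_run(path = "mme")` assembles the literal
$(1+n_{MC})$-order system (`build_full_mc_mme()`), extracts
$\mathbf{C}^{uss}$ by dense symmetric factorization (`solve_pev_block()`),
and evaluates the quadratic forms row by row, left to right, never forming
$\mathbf{U}\mathbf{C}^{uss}\mathbf{U}'$. That is the faithful large-scale
algorithm, and the right choice when $n \gg n_{MC}$. At desk scale the
regime is reversed — tens to hundreds of animals against tens of thousands
of samples — so the default `path = "gram"` uses the standard model
equivalence in the other direction: the pseudo-effect model is an
animal-level model with relationship matrix $\mathbf{U}\mathbf{U}'$, and
its MME of order $1 + n$ give the same PEV exactly whenever
$\mathbf{U}\mathbf{U}'$ is nonsingular (guaranteed in practice for
$n_{MC} \ge n$). The suite asserts the two paths agree to $10^{-8}$, and a
deterministic oracle (`deterministic_U_from_cholesky()`, which sets
$\mathbf{U} = \mathrm{chol}(\mathbf{G}_w)'$ so that
$\mathbf{U}\mathbf{U}' = \mathbf{G}_w$ exactly) checks the entire pipeline
— assembly, block inversion, quadratic form, $r^2$ formula — against exact
GBLUP end to end.

**Factorizations and jitter.** All symmetric systems go through Cholesky
factorization (`chol`/`chol2inv`). Matrices that should be positive
definite but are numerically borderline get a ridge escalating along the
ladder $0, 10^{-10}, 10^{-8}, 10^{-6}$; the jitter used is reported. A
factorization whose squared pivot ratio falls below $10^{-10}$ is treated
as failed so that the ladder escalates rather than returning a poorly
scaled inverse. One genuinely singular case deserves note: with observed
allele frequencies every column of $\mathbf{Z}_c$ sums to zero, so
$\mathbf{Z}_c\mathbf{Z}_c'$ annihilates the ones vector and the $w = 0$
blend is exactly singular. GBLUP at $w = 0$ therefore runs on the jittered
matrix and agrees with the (jitter-free) exact SNP-BLUP only to about the
ridge magnitude; any $w > 0$ blend with a pedigree component is positive
definite.

**Randomness.** Every stochastic routine takes an integer seed. All
Gaussian draws for $\mathbf{U}$ are generated in one fixed column-major
pass (marker effects first, then polygenic effects) of R's default
generator, so a seed fully determines the result; repeated calls are
bitwise identical.

## The synthetic data generator

`simulate_dataset()` produces populations with exactly the structure the
models assume: a random-mating pedigree with discrete generations
(`simulate_pedigree()`), unlinked biallelic markers gene-dropped through it
with founder frequencies uniform on $[\mathrm{maf}_{low},
\mathrm{maf}_{high}]$ (`gene_drop_genotypes()`), and phenotypes
$y = \mu + u + e$ with
$u = \sigma_u(\sqrt{1-w}\,\mathbf{Z}_c\mathbf{g} +
\sqrt{w}\,\mathbf{L}\mathbf{a})$, $\sigma_u^2 = h^2$,
$\sigma_e^2 = 1 - h^2$ — unit phenotypic variance, so
$\lambda = (1-h^2)/h^2$. The genotyped set defaults to the youngest
animals. Gene dropping makes realized identity by descent consistent with
the pedigree relationship matrix, which the suite checks through the
full-sib genotype covariance across many independent families.

Deliberate simplifications: no linkage disequilibrium (nothing in the
method uses linkage), no selection or assortative mating, no overlapping
generations, and one record per animal with user-chosen weights. The last
point matters for interpreting the approximation's bias, below.

**Study problem sizes.** The checked configurations are a 300-animal
pedigree with the youngest 150 genotyped and $m = 400$ markers for the
exact-model equivalence; 100 genotyped animals with $m = 300$, $w = 0.5$,
$h^2 = 0.3$ and $n_{MC} \in \{2000, 8000, 20000\}$ over five seeds for the
convergence study; and 50 animals with $n_{MC} = 10^5$ for the sampling
bound on $\mathbf{U}\mathbf{U}'$. These sizes make every property cheap to
recompute while keeping $n_{MC}/n$ spans on both sides of one.

## What the approximation does, and its bias direction

Across the convergence grid the mean squared error between full-MC and
exact reliabilities falls roughly in proportion to $1/n_{MC}$ and the
correlation rises toward one — at $n_{MC} = 20{,}000$ the correlation
exceeds 0.99 under the study conditions. The regression of exact on
approximate reliability summarizes bias: slope 1 and intercept 0 mean an
unbiased approximation.

A finding worth stating plainly: the *direction* of the slope's deviation
from 1 depends on the information structure of the population. When every
animal carries one equally weighted record — the generator's design — the
Monte Carlo error behaves as noise nearly independent of the exact value,
and the regression slope is attenuated *below* 1 (about 0.83 at
$n_{MC} = 2000$, approaching 1 from below as $n_{MC}$ grows). When the
population mixes weakly and strongly informed animals (e.g. recordless
candidates alongside heavily weighted proven animals, the situation in
operational evaluations), the approximation systematically *overestimates*
the low reliabilities — spurious sampled relationships leak information
toward poorly connected animals — compressing the approximate scale, and
the same regression slope comes out *above* 1, shrinking toward 1 as
$n_{MC}$ grows. Both regimes are reproducible with
`sweep_scenarios()` by changing only the record weights. Passing tests on
the uniform-weight generator therefore validate convergence and the error
magnitude, but the inflation seen in operational data only appears once
heterogeneous information is simulated.

## Tunable parameters

* `w` — RPG proportion in $[0,1]$; 0.2–0.8 covered by the study grids.
* `h2` / (`sigma_u2`, `sigma_e2`) — variance components;
  $\lambda = \sigma_e^2/\sigma_u^2$ drives shrinkage.
* `n_mc` — Monte Carlo samples; accuracy $\propto 1/\sqrt{n_{MC}}$,
  literal MME cost $\propto n_{MC}^3$, gram-path cost linear in $n_{MC}$.
* `sigma_mode` — `"mc"` (default, error-cancelling) or `"exact"`.
* `method` — VanRaden scaling 1 or 2 for $\mathbf{Z}_c$.
* record `weight` — per-record residual precision $w_i$;
  $R_{ii} = 1/w_i$.

## Known limitations

Dense factorizations only: the package targets method validation at desk
scale, not production evaluations (no iterative solvers, no sparse
$\mathbf{A}^{-1}$, no single-step treatment of non-genotyped animals).
One trait, one record per animal, overall mean as the only fixed effect.
The pedigree tabular method builds the full $\mathbf{A}$ before
subsetting, which is quadratic in pedigree size and intended for pedigrees
of at most a few thousand animals.
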