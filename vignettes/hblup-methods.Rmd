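---
title: "Single-step evaluation with tunable relationship matrices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step evaluation with tunable relationship matrices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hblupr)
```

## The problem

In livestock evaluation many phenotyped animals are never genotyped, but
they are connected to genotyped animals through the pedigree. Single-step
evaluation (HBLUP/ssGBLUP) merges the pedigree numerator relationship
matrix $A$ and the genomic relationship matrix $G$ into one matrix $H$ so
that every phenotyped animal — genotyped or not — contributes to the
prediction of genetic values. The catch is that $G$ and $A$ are
expressed on different scales and carry different information, and the
way $G$ is built and reconciled with $A$ is governed by three
hyper-parameters whose values materially change prediction accuracy:

* the **scale factor** $\alpha$, which sets how per-allele effect size is
  assumed to relate to allele frequency;
* the **blending weight** $\theta$, a convex shrink of $G$ toward
  $A_{22}$;
* the **tuning method**, an affine adjustment of $G$ toward the
  base-population scale implied by the pedigree.

This package implements the full stack — simulation, relationship
matrices, REML, prediction, and a cross-validated grid search over
$(\text{tune}, \theta, \alpha)$ — so the hyper-parameters can be
optimized per dataset rather than fixed by convention.

## Relationship matrices

**Pedigree.** $A$ is built by the tabular method in topological order:
$a_{ii} = 1 + \tfrac12 a_{s(i),d(i)}$ and
$a_{ij} = \tfrac12 (a_{j,s(i)} + a_{j,d(i)})$, with unknown parents
contributing zero. Inbreeding is therefore exact. Founders are treated
as unrelated, non-inbred base animals; unknown parents are coded `"0"`
by default and parents referenced but never listed are auto-inserted as
founders, both common conventions in field pedigree files. The $O(n^2)$
dense construction is deliberate: at the population sizes this package
targets (up to roughly $10^5$) memory is the binding constraint long
before time, and the dense matrix is what the downstream algebra needs
anyway. Sparse $A^{-1}$ tricks, unknown-parent groups and metafounders
are out of scope.

**Genomic.** With genotype counts $x_{ik} \in \{0,1,2\}$ and frequencies
$p_k$,
$$G_{ij} = \frac{1}{d} \sum_{k=1}^{L} (x_{ik} - 2p_k)(x_{jk} - 2p_k)\,
  [2p_k(1-p_k)]^{2\alpha},$$
the $\alpha$-family of estimators: $\alpha = -0.5$ standardizes every
SNP to unit variance (the GCTA/PLINK estimator), $\alpha = 0$ weights
SNPs by raw centered cross-products (VanRaden method 1). The exponent
$2\alpha$ on the heterozygosity arises because an effect-size scaling of
$[2p(1-p)]^{\alpha}$ enters the covariance twice.

Two normalizations are offered. The default *empirical* $d$ is the mean
weighted squared centered genotype over the sample, so
$\mathrm{tr}(G)/n = 1$ exactly for every $\alpha$ — convenient because it
puts all points of an $\alpha$ grid on a common variance scale. The
*theoretical* $d = \sum_k [2p_k(1-p_k)]^{1+2\alpha}$ is the
Hardy–Weinberg expectation of the diagonal and reproduces the
PLINK/GCTA convention at $\alpha=-0.5$; it is used in the package's own
oracle tests. Allele frequencies default to in-sample estimates; the
base-population correction is deliberately left to the tuning step
rather than folded into the frequencies. Monomorphic SNPs are dropped
with a message (their weight is undefined for negative $\alpha$), and
missing genotypes are mean-imputed to $2p_k$ before centering.

**Blending and tuning.** The blended matrix is
$\theta G + (1-\theta) A_{22}$, $\theta \in [0,1]$. By Weyl's
inequality its smallest eigenvalue is at least the convex combination of
the two smallest eigenvalues, which is why blending historically served
to repair indefinite $G$; with the direct AI-REML solver below that
repair is optional, so $\theta = 1$ is a legitimate grid point. Tuning
is $\beta G + \omega J$:

* method 1 matches both the overall mean and the diagonal mean of
  $A_{22}$ ($\beta$ from the diagonal/off-diagonal contrast,
  $\omega = \overline{A_{22}} - \beta \bar G$);
* method 2 fixes $\beta = 1$ and matches the overall mean only.

Published formulations of the method-1 estimator differ in typography
(where the $n$ versus $n^2$ divisors fall); this implementation is the
moment-matching form, chosen because it demonstrably satisfies both
moment identities, which the test suite asserts exactly on random
inputs. The default order applies tuning to the blended matrix; the
reverse order is available because the two operations do not commute.
Neither adjustment is applied silently: the defaults are $\theta = 1$,
tune 0, on the view that these are hyper-parameters to be optimized, not
constants.

**Assembly.**
$$H = \begin{pmatrix}
 A_{11} + A_{12}A_{22}^{-1}(G^\ast - A_{22})A_{22}^{-1}A_{21} &
 A_{12}A_{22}^{-1}G^\ast \\
 G^\ast A_{22}^{-1}A_{21} & G^\ast
\end{pmatrix}$$
with $G^\ast$ the adjusted genomic matrix. The genotyped block is
$G^\ast$ exactly (assigned, not recomputed) and $H = A$ identically when
$G^\ast = A_{22}$ — both are exact-identity tests in the suite. $A_{22}$
is factorized by Cholesky; failure is an error because it signals an
invalid pedigree rather than a numerical accident. A warning (optional)
flags $G^\ast$ with eigenvalues below $-10^{-8}$.

## Variance components and prediction

The mixed model is $y = Xb + g + e$ with
$g \sim N(0, K\sigma_g^2)$, $e \sim N(0, I\sigma_e^2)$, $K$ any of
$A$, $G$ or $H$ restricted to the phenotyped individuals. REML runs in
the eigenbasis of $K$: after one symmetric eigendecomposition the
per-iteration cost is $O(n)$, which is what makes a grid search with
hundreds of REML fits feasible. Updates are Average Information
(quasi-Newton) steps on the variance scale with three safeguards:

* a component pinned at the floor ($10^{-8}\,\mathrm{var}(y)$) whose
  score points further down is dropped from the update (active set),
  and the AI step is taken in the free component;
* any step that would make $V = K\sigma_g^2 + I\sigma_e^2$ indefinite
  or decrease the restricted likelihood is halved, falling back to the
  (always-ascending) EM direction if no AI step improves;
* convergence is declared when the log-likelihood changes by less than
  `tol` ($10^{-6}$ by default, `max_iter` 100).

Because only $V$ must be positive definite, $K$ itself may be
indefinite — the "direct" property that lets the grid include
$\theta = 1$ with an unrepaired $G$. Starting values split
$\mathrm{var}(y)$ equally between the components; the fixed part is an
intercept unless covariates are supplied. These numerical choices (start,
tolerance, floor) are not stated by the method's sources; they are the
package's own and are recorded here. AIC is $2P - 2\ln L$ with $P = 2$
variance components; only within-dataset differences ($\Delta$AIC) are
ever interpreted, so the parameter-count convention cancels.

Prediction of unphenotyped individuals uses the kinship form
$\hat g_t = \hat\sigma_g^2 K_{t,o} V^{-1}(y - X\hat b)$, algebraically
identical to Henderson's mixed-model equations (asserted against a
hand-built MME in the tests). Cross-validated accuracy is the Pearson
correlation between observed phenotypes and predicted genetic values of
the masked fold — no rescaling by $h$ — and RMSE is computed on the same
pairs; predictions are genetic values, not re-centered phenotypes, which
matters only for RMSE and only through the (near-zero) phenotype mean of
the simulated traits.

## The simulator

The forward simulator replaces an external package and defines the
conditions under which everything here is validated. A neutral biallelic
genome (default 30 chromosomes × 100 cM × 300 markers, all starting at
frequency 0.5, allele-flip mutation $2.8\times10^{-8}$) is dropped
through:

1. a **historical phase** — 100 generations at effective size
   $N_e$ = 100 (scenarios 1 and 3) or 1,000 (scenario 2), random union
   of gametes with independent random parent draws per offspring, so the
   realized effective size tracks the census size and the neutral decay
   $E[\mathrm{het}_t] = 0.5(1 - \tfrac{1}{2N_e})^t$ holds (a tested
   property). Scenarios 1 and 3 expand linearly to 1,000 over the last
   five historical generations (the growth profile of the expansion is
   not specified by the design this emulates; a linear ramp is the
   simplest monotone choice);
2. a **recent phase** — founders sampled from the final historical
   generation (50 sires + 500 dams in scenario 1), then five
   generations bred under the configured design: half-sib (each sire ×
   10 dams × 2 offspring, scenario 1) or monogamous full-sib pairs
   (scenarios 2–3).

Meiosis is Haldane: per-interval recombination
$r = \tfrac12(1 - e^{-2d})$ with independent assortment across
chromosomes, which at marker resolution is exactly the
Poisson-crossover, no-interference model. Sexes are assigned in exactly
balanced numbers per generation — the expectation of the nominal
Bernoulli(0.5) sex ratio — so that the prescribed founder counts are
always satisfiable; this is the one place the simulator is intentionally
less random than a literal Bernoulli sex draw. Scenario 3 as specified
is over-constrained (550 founders cannot produce 1,000 offspring in
disjoint monogamous pairs); this implementation keeps the founder count
and lets the generation size follow (550 = 275 pairs × 2).

Phenotypes take 1,000 causal loci from the marker panel (kept in the
panel for GRM building, since nothing in the emulated design removes
them), raw effects $u_k \sim N(0,1)$ scaled by
$[2p_k(1-p_k)]^{\alpha_\mathrm{true}}$, aggregate genetic values
standardized to variance $h^2$ and residuals $N(0, 1-h^2)$. The
generative $\alpha_\mathrm{true}$ and the GRM-side $\alpha$ are distinct
quantities on purpose: recovering the former by grid search over the
latter is the package's central experiment.

What the simulator does *not* emulate: selection (random mating and
random selection only), marker ascertainment, genotyping error,
non-additive architecture, and environmental structure. Tests passing
under these conditions show the machinery is correct and that the
hyper-parameters behave as designed in a clean additive world; they do
not show how large the accuracy gains are in any real population.

## Scaled designs

Family structure, not raw size, drives the statistical behaviour of the
designs, so `scenario_config(scale = )` shrinks the number of families
while preserving the half-sib/full-sib structure, the five-generation
layout, the founder-to-expansion ratio, and (scenarios 1 and 3) the
historical $N_e$. One scaling rule matters and is easy to get wrong:
the genome must shrink *with* the population. Prediction accuracy at
fixed heritability is governed by the ratio of discovery size to
effective genome segments (map length × $N_e$); keeping the full
3,000 cM genome under a one-fifth population drops accuracy and
destabilizes hyper-parameter selection, whereas scaling the map length
roughly in proportion (e.g. 1,000 cM for a 0.2–0.3 population scale)
restores the full design's ratio of about 1.5 phenotyped individuals
per cM. The package's own validation experiments use scaled designs
chosen on that principle, sized to keep each suite in minutes:

* exact identities and algebraic oracles: pedigrees of up to ~50
  individuals, 10×50 genotype matrices — these are exact to $10^{-10}$
  regardless of size;
* heritability recovery: 100 replicates (20 populations × 5 phenotype
  draws) of a scale-0.2 scenario 1 (1,000 phenotyped offspring, 1,000
  markers, 111 causal);
* replicate-averaged sensitivity and blending contrasts: scale-0.1
  populations (200 genotyped, 600 markers, 67 causal), 25–100
  replicates;
* single-dataset hyper-parameter recovery (including the acceptance
  script): scale-0.3 populations (1,665 individuals, 600 genotyped,
  folds of 120) with a 10-chromosome × 200-marker genome, 222 causal,
  and the coarse grids tune ∈ {0,1}, θ ∈ {0.5, 0.9, 1.0},
  α ∈ {−1, −0.5, 0, 0.5, 1}.

The causal fraction is kept at the full design's 1,000/9,000. On single
scaled datasets the accuracy differences between neighbouring grid
points are of the same order as 5-fold sampling noise — exactly as in
the full-size single-dataset experiment this mirrors (where the
0.9-versus-1.0 blending contrast is itself only ~0.003) — so selected
hyper-parameters are expected to match the generative values up to that
noise, and replicate-averaged properties (maximization at the true
$\alpha$, degradation away from it) are the sharper statements.

## Degenerate inputs and edge behaviour

* Pedigree cycles and duplicate ids are hard errors naming the
  offenders; self-parenting is rejected.
* All-missing SNPs are errors; monomorphic SNPs are dropped, not
  errored, because simulator output legitimately contains them.
* Tuning method 1 with a degenerate diagonal contrast (e.g. $G = J$)
  errors with advice to use method 2.
* REML non-convergence is a flagged result, not an exception;
  cross-validation drops non-converged folds from configuration means
  and warns.
* Ties in the grid search are broken toward parsimony: smaller
  $|\alpha|$, then larger $\theta$, then smaller tune index.

## Limitations

Single-trait, intercept-plus-covariates models only; no repeated
records, no multi-trait REML, no sparse mixed-model-equation solvers, no
APY-style $H^{-1}$ approximations, and no positive-definite repair
("bending") of $G$ — the solver tolerates indefiniteness instead. The
evolutionary-algorithm alternatives to grid search are out of scope; the
grid is exhaustive and reproducible, which is the point.
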