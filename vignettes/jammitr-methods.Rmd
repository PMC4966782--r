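---
title: "Sparse rank-1 joint analysis of multi-modal data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse rank-1 joint analysis of multi-modal data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jammitr)
```

## The problem

A multi-modal data set (MMDS) is a collection of $K$ data matrices
$D_1, \dots, D_K$, each $p_k \times n$ with variables in rows, measured on
one common, ordered set of $n$ biosamples — for example genome-wide mRNA,
microRNA and DNA methylation on the same tumours, or a whole-genome
expression matrix supervised by a handful of imaging-derived covariate
rows. At least one block is "big" ($p_k \gg n$), and the biological signal
of interest is typically carried by a small fraction of the measured
variables. The goal of the joint analysis is to find, across all data
types at once, the sparse set of rows that best explains a single
per-sample signal shared by the blocks.

## Model

After type-specific preprocessing, the blocks are stacked vertically into
the $p \times n$ super-matrix $D$ ($p = \sum_k p_k$), which is divided by
its Frobenius norm so that blocks with different row counts and dynamic
ranges live on one scale. The model is a penalized rank-1 approximation

$$
\min_{u, v} \; \|D - u v^\top\|_F^2 + \lambda \|u\|_1
\qquad \text{subject to} \qquad v = D^\top u ,
$$

where $u \in \mathbb{R}^p$ is the sparse *eigen-array* of per-variable
loadings, $v \in \mathbb{R}^n$ is the dense *eigen-signal* of per-sample
scores, and $\lambda \ge 0$ penalizes only $u$ (an asymmetric LASSO). The
variables with nonzero loadings form the multi-modal signature; parsing
them by stacking order gives per-type sub-signatures. At $\lambda = 0$
the fit reduces to the best rank-1 SVD approximation; above a data-driven
ceiling $\lambda^{\sup}$ the signature is empty.

### Optimization

`jammit()` alternates two exact updates from the SVD rank-1
initialization:

1. **Eigen-array update.** For fixed $v$ with $\|v\|_2 = 1$, the exact
   minimizer is row-wise soft thresholding:
   $u_i = \mathrm{sign}(z_i)\max(|z_i| - \lambda/2,\, 0)$ with
   $z_i = d_i^\top v$ (available standalone as `sparse_u_update()`, which
   keeps the general $\|v\| \neq 1$ closed form).
2. **Eigen-signal update.** For fixed $u$, the minimizer over the unit
   sphere is $v \propto D^\top u$.

Because each half-step is an exact coordinate minimization of the
penalized objective (with $v$ constrained to the sphere), the objective
recorded after every eigen-array update is non-increasing; the trace is
stored in the fit and asserted in the tests. Convergence is declared when
the relative $\ell_2$ change of both factors falls below `tol`
(default `1e-6`, cap `max_iter = 500`). If $u$ shrinks to all zeros the
fit stops immediately and is returned as empty.

### Exit convention: scale and debiasing

Two presentation choices are applied to the converged pair, both of which
matter in practice:

* **Scale.** The internal iteration keeps $v$ at unit norm for fixed-point
  stability. On exit, $u$ is normalized to unit $\ell_2$ norm (sign-fixed
  so its largest-magnitude entry is positive) and $v = D^\top u$ is
  recomputed, so the returned pair satisfies the constraint exactly and
  $u v^\top = u u^\top D$ is the best rank-1 approximation of $D$ in the
  fitted sparse direction. Without this, the exit product would carry a
  $\sigma^3$ scale instead of $\sigma$, the $\lambda = 0$ fit would not
  match the SVD truncation, and deflation would not remove the fitted
  component.
* **Debiasing.** The $\ell_1$ penalty is used for model selection only:
  the returned loadings on the selected support are the unpenalized
  least-squares weights (relaxed-lasso exit), not the soft-thresholded
  ones. Shrunk weights leave a $\lambda/2$-proportional slice of signal
  in every selected row after deflation; in sequential extraction this
  made the same planted signal re-surface for several extra rounds. With
  debiased loadings the deflated residual of a detected component is
  noise-level.

## Penalty selection by permutation FDR

`lambda_grid()` spans $[0, \lambda^{\sup}]$ with $L$ points (default 50,
linear; geometric option), where
$\lambda^{\sup} = 2\max_i |d_i^\top v_0|$ with $v_0$ the unit leading
right singular vector — the smallest penalty that empties the signature on
the first update.

`estimate_fdr()` compares the observed signature size $s_{\mathrm{obs}}
(\lambda)$ with sizes obtained on null matrices in which every row of the
super-matrix is independently shuffled. This destroys the shared column
signal while preserving each row's marginal distribution; it is the
standard row-wise permutation null. The estimate at each grid point is
the mean over $B$ permutations (default 100; a median option exists) of
$\min(1, s_{\mathrm{null}} / s_{\mathrm{obs}})$, with the convention
$\mathrm{FDR} = 1$ wherever $s_{\mathrm{obs}} = 0$. Per-type profiles are
computed identically from block-restricted counts, so a data type that
does not support the shared signal is visible as a flat per-type profile.

`select_lambda()` returns the smallest grid penalty whose joint FDR is at
or below the threshold (default 0.05) — the first crossing of the
profile's decay. The design here was genuinely open, and two alternatives
were rejected on simulated data:

* *Global FDR minimum.* With a planted signal the profile reaches exactly
  zero only at penalties so large that a handful of rows survive; the
  global minimum therefore systematically selects a near-empty signature
  that misses most of the true support.
* *First local minimum.* Estimated profiles at practical $B$ are noisy;
  the first dip tends to land a grid step or two into the decay and
  misses the weakest supported rows, whose leftovers then re-surface as
  small spurious components in the sequential procedure.

The first crossing keeps the signature as dense as the FDR budget allows:
on planted-signal simulations it captures essentially the whole support
at the nominal FDR, while on pure-noise matrices the profile never
reaches the threshold and no penalty is selected.

## Sequential extraction

`jammit_iterate()` repeats (grid, FDR profile, selection, fit, record,
deflate $D' = D - u v^\top$) on the running residual until no penalty
qualifies, a fit returns empty, or the iteration count reaches
$\min_k \mathrm{rank}(D_k)$. The FDR profile is re-estimated on each
residual with a fresh grid because deflation changes the scale of the
problem. Residual Frobenius norm is recorded per pass and decreases
strictly whenever a nonempty component is deflated.

`jammit_loocv()` assesses signature robustness at a fixed penalty: each
sample is dropped in turn, the reduced blocks are restacked and rescaled,
and the refitted signature is compared with the full-data one (fraction
recapitulated per sample, plus the intersection across all leave-one-out
signatures).

## The simulator

`simulate_mmds()` emulates the benchmark design used throughout the
tests: $K = 2$ blocks on $n = 50$ shared samples, block row counts drawn
from $\{1000, 2000, \dots, 10000\}$, and two planted signals — a step
($+1$ on the first half of samples, $-1$ on the second; a
differential-expression surrogate) and a standardized Gaussian random
signal (an unmeasured sample attribute) — each supported on a disjoint
2 % of rows per block (floor of 20 rows). Supported rows carry the signal
times an amplitude drawn uniformly from $[0.5, 1.5]$ with random sign;
noise is i.i.d. standard normal (a heavier-tailed $t_5$ option exists for
robustness checks). The signal matrix is rescaled globally so that
$10\log_{10}(\mathrm{var}(\hat\Sigma)/\mathrm{var}(\hat N))$ — computed
on the vectorized signal-only and noise-only stacks — hits the target
SNR exactly. Ground truth (supports, signals, realized SNR) is always
returned with the data, and a fixed seed reproduces a simulation
bit-exactly. The amplitude law and support fraction are the package's own
choices, made once to keep detection nontrivial but feasible; they are
configurable but their defaults are not tuned per experiment.

What the simulator does *not* emulate: correlated noise within or between
blocks, batch structure, heavy platform-specific marginals, missing
values, or signals carried by overlapping row sets. Passing tests on
these simulations therefore demonstrate correct behaviour under the
stated generative model, not performance guarantees on arbitrary real
data.

**Problem sizes.** The test suite and the acceptance script fix the block
size at 1000 rows per block for sweep/recovery checks, 250–500 rows for
permutation-FDR checks at $n = 30$, and $B = 20$ permutations with
$L = 15$–$25$ grid points; these are the package's chosen study sizes for
routine verification, with the defaults above remaining the recommended
analysis settings.

## Support-recovery evaluation

`roc_from_sweep()` turns the penalty path into a ROC curve: at each grid
penalty the detected set is the nonzero rows of the eigen-array, scored
against the known support; the curve is augmented with $(0,0)$ and
$(1,1)$, duplicate points are removed, and AUROC is computed by the
trapezoid rule. Because a single rank-1 pass tracks the dominant signal,
`evaluate_sim_auroc()` assigns extraction order by correlating the
unpenalized eigen-signal with each planted signal, sweeps the original
stack for the first-matched signal, deflates the unpenalized component,
and sweeps the residual for the other.

`compare_over_sims()` is the benchmarking harness: any detector that maps
a super-matrix to per-row scores (or to a family of detected sets) can be
plugged in; AUROC differences (sweep minus alternative) are summarized
per signal with an exact binomial sign test. Two baselines ship with the
package: `detector_svd_threshold` (rank rows by the magnitude of the
unpenalized leading left singular vector) and `detector_random` (the
chance baseline). Re-implementations of third-party joint-analysis
methods are deliberately out of scope; external implementations can be
wrapped as detectors.

## Eigen-survival analysis

For a signature realized as an $s \times n$ row-centered matrix, the
eigen-survival model (`extract_esm()`) is the dominant left singular
vector: a unit loading vector whose inner product with a sample's profile
is that sample's prognostic score. Using the dominant singular direction
rather than a raw average damps independent noise across the signature's
variables. Scores project onto unseen cohorts by ID-matched inner
products (`project_scores()`/`predict()`); the loading orientation is
mathematical (largest-magnitude loading positive), so whether a high
score is adverse is read off the sign of the fitted hazard ratio rather
than assumed.

`quartile_groups()` labels the $\lfloor m/4 \rfloor$ largest and smallest
scores (boundary ties broken by stable sample order; labels are invariant
under adding a constant to, or positively rescaling, the scores).
`logrank_test()`, `cox_ph()` (Efron tie handling) and `km_summary()`
wrap the survival package behind the module's interface; censoring is
coded 1 = censored and converted internally to events. `esm_prognosis()`
chains the steps and applies the conjunction rule exactly: a signature is
called predictive only when both the top-vs-bottom log-rank test and the
Cox model of the continuous score reach the significance level (default
0.05).

## Numerical choices and degenerate inputs

* Zero matrices are rejected wherever a rank-1 direction or a scale is
  required (fit, grid, Frobenius scaling, ESM extraction).
* Sign conventions everywhere fix the largest-magnitude loading positive;
  SVD signs are otherwise arbitrary.
* Beta-values are clipped to $[10^{-6}, 1 - 10^{-6}]$ before the M-value
  logit so boundary values stay finite; the generalized log2 transform
  `log2((x + sqrt(x^2 + c))/2)` covers background-subtracted (negative)
  intensities and converges to plain log2 as $c \to 0^+$.
* Quantile normalization resolves ties by averaging the reference values
  of tied ranks (via limma).
* Missing values are rejected at load time by default; row-median
  imputation is available behind an explicit flag.
* Permutations, simulations and stochastic detectors all consume
  explicit seeds; identical configuration and seed reproduce outputs
  byte-identically (the command-line driver serializes numbers at 12
  significant digits).

## Known limitations

* A single $\lambda$ penalizes the whole stacked eigen-array; per-block
  penalty weighting is not implemented (per-block Frobenius scaling
  before stacking is available as a flag and partially serves that role).
* The rank-1-per-pass design models one shared signal at a time;
  overlapping signals with correlated eigen-signals may split or merge
  across passes.
* Permutation FDR is computationally heavy: the profile costs
  $(B + 1) \times L$ fits per pass. The defaults are sized for matrices
  in the low tens of thousands of rows.
* The survival wrappers assume right-censoring and proportional hazards;
  no competing-risks or time-varying extensions are provided.
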