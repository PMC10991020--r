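---
title: "Sparse PCA: weights are not loadings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse PCA: weights are not loadings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(spcawl)
```

## The model and why two sparse variants exist

Principal component analysis decomposes a column-centered data matrix
$X$ ($I \times J$) as $X \approx T_R P_R^\top$ with orthonormality
constraints, where the scores are linear combinations of the variables,
$T_R = X W_R$. Two coefficient matrices appear: the *weights* $W_R$, which
build the summary scores, and the *loadings* $P_R$, which link components
back to variables in the reconstruction. In ordinary PCA both equal the
right singular vectors $V_R$ of $X$, so the distinction is invisible. Once
sparsity is imposed, it matters where: zeroing weights and zeroing loadings
define different models, estimated by different algorithms, and recoverable
from different kinds of data.

`spcawl` implements one estimator of each family, chosen so that both solve
a least-squares criterion, extract all components simultaneously, and allow
the number of zeros to be fixed exactly — so any performance difference is
attributable to the weights-versus-loadings choice rather than to
algorithmic detail:

* **Sparse weights** (`fit_spca()`): minimize
  $\lVert X - X W_R P_R^\top\rVert_F^2 + \lambda \sum_r \lVert w_r\rVert_1 +
  \lambda_2 \sum_r \lVert w_r \rVert_2^2$ subject to $P_R^\top P_R = I_R$.
  The weights update is an elastic-net regression of each current component
  $X p_r$ on the variables, solved along a LARS-EN path that is truncated at
  the knot where the $(q+1)$-th variable would enter
  (`cardinality_enet()`), which is what lets the number of non-zero weights
  per component be specified exactly. The loadings update is the orthonormal
  Procrustes solution $\mathrm{polar}(X^\top X\, W_R)$.
* **Sparse loadings** (`fit_uslpca()`): minimize
  $\lVert X - T_R P_R^\top \rVert_F^2$ subject to $T_R^\top T_R = I_R$ and
  $\mathrm{Card}(p_r) = k$. Given $P$, the scores are
  $\mathrm{polar}(X P)$; given $T$, the unconstrained loadings are the
  univariate regressions $X^\top T$ and the constraint is met by keeping the
  $k$ largest-magnitude entries per column. Weights are not part of this
  model; `weights_from_scores()` infers them post hoc as the minimum-norm
  least-squares solution $X^+ T$.

Both problems are non-convex; solutions depend on the starting values.
`init_strategy()` expresses the two protocols studied here: the SVD-based
start ($V_R$) and a multistart protocol with random $U(-1,1)$ start
matrices, from which `multistart_fit()` keeps the solution with the lowest
least-squares reconstruction loss.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `nonzeros` | (required) | Per-component cardinality. An *upper bound* for the weights method (a truncated path may activate fewer variables); *exact* for the loadings method. |
| `lambda` | 2 | Reporting weight of the $\ell_1$ term in the sparse-weights objective. The cardinality bound replaces $\lambda$ as the effective tuning device, so `lambda` affects only the recorded objective value, not the path. |
| `lambda2` | 0 (`fit_spca`), 1e-6 in the simulation runner | Ridge term; stabilizes the weight update under correlated variables and permits more than $I$ non-zeros when $J > I$. |
| `max_iter` | 200 (weights), 500 (loadings) | Iteration caps; see the convergence discussion below. |
| `tol` | 1e-8 | Relative change of the monitored loss at which alternation stops. |
| `n_random_starts` | 19 (simulation), 100 (toy protocol) | Random starts; the simulation protocol adds the SVD start. |

## Numerical choices

**Convergence and cycling.** Both half-steps of the sparse-loadings
alternation are exact minimizers, so its loss is non-increasing and the
1e-8 relative-change criterion terminates it. The sparse-weights update is
different in kind: the truncated-path solution minimizes the elastic net at
its *own* knot penalty, which moves from iteration to iteration, so no fixed
objective is guaranteed to decrease. On noisy data the alternation settles
into a regime where the weights cycle among near-equivalent knot solutions
(observed: relative weight changes plateau near $2\times10^{-3}$
indefinitely while the reconstruction loss wanders within a band of about
0.15%). In that regime the iteration cap is the effective stop, the fit is
flagged `converged = FALSE`, and the best iterate by reconstruction loss is
returned; the cap of 200 follows the customary default for this estimator
family. The recorded `loss_trajectory` (the full objective per iteration) is
consequently non-monotone for the weights method and exactly monotone for
the loadings method — the test suite asserts the latter, plus the guaranteed
half-step property of the former (the Procrustes update never increases the
reconstruction loss).

**Ties in hard thresholding.** When magnitudes tie at the $k$-th rank, the
lowest variable index is kept, with a relative tolerance of 1e-9 so that
exact ties survive floating-point noise. This is not cosmetic: on the
rank-two toy dataset below, the first unconstrained loadings update ties two
variables *exactly*, and the tie direction decides which local optimum the
SVD-initialized fit reaches.

**Multistart selection.** The accepted solution is the one with the lowest
reconstruction loss; reconstruction ties (relative 1e-8) are resolved by the
full reported objective, then by start order. On exactly low-rank data many
starts reconstruct perfectly, and the objective tie-break then selects the
least-penalized of those solutions deterministically.

**Component presentation.** Fitted components are ordered by per-component
variance accounted for, and signs are fixed so that each column's
largest-magnitude coefficient in the method's sparse block is positive.
Comparisons against a reference should still go through
`align_components()`, which matches columns by exhaustive search over
permutations and sign flips.

## The toy dataset and its exact reconstruction

`toy_dataset()` ships a $5 \times 3$ rank-two matrix generated from
orthonormal scores and sparse loadings $P = [[2,0],[\sqrt2,\sqrt2],[0,2]]$,
printed to two decimals. The printed rounding is not innocuous: for the
exact matrix, $X^\top X = P P^\top$ holds identically and the leading right
singular vector is $(1/2, \sqrt2/2, 1/2)$ — an exact magnitude tie between
the first and third variables. The SVD-initialized sparse-loadings fit
reaches its characteristic local optimum (loss 1.17, versus 0 for the
multistart fit) *because* of how that tie resolves; rounding the data to two
decimals breaks the tie by noise and sends the same algorithm to the global
optimum instead. The analysis protocol therefore runs on the exact
reconstruction `X_exact` (recoverable because any exactly orthonormal score
matrix yields the same $X^\top X$), which is also column-centered and has
squared norm exactly 12. It differs from the printed matrix by less than
0.012 per entry.

```{r toy}
reproduce_toy_table(n_random_starts = 100, seed = 1)$table
```

Reading the table: ordinary PCA and the SVD-initialized sparse-weights fit
share loadings and scores (the data is noiseless and rank two, so the SVD
start is already reconstruction-optimal for the weights method), yet their
weights differ — with one weight column using a single variable. The
sparse-loadings fit from the SVD start lands in a local optimum with 90% of
the variance; from 100 random starts it recovers the generating loadings
exactly. All five analyses disagree in their coefficient matrices: weights,
loadings and singular vectors are three different things once sparsity
enters.

## The three data-generating models

`generate_dataset()` draws data under the model the estimators assume, plus
the one they usually are not tested on:

* *spiked covariance*: $X = U_R S_R V_R^\top + E$ with sparse orthonormal
  $V_R$ — weights and loadings coincide ($V_R$ is both), the conventional
  benchmark;
* *sparse loadings*: the same construction read as $T = U_R$,
  $P = V_R S_R$;
* *sparse weights*: sparse $W_R$ applied to an initial data matrix,
  $T = X_{init} W_R$, with non-sparse Procrustes loadings — the neglected
  model, and the hard one, because different weight matrices can produce
  identical scores (with $J > I$ this indeterminacy is exact: add any
  null-space vector of $X$ to a weight column).

The error part is built from the trailing singular triplets of the initial
matrix (for the first two models, rotated into an orthonormal complement of
the sparse $V_R$; for the third, projected off the model's column space), so
model and error are *exactly* uncorrelated, and `scale_error_to_pev()`
makes the realized proportion of error variance exact rather than
approximate. Centering the initial matrix before its SVD makes every
derived column mean-zero, so the final data needs no re-centering that
would disturb this bookkeeping.

Two value choices deserve justification. The non-zero entries of the sparse
$V_R$ have equal magnitude $1/\sqrt{k}$ with random signs, as in the
classical spiked-covariance construction: if the entries were drawn
$U(-1,1)$ instead (available via `values = "uniform"`), some true
coefficients would be arbitrarily close to zero and *no* method could
classify them correctly, making perfect zero/non-zero recovery on noiseless
data unattainable in principle. The sparse weights $W_R$, by contrast, do
use $U(-1,1)$ values at uniformly random positions, as is usual for that
model family — recovery there is limited by indeterminacy, not by entry
magnitudes.

What the generators deliberately do not emulate: heavy-tailed or structured
noise, unequal spike strengths beyond what the initial matrix's singular
values provide, overlapping supports for the orthonormal sparse vectors, or
components of unequal sparsity. Passing tests on these generators therefore
says nothing about, e.g., robustness to outliers in real data.

## The simulation study and desk-scale profiles

`study_design()` defaults to the full factorial design: 3 models
$\times$ 2 dimensions ($100\times50$, $100\times500$) $\times$ 2 sparsity
levels (90%, 50%) $\times$ 3 error proportions (0%, 10%, 50%) = 36
conditions, 50 replicates, each dataset analyzed by 4 methods (both
estimators, SVD-based and multistart initialization, the latter adding 19
random starts to the SVD start), with the true cardinality supplied as
input. Any subset of factor levels keeps the full crossing. The test suite
pins two desk-scale profiles chosen to finish in minutes on one CPU: the
zero-noise grid (low-dimensional, both sparsity levels, 10 replicates),
where all four methods must and do achieve perfect recovery on spiked and
sparse-loadings data, and the full low-dimensional crossing at 10
replicates, which reproduces the qualitative orderings: recovery under the
sparse-weights model is markedly worse than under the other two, the
sparse-weights method explains more variance than the sparse-loadings
method on sparse-weights data, and the multistart solution never
reconstructs worse than the SVD-initialized one on the same data. Scores
remain well recovered (median congruence above 0.85) even where coefficient
recovery degrades — the signature of weight indeterminacy.

Seeds derive deterministically from a master seed per condition, replicate
and stream, so partial reruns match full runs; records carry the
reconstruction loss alongside the reported objective because the former is
the multistart selection criterion.

## Evaluation statistics

`recovery_rate()` is the fraction of coefficient positions whose
zero/non-zero status matches the truth, computed between the block the
model defines sparse and the block the method estimates sparse (weights for
the weights method, loadings for the loadings method), after alignment.
`tucker_phi()` is the cosine between vectorized score matrices; 0.85–0.94
is conventionally read as fair similarity. It is invariant to a global
rescaling but *not* to per-column rescaling, so it can sit slightly below 1
even under perfect per-column correlation when score normalizations differ.
`vaf()` reports total and per-component variance accounted for.
Because the sign and order of estimated components are not identified, both
recovery and congruence align the estimate to the reference first
(exhaustively — `R` is small by design here, at most 6).

## Known limitations

* The exhaustive component alignment is factorial in `R`; beyond 6
  components a Hungarian-type assignment would be needed.
* The weights-method objective is reported at a user-chosen $\lambda$; no
  tuning of $\lambda$ or of the cardinality is provided (the study design
  supplies the true sparsity as input, and cross-validation is out of
  scope).
* The multistart protocol mitigates but does not solve local optimality; on
  sparse-weights data with few starts the selected solution can remain a
  poor local optimum.
* `anova_screen()` and the CLI cover the end-to-end workflow on real
  matrices (screening, centering/standardization, fitting, serialization),
  but empirical datasets require user-supplied downloads and are not part
  of the test surface.
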