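---
title: "Minimum-redundancy feature selection by a relaxed binary integer program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-redundancy feature selection by a relaxed binary integer program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bipfs)
```

## The selection model

Given a labeled expression matrix $X \in \mathbb{R}^{N \times M}$ (samples by
features, $N \ll M$ in typical transcriptomics) with two-class labels
$y \in \{+1,-1\}^N$, the package selects $m$ features that are jointly
discriminative and mutually non-redundant. Selection is encoded by a binary
indicator $w \in \{0,1\}^M$ with $\sum_i w_i = m$.

**Separability.** Writing $A = yy^\top$ for the class-agreement matrix
($A_{ij} = +1$ for same-class pairs, $-1$ otherwise) and $L = D - A$ for its
Laplacian ($D = \mathrm{diag}(A\mathbf{1})$, which may carry negative
entries), the signed sum over sample pairs of squared distances in the
reweighted feature space — intra-class distances counted positively,
inter-class negatively — collapses to a *linear* function of the indicator:

$$\sum_{i,j} A_{ij}\,\lVert x_i \odot w - x_j \odot w\rVert^2
  \;=\; 2\, c^\top w, \qquad c_i = (X^\top L X)_{ii},$$

because $w_i^2 = w_i$ for binary $w$. Discriminative features have strongly
negative $c_i$; a constant feature has $c_i = 0$. `linear_term()` computes
$c$ as a column-wise quadratic form without materializing pairwise
distances, and `pairwise_objective_oracle()` is a brute-force double loop
kept solely to verify the identity in the tests (the factor 2 reflects the
ordered-pair double count; the single-count convention is used for $c$).

**Redundancy.** With $Q$ the $M \times M$ Pearson correlation matrix of the
feature columns — positive semi-definite, and a natural similarity under
the approximate normality of per-feature measurements — the average pairwise
similarity among selected features is $w^\top Q w / m^2$. Signed correlation
is used; taking $|r|$ would destroy positive semi-definiteness and with it
convexity, so it is available only as an explicit off-default choice.

**Program and relaxation.** The selection program

$$\min_w\; c^\top w + \frac{\lambda}{m^2}\, w^\top Q w
  \quad \text{s.t.}\quad w \in \{0,1\}^M,\; \textstyle\sum_i w_i = m$$

is NP-hard as stated; the binary constraint is relaxed to $w \ge 0$,
$\sum_i w_i = m$, giving a convex QP. No explicit upper bound is placed on
individual weights (the bound $w_i \le m$ is implied by the constraints).
Features are finally ranked by the relaxed $w$ and the top $m$ taken, with
exact ties broken by ascending column index for determinism.

## Low-rank treatment of Q

Forming and decomposing $Q$ is $O(M^2 N + M^3)$ — prohibitive for
$M \sim 10^4$. Instead the package builds a Nyström factorization from $k$
landmark pseudo-features: k-means centroids of the feature columns in
sample space (`kmeans_landmarks()`, 10 restarts, seeded; for $M$ above
5000 the clustering runs on a seeded subsample of 5000 columns, which
leaves centroid quality essentially unchanged and keeps the stage linear in
$M$). With $E \in \mathbb{R}^{M \times k}$ the feature–landmark
correlations and $W \in \mathbb{R}^{k\times k}$ the landmark–landmark
correlations,

$$Q \approx G G^\top, \qquad G = E\, W^{-1/2},$$

where $W^{-1/2}$ is computed by eigen-decomposition with relative
pseudo-inverse threshold $\tau = 10^{-10}$ (landmark sets are often
near-collinear). The top eigenpairs of $GG^\top$ come from the small
matrix $G^\top G$: if $G^\top G = U_G \Lambda_G U_G^\top$ then
$U_k = G\, U_G \Lambda_G^{-1/2}$ has orthonormal columns and
$U_k \Lambda_G U_k^\top = GG^\top$, all in $O(Mk^2)$. Note that
$\mathrm{rank}(Q) \le N - 1$, so the effective rank `k_effective` is capped
by the sample count regardless of the requested $k$.

Defaults: $k = \lceil 0.1\,M \rceil$ (capped at $M$), and

$$\lambda \;=\; \frac{m^2}{M}\,
   \frac{\lvert \sum_i c_i \rvert}{\sum_{ij} Q_{ij}},$$

with $\sum_{ij} Q_{ij}$ evaluated as $\lVert G^\top \mathbf{1}\rVert^2 \ge 0$
in the low-rank path. The absolute value in the numerator is deliberate:
$\sum_i c_i$ is negative for discriminative data while $\lambda$ must be
nonnegative to keep the program convex. If the denominator is numerically
zero, $\lambda$ falls back to 1 with a warning. Under this default the
quadratic term is mild — it acts as a redundancy-aware tie-breaker among
features of comparable separability rather than as a dominant penalty.

## Solving: why the low-rank QP is posed in the original coordinates

A tempting change of variables $\alpha = \Lambda_k^{1/2} U_k^\top w$ turns
the quadratic term into $\lVert\alpha\rVert^2$ and reduces the variable
count to $k$. But it also silently restricts $w$ to
$\mathrm{span}(U_k)$ — a subspace of dimension at most $N-1$. For
$M \gg N$ that subspace essentially never intersects the feasible slice
$\{w \ge 0,\ \sum_i w_i = m\}$: on this package's reference synthetic
conditions ($N=40$, $M=500$, $k=50$) the best attainable minimum
coordinate of any span member with $\sum_i w_i = m$ is about $-0.19$, i.e.
the substituted program is strictly infeasible, and an active-set solver
confirms inconsistency on every seed tried. The package therefore keeps the
approximation where it belongs — in the objective — and solves

$$\min_w\; c^\top w + \frac{\lambda}{m^2}\, w^\top (U_k \Lambda_k U_k^\top) w
  \quad\text{s.t.}\quad w \ge 0,\; \textstyle\sum_i w_i = m,$$

which is always feasible, coincides with the substituted program whenever
$Q$ has full rank, and coincides with the dense-$Q$ program whenever
$GG^\top = Q$. The span coordinates $\alpha$ are still reported, together
with the out-of-span residual $\lVert w - U_k U_k^\top w\rVert_\infty$.

`solve_reduced_qp()` solves this with a Mehrotra predictor–corrector
primal–dual interior-point method written for exactly this structure: each
Newton system $(H + D)\,\Delta w$ with $H = \frac{2\lambda}{m^2} U_k
\Lambda_k U_k^\top$ and barrier diagonal $D$ is solved through the
Woodbury identity in $O(Mk^2)$, so the whole pipeline is linear in $M$ at
fixed $k$. Convergence is declared when the scaled KKT residuals drop
below $10^{-10}$ (with stall detection accepting iterates within
$10^{-7}$ when floating point blocks further progress); the solver is
fully deterministic.

Two solver behaviors deserve explanation:

* **Interior limit versus exact vertex.** Curvature exists only on
  $\mathrm{span}(U_k)$; on the orthogonal complement the objective is
  linear, so the exact optimum concentrates its mass on few coordinates and
  sets the rest *exactly* to zero — carrying no ranking information there.
  The interior-point limit instead leaves strictly positive weights that
  decay with each feature's reduced cost, which is precisely the ordering a
  selection filter needs. `solve_reduced_qp()` therefore returns the
  interior iterate. The dense reference solver `solve_full_qp()` — used for
  closed-form and cross-solver checks — additionally *polishes* its iterate
  by an exact KKT solve on the identified free set (verified, with
  fallback), because there the target is agreement with analytic solutions
  at $10^{-6}$ even when the curvature $\lambda/m^2$ is tiny.
* **Two independent methods.** `solve_full_qp()` offers the interior-point
  route and a Goldfarb–Idnani active-set route (via \pkg{quadprog}, with a
  documented ridge of $10^{-9}\max(\mathrm{diag})$ when $Q$ is singular,
  since that method requires a positive-definite Hessian); the tests
  require the two to agree to $10^{-4}$.

`enumerate_binary_optimum()` exhaustively scores all $\binom{M}{m}$ binary
subsets (budgeted at $10^6$) and exists only as a test oracle for the
relaxation bound.

## Multi-task selection

For $K$ related datasets over one feature universe the objective sums
per-task terms under a single shared indicator:
$\min_w \sum_t c_t^\top w + \frac{\lambda}{m^2} w^\top (\sum_t Q_t) w$.
The sum of per-task Nyström factors is represented exactly by column
concatenation ($[G_1|\cdots|G_K][G_1|\cdots|G_K]^\top = \sum_t G_tG_t^\top$)
and re-truncated to the configured rank by one extra eigenpair pass,
keeping $O(M(Kk)^2)$ cost. Three deliberate choices:

* Tasks are *not* reweighted by sample size (the aggregate is an unweighted
  sum); `task_weights` overrides this.
* All tasks reuse the caller's single seed for their landmark k-means —
  the clusterings still differ because the data differ — so that a bundle
  of one task reproduces the single-task fit exactly.
* The solver is handed the per-task *average* ($c/K$, $\Lambda/K$) rather
  than the sum: the minimizer is unchanged (the objective merely scales by
  $K$, and the reported objective is scaled back), but the solver then sees
  single-task-scale inputs, so $K$ duplicated copies of one task reproduce
  the single-task computation and selection exactly.

The auto-$\lambda$ rule applies to the aggregated quantities; duplicating
every task leaves it unchanged (numerator and denominator both scale).

## Synthetic data: what it emulates, and what it does not

`generate_expression()` draws a two-class Gaussian study:
informative features are $\mathcal{N}(\pm\delta/2, 1)$ by class (a mean
shift of $\delta$ SD units); redundant blocks share a latent factor,
$x = \sqrt{\rho}\,z + \sqrt{1-\rho}\,\varepsilon$, giving within-block
correlation $\rho$ in closed form; everything else is
$\mathcal{N}(0,1)$ noise. Informative and block positions are placed
uniformly at random (and recorded in the ground truth) so that recovery
metrics cannot align with any positional convention such as the ranking
tie-break — an artifact that a leading-column layout would invite.
`generate_multitask()` derives per-task seeds from one master seed and
controls how much of the informative set is shared across tasks.

Defaults (40 samples, 500 features, 10 informative at $\delta = 1.5$,
balanced classes) describe a small two-class expression study and are the
conditions used by the package's own recovery checks. The generator is
Gaussian and complete-case by design: it does not emulate probe effects,
batch structure, heavy tails or missingness, so passing recovery tests
demonstrate correctness of the machinery under the stated model, not
robustness to real-array artifacts.

## Evaluation harness

`auc_score()` is the normalized Wilcoxon rank-sum statistic (ties count
1/2). `holdout_eval()` draws class-stratified training splits, z-scores
with training statistics only, re-runs the feature selector inside each
split, fits a pluggable scorer (default: linear SVM with cost 1 — standard
apparatus for small-sample expression classification, not part of the
method itself) on the selected features, and evaluates AUC on the held-out
remainder. Nothing upstream of scoring sees test labels; a sentinel test
corrupts them and asserts bitwise-identical selections and scores.

## Numerical choices and sizes used by the test-suite

* Interior-point KKT tolerance $10^{-10}$ (scaled), 300 iterations max,
  deterministic configuration; weights in $[-10^{-8}, 0)$ are clamped to 0
  before ranking and never materially occur.
* Pseudo-inverse / eigenvalue threshold $\tau = 10^{-10}$ relative to the
  largest eigenvalue, applied to both $W$ and $G^\top G$.
* Zero-variance features get unit self-similarity and zero
  cross-similarity; zero-variance landmarks are dropped with a warning;
  constant columns standardize to zero.
* Property checks run at deliberately modest sizes chosen to exercise the
  mathematics rather than the hardware: 200 random instances for the
  linear-term identity, $M \le 12$ for exhaustive relaxation bounds,
  $M \le 50$ for dense-versus-low-rank solver agreement, 20 seeded runs at
  $N=40$, $M=500$ for recovery, and a two-point $M = 2{,}000$ versus
  $10{,}000$ timing comparison at fixed $k = 100$ for the linear-scaling
  check.

## Known limitations

* Two-class problems only; multi-class labels are rejected.
* When the exact relaxed optimum is concentrated (few features dominate
  the separability term), ranks far beyond the optimum's support are
  determined by interior-point reduced costs — informative, but not
  backed by the optimization objective itself.
* Joint selection can hurt an unrelated task (negative transfer); the
  package selects one shared subset and makes no attempt to detect
  dissimilar tasks.
* The auto-$\lambda$ default keeps the redundancy term mild; applications
  that need aggressive de-duplication should raise $\lambda$ explicitly.
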