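---
title: "Estimating log-linear cognitive diagnosis models by EM and Differential Evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating log-linear cognitive diagnosis models by EM and Differential Evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcdmDE)
```

## The model

Cognitive diagnosis models classify test takers on a set of binary latent
skills ("attributes").  With $A$ attributes there are $C = 2^A$ latent
classes, one per mastery profile $\alpha_c \in \{0,1\}^A$.  A Q-matrix
$q_{ia}$ declares which attributes item $i$ measures.  The log-linear
cognitive diagnosis model (LCDM) gives person $p$ in class $c$ the correct
response probability

$$\pi_{ci} = \mathrm{logit}^{-1}\!\big(\lambda_{i,0} +
  \lambda_i^\top h(\alpha_c, q_i)\big),$$

where $h(\alpha_c, q_i)$ is a binary design vector with one element per
nonempty subset of the attributes item $i$ measures: singleton elements are
main effects, pairs and larger subsets are interactions, and an element is 1
exactly when the profile masters every attribute in the subset.  An item
measuring $K_i$ attributes therefore carries $2^{K_i}$ free parameters.  The
package freezes two conventions that the model itself leaves open: classes
are enumerated with attribute 1 as the most significant bit (class 1 is the
null profile, class $2^A$ full mastery), and within an item the effects are
ordered singletons ascending, then pairs lexicographically, then triples, and
so on.  Both choices only fix labels; they make parameter vectors and class
indices stable across runs, which matters once a population-based optimizer
carries flat parameter vectors between iterations.

Marginally over the class probabilities $v_c$, the log-likelihood of $N$
response vectors is

$$L = \sum_{p=1}^N \log \sum_{c=1}^C v_c \prod_{i=1}^I
  \pi_{ci}^{y_{pi}} (1-\pi_{ci})^{1-y_{pi}},$$

which the package always evaluates in log-sum-exp form.  Response
probabilities are clipped to $[10^{-10}, 1-10^{-10}]$ inside every
likelihood: the log terms are undefined at the boundary, and the clip bounds
are far outside any plausible estimate.

## The two estimators

`lcdm(y, q, method = "em")` is marginal maximum likelihood by EM.  The E-step
computes posterior class probabilities; the M-step updates the mixing vector
$v$ as the posterior column means and improves the item parameters by one
guarded Newton pass per item on the expected complete-data log-likelihood
$\ell = \sum_i \sum_c [r_{ci}\log\pi_{ci} + (n_c - r_{ci})\log(1-\pi_{ci})]$,
which is separable across items.  One inner pass (generalized EM) with
step-halving is enough to guarantee ascent and is markedly cheaper than inner
convergence.  The stop rule is an absolute log-likelihood change below `tol`
(default 0.001) or `max_iter` (default 1000) iterations.

Newton updates need the curvature $\partial^2 \ell / \partial \lambda^2$, and
this is exactly where derivative-based estimation of diagnostic models can
die: when posterior mass vanishes on the classes that distinguish a
parameter, the item's information matrix becomes singular.  The package
treats this as a first-class outcome, not a crash: the M-step signals a
structured `lcdm_convergence_failure` condition carrying the item index, and
`lcdm()` returns a non-converged fit with the failure recorded in
`$failure`.

`lcdm(y, q, method = "em-de")` keeps the identical EM structure but replaces
the Newton update with a derivative-free Differential Evolution search over
the item parameters, inside a box of $\pm 20$ per coordinate.  Because DE
needs only objective values, it cannot suffer curvature degeneracies, at the
price of substantially more objective evaluations.  The DE configuration
defaults follow the study conditions: the printed current-to-best mutation
variant (base vector a random member $\lambda_{\delta_o}$, plus
$F(\lambda_{best}-\lambda_{\delta_2}) + F(\lambda_{\delta_1}-\lambda_{\delta_2})$),
fixed $F = 0.8$ (a per-mutation $U(0,1)$ draw is available via
`F_policy = "uniform"`), binomial crossover with $CR = 0.5$, 500 candidate
solutions, and midpoint boundary repair (a violating coordinate is replaced
by the midpoint of the violated bound and the parent's coordinate).
Crossover follows the rule that coordinate $r$ comes from the mutant when a
fresh uniform draw $z_r < CR$; ties in the greedy one-to-one selection keep
the parent, and a non-finite trial objective never displaces a parent.

### The hybrid's M-step objective

Two objectives are available for the DE M-step.  `objective = "marginal"`
maximizes the marginal log-likelihood with $v$ held fixed at its E-step
value, over the joint parameter vector of all items.  `objective =
"expected"` (the default) maximizes the expected complete-data
log-likelihood $\ell$ — the classical M-step target.  The two have the same
fixed points and both yield monotone EM ascent, but $\ell$ is separable by
item, so DE searches $2^{K_i}$-dimensional spaces (2 to 8 dimensions here)
instead of one space with ~100 coordinates.  In a population optimizer whose
search effort scales steeply with dimension this is the difference between
minutes and hours per fit, which is why the separable objective is the
default; the joint marginal objective remains available and its ascent
property is exercised in the test suite.

Each EM iteration runs `gens` (default 20) DE generations per item group,
and the populations persist across EM iterations (`persist = TRUE`), so the
global search is amortized over the EM path rather than restarted: a full DE
convergence inside every M-step would be wasteful, and generalized-EM theory
only requires improvement.  Because the expected counts change every
iteration, the parents' objectives are re-evaluated at the start of each
M-step; the previous best member stays in the population, which is what
makes the ascent argument go through.  One population member is initialized
at the default starting values (an "educated guess"); the rest are uniform
in the box.  Items with the same number of measured attributes are advanced
together with shared index draws — common random numbers across independent
per-item searches; each item keeps its own population, objective, and
selection.

The hybrid stops when the marginal log-likelihood has changed by less than
`stall_tol` ($10^{-8}$) for `stall` (10) consecutive EM iterations, or at
`max_iter` (1000).  Exact float equality would be fragile; $10^{-8}$ on a
log-likelihood of magnitude $10^3$–$10^4$ is far below any substantive
change.  For the standalone `de_maximize()` the stall counter increments
when *no candidate* improved by more than the tolerance: counting only
changes of the single best member stops the search during the long plateaus
that narrow correlated objectives (like the worked least-squares example)
produce while the population is still closing in.

### Starting values

Intercepts start at $-1$, main effects at $+1$, interactions at $0$, and the
mixing vector uniform.  This weakly monotone start mimics common diagnostic
software defaults, respects the expected direction of the effects, and
anchors the class labels to the Q-matrix so no relabeling heuristic is
needed.  Monotonicity constraints (non-negative main effects) are available
via `monotone = TRUE` but off by default.  User-supplied starts are accepted
through `lcdm_control(start = ...)`.

## The simulation frame

The generator reproduces the package's reference study conditions and is
first-class, tested code:

* `sim_q_matrix(A, I)` builds a balanced Q-matrix: for $A = 3$ half the
  items measure one attribute and half measure two; for $A \in \{4, 5\}$,
  two or three.  Combinations are cycled so every attribute appears in
  (near-)equal counts, with seed-controlled shuffling — deterministic
  balance, random assignment.  A request that cannot cover every attribute
  is an error rather than a silent repair.
* `sim_attributes(N, A)` draws latent scores from $MV(0, \Sigma)$ with unit
  diagonal and off-diagonal correlations uniform on $[0.7, 0.9]$, and calls
  attribute $a$ mastered when the score exceeds zero, giving ~50% marginal
  mastery and strongly dependent profiles.  A non-positive-definite draw
  (possible at $A = 5$) is projected to the nearest correlation matrix.
* `true_item_params(q, quality)` sets the two quality levels: high quality
  uses main effects 2, intercepts $-1.5$, interactions (any order) 0.5; low
  quality 0.2, $-0.5$, 0.1.
* `lcdm_recovery()` runs the Monte-Carlo study: fresh Q-matrix, attributes,
  and responses per replication (a `fresh_q = FALSE` switch freezes the
  design), per-replication seeds derived from one master seed so runs are
  reproducible and order-independent, MAP classification by default (EAP via
  `rule = "eap"`), and RBIAS/RMSE pooled by parameter type.  RBIAS is
  $100 \cdot \mathrm{mean}((\hat\lambda - \lambda)/\lambda)$ and RMSE
  $100 \cdot \sqrt{\mathrm{mean}((\hat\lambda - \lambda)^2)}$ over
  replications and parameters of a type; the raw (unscaled) RMSE is also
  reported, since percent-like scaling of recovery error is a reporting
  convention, not a model quantity.  Estimator failures are counted and the
  replication continues; failed fits are excluded from the summaries.

What the generator does *not* emulate about real assessment data: item
quality varying across items, attribute hierarchies or structured Q-matrix
misspecification, missing responses, and local dependence beyond the latent
class structure.  Passing recovery tests therefore show the estimators are
correct under the model, not that the model fits any particular dataset —
that is what the MADcor and SRMSR indices are for.

```{r recovery-demo}
design <- lcdm_sim_design(A = 2, I = 10, N = 150, quality = "high",
                          replications = 3, seed = 7)
lcdm_recovery(design, estimators = "em")
```

## Classification and fit

`lcdm_classify()` converts posteriors to attribute calls.  MAP takes the
profile of the posterior-modal class, ties toward the lowest class index;
EAP thresholds the marginal mastery probabilities at 0.5 with ties called as
mastery.  The tie rules are arbitrary but deterministic.
`attribute_accuracy()` and `profile_accuracy()` score agreement per
person-attribute cell and per whole profile; the latter can never exceed the
former.

`lcdm_fit_indices()` compares observed and model-implied inter-item Pearson
correlations over all item pairs: MADcor is the mean absolute deviation,
SRMSR the root mean squared deviation.  Model-implied moments are computed
by exact summation over the $2^A \le 32$ classes — cheap and deterministic,
with no simulation error.  Items with zero observed variance cannot enter a
correlation and are dropped with a warning.

## Numerical choices, in one place

* Probabilities clipped to $[10^{-10}, 1 - 10^{-10}]$; linear predictors to
  $\pm\,\mathrm{logit}(1 - 10^{-10}) \approx \pm 23.03$.
* Likelihoods in log-sum-exp form; a person with zero mass under every class
  yields `-Inf`, and the E-step reports the person index rather than
  producing NaN posteriors.
* Newton steps are halved until the item objective does not decrease
  (30 halvings, then the old value is kept); degeneracy is declared when the
  information matrix has a vanishing diagonal or reciprocal condition number
  below $10^{-12}$.
* DE selection requires strict improvement; repair guarantees feasibility
  whenever the parent is feasible, so every population member stays in the
  box at all times and so do all reported estimates of the hybrid.
* All randomness flows through R's RNG: a fixed `seed` makes any fit,
  simulation, or recovery study bit-reproducible.

## Problem sizes used by the test suite

The packaged tests run the reference conditions at the sizes the study
states: the high- and low-quality EM conditions at 200 replications of
$N = 300$, $I = 30$, $A = 3$, the hybrid at 20 replications of the same
condition, and the large-sample parameter-recovery check at 20 replications
of $N = 2000$ with a frozen Q-matrix.  Smaller property tests use $A \le 3$,
$N \le 300$ instances where brute-force oracles (direct-product likelihoods,
explicit Bayes arithmetic, double-loop counts) are exact and fast.

## Known limitations

* Dichotomous responses only; no polytomous extension.
* No attribute hierarchies and no shipped DINA/DINO/RRUM presets (such
  submodels are expressible by hand through equality/zero constraints on the
  effects, but no constraint interface is provided).
* No standard errors or information-matrix output.
* Single deterministic start (plus optional user starts); no multi-start
  orchestration.  Occasional local maxima at small $N$ are visible in
  recovery runs as rare low-accuracy replications.
* The DE engine implements the three printed mutation strategies with box
  bounds and midpoint repair only — no self-adaptive variants, no penalty
  repair, no parallel evaluation (the objective contract would allow it).
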