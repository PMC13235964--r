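---
title: "Causal mixed graphical models with censored variables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal mixed graphical models with censored variables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Clinical and systems-biology cohorts mix three kinds of variables:
continuous measurements, categorical covariates, and censored time-to-event
outcomes recorded as pairs $(t_i, \delta_i)$ — an observation time and an
event indicator, with $\delta_i = 0$ meaning only a lower bound on the true
event time is known. Graphical-model structure learners built for
continuous/discrete data cannot consume such pairs, and the obvious
workarounds are both bad: treating the observed time as the event time
biases every coefficient that touches it (censoring systematically shortens
times — *expansion bias*), while restricting to samples with observed
events throws away most of the data under heavy censoring.

`coxmgm` handles censored variables natively in both stages of a two-step
causal discovery pipeline, and in the downstream survival predictors.

# The undirected model (CoxMGM)

The joint model assigns each node a conditional distribution given all
other variables:

* continuous node $x_s$: Gaussian linear regression with unit variance
  (data are standardized before fitting, so the residual scale is fixed and
  the penalties act on comparable coefficients);
* discrete node $y_j$ with $L_j$ levels: multinomial logistic regression
  with a full (non-reference) indicator encoding — group penalties make the
  overparameterization harmless, and grouping requires all $L_j$
  coefficients of a pair to vanish together;
* censored node $(t_m, \delta_m)$: Cox proportional-hazards partial
  likelihood in a linear predictor $\eta_m = \gamma_m^\top x + \psi_m(y)$,
  with Efron's correction whenever tied times occur.

Fitting minimizes the negative log-pseudolikelihood — the sum of all node
conditional negative log-likelihoods — plus five edge-type penalties:
lasso on continuous–continuous ($\beta_{st}$) and continuous–censored
($\gamma_{sm}$) scalars, group $\ell_2$ on continuous–discrete
($\rho_{sj}$) and discrete–censored ($\psi_{jm}$) level-vectors, and
Frobenius on discrete–discrete ($\phi_{jk}$) level-matrices. Each edge
parameter is shared by its two endpoint conditionals, the standard
pseudolikelihood construction.

## How censored variables enter other nodes' conditionals

A second-order expansion of the Cox partial likelihood around a linear
predictor $\hat\eta$ gives a diagonal weight matrix $W$
($\mathrm{diag}(W) = l''(\hat\eta)$) and working response
$z = \hat\eta - l''(\hat\eta)^{-1} l'(\hat\eta)$. At the null expansion
$\hat\eta = 0$ (Breslow tie convention), the product $Wz$ equals the
**Martingale residuals** of the covariate-free model,
$M_i = \delta_i - \hat\Lambda(t_i)$ — the difference between observed and
expected event counts up to the observation time. The package uses this
fixed null-model $Wz$ column as the representation of each censored
variable inside the continuous and discrete conditionals.

*Design choice.* Re-expanding $W, z$ at the current iterate each outer
iteration is attractive in principle, but it makes the objective a moving
target: the printed objective is then not guaranteed to decrease, and the
monotonicity contract of the optimizer would be vacuous. With the null
expansion the penalized objective is a fixed convex function, backtracking
proximal gradient descent provably decreases it at every step, and the
representation coincides exactly with what the conditional-independence
test uses — so the two halves of the pipeline see censored covariates
identically. The censored node's *own* conditional never needs the
quadratic surrogate at all: its exact partial-likelihood gradient is
available in closed form and is what the optimizer consumes.

## Optimizer

Proximal gradient descent with backtracking line search; scalar
soft-thresholding for $\beta, \gamma$, group soft-thresholding for
$\rho, \psi, \phi$; intercepts unpenalized. The backtracking surrogate is
evaluated in the canonical parameter space (each shared symmetric
$\beta_{st}$ counted once). The objective sequence is non-increasing by
construction; iteration stops when the relative objective change falls
below `tol` (default `1e-5`) or at `max_iter` (default 500). Group
penalties carry no $\sqrt{\text{group size}}$ weighting, matching the
objective as written; `params_to_graph()` reads edges off block norms above
`zero_tol = 1e-6` on standardized data.

One subtlety worth recording: the pseudolikelihood is additive over samples
for the Gaussian and multinomial conditionals but *not* for the Cox
conditional, whose partial likelihood couples samples through risk sets
(duplicating a dataset does not exactly double the Cox term). The test
suite checks additivity exactly on censoring-free data only.

# Penalty selection: StEPS, StARS, BIC

A log-spaced path of `K` penalties descends from $\lambda_{\max}$ — the
smallest value yielding an empty graph, located by a doubling search
started at the analytic stationarity bound (the largest penalized-group
gradient norm at the intercepts-only fit) and refined by bisection, with a
10% head margin so subsample fits at the head are also empty. On `B`
subsamples of size $b = \min(\lfloor 10\sqrt n\rfloor, \lfloor 0.75
n\rfloor)$ drawn without replacement, each edge's selection frequency
$\hat\theta$ yields the instability $2\hat\theta(1-\hat\theta)$.

* **StARS** pools instability over all possible edges, monotonizes the
  curve (running maximum in the direction of decreasing $\lambda$, so the
  threshold crossing is unique) and selects the smallest $\lambda$ whose
  monotonized instability stays at or below the threshold (default 0.05).
* **StEPS** applies the same rule to each edge type's own curve, read off
  the shared path — five selections for the five penalties, at a cost of
  $K \cdot B$ fits rather than a five-dimensional grid.
* **BIC** selects the path point minimizing
  $2\,\tilde l(\Theta) + \log(n)\,\mathrm{df}$, with df counting nonzero
  interaction blocks by support plus the unpenalized intercepts.

Per-subsample seeds are derived from the master seed by index, so profiles
are reproducible and independent of evaluation order.

# The conditional-independence test

For a censored $X$: Cox regression of $X$ on $Y$ and the expanded
conditioning set. Continuous $Y$: Wald statistic on $Y$'s coefficient,
referred to a $t$ distribution with (events − parameters) degrees of
freedom — Cox asymptotics would justify a normal reference; the $t$ is the
more conservative choice in small samples. Discrete $Y$: likelihood-ratio
test between the null and full Cox models, $\chi^2$ with $L-1$ degrees of
freedom.

For non-censored pairs: partial-correlation $t$-test (continuous pair),
Gaussian LRT adding the discrete variable to the model of the continuous
one ($\chi^2$, $L-1$), and multinomial LRTs run in both directions and
symmetrized by the larger p-value (discrete pair).

Censored members of the conditioning set are replaced by their null-model
Martingale residual column — all $n$ samples are retained, versus the
complete-case workaround that keeps only the observed-event fraction (30%
under heavy censoring). The residual is a *proxy* for the latent event
time, not the thing itself: conditioning on it removes much of the
dependence induced by a censored confounder (the test statistic roughly
halves in the packaged simulation) but not all of it, and the test suite
asserts exactly that contraction rather than full type-I calibration in
that scenario.

When **both** variables are censored — a case the constraint-based stage
does encounter — each side is tested as the Cox target with the other
entering as its Martingale-residual covariate, and the larger p-value is
returned; this symmetrized construction is a package design decision.

# Constraint-based orientation

`mpc_stable()` runs PC-Stable (adjacency sets frozen per depth, so removal
order cannot change the result), then majority-rule collider orientation:
for each unshielded triple $X - Z - Y$, all separating subsets of the
adjacency sets of $X$ and $Y$ up to the depth bound are collected by
re-testing, and the triple becomes a collider iff $Z$ appears in fewer
than half of them (exactly half: left unoriented, logged). Meek rules
R1–R4 close the result to a CPDAG. `fci()` adds possible-D-SEP pruning and
Zhang's orientation rules R1–R4 and R8–R10 to a fixpoint; the
selection-bias rules R5–R7 cannot fire under the package's stated
no-selection-bias assumption and are omitted. The default conditioning
depth is 3 — benchmark graphs reach hundreds of nodes, and unbounded
depth is exponential; a larger bound is a parameter away.

Failed tests (non-convergence, singular designs) conservatively retain the
edge: a false adjacency can still be pruned or ignored downstream, a lost
one cannot be recovered. All p-values are cached by (pair, conditioning
set), which makes majority voting and $\alpha$ sweeps cheap and exactly
reproducible.

# Simulator

Ground-truth DAGs: Erdős–Rényi graphs place exactly
$\lfloor N d/2 \rfloor$ edges uniformly and orient them along a random
topological order; scale-free graphs grow by preferential attachment with
$m = d/2$ edges per node (topped up or trimmed to the same count),
oriented old→new. Node types are assigned uniformly in the configured
proportions (default 5/11 continuous, 5/11 discrete, 1/11 censored, by
largest-remainder allocation); edge coefficients are drawn uniformly from
$\pm[0.3, 1.0]$ — strong enough to be detectable at $n = 500$, weak
enough not to be trivial.

Ancestral sampling: continuous children are linear in parent contributions
plus unit Gaussian noise; discrete children (3 levels by default) are
multinomial-logistic with equally spaced level loadings $s_\ell \in
[-1, 1]$ on the scalar parent contribution; censored children draw an
event time from a Weibull proportional-hazards model (shape 1.5,
increasing hazard) whose linear predictor is the parent contribution.
Discrete and censored parents contribute standardized level scores and
standardized log latent event times, respectively. Censoring times are
independent exponentials whose rate is solved by bisection on the realized
latent event-time sample so that the expected censored fraction
$\tfrac1n\sum_i (1 - e^{-c\,T_i})$ equals the condition — 30% ("light"),
70% ("heavy") — making the achieved fraction unbiased by construction;
the recorded value is $(\min(T, C),\ \mathbf 1[T \le C])$.

What the generator does *not* emulate: nonlinear or interaction effects,
informative censoring, missing data, measurement error, and the
correlation structure of real omics platforms. Passing the recovery tests
therefore demonstrates correctness of the algorithms under the generating
assumptions, not performance on any particular real cohort.

# Evaluation conventions

Orientation metrics and SHD are computed against the **CPDAG of the true
DAG** (its Markov equivalence class), not the raw DAG: orientations that
no algorithm could determine from observational data are not counted as
errors. An estimated edge scores an orientation true positive only when
both endpoint marks match the MEC's; circle marks count as unoriented.
AUPRC integrates the precision–recall trapezoid over the achieved recall
range without extrapolating to recall 1 (conservative). Markov blankets in
CPDAGs/PAGs count undirected or circle-marked neighbours as possible
parents/children.

Harrell's concordance uses the standard comparable-pair convention (the
earlier time must be an observed event; tied times are not comparable;
score ties count one half), with an optional horizon $\tau$ that excludes
pairs whose earlier time exceeds it.

# Problem sizes used by the test suite

The packaged checks run at deliberately reduced scale, chosen as the
smallest sizes at which each property is cleanly visible: exhaustive
oracle-equivalence on all 543 labeled 4-node DAGs plus 150 sampled sparse
5-node DAGs; CI-test null calibration over all 6 pair-kind × 4
conditioning-kind combinations at $n = 150$ with 400 replicates (the
3-standard-error acceptance band widens accordingly); and a recovery study
on 20-node, degree-4 ER models over $n \in \{100, 500, 5000\}$ with 10
seeds, path length 6, 6 subsamples per stability profile, and conditioning
depth 2 in the orientation stage. The
acceptance script re-derives the censoring calibration at the benchmark's
native 110-node scale with $n = 10{,}000$ and 20 seeds per condition.

# Known limitations

* The pseudolikelihood is a surrogate, not the joint likelihood; the
  learned undirected model is a skeleton estimate, and its asymmetric
  information about censored nodes is folded through the null-model
  residual representation.
* Martingale-residual conditioning is approximate; with strongly censored
  confounders some residual dependence survives, which can leave extra
  edges that the orientation stage does not remove.
* Constraint-based orientation assumes faithfulness and acyclicity, and
  inherits the usual sensitivity to test errors at small $n$; below a few
  hundred samples orientation recovery is unreliable even when adjacency
  recovery is good.
* Linear interactions only; the nonparanormal marginal transform
  (`nonparanormal_transform()`) relaxes this to monotone-additive effects
  on continuous variables but does not handle genuine interactions.
* Competing risks, time-varying covariates, selection bias, and missing
  data beyond complete-case filtering are out of scope.
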