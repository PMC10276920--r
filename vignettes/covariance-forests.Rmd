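---
title: "Conditional covariance estimation with random forests: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional covariance estimation with random forests: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Let $Y$ be an $n \times q$ matrix of responses ($q \ge 2$) and $X$ an
$n \times p$ matrix of covariates, numeric or categorical. Classical
multivariate regression models the conditional mean $E[y \mid x]$;
`covforest` instead estimates the conditional covariance matrix
$\Sigma_x = \mathrm{Cov}[y \mid x]$ as a nonparametric function of the
covariates. Typical uses are biomarker panels whose co-variability shifts
with age, sex or diagnosis, co-occurrence networks that reorganize along
environmental gradients, and checking the homoscedasticity assumption
behind a multivariate mean regression.

## The forest

Each tree is grown CART-style on a random subsample of
$\lfloor 0.632\,n \rfloor$ observations drawn *without replacement*. At a
node, `mtry` covariates are drawn; for each, up to `nsplit` random cut
points (numeric: midpoints of consecutive distinct in-node values) or
random proper level subsets (categorical) are proposed. A candidate split
into children $t_L, t_R$ with unbiased sample covariances
$\Sigma^L, \Sigma^R$ is scored by

$$\sqrt{n_L n_R}\; d(\Sigma^L, \Sigma^R), \qquad
d(D, E) = \Big(\sum_{i \le j} (D_{ij} - E_{ij})^2\Big)^{1/2},$$

the Euclidean distance over the upper triangle (each covariance counted
once, avoiding double weight on symmetric entries); the maximizing
candidate wins. The splitting rule therefore seeks children whose
response covariance matrices differ most, weighted toward balanced
splits. Splitting continues until a node holds `nodesize` or fewer
members, or no candidate leaves both children with at least `min_child`
members.

For a target observation $x^*$, the **bag of observations for prediction**
is the union over trees of the out-of-bag (OOB) observations sharing
$x^*$'s terminal node. Because OOB observations never influenced the
tree that assigns them, they behave like fresh data — the same honesty
idea as double-sample trees. $\hat\Sigma_{x^*}$ is simply the sample
covariance of the BOP members' responses. For a *training* row $i$, only
trees where $i$ itself is OOB contribute, and $i$ is excluded from its
own neighbour set, keeping the estimate out-of-sample; this is the
estimate used for tuning and testing.

Assumptions worth stating: responses are observed without missingness,
$\Sigma_x$ is locally constant enough to be recovered by axis-aligned
partitions, and BOP sizes are large relative to $q$ so that the local
sample covariance is stable.

## Parameters

* `ntree` (1000): more trees enlarge and stabilize the BOPs; the cost is
  linear.
* `mtry` ($\lceil p/3 \rceil$): the usual regression-forest fraction.
* `nsplit` ($\max\{\lceil n/50 \rceil, 10\}$): randomized split search;
  raising it approaches exhaustive search at linear cost.
* `sampsize` ($\lfloor 0.632\,n \rfloor$): subsampling without
  replacement guarantees the in-bag observations are distinct, so a node
  of size $m$ really holds $m$ distinct observations — important because
  a covariance from fewer than $q+1$ distinct points is singular.
* `nodesize` (tuned): the stop-splitting threshold, i.e. the scale at
  which the forest localizes. We read "target terminal size" as *a node
  with more than `nodesize` members may still be split*; with that
  reading `nodesize >= sampsize` yields root-only trees, which is the
  testable boundary case.
* `min_child` (2): the smallest child for which a sample covariance
  exists at all ($n-1 \ge 1$). This is plumbing, not science.

### Nodesize tuning

The estimation target $\Sigma_x$ is unobserved, so nodesize cannot be
tuned by OOB error. Instead, one forest is fitted per candidate level
$s(1) < \dots < s(M)$, where the candidates are
$[\,\mathrm{sampsize} \cdot 2^{-k}\,]$ (rounded half away from zero,
a choice the bracket notation leaves open) kept while $> q$. With
$\mathrm{MAD}(D,E) = \frac{2}{q(q+1)} \sum_{i \le j} |D_{ij} - E_{ij}|$,
the criterion

$$\mathrm{MAD}_j = \frac{1}{n} \sum_i
  \mathrm{MAD}\big(\hat\Sigma^{s(j)}_{x_i}, \hat\Sigma^{s(j+1)}_{x_i}\big),
  \quad j = 1, \dots, M-1,$$

measures how much the OOB estimates move when the node scale halves; the
$s(j)$ minimizing $\mathrm{MAD}_j$ is selected (ties to the smallest
$j$; $s(M)$ is never selected since $j \le M-1$). All candidate forests
reuse the same per-tree subsamples (the subsample draw depends only on
the master seed and tree index), a common-random-numbers choice that
removes subsampling noise from consecutive-level comparisons; whether
the original procedure shares subsamples is unspecified, so this is our
determination. Rows lacking a usable OOB estimate at any level are
dropped from every $\mathrm{MAD}_j$ average, since pairwise-complete
averages would weight levels inconsistently.

## Significance tests

For a covariate subset of interest, the null hypothesis is that the
conditional estimates given all covariates equal the estimates given
only the *control* covariates, compared through

$$T = \frac{1}{n} \sum_{i=1}^n d\big(\hat\Sigma_{x_i},
\hat\Sigma_{x^c_i}\big).$$

The null distribution is obtained by permutation and refitting; the
p-value is the proportion of permuted statistics *strictly* exceeding
the observed $T$, so $p = 0$ is a legitimate report. A conventional
$(1 + \#)/(1 + R)$ estimate is also returned for users who need a
positive lower bound. Two cases:

* **global**: the control model is the unconditional sample covariance
  $\Sigma_{root}$ of $Y$ (denominator $n-1$); the rows of $X$ are
  permuted as whole vectors (covariate-covariate structure preserved,
  covariate-response link broken); one forest per sample, $R + 1$
  forests in total.
* **partial**: a forest on the full covariate set and one on the control
  set per sample, $2R + 2$ forests in total. Here only the rows of the
  *tested* (non-control) columns are permuted, jointly, while the
  control columns stay aligned with $Y$.

The partial test's permutation scheme is the one design question we
settled empirically: permuting whole rows of $X$ also destroys the
*control* covariates' link to $Y$, so when the controls carry real
signal the permuted statistics collapse toward zero and the test
rejects for irrelevant tested covariates (type-I error near 0.8 in the
compound-symmetry null scenario). Holding the control columns fixed
makes the permutation respect the null "no effect *beyond* the
controls". The control forest is still refit with a fresh seed at every
permutation even though its data are unchanged: $T$ is a distance
between two independently grown forests, and the refit puts the same
two-forest Monte-Carlo noise into every $T_r$.

Nodesize is tuned once on the original data (separately for full and
control models) and reused across permutations — retuning inside every
permutation would multiply the cost by the grid size while changing the
null distribution little. Rows whose BOP degenerates (fewer than two
members — rare at practical `ntree`) fall back to $\Sigma_{root}$
inside the tests so that every replicate statistic averages over the
same $n$ rows.

## Variable importance

With no observed target, importances come from a *fit-the-fit*: the
flattened upper triangles $z_i$ of the estimated matrices (length
$q(q+1)/2$, row-major order) become the multivariate response of a
re-prediction forest, and OOB permutation importance is read off that
forest. Its splitting rule is Mahalanobis impurity

$$I(t) = \sum_{i \in t} (z_i - \bar z_t)^\top V^{-1} (z_i - \bar z_t),$$

with $V$ the *root-node* covariance of $z$, regularized by adding
$\varepsilon\,\mathrm{diag}(V)$ ($\varepsilon = 10^{-6}$, escalated
tenfold until invertible) when ill-conditioned; splits maximize the
parent-minus-children impurity decrease. Fixing $V$ at the root keeps
the metric identical across nodes and the evaluation $O(1)$ per
candidate from sufficient statistics. Per-covariate importance is the
mean increase in per-response *standardized* squared error after
permuting that covariate's OOB values within each tree, averaged over
the $q(q+1)/2$ responses and the trees; standardization stops
large-variance covariance entries from dominating the average. The
published method delegates these details to a multivariate-forest
backend whose exact rule is not reproduced; our definitions are declared
substitutes validated through rank-separation behaviour, not through
numeric equality with any external implementation. The re-prediction
forest uses `nodesize = 5` (the customary regression default) and is not
tuned.

## Synthetic generators

Four generators produce $(X, Y)$ pairs with known per-observation truth
$\Sigma_{x_i}$, each drawing $y_i \sim N(0, \Sigma_{x_i})$:

* `dgp1`: one uniform $[-1,1]$ covariate,
  $\Sigma_x = \Psi + B (1, x)^\top (1, x) B^\top$ — the linear
  covariance-regression model.
* `dgp2`: the same with regressor $(1, x + x^2)$, adding curvature a
  linear model cannot capture.
* `dgp3`: seven standard-normal covariates; a fixed depth-3 tree
  (thresholds at 0 on $X_1$; $X_2/X_3$; $X_4..X_7$) assigns one of eight
  distinct base correlations $\rho \in [0.05, 0.9]$; AR(1) structure
  $\Sigma_{jk} = \sigma_j \sigma_k \rho^{|j-k|}$ with
  $\sigma_j = 1 + \rho j / q$.
* `dgp4`: compound symmetry with
  $\rho_i = \mathrm{logit}^{-1}(2 X_{i1} + 1 X_{i2} + 0.5 X_{i3})$, so
  $X_1$ is the strongest and $X_3$ the weakest driver; variances again
  $\sigma_j = 1 + \rho j / q$.

The constants ($\Psi = I$, $B$ with rows $(1, 0.9)$ and $(0.5, -0.8)$,
the leaf correlations, the logit coefficients) are this package's frozen
choices: chosen once so that correlations and variances both vary
substantially over the covariate range, every generated matrix is
positive definite, and the generators expose the qualitative regimes the
estimator must recover (smooth quadratic heteroscedasticity, sharp
tree-structured regimes, monotone single-index correlation). They are
*synthetic substitutes*, not constants lifted from any external study,
and validation built on them supports qualitative claims (consistency,
calibration, power ordering, rank separation) rather than any published
numeric value. What they do not emulate about real data: non-Gaussian
and heavy-tailed responses, missingness, covariate measurement error,
and mean structure (all generators have $E[y \mid x] = 0$); passing
tests therefore says nothing about robustness to those features.

## Numerical and design choices

* BOP pooling follows the set-union definition — an observation
  contributed by several trees is counted once. Earlier
  nearest-neighbour-forest constructions pool with multiplicity; the
  `bop_multiset = TRUE` flag provides that variant for comparison.
* Self-exclusion of a training row from its own BOP is the default
  (keeping the estimate out-of-sample); the published algorithm text
  leaves this open.
* Tie-breaks in split search: candidates are evaluated in drawn
  covariate order with cut points ascending, first maximum wins —
  deterministic rather than arbitrary.
* Categorical splits are canonicalized (the smallest observed level
  always on the left) to avoid duplicate partitions; levels unseen in a
  node are routed right, and query rows with levels unseen at fit time
  are routed down both children with merged contributions.
* Stein's loss is fixed as
  $\mathrm{tr}(\hat\Sigma \Sigma^{-1}) - \log\det(\hat\Sigma \Sigma^{-1}) - q$,
  i.e. the KL divergence of $N(0, \hat\Sigma)$ from $N(0, \Sigma)$ with
  the estimate first; the direction is otherwise ambiguous.
* Degenerate BOPs (< 2 members) raise an error by default;
  `degenerate = "unconditional"` substitutes the sample covariance of
  all of $Y$.
* All randomness flows from one master seed through per-tree
  deterministic streams, so fits, tuning traces and tests are exactly
  reproducible and per-tree subsamples are shared across nodesize
  levels.

## Validation scales

The test suite exercises the operating characteristics at reduced
Monte-Carlo scales chosen to keep a serial run tractable: type-I error
of the global test from 200 independent-null replicates ($n = 100$,
$q = 5$, $p = 10$, 100 trees, $R = 100$); power growth on the
tree-regime generator at $n \in \{50, 100, 200\}$ (50 replicates each);
partial-test calibration from 120 replicates and power ordering from 40
replicates per scenario at $n = 300$ ($R = 60$, 60 trees); consistency
at $n_{train} \in \{100, 500, 1000\}$ with 200-tree forests; and
importance rank separation over 10 seeds at $n = 500$. Binomial noise at
these scales is accounted for in the assertions.

## Limitations

Axis-aligned splits cannot represent covariance structure driven by
rotated directions of the covariate space except by approximation;
estimates are sample covariances of moderate-size neighbourhoods, so
$q$ much larger than typical BOP sizes will produce ill-conditioned
estimates (sparse or shrinkage local estimators are out of scope);
p-values from $R$ permutations have granularity $1/R$; and computational
cost grows as $O(n q^2)$ per node evaluation, making very large $q$
expensive.
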