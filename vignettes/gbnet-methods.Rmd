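---
title: "Gaussian Bayesian networks for regional gray-matter structural associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian Bayesian networks for regional gray-matter structural associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbnet)
```

## The model

`gbnet` models the joint distribution of regional gray-matter volumes within
a small anatomical network (five or six regions of interest, ROIs) as a
linear Gaussian Bayesian network. A directed acyclic graph $G$ assigns each
ROI $X_j$ a parent set $\pi_j$, and the joint density factorizes as

$$p(X_1,\dots,X_n) \;=\; \prod_{j=1}^{n} p(X_j \mid \pi_j),$$

with each conditional a univariate normal whose mean is linear in the
parents:

$$X_j \mid \pi_j \;\sim\; \mathcal N\!\Big(u_j + \sum_{p \in \pi_j}
\beta_{p}\,(X_p - u_p),\; \sigma_j^2\Big).$$

Here $u_j$ is the unconditional mean of $X_j$ (volume units), the
$\beta_{p}$ are dimensionless *connection weight coefficients* — the
quantity of scientific interest, read as the strength of the structural
association from parent region to child region — and $\sigma_j > 0$ is the
residual standard deviation. The implied joint is multivariate normal with
covariance $(I - W)^{-1} D (I - W)^{-\top}$, where $W$ collects the weights
and $D$ the residual variances; `log_density()` is tested to agree with that
closed form to $10^{-8}$, and the classifier below is exactly an MVN
likelihood-ratio rule because of it.

Volumes enter on their raw scale with mean-centering inside the conditional
mean, as written above. A `standardize` switch (off by default) z-scores
each column first; it is off because the model is stated on raw volumes and
every BIC comparison is invariant to per-column rescaling anyway.

## Fitting and scoring

For a fixed graph, `fit_mle()` computes the maximum-likelihood parameters:
column means, ordinary-least-squares weights of the centered child on the
centered parents, and the divide-by-$N$ residual variance. The divide-by-$N$
convention is not negotiable here: the search score is

$$\mathrm{BIC} = \log p(D \mid \hat\theta) - \frac{d}{2}\,\log N,$$

and the first term must be the *maximized* likelihood. Natural logarithms
throughout. The free-parameter count is $d = \sum_j (|\pi_j| + 2)$ — one
mean, one residual variance, and one weight per parent for every node. The
model series never states a counting convention beyond "free parameters";
this complete count is used because it preserves score equivalence: two
graphs with the same skeleton and v-structures (the same Markov equivalence
class) have identical maximized likelihood and identical $d$, hence
identical BIC, which the suite verifies to $10^{-6}$ on random data.

The score decomposes over node families $(j, \pi_j)$. The implementation
caches family scores in a bitmask-indexed table keyed by (child, parent
set), so a hill-climbing move re-scores only the one or two affected
families, and the thousands of relearns inside the permutation test below
stay affordable.

## Structure search

`greedy_search()` starts from the empty graph and repeatedly applies the
best single-edge **addition, removal, or reversal** (steepest ascent),
stopping when no move improves the BIC. Legality means the result stays
acyclic. Ties are broken deterministically: move kind (add < remove <
reverse), then lexicographic (parent, child) order.

Two numerical choices matter more than they look:

* **Tie margin.** Score-equivalent moves — most visibly the two
  orientations of a newly added edge — tie *mathematically* but differ by
  $\sim 10^{-13}$ in floating point. Without a margin the "chosen"
  orientation is decided by that noise and varies arbitrarily between data
  sets, which destroys the reproducibility of downstream directed-edge
  statistics. A candidate therefore replaces the incumbent best move only
  when it improves on it by more than $10^{-6}$; within that margin the
  first candidate in scan order wins. $10^{-6}$ is far below any
  scientifically meaningful BIC difference at these sample sizes and far
  above accumulated rounding error.
* **Restarts.** The single empty-start climb is a local optimizer. Measured
  against exhaustive enumeration on random 4-node data sets ($n = 300$) it
  reaches the global BIC optimum in only ~76/100 instances, and on
  5000-subject draws from the built-in 6-node templates it returns a
  locally optimal wrong skeleton in up to a quarter of replicates — in
  every diagnosed case the true-structure fit scored higher and no single
  move improved the returned graph, the signature of a genuine local
  optimum. `greedy_search()` therefore runs 30 additional climbs from
  random sparse starts by default (seeded, RNG-isolated, so the search is a
  deterministic function of data and configuration; each climb costs
  milliseconds at these sizes). With the default, the exhaustive-oracle
  agreement is 99/100 and remaining skeleton errors are data-genuine: at
  $n = 5000$ the BIC truly prefers one spurious edge in roughly 2–3% of
  samples, matching the $\chi^2_1$ tail probability
  $P(\chi^2_1 > \log n)$ summed over non-adjacent pairs.

`exhaustive_search()` enumerates all DAGs on up to five nodes (25 / 543 /
29281 for 3 / 4 / 5 nodes), scores them through the same family cache, and
breaks ties by fewest edges then lexicographic edge list. It exists as the
search oracle, not as a user-facing fitter.

Because the BIC cannot distinguish Markov-equivalent graphs, structure
recovery is always stated on the CPDAG: `cpdag()` keeps the skeleton,
orients unshielded colliders, and closes under the Meek rules R1–R3 (R4
cannot fire without externally supplied orientations). Its compelled-edge
set is tested against an enumerate-the-class oracle.

## Between-group comparison of connection weights

`compare_groups()` learns one network per group, takes the union of the two
directed edge sets as the tested edges, and uses as the per-edge statistic
the difference of fitted weights, with weight 0 where a model lacks the
edge. The null distribution comes from relabelling: each of
`n_permutations` (default 5000) permutations reassigns subjects to two
pseudo-groups of the original sizes and relearns *both structure and
parameters* per pseudo-group. Tail counting is complementary —

$$p_{A>B} = \frac{\#\{\text{permuted diff} \ge \text{observed diff}\}}{B},
\qquad p_{B>A} = 1 - p_{A>B}$$

— so the two one-sided probabilities of every edge sum to one exactly, and
a small value in either column marks a significant directed difference at
$\alpha = 0.05$ (no multiple-testing correction by default; a
Benjamini–Hochberg option and an add-one corrected $(r+1)/(B+1)$ p-value
are available but off, since both would break the sum-to-one reporting
convention). Oppositely oriented homotopic edges are deliberately treated
as two distinct tested edges. Size-preserving label shuffles are the
standard exchangeable scheme; permutations whose relearn fails (singular
pseudo-group design) are redrawn, with an error if more than 10% fail.

**Calibration caveat (a deliberate finding, not a bug).** For any *fixed*
edge the permutation p-value is exchangeable-valid, and the suite verifies
that a stably present edge's p spreads uniformly under a null cohort. But
the *tested set* is selected by the observed fit: an edge whose presence or
orientation is unstable enters the union precisely in those labelings where
its observed difference is extreme, and with a deterministic learner the
permuted relearns almost never reproduce the minority configuration. The
result is a conditionally inflated per-edge rejection rate under the null —
measured at roughly 0.14–0.20 against the ~0.109 that two one-sided tests
at 0.05 with $B = 200$ would give for always-tested edges. This inflation
is inherent to per-directed-edge testing with full structure relearning;
readers of the edge reports should treat flags on unstable edges (weight 0
in one group) with corresponding caution, and the stable-edge differences
as the trustworthy findings.

The permutation engine applies the *identical* search (empty-start climb by
default; `restarts` configurable and applied to observed and permuted fits
alike) on both sides of the comparison, so whatever the search quality, the
observed statistic is exchangeable with the permuted ones.

## Classification by joint density

`classify()` assigns a subject to the group whose fitted network gives the
larger joint log-density — with equal class priors this is the Bayes rule
between the two fitted distributions, and identically the MVN
likelihood-ratio rule (tested for exact agreement in decisions and ROC).
Exact ties (only possible with identical models) go to the group listed
first. The ROC sweeps the decision threshold over all observed log-density
differences, from $+\infty$ (nobody assigned positive, point $(0,0)$) down
to the minimum (everybody positive, $(1,1)$); accuracy is
$N_{\text{correct}} / (N_{\text{correct}} + N_{\text{incorrect}})$.
`evaluate_protocol()` offers resubstitution (fit on all, classify all — the
in-sample protocol matching how such accuracies are usually reported) and
leave-one-out (the held-out subject's group model is refit without it),
which is never more optimistic on average.

A note on expectations: the synthetic cohorts below differ between groups
*only* in connection weights — means and residual scales are shared. The
Bayes-optimal accuracy for such pairs is modest (about 0.55 for the motor
young/old template pair; about 0.65–0.70 in-sample for the auditory one).
Cohorts of real young and old brains additionally differ strongly in mean
regional volumes, which is what makes high published accuracies possible.
Passing classification tests here demonstrates the correctness of the
density comparison, not a claim about attainable real-data accuracy.

## ROI volume extraction

`extract_roi_means()` averages, for each ROI, the voxels of a modulated
gray-matter image that carry the ROI's integer label in the atlas mask
*and* exceed the intensity cut-off (default 0.15, excluding probable
non-gray-matter voxels). The comparison is strictly greater-than: a voxel
at exactly 0.15 is excluded. Averaging is over voxels on the common grid;
image and mask must agree in shape (and affine, when NIfTI headers are
present). `build_table()` maps per-subject images to the subjects × ROIs
table and records threshold and mask checksum as provenance. Atlas
construction itself is upstream and out of scope; `write_toy_images()`
realizes any cohort table as tiny NIfTI fixtures whose extraction
reproduces the table exactly, which is how the path is tested end-to-end.

## Synthetic cohorts

`builtin_spec()` carries the young/old template pairs for the auditory
(6 ROIs, 7 + 7 edges), visual (6 ROIs, 7 + 5 edges) and motor (5 ROIs,
5 + 5 edges) networks with the published connection weight coefficients,
and default group sizes 109 and 82. Unconditional means and residual sds
are *not* published; the defaults (mean 7.0 volume units, sd 0.5) are
synthetic scaffolding chosen once as a plausible regional-volume scale, and
are configurable. What the generator emulates: group-specific linear
dependence structure over ROI volumes at realistic sample sizes. What it
does not emulate: between-group mean differences (atrophy), heteroscedastic
regions, spatial smoothing-induced noise correlation, and non-Gaussian
tails. Tests passing on these cohorts therefore validate the estimator,
search, test and classifier machinery — not effect sizes on real cohorts.

## Problem sizes used by the checks

The shipped verification suite uses: 1000 random points for the MVN
equivalence check; 100 random 4-node, $n = 300$ data sets for the
greedy-vs-exhaustive comparison; 50 covered-edge-reversal pairs for score
equivalence; $10^5$ draws per template for coefficient recovery (observed
max error ≈ 0.008 against the ±0.03 requirement); 20 replicates per
network at $n = 5000$ per group for skeleton recovery; and 50 null-cohort
replicates at 200 permutations each for calibration. These sizes make each
property measurable with comfortable margins while keeping the whole suite
in a few minutes.

## Known limitations

* Per-directed-edge permutation flags are conditionally anti-conservative
  for selection-unstable edges (discussed above).
* The BIC orientation of reversible edges is a tie-break, not evidence;
  only CPDAG-compelled directions are inferential.
* No missing data, discrete/hybrid nodes, or Bayesian posterior
  parameter estimation; networks beyond 12 nodes are rejected by the
  bitmask score cache (the intended use is small, pre-specified anatomical
  networks).
* Leave-one-out refits make `evaluate_protocol(..., "leave-one-out")`
  $O(N)$ structure searches; it is meant for cohort-sized tables, not
  voxel-scale problems.
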