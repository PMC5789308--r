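---
title: "Methods: co-lying association networks in pen-housed pigs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-lying association networks in pen-housed pigs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pignet)
```

# The observation process and its data model

The unit of observation is an instantaneous scan: at fixed intervals
(conventionally 10 min over a 6 h session, giving
`scanCountForDuration(6, 10) = 36` scans) every animal in a pen is recorded
as lying or not, and every *pair* lying in body contact is recorded as a
co-lying event. `PenObservations` stores exactly this: an n × S logical
lying matrix plus a per-scan list of unordered co-lying pairs.

Two modeling commitments are baked into the container rather than left to
downstream code:

* **Co-lying is pairwise, not group-wise.** A row of three pigs in contact
  is two pairs, not a clique; transitivity is never imposed, because the
  dyadic counts are all the association index consumes.
* **Missing posture rows are errors, not zeros.** A scan file must contain
  one posture row per animal per scan; silently treating an absent row as
  "not lying" would hide data loss, so `readScanCSV` refuses instead.

Scan timestamps are deliberately not modeled — every quantity in the
pipeline is a count over scans, so only the ordinal index matters, and the
time-budget and HWI computations are invariant to scan order (a property
the test suite checks directly).

# From counts to the half-weight association index

Summing the per-scan binary co-lying matrices gives the pair counts
`x_ab`; row sums of the lying matrix give the per-animal lying counts
`n_a`. The half-weight association index is

$$\mathrm{HWI}_{ab} = \frac{x_{ab}}{(n_a + n_b)/2},$$

the standard form of the index in the association-sampling literature: the
denominator is the pair's *average* number of lying scans, so the index is
the fraction of joint lying opportunity realized as co-lying and is bounded
by 1 since `x_ab ≤ min(n_a, n_b)`. A pair in which neither animal ever lies
has an empty opportunity set; its HWI is defined as 0 (not NA) so that
pen-level sums remain well defined — the same convention that makes an
animal never observed lying have strength 0.

Note the typographic trap in the formula: read as `x / (n_a + n_b) / 2`
(left-associative) the index would be bounded by 0.25, which is
incompatible with observed strong-tie cut-offs well above 0.4. The package
implements the standard parse, `x / ((n_a + n_b)/2)`.

All HWI values are kept at full double precision internally; rounding (3
decimals for densities, 2–3 for HWI) happens only in report files written
by `runPipeline`, while the per-pen HWI matrices are serialized at full
precision (`%.17g`) and round-trip exactly.

# Network measures

* **Density** is the mean of the `C(n, 2)` pairwise HWI values. For n = 8
  the divisor is 28. It equals the sum of all strengths divided by
  `2 C(n, 2)`, an identity the tests use as a conservation check.
* **Tie classification** uses two thresholds. The absent cut-off defaults
  to 0.15 — the study-wide mean HWI, interpreted as the rate at which any
  pair would co-lie by chance — with the *closed* boundary on the absent
  side (`HWI ≤ τ` is absent), which is the explicit convention of the
  source protocol. The strong boundary is also closed (`HWI ≥ τ` is
  strong), chosen so that a user-supplied cut-off equal to an observed
  value includes that value.
* **Strength** is the row sum of the HWI matrix.
* **Eigenvector centrality** is the principal eigenvector of the *valued*
  matrix (never a binarized one), computed by a full symmetric
  eigendecomposition (`eigen`), sign-fixed to be nonnegative and scaled to
  unit Euclidean norm. The test suite cross-checks it against power
  iteration (to 1e-10) and against igraph. For a disconnected
  positive-weight graph the principal eigenvector concentrates on the
  dominant component; the function warns rather than fails, and an
  all-zero matrix is a hard error since no principal direction exists.

## The default strong-tie break-point

Break-point procedures that split weak from strong ties do so from the
within-pen spread of HWI, but the exact algorithm behind published
per-pen cut-offs is not available. The package's default is

$$\tau_{strong} = \max(\tau_{absent} + 0.01,\; \bar{w} + s_w),$$

mean plus one standard deviation of the pen's pairwise HWI values: with
mean HWI near 0.15 this lands in the 0.3–0.4 range that published cut-offs
occupy, degrades gracefully for low-variance pens (the `+0.01` floor keeps
it above the absent cut-off), and is always echoed in the result so
reports are self-describing. It is a documented approximation, not a claim
about any particular software's internals — which is why the cut-off is
also directly settable. One consequence worth knowing: a mean-plus-SD rule
marks the upper tail of *any* HWI distribution (about 16% of pairs when
the distribution is roughly symmetric), so pens with no real structure
still show a few "strong" ties under the default, whereas a fixed cut-off
like 0.35 correctly finds essentially none (the simulator's uniform preset
averages 0.14 such ties per pen).

# Resampling inference

Dyadic observations within a pen are not independent, so classical
standard errors do not apply. Three resampling procedures are provided,
each fully determined by `(input, B, seed)` — bit-reproducible, with the
seed echoed in every result object and report row. `B` defaults to 5000.

**Density vs a theoretical value (node bootstrap).** Animals (nodes) are
resampled with replacement; the density of each resampled matrix is
computed over pairs of distinct sampled positions whose underlying animals
differ, because a duplicated animal contributes no information about its
association with itself. The bootstrap SD of these densities is the
standard error; `z = (estimate − theoretical)/se` is referred to the
standard normal, two-tailed. Degenerate cases (an all-equal or all-zero
matrix resamples to a constant) are flagged rather than thrown: p is 1
when the estimate equals the reference and bounded by 1/B otherwise.

**QAP correlation.** The observed statistic is the Pearson correlation of
the `C(n, 2)` upper-triangle cells of two matrices over the same roster.
The null distribution relabels the nodes of the second matrix — rows and
columns permuted together, preserving its internal dependence — and the
two-tailed p-value uses the add-one estimator `(1 + k)/(B + 1)`, which
cannot return zero and is conservative by construction. Two-tailed on |r|
because both positive and negative dependence between observation periods
are of interest. At n ≤ 7 the test suite compares the Monte-Carlo p
against full enumeration of all n! relabelings.

**Two-group comparison of animal-level metrics.** Groups (e.g. victimized
vs non-victimized pigs) contain *different* animals, so the comparison is
an unpaired difference of group means: animals are resampled with
replacement within each group and `p = 2 · min(#\{d^* ≤ 0\}, #\{d^* ≥ 0\})/B`,
clipped to `(1/B, 1]`. This percentile-type construction is the stated
contract of the procedure, and it carries a known small-sample bias: the
bootstrap SD of a mean of n values understates the sampling SD by the
factor `sqrt((n−1)/n)`, which for groups of 4 makes the effective
two-sided criterion ≈ 1.70 rather than 1.96, i.e. the test rejects a true
null noticeably more often than the nominal 5% (the acceptance suite
measures this honestly and the corresponding calibration check fails at
group size 4 + 4 while approaching nominal at 8 + 8). For the group sizes
this test is meant for, treat its p-values as descriptive rather than
strictly calibrated.

**Chi-square on contingency tables** delegates to the classical Pearson
statistic (no continuity correction), with explicit precondition checks —
a zero row or column margin is reported by name instead of producing NaN.
Significance conventions (p < 0.05 significant, p < 0.10 a trend) are
report annotations only; nothing filters on them.

# The synthetic pen generator

`simulatePen` emulates the observation process, not pig physiology: each
animal's lying state follows a two-state chain that keeps its previous
state with probability `boutPersistence` and otherwise draws fresh from
`Bernoulli(lieProb)` — so the stationary lying probability is exactly
`lieProb` for any persistence — and each pair with both members lying
co-lies independently with probability `preference[a, b]`. With
persistence 0 the scans are exchangeable and the closed forms
`E[x_ab] = S p_a p_b w_{ab}`, `E[n_a] = S p_a` make the generator
analytically checkable: at large S, pairwise HWI concentrates on
`p · w` (tested at S = 10^4), and the moment estimator
`recoverPreferences` (`x_ab` over scans with both lying) recovers `w`
to ±0.05 at S = 5000.

Defaults are the study conditions the pipeline targets: pens of 8, 36
scans, lying probabilities in [0.60, 0.89], and a uniform preference of
0.20 so that expected HWI sits near the empirical mean of 0.15. The three
presets fix one parameter bundle each:

| preset | lieProb | preference blocks (pairs × w) | expected density |
|---|---|---|---|
| `non_littermate_like` | U[0.64, 0.72] | 2 × 0.62, 14 × 0.33, 12 × 0.12 | ≈ 0.174 |
| `littermate_like` | U[0.56, 0.64] | 2 × 0.667, 6 × 0.367, 20 × 0.10 | ≈ 0.119 |
| `null_uniform` | 0.65 | all 0.23 | ≈ 0.15 |

The block structure follows from `E[HWI] ≈ w · p`: the two high-preference
pairs are strong-tie candidates (pens in the field average about two
strong ties), the medium block populates the weak class, and the low block
the absent class; expected densities and mean lying budgets then match the
published pen-level contrast (≈ 0.17 vs ≈ 0.12, budgets ≈ 68% vs ≈ 60%).
The within-pen *variance* of HWI is not constrained by any published
value, so the presets are calibrated to means only.

What the simulator does not model — and hence what passing tests do not
establish about real pens: spatial lying clusters (co-lying is generated
pairwise), diurnal or thermally driven changes in lying rates, identity
confusion in video scoring, and any coupling between association and
health outcomes. Bout persistence is a single scalar because scan-to-scan
autocorrelation is plausible at 10 min intervals but unquantified; the
default of 0 keeps the base model exchangeable and checkable.

# Pipeline, reproducibility and numerical conventions

`runPipeline` derives one seed per stochastic stage from the master seed
via a fixed hash (`deriveSeed`), so partial re-runs and full re-runs
agree, and two runs with the same config are byte-identical in every
report file. All RNG use is scoped: functions restore the caller's RNG
state, so library code never perturbs a user's stream.

Numerical conventions collected in one place:

* symmetry tolerance for weight matrices, 1e-12; HWI upper bound checked
  with the same slack;
* degenerate-bootstrap flag at se < 1e-12;
* QAP exceedance comparison uses `|r_perm| ≥ |r_obs| − 1e-12` so exact
  ties (e.g. the identity relabeling) count as exceeding;
* eigenvector sign fixed by the positive-sum orientation, with `abs()`
  fallback only when entries are materially negative (equal-eigenvalue
  disconnected case);
* report rounding: densities and strengths 3 decimals, bootstrap se 4,
  z 2, percentages 1.

Problem sizes used by the test suite are chosen to keep each property
sharp at small cost: 100 simulated pens for the HWI oracle equivalence,
S = 10^4 for the closed-form expectation check, S = 5000 for parameter
recovery, 500 simulation pairs for QAP null uniformity, 600 for the
group-bootstrap size check, and full enumeration (720 relabelings) for
the exhaustive QAP oracle at n = 6.

# Known limitations

* The two-group bootstrap is anticonservative at very small group sizes
  (see above); that is a property of its stated contract, not fixable
  without changing the estimator.
* The default strong-tie break-point is a reasoned approximation to
  undocumented break-point software; comparisons of strong-tie *counts*
  across studies should fix an explicit cut-off instead.
* Betweenness and closeness centrality are deliberately absent: on valued
  matrices they would require binarization, which discards exactly the
  information the HWI carries.
* Node-bootstrap standard errors at n = 8 rest on 8 resampled units;
  their own Monte-Carlo variability is visible between seeds, which is
  why every result records `B` and the seed used.
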