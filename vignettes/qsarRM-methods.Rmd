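---
title: "Methods: replacement-method linear QSAR modelling"
author: "qsarRM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replacement-method linear QSAR modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model and its assumptions

`qsarRM` builds quantitative structure–activity relationship (QSAR) models
of the form

$$\log_{10} IC_{50} \;=\; \beta_0 + \sum_{k=1}^{d} \beta_k x_k + \varepsilon,$$

where the $x_k$ are $d$ molecular descriptors chosen from a pool of $D \gg
d$ precomputed columns and $IC_{50}$ is the half-maximal inhibitory
concentration in nM. The assumptions are those of ordinary least squares
with an intercept: a linear mean structure in the selected descriptors,
homoscedastic errors on the log scale, and a training set whose chemical
space covers the compounds to be predicted (the applicability-domain
machinery exists precisely to police the last assumption). Everything
downstream is defined in terms of two training statistics:

* $R^2$, the coefficient of determination of the training fit, and
* $S = \sqrt{RSS/(n - d - 1)}$, the regression standard deviation.

The denominator counts the intercept among the fitted parameters. This
convention is fixed package-wide and is corroborated by the warning
leverage: $h^* = 3(d+1)/n$ evaluates to 0.1019 for $d = 8$, $n = 265$,
matching the value such models conventionally report, which pins the
parameter count at $d + 1$.

For validation and test subsets, $R^2$ is computed as the **squared
Pearson correlation** between observed and predicted activities, the
convention of the Golbraikh–Tropsha external-validation framework; $S$
keeps the $n - d - 1$ denominator with $n$ the subset size. The two $R^2$
definitions coincide on the training fit, which the test suite asserts.

# Pipeline stages and the parameters that matter

## Prefiltering

Raw descriptor pools contain columns that can never inform a regression:

| parameter | default | meaning |
|---|---|---|
| `nearConstFrac` | 0.95 | a column whose modal value frequency reaches this is dropped |
| `r2Threshold` (`collinearR2`) | 0.998 | pairwise squared Pearson correlation at which the later column is dropped |

Columns with *any* missing entry are removed first, then constants, then
near-constants; the collinear scan is greedy in file order, keeping the
earlier column — deterministic and order-stable. The defaults are design
choices: the near-constant cutoff is a conventional 95% modal frequency,
and 0.998 targets only effectively linearly dependent pairs, matching the
intent of removing "linearly dependent" duplicates without discarding
merely correlated chemistry. Both filters are idempotent and the surviving
pool provably satisfies its own admission rule (asserted by a full
pairwise scan in the tests). Univariate screening against the response is
deliberately **not** offered — filtering on the response would bias the
subsequent selection.

## Balanced subsets splitting (BSM)

The split must make train, validation and test sets structurally
representative of each other. Compounds are clustered by k-means
(Euclidean distance) and each cluster is spread across the three subsets:

| parameter | default | rationale |
|---|---|---|
| `fractions` | 0.5 / 0.25 / 0.25 | half for calibration, a quarter each for validation and test |
| `kClusters` | $\lceil N/20 \rceil$, min 2 | ~20 compounds per cluster; exposed because no canonical value exists |
| `standardize` | TRUE | Euclidean k-means is scale-sensitive; pools mix binary and continuous columns |
| `nInit` | 10 | k-means restarts, best inertia kept |

Global subset sizes follow **largest-remainder apportionment** with ties
favouring train, then val: for 530 compounds at 0.5/0.25/0.25 this yields
265/133/132. (A naive "floors, remainder to train" rule would give
266/132/132 instead; largest remainder is the rule consistent with the
published 265/133/132 convention, so it is the one implemented.) Within a
cluster, members are ordered by distance from the centroid and allocated
closest-first to train — making the "training set represents the others"
goal explicit — with per-cluster counts apportioned by the same rule, so
any cluster of three or more compounds feeds all three subsets. A final
deterministic adjustment pass moves boundary members (farthest from their
centroid) between subsets until the global targets are met exactly.

`balanceDiagnostics()` reports per-subset activity summaries and
Kolmogorov–Smirnov distances from the training set; it is diagnostic only
and takes no decision.

## Replacement-method search

The exact minimum of $S_{train}$ over all $\binom{D}{d}$ subsets is
unreachable for realistic $D$; the replacement method approaches it by
local moves guided by the *relative errors* of the coefficients:

1. start from a random full-rank $d$-subset;
2. rank positions by decreasing $|SE(\beta_k)/\beta_k|$;
3. for the worst-ranked position not yet visited this sweep, try every
   pool descriptor outside the subset as a replacement and keep the
   candidate minimising $S_{train}$ — only if it strictly improves on the
   incumbent; ties go to the lower pool index;
4. re-rank and continue; a full sweep over all $d$ positions with no
   accepted replacement terminates the start.

Design choices the algorithm sketch leaves open, fixed here for
reproducibility: `nStarts = 30` random starts by default; acceptance
requires strict improvement; candidates that would make the design
rank-deficient are skipped silently; `maxSweeps = 25` caps pathological
cycling (never observed in practice — convergence typically takes 2–5
sweeps). Each candidate scan is evaluated through one QR projection of the
fixed columns ($RSS_{cand} = RSS_{fixed} - (w^\top e)^2 / w^\top w$ with
$w$ the candidate's residual against the fixed design), which makes the
scan $O(nDd)$ per position instead of $D$ separate refits; correctness of
this fast path is pinned to the naive per-candidate refit by a regression
test. On 100 small instances (60 compounds, 25 descriptors, $d = 3$) the
search reproduces the exhaustive optimum in every instance and by
construction can never beat it.

`modelLadder()` runs the search for each size in `dRange` (default 1–9)
and selects the **smallest** $d$ whose validation $S$ is within
`selectTol = 0.01` of the ladder minimum — the parsimony rule of keeping
the model dimension as small as possible when validation quality is tied.
With `warmStart = TRUE` each size also starts from the previous optimum
extended by the best single addition, which enforces a monotone
non-increasing training-$S$ ladder.

## Validation battery

* **Leave-one-out** uses the hat-matrix identity $e_i/(1-h_i)$; the naive
  $n$-refit path is retained as an oracle and the two agree to $10^{-8}$
  on every fixture. $r^2_{loo}$ is the squared Pearson correlation of
  observed and LOO-predicted values; $s_{loo} = \sqrt{PRESS/(n-d-1)}$.
* **Leave-n%-out** (default 30%, i.e. 80 of 265 compounds per case)
  repeats random exclusions `l30Cases` times and **pools** all (observed,
  predicted) pairs before computing $r^2$ and $s$ — pooling, rather than
  per-case averaging, is the reading consistent with reporting a single
  statistic over hundreds of thousands of cases. Desk-scale default is
  5,000 cases (2,000 in the acceptance script); the statistics are means
  and stabilise far below published case counts, which users can restore
  by config.
* **Y-randomization** permutes the response, refits the same subset, and
  reports the **mean** $R^2$ and $S$ over permutations (default 2,000).
  The identity permutation is excluded. A valid model must show
  $S_{rand} > S_{train}$. The scan is vectorised through a single QR of
  the fixed design, so paper-scale permutation counts (100,000) remain
  cheap.
* **Golbraikh–Tropsha block**: $k$ is the slope of the through-origin
  regression of predicted on observed, $k'$ the converse; $R_0^2$ and
  $R_0'^2$ are the determination coefficients of those lines on their own
  axes; $r_m^2 = R^2(1 - \sqrt{R^2 - R_0^2})$ uses $R_0^2$ (the unprimed
  variant — the published criteria offer "or" alternatives, and the
  unprimed choice is the common one). Pass thresholds: ratio tests
  $< 0.1$, slopes in $[0.85, 1.15]$, $r_m^2 > 0.5$.
* **o3**: training compounds with $|residual| > 3 S_{train}$.

## Applicability domain

The leverage approach computes $h_i = x_i^\top (X^\top X)^{-1} x_i$ on the
intercept-augmented training design and flags $h_i \ge h^* = 3(d+1)/n$.
The standardization approach computes per-descriptor **absolute**
standardized deviations $s_{ik}$ (the $\le 3$ comparisons are only
meaningful on magnitudes); a compound with $\max_k s_{ik} \le 3$ is
inside; otherwise, when $\min_k s_{ik} < 3$, the fallback
$s_{new} = \langle s_i \rangle + 1.28\,\sigma_{s_i} \le 3$ decides, with
$\sigma_{s_i}$ the **sample** SD ($d-1$ denominator) of the $d$ values —
a choice exposed in the documentation since either convention is
defensible; 1.28 is the 90th percentile of the standard normal, taken as
given. On in-range synthetic queries the two criteria agree on well over
90% of compounds, mirroring how the two approaches approximately coincide
in practice. `williamsTable()` emits the exact data of a Williams plot
(leverage vs standardized residual, per subset, with both flags).

## Classification

Predictions are thresholded at 1000 nM **in log space** (a compound at
exactly 1000 nM is active; applying the threshold on the log scale avoids
re-exponentiation error), and scored with accuracy (%), sensitivity,
specificity and MCC. A zero factor in the MCC denominator yields MCC = 0,
the standard convention. Note the symmetry facts: relabelling the
positive class on both sides exchanges sensitivity and specificity but
leaves MCC unchanged; inverting only the predicted classes negates MCC.

# The synthetic-data generator

`generateSynthetic()` emulates the statistical structure of a curated
kinase-inhibitor descriptor table; its defaults are the study conditions
of the rest of the package:

| parameter | default | emulates |
|---|---|---|
| `nCompounds` | 530 | a curated ChEMBL-scale inhibitor set |
| `nDescriptors` | 2000 | a post-filter pool large enough to exercise the search while staying desk-tractable (configurable to $10^4$) |
| `nSignal`, `noiseSd` | 8, 0.8 | an 8-descriptor model with ~0.8 log units of residual noise |
| `fracBinary` | 0.6 | the share of fingerprint-type columns in mixed pools |
| `fracConstant`, `fracNearConstant`, `fracMissingCols` | 0.02 / 0.02 / 0.01 | uninformative columns as emitted by real descriptor software |
| `collinearBlockCount`, `collinearBlockSize` | 10, 3 | exact affine duplicates across descriptor families |
| `activityRange` | $(\log_{10} 0.8,\ \log_{10} 145000)$ | activities spanning about 5.3 log units |

Signal columns are standard normal; raw coefficients are drawn uniformly
in $\pm[0.3, 3]$ (magnitudes of the order published linear QSAR equations
exhibit). Near-constant means modal frequency above 95% — a concrete,
testable definition. Decoys are i.i.d. standard normal or Bernoulli with
per-column prevalence uniform in [0.1, 0.5]; collinear blocks are exact
affine copies of a fresh parent, so the duplicated pair has $|r| = 1$
exactly. Identical seeds give bit-identical output, and the generator
restores the caller's RNG state.

**Range mapping and its consequence.** With unit-variance signal columns
and coefficients up to 3, the clean activity of an 8-descriptor model
would span 25–30 log units; real IC50 data span about 5. The generator
therefore affinely maps the clean activity into `activityRange` whenever
it would overflow, and records the *effective* (post-map) coefficients as
the planted truth — the planted model stays exactly linear, so noiseless
fits still give $R^2 = 1$, $S = 0$. The flip side is a genuine property
of compressed-range data, not of the search: the mapping caps the total
clean-signal SD near 1 log unit, so when the raw coefficient magnitudes
spread 10:1, the weakest one or two planted descriptors carry effective
$t$-statistics of 2–3 at $n = 265$ and noise 0.8 — below the noise floor
of the best of ~2000 decoys. Full recovery of all planted descriptors
under paper-scale geometry is therefore *not* statistically identifiable;
the recovery tests and the acceptance report measure exactly how much is
recoverable, and the dedicated search-quality check (against the
exhaustive oracle, where identifiability is not confounded) shows the
search itself is near-exact. Tests that target *selection logic* rather
than attenuation use a wider activity range so every planted coefficient
stays detectable; this is stated in the fixtures.

What the generator does **not** emulate: descriptor semantics (no SMILES,
no chemistry), correlated-but-not-collinear descriptor families,
activity-dependent heteroscedasticity, assay noise structure, or
activity cliffs. Passing tests therefore demonstrate the statistical
machinery, not chemical validity on real data.

# Numerical choices and degenerate inputs

* All least-squares solves go through QR (never normal equations);
  rank-deficient designs are rejected naming the offending columns.
* Coefficient SEs honour QR pivoting; leverages come from $Q$ row norms.
* The candidate scan skips replacements whose residual norm against the
  fixed design falls below $10^{-10}$ of the column norm (numerical rank
  deficiency).
* Strict-improvement acceptance uses a $1-10^{-12}$ relative guard so
  floating-point ties cannot cycle.
* $S_{train} = 0$ (perfect fit): the o3 count is 0 by definition and
  Williams standardized residuals of exactly-zero residuals are reported
  as 0.
* Zero-variance columns in the standardization AD are excluded with a
  warning; zero-variance subsets flag $r^2$ as undefined rather than
  returning a number.
* Delimiters are auto-detected among comma/tab/semicolon and overridable;
  write/read round trips are exact for finite values (17 significant
  digits).
* The master pipeline seed derives fixed per-stage sub-seeds (all below
  $2^{31}$), so a run is reproducible end to end and byte-identical
  across repeats.

# Problem sizes used by the test suite

The suite favours many medium fixtures over few giant ones: search-oracle
checks use 60-compound, 25-descriptor instances where the exhaustive
optimum is computable; recovery checks run 20 seeds at 265 compounds and
a 2000-descriptor pool; cross-validation and Y-randomization checks use
hundreds to a few thousand cases, since the reported statistics are means
that stabilise quickly. The acceptance script runs one full pipeline at
530 compounds and a 2000-descriptor pool. These sizes are the package's
own choices for a reproducible desk-scale battery; every count is a
config knob and can be raised to published scales.

# Known limitations

* The S and $R^2$ conventions for validation/test subsets (Pearson$^2$;
  $n - d - 1$ denominator) are one defensible reading of common practice;
  packages differing on either convention will report slightly different
  Sval/Stest for identical predictions.
* The collinearity threshold that reproduces any particular published
  pool size cannot be recovered without the original descriptor files;
  0.998 is a default, not a claim.
* k-means splitting depends on the clustered feature space (the full
  prefiltered pool here) and on k; both are exposed as configuration.
* The replacement search is a local heuristic: optimality is demonstrated
  statistically on small instances, not guaranteed.
* Descriptor computation itself (PaDEL, Mold2, QuBiLs-MAS, file-format
  conversion) is out of scope; the package ingests numeric tables.
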