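---
title: "Fuzzy FMEA risk prioritization with TRIZ solution mapping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy FMEA risk prioritization with TRIZ solution mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmeatriz)
```

## The problem this package addresses

Service processes in combined medical and elderly care (CMEC) institutions
fail in ways that are hard to score objectively: panels of managers and
front-line staff rate each candidate failure mode on coarse Likert scales,
and the ratings carry linguistic vagueness that a plain arithmetic mean
flattens. `fmeatriz` implements a three-phase workflow around that problem:

1. **Service process analysis.** A service blueprint — a laned, acyclic
   action graph separating customer actions, front-stage staff actions and
   back-stage staff actions by the lines of interaction and visibility —
   carries annotations tying failure modes to the process steps where they
   occur.
2. **Service failure diagnosis.** A multi-rater panel scores each failure
   mode on severity (S), occurrence (O) and detectability (D); the scores
   are fuzzified, aggregated, defuzzified and multiplied into a fuzzy risk
   priority number (FRPN) that ranks the failures.
3. **Solution generation.** The causes of the top-ranked failures are mapped
   through service-quality determinants to TRIZ improving parameters,
   crossed with the worsening parameters in a contradiction matrix, and the
   resulting inventive principles are screened by an expert roster.

## The fuzzy scoring model

### Linguistic scale

Each 1–5 Likert score maps to a triangular fuzzy number (TFN)
$(q, o, p)$ with $0 \le q \le o \le p \le 1$: membership rises linearly
from $q$ to 1 at the mode $o$ and falls to 0 at $p$. The default scale is

```{r}
default_scale()
```

The detectability factor keeps its questionnaire orientation — a higher
score means the failure is detected only at or after occurrence, i.e.
worse — and the package never re-orients it. The scale is configurable
(`read_scale()`), but a replacement must keep five levels with scores
1..5 and TFNs non-decreasing in the score; that monotonicity is what makes
the aggregation and ranking monotone in any single rater's score.

### Aggregation

With $n$ raters, rater $t$'s TFN for factor $j$ of failure $i$ being
$(q_{tij}, o_{tij}, p_{tij})$, the panel aggregate is the component-wise
arithmetic mean

$$Q_{ij} = \tfrac1n \sum_t q_{tij},\qquad
  O_{ij} = \tfrac1n \sum_t o_{tij},\qquad
  P_{ij} = \tfrac1n \sum_t p_{tij}.$$

This is permutation-invariant, idempotent on constant panels, and monotone:
raising any single rater's score can only raise (never lower) each
component of the aggregate, because the scale TFNs are component-wise
non-decreasing in the score.

### Defuzzification: centroid vs trapezoidal

Two closed forms collapse the aggregate $(Q, O, P)$ to a crisp value in
$[Q, P]$:

* **centroid** (default): $X = (Q + O + P)/3$;
* **trapezoidal** (`trapezoidal_eq4`): $X = (Q + 2O + P)/4$, the
  trapezoidal-fuzzy-number formula applied to the degenerate trapezoid
  $(Q, O, O, P)$.

They coincide exactly on symmetric TFNs ($P - O = O - Q$), where both
return the mode $O$. On asymmetric aggregates they differ slightly, and the
difference is observable against the bundled case study's published
worksheet: the centroid reproduces **every** published defuzzified factor
value at 3 dp (top severity row: $(15 + 23.75 + 31.5)/(3 \times 35) =
0.6690 \to 0.669$), while the trapezoidal form gives $0.6714 \to 0.671$ on
that row. The package therefore defaults to the centroid, keeps the
trapezoidal form available for users who want the quadruple-based
convention, and emits a notice whenever the latter is chosen
(`options(fmeatriz.strict = TRUE)` or the CLI `--strict` flag promotes the
notice to an error, forcing an explicit method choice in regulated use).

### FRPN and ranking

Per failure, the FRPN is the product of the three defuzzified factors,
$\mathrm{FRPN} = S \times O \times D \in [0, 1]$; the traditional crisp RPN
is computed alongside as the product of the three per-factor raw-score
means, in $[1, 125]$. Ranking is by descending key with ties broken by
ascending failure id — deterministic, and the ranks always form a
permutation of $1..N$. Missing cells are a hard error, never imputed:
partial panels must be subset explicitly.

Reported values are rounded **half-up** (3 dp for risk values, 2 dp for
percentages) at the reporting layer only; all internal computation is at
full precision. Half-up is implemented with a $10^{-9}$ guard against
binary representation of decimal inputs, which is safe for values of the
magnitudes that occur here.

### Expert vote percentages

When a panel of experts each endorses one of the candidate prioritization
methods, the tally is reported as percentages that sum to exactly 100: each
option's share is truncated at 2 dp and the truncation residue is credited
to the winning option, so the winner's share is the complement of the
others (10 of 13 gives 76.93 / 23.07). A plain independent half-up
convention (76.92 / 23.08) is available via `convention = "half_up"`. The
residual-to-winner convention is the default because it matches the
reporting style of the bundled case worksheet.

## The TRIZ stage

Causes carry determinant tags; the determinant map sends each determinant
to one of the 39 classical TRIZ engineering parameters. The bundled case
map has five entries (number of nursing staff → 26 amount of substance;
service adaptability → 35 adaptability or versatility; service capacity →
26; healthcare workers' attitude → 17 temperature; service delivery time →
9 speed) and is user-extensible by config; no invented determinants are
bundled. A cause without a tag, or with a tag absent from the map, is an
error naming the cause — silent drops would corrupt the provenance chain.

The bundled contradiction matrix ships exactly the eight cells the case
study exercises (improving {9, 17, 26, 35} × worsening {22 loss of energy,
36 system complexity}). We deliberately do not bundle a full 39×39 matrix:
published transcriptions of the classical matrix vary cell by cell, and
shipping ~1,500 unverifiable entries would lend false authority to data the
package cannot vouch for. The loader accepts any user-supplied matrix
(JSON/CSV of improving/worsening/principles triples), and
`validate_matrix_assets()` enforces the eight authoritative cells over any
conflicting upstream source, plus the 39/40 registry sizes.

`suggest_principles()` pools the improving parameters across the supplied
failures by default (`mode = "pooled"`), mirroring how the case study
queried the matrix once for its top three failures; `mode = "per_failure"`
keeps the same raw union but records cells failure by failure. Screening is
always an explicit roster intersection — an expert decision the package
records but never automates.

## The blueprint model

Blueprints are stored, not inferred: the scenario tag (mild vs severe
illness) is data, and the mild/severe boundary carries no logic. Validation
checks referential integrity, lane membership, acyclicity (Kahn's
algorithm) and the line-of-interaction rule: any edge touching the customer
lane must have its other endpoint in the front stage. The bundled CMEC
fixtures are synthetic lane-level reconstructions — faithful at the level
of lanes, roles and failure-point placement (F4 annotated only in the
mild-illness scenario, F5 only in the severe one), but the exact arrow
topology of the original diagrams is not recoverable from text, so the
fixtures claim structural fidelity only at that level.

## The panel simulator and reverse fitter

The study's raw questionnaires are unpublished, so the package makes the
pipeline testable from the published summary tables in two ways.

**Forward simulation** (`simulate_panel()`): one categorical distribution
over scores 1..5 per (failure, factor) cell, a single Mersenne–Twister
stream seeded from the config, draws restored-state-local so no global RNG
state leaks. Identical config ⇒ bit-identical panel. Replicate $r$ of
`rank_stability()` uses seed $s + r - 1$, keeping the whole resampling
analysis reproducible. The simulator emulates independent raters with a
common per-cell distribution; it does **not** model rater covariance,
systematic leniency/severity bias, or within-rater correlation across
factors — so passing tests show pipeline correctness under idealised
panels, not robustness to those real-data features.

**Reverse fitting** (`fit_counts_to_fuzzy_mean()`): given a published
component-wise mean, enumerate all compositions of $n$ into five parts
(82,251 for $n = 35$ — small enough for exact enumeration, no heuristic
search) and return the first composition in lexicographic order whose
fuzzified means match within 0.0005 per component. The tolerance is chosen
because published 3-dp means are rounded values: rounding perturbs each
component by at most 0.0005. Attainable component sums are multiples of
$1/(4n)$, so the tolerance window pins the component sums uniquely;
several compositions can share those sums (eight do for the case study's
top severity cell), but they are mean-equivalent — and also share the raw
score mean, since the admissible moves between them leave the score total
unchanged — so every downstream quantity is invariant to the lexicographic
choice. An unattainable target (including triples violating the TFN
ordering) returns `NULL` rather than throwing: infeasibility is an answer,
not a failure.

The 18-cell case fixture built this way reproduces the published
defuzzified factor tables and all six published FRPNs exactly at 3 dp, and
the published prioritization F1 → 1, F6 → 2, F2 → 3, F4 → 4, F3 → 5,
F5 → 6. Recomputing the defuzzified values from the *printed* 3-dp means
instead of the reconstructed panel agrees within ±0.001 (one row lands on
0.609 vs the printed 0.610 — pure rounding noise, since the full-precision
value is $64/105 = 0.6095$).

## Known limitations

* **FRPN and traditional RPN are not order-equivalent**, even on unanimous
  panels. Both are products of per-factor transforms that are individually
  increasing in the score, but a product of increasing transforms is not
  rank-preserving on products: unanimous score triples $(1,5,5)$ and
  $(2,3,4)$ order as $25 > 24$ on the traditional key yet
  $121/1728 < 3/32$ on the FRPN key. Exhaustive enumeration of all $5^3$
  unanimous triples finds 108 of 7,750 pairs discordant. Agreement *is*
  guaranteed on componentwise-ordered (comonotone) score triples, and the
  test suite checks exactly that weaker property; observed agreement on
  real worksheets (Kendall $\tau = 13/15$ on the case study's published
  rankings) is an empirical fact about those data, not a theorem.
* The traditional RPN of a panel is computed as the product of per-factor
  raw-score means — the standard crisp-FMEA panel reading. Published
  traditional RPN values for the case study are not reproducible from the
  published summary tables (the raw questionnaires are unavailable), so
  only the comparison machinery, not those numbers, is validated.
* The bundled case panel is a reconstruction that is faithful to the
  published cell means; the study's true per-cell count vectors are
  unknowable from rounded means.

## Problem sizes used by the test suite

Exhaustive pieces run at their natural size (82,251 compositions per fitted
cell; all 125 unanimous score triples). Stochastic pieces use 35-rater
panels, 100–200 resampling replicates and fixed seeds — sizes at which the
empirical checks (e.g. a well-separated failure taking rank 1 in ≥ 95% of
replicates) were verified stable before being frozen into tests.
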