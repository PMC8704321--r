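---
title: "Ternary activity relations: completeness and interval-valued polypharmacology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ternary activity relations: completeness and interval-valued polypharmacology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ternact)
```

## Why three states

Thresholded ligand–target (LT) datasets are usually handled with two-state
logic: a pair is active (1) or inactive (0). But in public datasets most
pairs have simply never been measured, and classifying them as inactive is a
modelling decision with consequences — a fraction of them would certainly be
active, and because the unmeasured pairs are numerous, even a small active
fraction among them changes activity counts materially. `ternact` therefore
assigns every cell of the `n × m` grid exactly one of three states: active,
inactive, or **null** (unmeasured). This is a total ternary relation; the
three per-state indicator matrices partition the grid cell-wise, which the
constructor enforces and the test suite re-checks as an invariant.

The relation is stored as an integer code matrix rather than as explicit
(ligand, target, state) triples over the three-dimensional reference set:
the two representations are information-equivalent (the projections are
faithful), and the matrix form makes every operation a vectorized mask. The
equivalence is itself tested against a naive triple-enumeration
implementation on small random relations.

Absence of data *is* the null state: any grid cell not mentioned when
building a relation becomes null, and there is deliberately no
"implicitly inactive" construction mode. Duplicate (ligand, target) rows
are a hard error at construction; merging conflicting measurements is the
thresholding layer's job (below), so that no silent precedence rule can
fabricate certainty.

## Data completeness

Global data completeness (GDC) is the fraction of pairs with known status.
Its local analogues restrict the fraction to one ligand's row (`LDC(l)`) or
one target's column (`LDC(t)`). The means of the two local families both
equal the GDC — an algebraic identity, not an approximation — and
`completeness()` verifies it at `1e-12` relative tolerance on every call,
whatever the missingness structure (uniform or block-wise "islands of
data").

Two reporting conventions are fixed here because the choice is genuinely
open: the median of an even number of LDC values is the midpoint of the two
central values, and the LDC distribution is emitted as an exact empirical
step CDF over the observed values, with no binning or interpolation, so the
numbers behind a plot are reproducible independently of plotting choices.

`validate_summary_counts()` checks externally published summary rows (grid
dimensions, class counts, totals) for internal consistency. It never
reconciles: a row whose class counts do not sum to its printed total is
reported as inconsistent, with the discrepancy spelled out, while the GDC is
still computed from the known-pair counts over the true `n·m` grid. (The
reference kinase-panel summary used in the acceptance tests is such a row:
its three class counts oversum the printed total by 2.)

## Simple polypharmacology as an interval

For ligand `l` with profile sets `S₊(l)`, `S₋(l)`, `S∅(l)`:

* `Pmin(l) = |S₊(l)|` — all null pairs assumed inactive;
* `Pmax(l) = |S₊(l)| + |S∅(l)|` — all assumed active;
* the true polypharmacology lies in `[Pmin, Pmax]`, and the interval width
  `ΔEmax(l) = |S∅(l)|` shrinks by 1 for every new measurement of this
  ligand, active *or* inactive.

The urn-model rate `p̂(l) = |S₊(l)|/(|S₊(l)|+|S₋(l)|)` estimates the
probability that a null pair is active, giving the expectation-valued upper
bound `P̃max(l) = |S₊(l)| + p̂(l)·|S∅(l)|` and expected error
`ΔẼ(l) = p̂(l)·|S∅(l)|`. These are kept real-valued throughout — they are
expectations, and rounding them to integers would silently re-introduce a
point-estimate reading of an interval method.

**Zero-denominator policy.** A ligand with no measured pairs has no
ligand-specific rate. The default policy substitutes the dataset-wide
active fraction among known pairs, always flagged as `global-fallback` in
the output; a `strict` mode emits `NA` instead. The fallback is the most
defensible single number available within the dataset, but it ignores
between-ligand heterogeneity, which is why it is flagged rather than
silent.

**Confidence intervals.** Modelling the measured pairs as Bernoulli trials,
the Jeffreys interval — the central `α/2`, `1−α/2` quantiles of the
Beta(k+½, n−k+½) posterior, with endpoints pinned to 0 when `k = 0` and 1
when `k = n` — gives an interval for `p̂`, which is mapped affinely through
`P̃max`: `ci = |S₊| + q·|S∅|`. For a ligand with no data the interval is
the whole unit interval, which maps to `[Pmin, Pmax]` — the honest answer.
`α` defaults to 0.05.

A consequence worth stating plainly: the affine interval quantifies
*estimation* uncertainty in the rate only. The realized number of active
null pairs also carries binomial *realization* noise (variance
`|S∅|·p(1−p)`), which the affine map does not include. So the interval
covers the conditional expectation `|S₊| + p·|S∅|` at very nearly the
nominal rate — `recovery_trial()` reports this as `ci_coverage_mean`, and
at the default study conditions it is ≈ 0.95 — but covers the realized
integer count at a lower rate (`ci_coverage_count`, ≈ 0.7 at those same
conditions, where the null set is large). Both coverages are computed and
reported; treating the interval as a prediction interval for the realized
count would require widening it by the binomial term and is deliberately
not what this construction does.

## Joint polypharmacology

For a pair `(l, l′)` the targets are cross-partitioned into the 3×3 table
of state combinations; the nine counts sum to `m`. Then
`Pmin(l,l′) = |S₊,₊|` and
`Pmax(l,l′) = |S₊,₊| + |S₊,∅| + |S∅,₊| + |S∅,∅|`, and
`Pmin(l,l′) ≤ min[Pmin(l), Pmin(l′)]` because intersections cannot exceed
either factor. Self-pairs are permitted and collapse to the simple
quantities; reports enumerate unordered pairs `l < l′` in reference order,
`n(n−1)/2` of them.

The probability-weighted upper bound needs three conditional
probabilities, estimable two ways:

* **joint mode** uses only the doubly measured targets, e.g.
  `Pr(∅+,∅+) = |S₊,₊| / (|S₊,₊|+|S₊,₋|+|S₋,₊|+|S₋,₋|)`. It reflects
  dependence between the two ligands' profiles but can run out of data
  (zero denominators fall back to the dataset-wide rate, flagged, or `NA`
  in strict mode);
* **independence mode** factorizes through the marginal rates,
  `Pr(∅+,∅+) = p̂(l)·p̂(l′)`, with the mixed terms using the partner
  ligand's marginal rate — the natural reading of the factorization, since
  under independence the already-known state of one ligand carries no
  information about the other.

An empty cell contributes nothing regardless of its probability, so an
undefined probability only blocks the estimate when its cell is populated.

**Joint confidence intervals.** No closed-form interval is attempted.
`joint_ci()` draws each underlying probability from its Jeffreys Beta
posterior (using the success/trial counts of the corresponding estimator),
evaluates the upper-bound expression per draw, and reports the central
empirical quantiles — a seeded Monte Carlo propagation, deterministic given
the seed, defaulting to 2000 draws (endpoint Monte Carlo error well under
the reporting precision for the cell counts involved; the convergence test
doubles the draws and checks stability). This construction is a design
choice of this package: it propagates the same estimation-only uncertainty
as the simple-polypharmacology interval, and inherits the same caveat about
realization noise. Because its cost scales with pairs × draws, per-pair CIs
are off by default in the all-pairs report and enabled with `ci = TRUE`.

## Thresholding protocol

Raw records are thresholded per measurement: a qualitative "not active"
annotation is inactive; a Kd or Ki strictly above 3 µM is inactive,
otherwise active; a pKd or pKi below 5.5 is inactive, otherwise active.
The boundary direction is fixed by reading "larger than" strictly, so a Kd
of exactly 3 µM is active, and the pK comparison mirrors it with ≥ 5.5
active. Note 3 µM corresponds to pK 5.52, not 5.50; the nominal 5.5 is kept
as its own threshold for pK-typed records rather than recomputed, so
mixed-type records for one pair can disagree in the 5.50–5.52 sliver — and
then resolve to null like any other conflict, which is the protocol's
stated behaviour for disagreement. Only Kd/Ki/pKd/pKi are thresholded;
other measure types (IC50 and the like) are rejected unless the caller maps
them explicitly, because mixing assay read-outs under one cutoff is a
modelling decision, not a parsing default. Aggregation beyond the conflict
rule (e.g. replicate averaging before conflict detection) is deliberately
not implemented.

Per-pair aggregation maps agreement to the agreed status and any
active/inactive disagreement to null; the output is sorted by (ligand,
target), so thresholding is idempotent and independent of record order.

## The synthetic generator

`synthetic_spec()`/`simulate_lt()` draw a *complete* truth — each pair of
ligand `l` active with probability `rate(l)`, else inactive, no nulls —
then mask cells independently; masked cells are null in the observed
relation. Defaults emulate the reference kinase panel: a 250 × 433 grid,
uniform observation probability 0.685 (its published global completeness),
and per-ligand rates drawn from Beta(1, 14.7), whose mean 0.0637 matches
the panel's dataset-wide active fraction among known pairs (4,729/74,148 ≈
0.0638) while giving the heterogeneous per-ligand active fractions such
panels show. Block missingness ("islands of data") and a publication-bias
multiplier (actives more likely observed) are available; under bias the
urn-model rate is optimistic and interval coverage is expected to degrade —
this is documented behaviour, demonstrated but not asserted as a quality of
the estimator.

What the generator does *not* emulate: correlation between structurally
similar ligands' profiles (no generative model for it is attempted), and
target-specific activity rates (the estimators condition only on ligands).
Passing recovery tests on this generator therefore shows correctness of the
bounds and calibration under MCAR heterogeneous-rate sampling — not
robustness to assay heterogeneity or reporting bias in real panels.

Two structural guarantees hold in every replicate, not just on average: the
true polypharmacology lies in `[Pmin, Pmax]`, and the true joint value lies
in the joint bounds — masking can only move known cells to null, never flip
a state. `recovery_trial()` checks these, plus the shrinkage of
`|p̂ − p_true|` with completeness and both CI coverage measures discussed
above.

## Sizes, determinism, degenerate inputs

* All randomized routines (`simulate_lt`, `joint_ci`, CLI subsampling) take
  an explicit seed and restore the caller's RNG state afterwards.
* Test-suite problem sizes: identity properties on 1,000 random relations
  up to 50 × 100; oracle equivalence on 500 random relations up to 6 × 6;
  estimator recovery on 200 replicates of a 5 × 433 panel at completeness
  0.685 and rate 0.1 (the reference panel's geometry, with a small ligand
  count per replicate since ligands are independent given the generator).
* Degenerate inputs: empty grids are constructible but completeness and
  fractions reject them; all-null relations give `Pmin = 0`,
  `Pmax = m`, undefined rates (fallback policy applies), and the no-data CI
  `[Pmin, Pmax]`; fully measured relations collapse every interval to the
  point `Pmin = Pmax`.
* Matrix serialization uses `1`/`0`/`.` cell tokens — the dot keeps nulls
  visually distinct from inactives, which is the package's central
  distinction.

## Known limitations

* The affine CI is not a prediction interval for the realized count (see
  above); both coverage measures are reported so the distinction stays
  visible.
* The urn model assumes a ligand's measured targets are representative of
  its unmeasured ones; publication bias violates this in a direction that
  inflates `p̂`.
* Single-threshold partitioning only: no multi-threshold activity classes,
  no concentration-dependent analysis, and no profile-similarity measures.
* The joint-mode probability estimates need doubly measured targets and are
  noisy for sparsely co-measured pairs; the independence mode is the more
  stable default for reports.
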