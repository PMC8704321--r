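# ternact: ternary ligand–target relations, data completeness, and polypharmacology bounds

Public ligand–target (LT) bioactivity datasets are extremely sparse: for most
compound–target combinations no measurement of any kind exists. Treating
those unmeasured pairs as inactive — the default in most two-state analyses —
silently undercounts activity, and in particular undercounts
**polypharmacology**, the number of targets a compound is active against.

`ternact` is for cheminformaticians and chemogenomics analysts who work with
thresholded activity matrices (kinase panels, ChEMBL extracts, and the like)
and want the *unknown* pairs treated as a first-class third state. Every LT
pair carries exactly one of three states:

* **active** — measured activity at or better than the threshold,
* **inactive** — measured lack of activity (or an explicit "not active"
  annotation),
* **null** — never measured; *distinct from inactive*.

## The model

The dataset is a ternary relation: a total assignment of each cell of the
`n × m` ligand–target grid to one of the three states, so for every pair
exactly one of the indicator values `r₊(l,t)`, `r₋(l,t)`, `r∅(l,t)` is 1.
Projecting one ligand's row down to the target set yields its activity
profile: three disjoint sets `S₊(l)`, `S₋(l)`, `S∅(l)` that partition the
targets.

From these the package computes:

* **Data completeness.** Global data completeness
  `GDC = (#active + #inactive) / (n·m)` and its local analogues
  `LDC(l) = (|S₊(l)| + |S₋(l)|)/m` per ligand and `LDC(t)` per target, with
  exact empirical CDFs. The mean of the ligand LDCs, the mean of the target
  LDCs, and the GDC are algebraically identical — the package verifies this
  identity on every report.
* **Simple polypharmacology intervals.** `Pmin(l) = |S₊(l)|` (every null
  pair assumed inactive) and `Pmax(l) = |S₊(l)| + |S∅(l)|` (every null pair
  assumed active) bracket the true polypharmacology. An urn-model estimate
  of the probability that a null pair is active,
  `p̂(l) = |S₊(l)| / (|S₊(l)| + |S₋(l)|)`, tightens the upper bound to the
  expectation `P̃max(l) = |S₊(l)| + p̂(l)·|S∅(l)|`, and the Jeffreys
  Beta(k+½, n−k+½) interval on `p̂`, mapped through the same expression,
  gives a confidence interval at significance level α (default 0.05).
* **Joint polypharmacology over ligand pairs.** The targets are
  cross-partitioned by the two ligands' states into a 3×3 table;
  `Pmin(l,l′) = |S₊,₊|` and
  `Pmax(l,l′) = |S₊,₊| + |S₊,∅| + |S∅,₊| + |S∅,∅|` bound the number of
  shared active targets, with probability-weighted upper-bound estimates
  under either a joint (doubly measured targets) or an independence
  (product of marginal rates) model, and seeded Monte Carlo confidence
  intervals.
* **Thresholding.** Raw Kd/Ki measurements (molar units, 3 µM cutoff) and
  pKd/pKi values (cutoff 5.5) or qualitative "not active" annotations are
  converted to statuses; conflicting annotations for one pair resolve to
  null.
* **Synthetic data with ground truth** for estimator validation, emulating
  a sparse kinase panel (default 250 × 433 grid at 0.685 completeness,
  heterogeneous per-ligand activity rates, optional "islands of data" block
  missingness and publication bias).

## Worked example

The two-ligand, five-target dataset used throughout the documentation:
`l1` is active on `t1`,`t2` and inactive on `t3`; `l2` is active on
`t2`,`t4` and inactive on `t5`; the other four pairs are unmeasured.

```r
library(ternact)
rel <- toy_example_relation()
rel
#> Ternary ligand-target relation: 2 ligands x 5 targets
#>   active: 4  inactive: 2  null: 4
#>   global data completeness: 0.6000

polypharm(rel)
#> Simple polypharmacology estimates for 2 ligands (alpha = 0.05)
#>   ligand n_active n_inactive n_null p_min  p_hat    p_hat_source p_tilde_max
#> 1     l1        2          1      2     2 0.6667 ligand-specific       3.333
#> 2     l2        2          1      2     2 0.6667 ligand-specific       3.333
#>   ci_low ci_high p_max delta_e_max delta_e_tilde
#> 1  2.353   3.923     4           2         1.333
#> 2  2.353   3.923     4           2         1.333
```

Reading `l1`'s row: it is known active on 2 targets (`p_min`), could be
active on at most 4 (`p_max`, its 2 null targets included), and since 2 of
its 3 measured targets are active (`p_hat = 0.667`) the expected
polypharmacology is `2 + 0.667·2 ≈ 3.33` (`p_tilde_max`), with 95% CI
[2.35, 3.92] obtained by mapping the Jeffreys interval on `p_hat` through
the same formula.

```r
joint_polypharm(rel, ci = TRUE, seed = 42)
#> Joint polypharmacology estimates for 1 ligand pair (mode = independence, alpha = 0.05)
#>   id1 id2 n_pp n_pi n_p0 n_ip n_ii n_i0 n_0p n_0i n_00 p_min p_tilde_max_joint
#> 1  l1  l2    1    0    1    0    0    1    1    1    0     1                 3
#>   p_tilde_max_indep ci_low ci_high p_max delta_e_max delta_e_tilde
#> 1             2.333  1.596   2.787     3           2         1.333
```

The pair shares 1 known co-active target (`p_min`), at most 3 (`p_max`);
under the independence model the expected joint polypharmacology is
`1 + (2/3)·1 + (2/3)·1 + (4/9)·0 = 7/3 ≈ 2.33`.

## Command line

A thin wrapper `inst/scripts/ltpp` (installed under
`system.file("scripts", "ltpp", package = "ternact")`) drives the same
functions from a shell:

```sh
ltpp validate     --input status_triples.tsv
ltpp completeness --input status_triples.tsv --out-dir out/
ltpp polypharm    --input status_triples.tsv --alpha 0.05 --out-dir out/
ltpp joint        --input status_triples.tsv --ligand CHEMBL123 --seed 1 --out-dir out/
ltpp threshold    --input measurements.tsv --threshold 3e-6 --out-dir out/
ltpp simulate     --n-ligands 250 --n-targets 433 --seed 1 --out-dir out/
```

Identical config and seed produce byte-identical outputs.

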