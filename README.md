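# scansoc

Spatial position, dominance and affiliative network structure from
scan-sampling data.

`scansoc` is for behavioural ecologists analysing instantaneous
scan-sampling records of individually identified animals competing for a
monopolisable food patch. From three tabular inputs — per-scan positions on
an observation grid, an agonistic interaction log, and individual metadata
(sex, age, matriline) — it answers three questions about a social group:

1. **Does dominance explain spatial position?** Per-individual spatial
   frequencies near (`F10M`, and its square root `SRF10M`) and far
   (`F20M`, including out-of-sight scans) from the feeding-zone door are
   correlated with dominance scores using one-tailed permutation Pearson
   tests.
2. **Do affiliative subgroups explain it too?** A half-weight association
   index (HWI) network is built from 1-m proximities,
   `HWI = x / (x + y_AB + (y_A + y_B)/2)`,
   tested for nonrandom structure by permuting associations within each
   scan (CV of the indices as statistic), and partitioned into subgroups by
   Newman's leading-eigenvector modularity. Variance partitions with
   semipartial *r*² then split each spatial outcome between the dominance
   score (Df 1) and the subgroup block (Df = levels − 1).
3. **Who tolerates whom at the patch?** A 5-m co-occurrence HWI network at
   the door is regressed on dominance distance, kinship, age distance and
   sex similarity by MRQAP with double-semi-partialing, and compared
   (Mantel test, binary overlap percentage) with the affiliative network
   recomputed without feeding-zone associations.

Dominance itself comes from dyadic agonistic records: chance-corrected
dyadic indices `D_ij = P_ij − (P_ij − 0.5)/(n_ij + 1)`, modified David's
scores `DS = w + w₂ − l − l₂` (they always sum to zero), and de Vries'
linearity `h' = h + 6u/(N³ − N)` with a randomisation test over unknown
relationships.

Because the underlying field data are not released, the package ships a
first-class synthetic-data generator (`simulate_study()`) that emulates the
study design — 39 adults, 26 scans/day over two daily observation blocks,
afternoon-biased attendance, a door whose attraction grows with latent
dominance, matriline-assorted subgroups, and logistic agonistic outcomes —
so the whole pipeline is testable end to end, including parameter-recovery
checks against the generator's latent truth.

## Worked example

```r
library(scansoc)

study  <- simulate_study(sim_config(n_days = 8), seed = 2012)
cfg    <- pipeline_config(n_perm = 999, n_randomizations = 1000,
                          assoc_n_perm = 199, seed = 2012)
report <- run_pipeline(study$scans, study$agonistic, study$individuals, cfg)
report
```

```
== Scan-sampling pipeline report ==
39 individuals (0 juveniles excluded), 208 scans
agonistic records discarded: 35 polyadic, 53 unclear

Dominance: h' = 0.355, p = 0.000999; 0 individuals without MDS
Association: CV = 1.870, p = 0.005 (199 perms)
Subgroups: 4, Q = 0.507

H1: SRF10M ~ MDS r = 0.40393, p = 0.005
    F20M   ~ MDS r = -0.26415, p = 0.06

H2 (semipartial r^2):
  SRF10M: MDS = 0.1269 (p = 0.029), Subgroups = 0.3269 (p = 0.003), adj R^2 = 0.4301
  F20M: MDS = 0.0297 (p = 0.315), Subgroups = 0.1330 (p = 0.172), adj R^2 = 0.1090

H3 (MRQAP on co-occurrence HWI):
     term partial_r p.value
 mds_dist -0.030841   0.577
  kinship  0.137534   0.012
 age_dist  0.072575   0.083
 sex_same  0.003921   0.916
  Mantel co-occurrence ~ zone-excluded affiliative: r = -0.0327, p = 0.722
  41.5% of co-occurrence dyads also associate elsewhere
```

Reading this: the hierarchy is significantly more linear than chance
(`h'` with its randomisation p), the 1-m association indices vary more
across dyads than the within-scan permutation null allows (preferred
companionships exist), and modularity finds a useful subdivision
(`Q > 0.3`). Higher-scoring animals are seen closer to the door (positive
`SRF10M` correlation), and subgroup membership explains more of the
spatial variance than the dominance score does (semipartial 0.33 vs 0.13
for `SRF10M`). In this short 8-day simulation the far-distance and H3
contrasts are noisier — with the full 24-day default they sharpen.

Every result object is a tidy citizen:

```r
head(tidy(report$dominance), 3)
#> # A tibble: 3 × 2
#>   individual   MDS
#>   <chr>      <dbl>
#> 1 ind04       161.
#> 2 ind34       147.
#> 3 ind30       144.

glance(report$communities)
#> # A tibble: 1 × 5
#>   n_subgroups     Q useful_subdivision min_size max_size
#>         <int> <dbl> <lgl>                 <int>    <int>
#> 1           4 0.507 TRUE                      8       14
```

plus `autoplot()` methods for dominance profiles, HWI heatmaps, subgroup
certainty and permutation nulls, and readers/writers
(`read_scan_table()`, `write_matrix_csv()`, …) for all on-disk formats.

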