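# pasdrift

Pathway Activation Strength (PAS) scoring and signalome drift analysis for
case-versus-reference expression studies of aging, replicative senescence
and progeria (HGPS) fibroblasts.

Expression profiling of aging cells shows coordinated shifts in signaling
pathway activation — "pathway activation drift" — with increasing culture
passage or donor age, and progeria fibroblasts resemble aged ones at this
level. Testing that resemblance needs two uncommon ingredients: a
*per-sample* pathway score computed against a within-dataset reference
group (so that multi-platform datasets can be pooled), and *equivalence
tests*, which can positively declare two or more groups similar instead of
merely failing to find a difference. `pasdrift` implements both, plus the
drift summaries built on them and a synthetic study generator with known
ground truth for end-to-end validation.

## The model

For a case sample scored against its dataset's reference group, each
pathway's activation strength is

```
PAS_p = sum over member genes n of  ARR_n * BTIF_n * lg(CNR_n)
```

* `CNR_n` — case-to-normal ratio: the gene's expression in the case sample
  over its mean in the reference samples (linear scale);
* `BTIF_n` — 0/1 flag from the group-level differential test (pooled
  Student's t on log2 values, BH-FDR `q < 0.05`, fold-change gate
  `max(FC, 1/FC) >= 1.5`), or 1 for every gene in unfiltered mode;
* `ARR_n` — the gene's activator/repressor role coefficient in the pathway
  (+1 activator, +0.5 rather activator, 0 unknown, -0.5 rather repressor,
  -1 repressor).

Positive PAS = up-regulated pathway. Group similarity is then declared by
standardized-margin equivalence tests: pairwise via a pooled t statistic
compared against `sqrt` of the alpha-quantile of the noncentral
`F(1, nA+nB-2)` distribution at `lambda = eps^2 * nA*nB/(nA+nB)`, and for
3–4 groups via the one-way ANOVA F statistic against the alpha-quantile of
noncentral `F(k-1, N-k)` at `lambda = N * eps^2`, with margins
`eps = 0.74` (pairs) and `0.74/sqrt(2)` (3–4 groups) at `alpha = 0.05`.
Each pathway is assigned to the Venn region of the largest group subset
declared equivalent.

## Worked example

```r
library(pasdrift)

# a 4-group study (Young/Middle/Old/HGPS fibroblasts, 15/25/16/26 samples
# over 7 pseudo-datasets) with planted pathway regulation
study <- make_paper_like_study("aging4", seed = 1)

pas <- score_study(study)          # per-sample PAS, filtered mode
pas
#> pas_matrix: 65 pathways x 82 samples (mode: filtered)
#>
#>   HGPS Middle    Old  Young
#>     26     25     16     15

venn <- venn_similarity(pas, group_order = c("Young", "Middle", "Old", "HGPS"))
venn
#> venn_summary over groups: Young, Middle, Old, HGPS
#>   Middle+HGPS: 9 pathway(s)
#>   Middle+Old+HGPS: 8 pathway(s)
#>   Young+Middle+Old+HGPS: 5 pathway(s)
#>   Middle+Old: 2 pathway(s)
#>   unassigned: 41

near_zero_pathways(pas, venn)
#> [1] "pw26" "pw27" "pw28" "pw29" "pw30"

cm <- correlation_cluster(pas)
c(r_HGPS_Old   = mean_between_group_cor(cm, "HGPS", "Old"),
  r_HGPS_Young = mean_between_group_cor(cm, "HGPS", "Young"))
#>   r_HGPS_Old r_HGPS_Young
#>        0.704        0.030
```

Reading the output: this seed planted 13 pathways equally activated in
Middle/Old/HGPS, 12 in Middle/HGPS, and 5 null pathways. The five nulls are
recovered exactly (4-way equivalent and flagged near-zero, `pw26`–`pw30`).
The region counts come back *lower* than planted (8 and 9 here): at these
group sizes the equivalence tests declare even identical distributions
similar only part of the time, and the finite within-dataset reference
groups add dataset-level PAS offsets — both effects are quantified in the
methods vignette. The correlation summary shows the drift signature: HGPS
profiles correlate strongly with Old (r ≈ 0.70) and not with Young
(r ≈ 0.03).

The full workflow (simulate → score → equivalence/Venn → drift tables)
lives in `analysis/01_simulate.R` … `analysis/04_drift.R`; each step writes
its tables under `results/` and prints what it found.

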