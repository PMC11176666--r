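# stressrank

Social rank shapes how group-living primates weather chronic stress: who
rises in cortisol, whose oxytocin keeps climbing during recovery, who stops
being attacked and who starts being groomed. `stressrank` is an R package
for analysing exactly this kind of study — small stable colonies, directed
behavior logs summed over six-day observation windows before and after a
stressor, and short longitudinal physiology panels — and for simulating
such studies so the whole analysis chain can be validated without animal
data.

It is written for behavioral ecologists and biostatisticians working with
dyadic interaction data at colony scale (5–15 animals per group).

## What it computes

* **Dominance ranking.** Wins of *i* over *j* are aggression *i → j* plus
  submission *j → i*. Dyadic indices are either raw win proportions
  `P_ij = W_ij / n_ij` or the chance-corrected
  `D_ij = P_ij − (P_ij − 0.5)/(n_ij + 1)` (default). David's score
  `DS_i = w_i + w2_i − l_i − l2_i` sums first- and second-order win and
  loss terms and sums to zero per group. Per-group normalization
  `DS′_i = DS_i + |DS_min|`, `normDS_i = DS′_i / DS′_max` puts the top
  animal at 1 and the bottom at 0; `normDS > 0.5` is high-ranking (HR),
  `< 0.5` low-ranking (LR), exactly 0.5 is flagged `BOUNDARY`.
* **Longitudinal statistics.** Proportional change scores
  `Δ = (x_i − x_j)/x_j`; split-plot (two-way mixed) repeated-measures
  ANOVA with Mauchly's sphericity test, Greenhouse–Geisser correction and
  partial η²; Holm-adjusted paired time contrasts; a rank-collapsed
  correlation (rank within each colony, pool, Pearson on pooled ranks)
  that absorbs colony-level differences; first-order partial correlation.
* **Dyad analyses.** Ordered dyads typed LL/HL/LH/HH by the members'
  baseline classes; Zero/Low/High appearance strata with half-open
  thresholds (fixed or auto-balanced); baseline-vs-change correlations
  restricted to existing pairs.
* **Synthetic colonies.** A generator that plants a strict hierarchy in
  two colonies (7 + 6 females), simulates decided agonistic encounters,
  grooming and proximity with per-dyad rate heterogeneity, applies
  post-stress behavioral shifts, and draws rank-dependent physiology —
  fully reproducible from one seed with independent behavioral and
  physiological substreams.

## Worked example

Simulate a study, rank one colony from its baseline observation, and test
whether the cortisol response tracks rank:

```r
library(stressrank)

cfg   <- simulation_config(seed = 7)
paths <- generate_fixture_study(cfg, file.path(tempdir(), "demo"))

ev  <- read_event_log(paths[["events"]])
agg <- aggregate_interactions(ev[ev$group_id == "BJ", ], "AGG", "OBS1")
sub <- aggregate_interactions(ev[ev$group_id == "BJ", ], "SUB", "OBS1")
dominance_ranks(build_win_matrix(agg, sub))
#>   subject     DS normDS ordinal_rank class
#> 1    BJ-1  15.25  1.000            1    HR
#> 2    BJ-2  12.09  0.902            2    HR
#> 3    BJ-3   7.22  0.752            3    HR
#> 4    BJ-4  -1.94  0.470            4    LR
#> 5    BJ-5  -5.83  0.349            5    LR
#> 6    BJ-6  -9.64  0.232            6    LR
#> 7    BJ-7 -17.15  0.000            7    LR
```

The planted hierarchy (BJ-1 highest) is recovered exactly; `normDS` spans
[0, 1] and the 0.5 line splits the colony 3 HR / 4 LR. Now the hair
cortisol change from baseline (S1) to end of stress (S2), against
within-colony rank pooled across both colonies:

```r
pan  <- read_physio_panel(paths[["physiology"]])
hc   <- pan[pan$analyte == "HC", ]
wide <- reshape(hc[, c("subject_id", "timepoint", "value")],
                direction = "wide", idvar = "subject_id",
                timevar = "timepoint")
d_hc <- change_score(wide$value.S2, wide$value.S1)

ds   <- ds_table(ev)
base <- ds[ds$observation_id == "OBS1", ]
rk   <- ave(base$normDS, base$group_id, FUN = rank)
rank_collapse_correlation(rk[match(wide$subject_id, base$subject_id)], d_hc,
                          base$group_id[match(wide$subject_id, base$subject_id)])
#> RANK_COLLAPSED correlation: r = 0.7841, p = 0.001512, n = 13
```

Higher-ranked animals show the larger cortisol rise (the generator plants
a positive rank slope). The repeated-measures ANOVA of cortisol over the
three sample points by rank class:

```r
dat <- data.frame(unit = hc$subject_id, within = hc$timepoint,
                  value = hc$value)
dat$between <- base$class[match(dat$unit, base$subject_id)]
mixed_anova(dat, between = "between")
#> Mixed repeated-measures ANOVA (13 units, 3 within levels)
#> Mauchly W = 0.3169 (p = 0.003194); Greenhouse-Geisser epsilon = 0.5941 [correction applied]
#>          effect      SS df_num df_den        F          p partial_eta_sq       p_gg
#>          within 5700.77      2     22 168.1591 4.6740e-14        0.93860 3.7494e-09
#>         between  827.59      1     11  28.7384 2.2998e-04        0.72319 2.2998e-04
#>  within:between  174.04      2     22   5.1338 1.4798e-02        0.31820 3.6216e-02
```

Cortisol changes over time (within effect), differs by rank class
(between), and the two interact — with the Greenhouse–Geisser-corrected
p-values reported because Mauchly's test rejected sphericity.

The one-shot driver runs everything and writes `ds_table.tsv`,
`anova_table.tsv`, `posthoc.tsv`, `correlations.tsv`, `dyad_summary.tsv`
plus a JSON manifest:

```r
run_pipeline(pipeline_config(paths[["events"]], paths[["physiology"]],
                             out_dir = "analysis-out"))
```

or from a shell, `Rscript inst/scripts/colony-pipeline.R run-all
--events events.csv --physio physiology.csv --out analysis-out`.

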