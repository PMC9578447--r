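# micromed

Quantitative microbiome analysis for Mediterranean-diet (MED) lifestyle
intervention studies with paired (pre/post) stool sampling.

Short dietary-intervention cohorts pose two linked problems: adherence must
be measured at the cadence of the intervention (daily, not by recall
questionnaires), and compositional 16S profiles hide changes in microbial
*density* — a genus can rise in relative abundance while its absolute
population shrinks. `micromed` implements an analysis chain built around
those two ideas, for dietitians and microbiome analysts working with
genus-level amplicon tables, qPCR bacterial loads, and daily checklist
questionnaires.

## What it computes

**Daily MED adherence score (0–30).** Eleven checklist items, one point per
serving up to a cap: vegetables 0–5, fruits 0–3, distinct food colors 0–6
(red/green/yellow/orange/white/purple), olive-oil tablespoons 0–3,
nuts & seeds 0–1, legumes & soy 0–1, yogurt 0–1, whole grains 0–3, water
glasses 0–5, daily step goal 0–1, exercise 0–1. Per-subject change is the
intervention-window mean minus the baseline-window mean.

**Quantitative (absolute) profiling.** With per-sample bacterial load
`L_s` (µg bacterial DNA / mg stool, from qPCR directly or via a standard
curve `Ct = a + b·log10(DNA)`), absolute abundance is
`A_gs = R_gs · L_s` for relative abundance `R_gs`, so column sums equal the
loads.

**Paired delta matrices.** `Δ_gj = A_g(Tend, j) − A_g(T0, j)` per subject
`j`, with retention of genera whose delta is nonzero in ≥ 10 subjects *and*
exceeds 1 % (relative scale) in ≥ 1 subject; rare features (prevalence < 10
samples) are dropped before any correlation screen.

**Beta diversity from first principles.** Bray–Curtis dissimilarity
`D_ij = 1 − 2·Σ_g min(x_gi, x_gj) / (Σ_g x_gi + Σ_g x_gj)`; principal
coordinates via Gower double-centering (−½ J D² J) and eigendecomposition;
single-term PERMANOVA with the McArdle–Anderson trace identity and, for
paired designs, restricted permutations within subject blocks (the analogue
of `strata` in `vegan::adonis`).

**Association screens.** Spearman correlations (average ranks for ties,
t-approximation p-values), one Benjamini–Hochberg FDR family per screen
(q-values), OLS models with classical inference for lifestyle covariates,
and deterministic average-linkage ordering for correlation heatmaps.

**Synthetic cohort generator.** `generateCohort()` simulates the whole data
bundle — counts, loads, questionnaires, clinical metadata — with planted,
recorded effects (adherence-responsive genera, an inverse
adherence–calprotectin link, a steps effect, a sweets-driven eukaryal
taxon), so every stage of the pipeline can be validated against a known
truth.

## Worked example

```r
library(micromed)

ch <- generateCohort(cohortSpec(seed = 42))   # 20 subjects, T0 + Tend
tr <- cohortTruth(ch)
q  <- cohortQuestionnaires(ch)

mean(summarizeScores(q, tr$t0_window)$mean)    # 16.2
mean(summarizeScores(q, tr$tend_window)$mean)  # 22.6
ds <- deltaScore(q, tr$t0_window, tr$tend_window)

rel <- toRelative(cohortCounts(ch))
ab  <- toAbsolute(rel, cohortLoads(ch))
md  <- cohortMetadata(ch)

permanova(brayCurtis(rel), setNames(md$subject, md$sample_id),
          nPerm = 999, seed = 1, term = "subject")
#> PERMANOVA: subject  pseudo-F = 2.121  R2 = 0.668  p = 0.001 (999 perms)

ss <- setNames(md$subject, md$sample_id)
st <- setNames(md$timepoint, md$sample_id)
dAbs <- buildDelta(ab, ss, st)
kept <- featureIDs(deltaRetentionFilter(buildDelta(rel, ss, st)))
subj <- colnames(abundanceValues(dAbs))
head(correlationScreen(abundanceValues(dAbs)[kept, ],
                       data.frame(delta_med_score = ds[subj],
                                  row.names = subj)), 7)
#>   feature       covariate    rho        p       q  n
#> 1    g003 delta_med_score  0.761 0.000098 0.00220 20
#> 2    g004 delta_med_score  0.761 0.000098 0.00220 20
#> 3    g005 delta_med_score  0.728 0.000275 0.00413 20
#> 4    g001 delta_med_score  0.618 0.003681 0.04142 20
#> 5    g025 delta_med_score -0.583 0.006923 0.06230 20
#> 6    g095 delta_med_score -0.543 0.013387 0.10040 20
#> 7    g002 delta_med_score  0.462 0.040458 0.26008 20
```

Here subject identity explains 67 % of Bray–Curtis variance (p = 0.001),
and the delta screen ranks four of the five planted adherence-responsive
genera (`g001`–`g005`, see `cohortTruth(ch)`) at q < 0.05 — the fifth
(`g002`) lands just past the q < 0.2 reporting cut-off in this particular
realization, which is what an 80 %–90 % average recovery rate looks like
seed by seed.

The same chain runs end-to-end from files:

```sh
Rscript inst/exec/medpipe simulate --seed 3 --subjects 20 --out cohort
Rscript inst/exec/medpipe run --config cfg.yaml --out results
# [medpipe] run: results -> results (3.0s)
# [medpipe] PERMANOVA subject R2 = 0.724
```

`runPipeline()` writes adherence scores, the Bray–Curtis matrix, PCoA
coordinates, the PERMANOVA table, three correlation screens
(post-intervention, delta, PCoA axes), OLS fits for the steps association,
and a JSON manifest carrying the config hash and seed.

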