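# cpmcluster

Phenotyping of conditioned pain modulation (CPM) and temporal summation
of pain (TSP) responses from raw quantitative-sensory-testing sessions.

Chronic-pain cohorts are heterogeneous: some patients inhibit a tonic
painful stimulus after a conditioning stimulus ("pain inhibits pain"),
others facilitate it, and the two endogenous systems — descending
inhibition and spinal facilitation — vary independently. This package
implements, as a tested and reusable pipeline, the analysis used to
phenotype pediatric chronic-pain patients on both systems at once:

1. **Scoring.** Raw session time series (thermode ramp pretests rated on
   a 0-100 computerized visual analogue scale, two 120-s tonic heat test
   stimuli at the individually calibrated T50, and a 120-s cold-pressor
   conditioning stimulus rated 0-10 every 15 s) are scored into
   per-participant indicators:
   - heat pain threshold and T50 (interpolated ramp crossings),
   - TSP₁, TSP₂ = CoVAS(120 s) − CoVAS(60 s), the signed change over the
     temporal-summation phase of each test stimulus, categorized at the
     inclusive ±20/100 cutoff,
   - CS mean pain, with early withdrawal imputed as 10/10,
   - CPM efficiency = 100% × (CoVAS_after − CoVAS_before)/CoVAS_before,
     categorized as optimal (≤ −30%), suboptimal (−30, −10] or
     inefficient (> −10%).
2. **Clustering.** Patients are clustered on the four z-scored
   indicators (TSP₁, CS mean, TSP₂, CPM%) by a Ward hierarchy (heights =
   within-inertia gains), the partition with the highest relative loss of
   inertia Δ(k) = (W(k−1) − W(k))/W(k−1) over k = 2..6, and k-means
   consolidation from the hierarchical centroids.
3. **Reporting.** Pearson χ² (no continuity correction),
   gender-controlled one-way ANOVA (Type II SS) with ω² effect sizes,
   Scheffé and Fisher-LSD pairwise comparisons, and Spearman correlations
   with Fisher-z confidence intervals.
4. **Synthetic cohorts.** Because raw CPM session data are not publicly
   deposited, a generator emits raw traces from a three-phenotype patient
   mixture plus controls (parameters follow the published cluster profile
   of the pediatric cohort it emulates), with a latent-truth table so the
   full pipeline can be validated end to end.

## Worked example

The analysis is organised as numbered drivers under `analysis/`:

```sh
Rscript analysis/01_simulate.R   # emit raw cohort CSVs + latent truth
Rscript analysis/02_score.R      # parse, filter, score -> scores.csv
Rscript analysis/03_cluster.R    # z-score, Ward + consolidation
Rscript analysis/04_report.R     # tables, chi-squared, Spearman
```

With the default seed the run prints:

```
Simulated 699 sessions (639 patients, 60 controls) with seed 1
Scored 668 of 699 sessions (31 excluded: missing TS1; ...)
Patients: n=608, CPM % mean -25.73 (SD 41.42); controls: n=60, mean -30.81
Patient CPM categories: INEFFICIENT=199, OPTIMAL=295, SUBOPTIMAL=114
Clustered 608 patients: chose k = 3 (relative inertia loss: k=2 0.198,
  k=3 0.209, k=4 0.083, k=5 0.085, k=6 0.071)
Cluster sizes: 276/167/165; 40.19% of total inertia between clusters
Adjusted Rand index vs latent phenotypes: 0.567
```

Reading: of 699 simulated sessions, 31 were incomplete and excluded,
leaving 608 analyzable patients. The mean patient CPM efficiency of
−25.7% sits between "suboptimal" and "optimal"; the relative-loss rule
peaks at k = 3, and the consolidated three-cluster solution recovers the
latent phenotypes with ARI 0.57 — imperfectly, because the phenotypes
overlap by construction (see the methods vignette).

The same objects are available programmatically:

```r
library(cpmcluster)
run <- run_pipeline(run_config(
  sim_config = generator_config(n_patients = 639, n_controls = 60, seed = 1),
  seed = 1, out_dir = "results/report"))
run$clusters            # k, labels, inertia decomposition
head(run$table2)        # indicators by cluster + controls, ANOVA/omega^2
```

Single-session scoring works on plain objects:

```r
ts1 <- thermal_trace(0:120, c(rep(50, 61), 50 + 20 * (1:60) / 60), phase = "TS1")
temporal_summation(ts1)      # +20 (a clinically significant increase)
classify_tsp(20)             # "INCREASE"
cpm_efficiency(50, 35)       # -30: 30% inhibition
classify_cpm(-30)            # "OPTIMAL"
```

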