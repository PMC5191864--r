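# mitoburden

Somatic mitochondrial DNA mutational-load analysis for paired
tumor–normal cohorts, in R.

## What it does, and for whom

Tumors acquire somatic mutations in their mitochondrial genomes that are
observed as heteroplasmic allele frequencies (AFs). For cancer-genomics
groups studying whether *total* mtDNA mutational burden (rather than any
single recurrent variant) predicts disease aggressiveness, `mitoburden`
implements the full analysis as a reusable, seeded pipeline:

1. **Somatic calling** from matched tumor–normal AFs (or raw read
   counts), using the rule AF<sub>tumor</sub> − AF<sub>normal</sub> > 0.10
   (strict, tumor gains only; allele losses go to a diagnostics stream).
2. **Annotation** on the 16,569 bp mitochondrial reference coordinate
   system (rCRS numbering): 37-gene region map, control-region origin
   wrap, overlapping-gene handling, strand-aware codon translation under
   the vertebrate mitochondrial genetic code.
3. **Burden metrics** per patient: SNV count *n*, purity-adjusted allele
   frequencies AF/purity (uncapped), cumulative variant frequency
   CVF = Σ adjusted AF, functional flags (adjusted AF > 0.70), unique
   variant deduplication across patients, per-region densities (SNVs/kb)
   and Fisher-exact region-enrichment tests.
4. **Outcome association**: ANOVA linear models of Gleason grade
   (ordinal categories <7 / =7 / >7 coded 1/2/3) on burden with a
   Bonferroni-annotated 7-test battery; Kaplan–Meier / log-rank analysis
   of biochemical relapse by burden strata with Mantel–Haenszel hazard
   ratios exp((O₁−E₁)/V); in-sample ROC curves for Gleason, burden and
   their logistic combination, compared by DeLong's paired AUC test.
5. **Synthetic cohorts**: a generator with known truth (Poisson burden
   per Gleason category, truncated-Beta heteroplasmy in tumor-cell
   fraction space times purity, proportional-hazards relapse, binomial
   read counts) so every stage is testable offline.

The packaged reference FASTA is a **synthetic stand-in** for NC_012920
(real gene coordinates, computer-generated bases with valid reading
frames); see the methods vignette before interpreting base-level results
on real data.

## Worked example

```r
library(mitoburden)

cfg <- pipeline_config(
  simulation = cohort_config(seed = 7),  # 115-patient stated-world cohort
  seed = 7, log_level = "error")
report <- run_pipeline(cfg)
print(report)
```

Output (abridged):

```
== mtDNA mutational-load cohort report ==
patients: 115 | somatic SNV calls: 62 | unique variants: 62

-- burden summary by Gleason category --
 category n_patients total_snvs patients_with_snv mean_snv_count ... mean_cvf
       <7         30          9                 6          0.300 ...    1.053
       =7         35         19                16          0.543 ...    0.846
       >7         50         34                26          0.680 ...    0.981
      ALL        115         62                48          0.539 ...    0.945

-- burden-pathology ANOVA battery --
                 test slope f_statistic p_value bonferroni_threshold significant_bonferroni
   gleason_rp ~ n_snv 0.235        5.15 0.02511               0.0071                  FALSE
     gleason_rp ~ cvf 0.320        5.61 0.01959               0.0071                  FALSE
  gleason_rp ~ purity 1.687       11.00 0.00123               0.0071                   TRUE
  ...

-- survival, burden cutoff >= 1 --
Log-rank test (high vs low): chi-square = 3.691, p = 0.05469
Mantel-Haenszel HR = 1.828 (95% CI 0.988 - 3.381)

-- relapse prediction (in-sample AUC) --
  gleason    AUC = 0.531
  n_snv      AUC = 0.538
  combined   AUC = 0.537
  DeLong gleason vs combined: p = 0.7186
```

Reading it: this one seeded 115-patient draw produced 62 somatic calls in
48 patients; SNV count and CVF rise with Gleason category (mean count
0.30 → 0.68), the burden–grade ANOVA models have p ≈ 0.02–0.04 (raw, not
surviving the 0.0071 Bonferroni threshold at this cohort size), and
patients with ≥ 1 SNV have a log-rank hazard ratio of 1.83 for relapse —
a single n = 115 realization of a generator whose true carrier HR is
2.17. At n = 115 single draws are noisy by design; the parameter-recovery
guarantees (HR within [1.7, 2.35] in ≥ 90% of n = 2000 replicates, etc.)
are enforced in `tests/testthat/test-acceptance.R`.

With `out_dir` set, the pipeline writes every intermediate table (somatic
calls, unique variants, burden profiles, densities, KM and ROC
coordinates) as commented TSV plus `report.json` / `report.txt`.

## Command line

```sh
Rscript inst/cli/mitoburden.R simulate --config config.json --out sim/
Rscript inst/cli/mitoburden.R validate --variants sim/paired_calls.tsv --clinical sim/clinical.tsv
Rscript inst/cli/mitoburden.R all --config config.json --out report/
```

Subcommands `call`, `burden`, `associate`, `survive`, `roc` run the same
pipeline and print the corresponding stage output. Exit codes: 0 success,
2 validation failure, 1 runtime error. Configs are JSON (YAML accepted
when the `yaml` package is installed).

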