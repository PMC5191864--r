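---
title: "Methods: somatic mtDNA mutational load, from paired allele frequencies to outcome association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic mtDNA mutational load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Prostate tumors acquire somatic mutations in their mitochondrial genomes.
Because each cell carries many mtDNA copies, a somatic variant is observed
as a *heteroplasmic* allele frequency (AF) between 0 and 1 rather than as a
discrete genotype. Comparing the tumor AF with the AF in the same patient's
blood separates acquired (somatic) variation from inherited variation, and
the per-patient *mutational load* — how many somatic single-nucleotide
variants (SNVs) a tumor carries, and at what cumulative frequency — can be
related to pathology grade (Gleason score) and to biochemical relapse after
prostatectomy. `mitoburden` implements that entire analysis as a tested,
seeded pipeline, together with a synthetic-cohort generator so every stage
can be verified offline against known truth.

## The somatic-calling model

The caller starts from per-site paired allele frequencies, or from raw
alt/total read counts converted to frequencies under a configurable depth
floor. A site is called somatic when

$$\mathrm{AF}_{tumor} - \mathrm{AF}_{normal} > 0.10$$

with a *strict* inequality. Three deliberate conventions:

* **Tumor gains only.** The AF-difference rule is directional: only excess
  tumor allele frequency counts as somatic. Sites where the blood AF
  exceeds the tumor AF by more than the threshold ("losses") are a
  biologically different event; they are surfaced in a diagnostics stream
  and never enter burden statistics.
* **Strict inequality at the boundary** (`0.10` exactly is not somatic).
* **No additional AF floor.** A heteroplasmic variant at tumor AF 0.17 and
  blood AF 0 is a legitimate call; no minimum tumor AF is imposed beyond
  the pair rule.

The depth floor for AF estimation from counts defaults to 100 reads; sites
below it are *missing*, not AF 0, and are excluded from calling.

Indels are parsed from VCF input but flagged and excluded from all burden
statistics; only SNVs are analyzed.

## Reference annotation

Positions are 1-based coordinates on the 16,569 bp circular mitochondrial
reference (rCRS numbering). The packaged region map contains the 37 genes
(13 protein-coding, 2 rRNA, 22 tRNA, true NC_012920 feature-table
coordinates) plus the control region, stored as two segments
(16024–16569, 1–576) to express the origin wrap. Positions covered by no
record are intergenic spacers ("other noncoding"). Conventions chosen
where the field has no single standard:

* A variant inside overlapping genes (ATP8/ATP6, ND4L/ND4, the shared
  ATP6/CO3 base) is classified with the **most severe** effect across
  frames (stop_gain > non-synonymous > synonymous), keeps **all** region
  memberships for per-region density tallies, but counts **once** in
  genome-wide and class-aggregate totals.
* Codons are translated under the vertebrate mitochondrial genetic code
  (TGA = Trp, ATA = Met; stops TAA, TAG, AGA, AGG), strand-aware:
  light-strand genes are read on the reverse complement.
* Genes whose spans are not whole codon multiples end in documented
  incomplete stop codons (completed by polyadenylation in vivo). These
  trailing bases are listed in packaged metadata, never silently
  "corrected"; a substitution there has no complete codon to translate and
  is classified `noncoding`.

### The synthetic reference sequence

The true NC_012920 base sequence is not redistributable in this build
environment, so the packaged FASTA (`rcrs_synthetic.fa`) is an explicitly
**synthetic stand-in**: pseudo-random bases on the real coordinates,
constrained so every protein-coding gene has an ATG start, a stop-free
internal frame on the correct strand, and the proper complete/incomplete
terminal stop. Every coordinate-level statement (region classes, overlap
behavior, position mt.16093 in the control region) is exact; base-level
examples in the tests are located by scanning the packaged sequence rather
than hard-coding rCRS bases. Analyses of real data should treat ref-base
consistency checks against this sequence as a structural convention, not
as a claim about the true human sequence.

## Burden metrics

* **Purity adjustment.** Observed AFs are divided by the
  pathologist-estimated tumor purity: `adjusted = raw / purity`. The
  result is *not* capped at 1 — observed AFs can exceed the purity
  estimate, and values above 1 carry information (sampling error in either
  quantity); capping would bias the cumulative statistics.
* **CVF** (cumulative variant frequency) is the per-patient sum of
  adjusted AFs, 0 for variant-free patients. Because published summary
  tables in this field do not always reconcile adjusted-AF means with CVF
  means under a single definition, the raw-AF variant of CVF is available
  behind a config switch (`cvf_definition = "raw"`); the adjusted
  definition is the default and the documented one.
* **Functional flag**: adjusted AF strictly above 0.70, the conventional
  threshold for a heteroplasmy level able to impair mitochondrial
  function. The threshold applies to the *adjusted* AF — that is the whole
  point of the purity correction.
* **Summary conventions**: mean SNV count divides by *all* patients in a
  Gleason category; mean CVF and per-variant AF means average over
  variant-carrying patients/variants only.
* **Region densities** count unique variants (deduplicated across
  patients) per region, scaled to SNVs per kb. Enrichment between two
  genome partitions is tested with a 2×2 Fisher exact test whose trials
  are bases: `[variants in A, variant-free bases in A; variants in B,
  variant-free bases in B]`. This is the only 2×2 construction that uses
  exactly the available inputs (counts and region lengths); it treats
  bases as independent trials, which is a simplification.

## The statistics engine

All tests are implemented from first principles and verified against
independent oracles in the test suite (full enumeration, `stats::lm`,
`survival::survfit`/`survdiff`, permutation, jackknife):

* **Fisher 2×2**: exact hypergeometric enumeration; two-sided p by the
  small-p-values convention (sum of probabilities of tables no more
  probable than the observed one, relative tolerance 1e-7). r×c tables use
  seeded Monte-Carlo over fixed-margin tables (100,000 draws by default)
  with the Monte-Carlo standard error reported.
* **ANOVA linear model**: OLS with intercept; F = MS(model)/MS(residual)
  on (1, n−2) df. Gleason grade enters as the ordinal category code 1/2/3
  for `<7 / =7 / >7` (raw scores 4–10 are accepted as inputs and
  categorized). Following the source convention, the pathology grade is
  the response and burden the predictor; for a simple two-variable OLS the
  F and p are identical in either direction, so the choice is cosmetic.
* **Bonferroni**: the per-test threshold is α/m with m the number of
  tests actually run in the association battery (7: four primary
  grade-vs-burden models, two variant-subgroup models, one grade~purity
  model); every reported p is annotated with the threshold.
* **Kaplan–Meier**: product-limit estimator; censored times shrink the
  risk set without steps.
* **Log-rank / hazard ratio**: standard chi-square over shared event
  times; the HR is the Mantel–Haenszel one-step estimate
  exp((O₁−E₁)/V) with CI exp((O₁−E₁)/V ± 1.96/√V). Cox regression is
  deliberately out of scope — the one-step estimate is what the standard
  GraphPad-style survival analysis reports and is adequate for a two-group
  comparison. It is mildly biased toward the null for large true HRs; the
  parameter-recovery test quantifies this (true HR 2.0 recovered within
  [1.7, 2.35] in ≥ 90% of replicates at n = 2000).
* **Relapse rule**: event when surgery was non-curative (event month 1,
  a timing convention), on metastasis/disease death, or at the month of
  the second of two consecutive PSA measurements > 0.2 ng/mL; otherwise
  censored at end of follow-up.
* **ROC/AUC**: empirical curve over all score thresholds; AUC by the
  Mann–Whitney identity with ties counted ½.
* **Predictor combination**: in-sample logistic regression (IRLS,
  tolerance 1e-8, ≤ 100 iterations) of relapse on grade code and SNV
  count; the combined score is the linear predictor. Complete separation
  triggers a warning and a fallback to the sum of rank-standardized
  predictors.
* **DeLong test**: placement values per positive/negative subject;
  variance of the paired AUC difference from their empirical covariances;
  two-sided normal test. Identical score vectors give p = 1 by
  construction.

## The synthetic cohort: a stated world

The generator's defaults restate the observed cohort structure and are not
tuned: 115 patients split 26/40/49 across Gleason `<7 / =7 / >7`;
per-category Poisson SNV-count means 0.23/0.68/0.88; purity Beta-distributed
per category with means ≈ 0.47/0.60/0.60 truncated to [0.05, 0.85]
(reproducing the purity–grade correlation in direction); variant positions
uniform over the genome (a `hotspot_fraction` switch concentrates a chosen
fraction into control region + tRNAs to exercise the density tests);
tumor-cell-fraction AFs from Beta(3, 1) truncated to [0.12, 1]
(mean ≈ 0.75, matching the reported adjusted-AF mean; the Beta shape
itself is a free config choice, not a claim about real tumors); observed
tumor AF = tcf-AF × purity, so the purity adjustment inverts the generator
exactly; blood contamination AF 0 by default; relapse times exponential
with hazard 0.004/month (chosen once so that ≈ 36% of patients relapse
within the follow-up window, as observed) times 2.17 for patients with ≥ 1
SNV; administrative censoring uniform on 24–150 months. Read counts, when
requested, are Binomial(depth, AF) at fixed depth (default 2000×).

What the simulator does **not** model: sequencing error and strand bias,
NuMT contamination, platform-specific artifacts, within-tumor clonal
structure, haplogroup-dependent mutation spectra, and any AF distribution
shape beyond the truncated Beta. A green end-to-end test therefore
establishes that the pipeline's logic is correct under its stated
assumptions — not that the caller is robust to real sequencing noise.

One modeling consequence worth noting: because observed AF = tcf × purity
with tcf ≤ 1, the simulated adjusted AFs never exceed 1, whereas real
cohorts report adjusted AFs up to ≈ 1.8. `adjust_af` itself is uncapped;
only the generator's stated world is conservative here.

## Numerical and degenerate-input choices

* All randomness flows from one master seed through named per-stage
  substreams (`substream_seed`), so partial re-runs are reproducible and
  two runs with the same config are byte-identical.
* Zero-burden cohorts run end-to-end: the ANOVA battery reports NA rows
  for constant predictors (with the reason), survival strata collapse is
  recorded as a warning, and ROC degenerates are caught — the report is
  emitted regardless.
* Fisher two-sided convention, tie handling in AUC, and the strict
  thresholds at 0.10 / 0.70 are all boundary-tested.
* `fisher_exact_rxc` reports its Monte-Carlo SE; the haplogroup
  expected-vs-observed comparison is cast as a 2×k table of observed
  counts versus `round(n × expected frequency)` — the construction is a
  documented choice, since count-vs-frequency comparisons have no
  canonical contingency form.

## Known limitations

* No Cox modeling, no multivariable adjustment beyond the two-predictor
  logistic combiner, no confidence bands on KM curves, no cross-validated
  AUC (all AUCs are in-sample, as in the source analysis).
* Effect classification is single-codon; no transcript-model annotation,
  no indel effects, no computational damage prediction (damage labels are
  accepted as input annotation if present).
* The packaged reference sequence is synthetic (see above); per-gene
  density *rankings* on real data should be recomputed against the true
  rCRS before interpretation.
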