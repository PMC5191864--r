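# Purity adjustment, CVF, functional flags, cohort summary, densities,
# enrichment tests.

test_that("adjust_af divides by purity without capping", {
  expect_equal(adjust_af(0.5, 1.0), 0.5)
  expect_equal(adjust_af(0.5, 0.5), 1.0)
  expect_equal(adjust_af(0.9, 0.5), 1.8) # above 1 is meaningful
  # strictly decreasing in purity
  expect_true(adjust_af(0.4, 0.3) > adjust_af(0.4, 0.6))
  expect_error(adjust_af(0.5, 0), "purity-domain")
  expect_error(adjust_af(0.5, 1.2), "purity-domain")
  # simulator inversion: adjusted AF recovers the true tumor-cell fraction
  sim <- simulate_cohort(cohort_config(n_patients = 200, seed = 55))
  tv <- sim$truth$variants
  pur <- sim$truth$patients$purity[match(tv$patient_id,
                                         sim$truth$patients$patient_id)]
  expect_equal(adjust_af(tv$tumor_af, pur), tv$true_af, tolerance = 1e-12)
})

test_that("compute_cvf sums adjusted AFs, permutation-invariant", {
  expect_equal(compute_cvf(numeric(0)), 0)
  expect_equal(compute_cvf(0.28), 0.28)
  expect_equal(compute_cvf(c(1.0, 0.75, 1.5)), 3.25)
  expect_equal(compute_cvf(c(1.5, 1.0, 0.75)), 3.25)
})

test_that("flag_functional is strict at the 0.70 boundary", {
  expect_false(flag_functional(0.70))
  expect_true(flag_functional(0.71))
  expect_true(flag_functional(1.79))
  expect_error(flag_functional(-0.1), "domain error")
})

test_that("burden_profiles aggregates per patient with both CVF modes", {
  clinical <- data.frame(patient_id = c("A", "B"), purity = c(0.5, 0.8),
                         gleason_cat = c("=7", ">7"))
  somatic <- data.frame(patient_id = c("A", "A"),
                        position = c(100, 200), ref = "C", alt = "T",
                        tumor_af = c(0.3, 0.4),
                        normal_af = 0, somatic_af = c(0.3, 0.4),
                        effect = c("non_synonymous", "synonymous"))
  p <- burden_profiles(somatic, clinical)
  expect_equal(p$n_snv, c(2L, 0L))
  expect_equal(p$cvf[1], 0.3 / 0.5 + 0.4 / 0.5)
  expect_equal(p$cvf[2], 0)
  expect_equal(p$n_functional[1], 1L) # 0.8 > 0.7, 0.6 is not
  expect_equal(p$n_nonsynonymous[1], 1L)
  praw <- burden_profiles(somatic, clinical, cvf_definition = "raw")
  expect_equal(praw$cvf[1], 0.7)
  expect_error(burden_profiles(transform(somatic, patient_id = "Z"),
                               clinical), "join error")
})

test_that("single-patient arithmetic: CVF 1.4, one functional variant", {
  clinical <- data.frame(patient_id = "A", purity = 1, gleason_cat = "=7")
  somatic <- data.frame(patient_id = "A", position = c(10, 20),
                        ref = "C", alt = "T", tumor_af = c(0.6, 0.8),
                        normal_af = 0, effect = "noncoding")
  p <- burden_profiles(somatic, clinical)
  expect_equal(p$cvf, 1.4)
  expect_equal(p$n_functional, 1L)
})

test_that("cohort_summary reproduces reference-cohort marginal arithmetic", {
  fx <- make_marginal_fixture()
  s <- cohort_summary(fx$profiles, fx$clinical)
  expect_equal(s$category, c("<7", "=7", ">7", "ALL"))
  expect_equal(s$total_snvs, c(6, 27, 43, 76))
  expect_equal(s$patients_with_snv, c(4, 19, 27, 50))
  expect_equal(round(s$mean_snv_count, 2), c(0.23, 0.68, 0.88, 0.66))
  # totals: category columns sum to the overall column
  expect_equal(sum(s$total_snvs[1:3]), s$total_snvs[4])
  expect_equal(sum(s$patients_with_snv[1:3]), s$patients_with_snv[4])
  # all-zero cohort
  zero <- fx$profiles
  zero$n_snv <- 0L; zero$cvf <- 0
  s0 <- cohort_summary(zero, fx$clinical)
  expect_true(all(s0$mean_snv_count == 0))
  expect_true(all(s0$patients_with_snv == 0))
})

test_that("region_densities counts unique variants and aggregates", {
  expect_equal(sum(region_densities(
    data.frame(position = integer(0)))$regions$n_variants), 0)
  # 12 variants in the 1122 bp D-loop
  dl_pos <- c(seq(16030, 16130, by = 10), 100)
  d <- region_densities(data.frame(position = dl_pos))
  dl <- d$regions[d$regions$name == "D-loop", ]
  expect_equal(dl$n_variants, 12)
  expect_equal(dl$length_bp, 1122)
  expect_equal(dl$density_per_kb, 12 * 1000 / 1122)
  # aggregate bookkeeping: noncoding_total recomputed from its parts
  agg <- d$aggregates
  get <- function(cls, col) agg[agg$region_class == cls, col]
  expect_equal(get("noncoding_total", "n_variants"),
               get("control_region", "n_variants") +
                 get("tRNA", "n_variants") +
                 get("other_noncoding", "n_variants"))
  expect_equal(get("noncoding_total", "length_bp"),
               get("control_region", "length_bp") +
                 get("tRNA", "length_bp") +
                 get("other_noncoding", "length_bp"))
  # genome tiling: class lengths + gaps cover 16569 (overlaps counted once)
  expect_equal(get("other_noncoding", "length_bp") +
                 sum(mitoburden:::.covered_length()), 16569)
  # overlap convention: a variant in ATP8/ATP6 counts once per gene but
  # once in the protein_coding aggregate
  d2 <- region_densities(data.frame(position = 8550))
  expect_equal(sum(d2$regions$n_variants), 2)
  expect_equal(d2$aggregates$n_variants[
    d2$aggregates$region_class == "protein_coding"], 1)
  # enriched fixture: control-region density exceeds protein-coding
  sim <- simulate_cohort(cohort_config(n_patients = 500,
                                       hotspot_fraction = 0.9, seed = 77))
  uniq <- deduplicate(sim$calls)
  d3 <- region_densities(uniq)
  a3 <- d3$aggregates
  expect_gt(a3$density_per_kb[a3$region_class == "control_region"],
            a3$density_per_kb[a3$region_class == "protein_coding"])
})

test_that("region_enrichment_test builds the base-level 2x2 table", {
  # equal densities: no association
  expect_equal(region_enrichment_test(10, 10000, 10, 10000)$p_value, 1)
  # frozen enumeration value for [5, 995; 0, 9000]
  expect_equal(region_enrichment_test(5, 1000, 0, 9000)$p_value,
               9.910256e-06, tolerance = 1e-6)
  expect_equal(region_enrichment_test(5, 1000, 0, 9000)$p_value,
               oracle_fisher_2x2(5, 995, 0, 9000), tolerance = 1e-10)
  # extreme split is overwhelmingly significant
  expect_lt(region_enrichment_test(50, 1000, 0, 15000)$p_value, 0.01)
  expect_error(region_enrichment_test(1, 0, 1, 100),
               "degenerate-partition")
})
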