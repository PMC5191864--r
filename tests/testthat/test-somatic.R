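# Somatic calling, substitution spectrum, deduplication, novelty.

test_that("estimate_af applies the depth floor and count checks", {
  expect_equal(estimate_af(50, 100, 20), 0.5)
  expect_equal(estimate_af(0, 100, 20), 0)
  expect_true(is.na(estimate_af(5, 10, 20)))
  expect_error(estimate_af(11, 10, 5), "count-consistency")
})

test_that("call_somatic applies the strict >10% tumor-gain rule", {
  expect_true(call_somatic(0.50, 0.00))
  expect_false(call_somatic(0.15, 0.08))   # 0.07 <= 0.10
  expect_false(call_somatic(0.10, 0.00))   # strict boundary
  expect_true(call_somatic(0.101, 0.00))
  # losses are never somatic
  expect_false(call_somatic(0.05, 0.60))
  expect_error(call_somatic(NA, 0.1), "incomplete-pair")
  # monotone in the threshold: raising it never adds calls
  withr::with_seed(41, {
    taf <- runif(500); naf <- runif(500, 0, 0.3)
    thr <- sort(runif(5, 0.05, 0.5))
    calls <- vapply(thr, function(th) sum(call_somatic(taf, naf, th)),
                    numeric(1))
    expect_true(all(diff(calls) <= 0))
  })
})

test_that("classify_substitution collapses to the pyrimidine strand", {
  expect_equal(classify_substitution("G", "A"),
               list(class = "C>T", is_transition = TRUE))
  expect_equal(classify_substitution("T", "C"),
               list(class = "T>C", is_transition = TRUE))
  expect_equal(classify_substitution("C", "G"),
               list(class = "C>G", is_transition = FALSE))
  expect_equal(classify_substitution("A", "G")$class, "T>C")
  expect_error(classify_substitution("C", "C"), "differ")
  expect_error(classify_substitution("N", "A"), "sequence-alphabet")
})

test_that("deduplicate counts cross-patient recurrence and is idempotent", {
  calls <- make_recurrent_calls(76, recur = 3)
  uniq <- deduplicate(calls)
  expect_equal(nrow(uniq), 74)
  expect_equal(sum(uniq$recurrence), 76)
  expect_equal(uniq$recurrence[uniq$position == 16093], 3)
  # idempotence: deduplicating the unique set changes nothing
  uniq2 <- deduplicate(cbind(patient_id = sprintf("Q%03d",
                                                  seq_len(nrow(uniq))),
                             uniq[, c("position", "ref", "alt")]))
  expect_equal(uniq2$position, uniq$position)
  expect_true(all(uniq2$recurrence == 1))
  # empty input and within-patient duplicates
  expect_equal(nrow(deduplicate(calls[0, ])), 0)
  dup <- rbind(calls, calls[1, ])
  expect_error(deduplicate(dup), "input-duplication")
  # 5 identical calls in 5 patients collapse to recurrence 5
  five <- data.frame(patient_id = paste0("P", 1:5), position = 2000,
                     ref = "C", alt = "T")
  expect_equal(deduplicate(five)$recurrence, 5)
})

test_that("annotate_novelty picks the most specific context", {
  uniq <- deduplicate(make_recurrent_calls(76, 3))
  none <- annotate_novelty(uniq, NULL)
  expect_true(all(none$novelty == "novel"))
  # catalog of 6 prostate-context variants leaves 68 novel
  catalog <- data.frame(position = uniq$position[1:6], ref = uniq$ref[1:6],
                        alt = uniq$alt[1:6], context = "prostate")
  ann <- annotate_novelty(uniq, catalog)
  expect_equal(sum(ann$novelty == "novel"), 68)
  expect_equal(sum(ann$novelty == "known_prostate"), 6)
  # specificity: prostate beats cancer for the same variant
  catalog2 <- rbind(catalog[1, ],
                    transform(catalog[1, ], context = "cancer"))
  ann2 <- annotate_novelty(uniq[1, , drop = FALSE], catalog2)
  expect_equal(as.character(ann2$novelty), "known_prostate")
  # malformed rows are skipped with a warning and counted
  bad <- rbind(catalog, data.frame(position = -5, ref = "X", alt = "Y",
                                   context = "prostate"))
  expect_warning(ann3 <- annotate_novelty(uniq, bad), "skipped 1")
  expect_equal(attr(ann3, "n_skipped"), 1L)
})

test_that("spectrum_summary sums to 1 and respects strand collapse", {
  all_ga <- data.frame(ref = rep("G", 5), alt = rep("A", 5))
  sp <- spectrum_summary(all_ga)
  expect_equal(unname(sp["C>T"]), 1)
  expect_equal(sum(sp), 1)
  # equal counts of all 6 classes
  six <- data.frame(ref = c("C", "T", "C", "C", "T", "T"),
                    alt = c("T", "C", "A", "G", "A", "G"))
  expect_true(all(abs(spectrum_summary(six) - 1 / 6) < 1e-12))
  # constructed 54% C>T / 24% T>C mix (50 variants)
  mix <- data.frame(ref = c(rep("C", 27), rep("T", 12), rep("C", 11)),
                    alt = c(rep("T", 27), rep("C", 12), rep("A", 11)))
  spm <- spectrum_summary(mix)
  expect_equal(unname(spm["C>T"]), 0.54)
  expect_equal(unname(spm["T>C"]), 0.24)
  # invariance under reverse-complement relabeling
  mix_rc <- data.frame(ref = chartr("ACGT", "TGCA", mix$ref),
                       alt = chartr("ACGT", "TGCA", mix$alt))
  expect_equal(spectrum_summary(mix_rc), spm)
  expect_error(spectrum_summary(mix[0, ]), "empty-set")
})

test_that("call_somatic_variants annotates and splits losses", {
  seqc <- mitoburden:::rcrs_chars()
  pos <- c(16093, 8550, 3400)
  calls <- data.frame(patient_id = c("A", "A", "B"),
                      position = pos, ref = seqc[pos],
                      alt = vapply(seqc[pos], function(r)
                        setdiff(c("A", "C", "G", "T"), r)[1], character(1)),
                      tumor_af = c(0.5, 0.05, 0.3),
                      normal_af = c(0, 0.4, 0.1))
  res <- call_somatic_variants(calls)
  expect_equal(nrow(res$somatic), 2)
  expect_equal(nrow(res$losses), 1)
  expect_equal(res$losses$position, 8550)
  expect_true(all(c("somatic_af", "substitution_class", "region",
                    "effect") %in% names(res$somatic)))
  expect_equal(res$somatic$effect[res$somatic$position == 16093],
               "noncoding")
  expect_equal(res$somatic$region[res$somatic$position == 16093], "D-loop")
})

test_that("calling from counts converges to calling on true AFs", {
  # at depth 20000 the estimated AFs agree with truth-based calls at
  # >= 99.9% of sites (truth + null sites, cohort-default AF distribution)
  cfg <- cohort_config(n_patients = 1500, seed = 42, depth = 20000,
                       n_null_sites = 2000)
  sim <- simulate_cohort(cfg)
  counts <- emit_allele_counts(sim)
  res_counts <- call_somatic_variants(counts, min_depth = 100)
  truth_af <- rbind(
    data.frame(patient_id = sim$calls$patient_id,
               position = sim$calls$position,
               somatic = call_somatic(sim$calls$tumor_af,
                                      sim$calls$normal_af)),
    data.frame(patient_id = counts$patient_id[counts$is_null_site],
               position = counts$position[counts$is_null_site],
               somatic = FALSE))
  key_called <- paste(res_counts$somatic$patient_id,
                      res_counts$somatic$position)
  agree <- (paste(truth_af$patient_id, truth_af$position) %in% key_called) ==
    truth_af$somatic
  expect_gte(mean(agree), 0.999)
})
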