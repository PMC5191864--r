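# End-to-end orchestration: configuration, input validation, stage
# execution, cohort report assembly and file emission.

.log_levels <- c(debug = 1, info = 2, warn = 3, error = 4)

log_msg <- function(level, stage, msg, config_level = "info") {
  if (.log_levels[[level]] >= .log_levels[[config_level]]) {
    message(sprintf("[%s] %s: %s", level, stage, msg))
  }
}

#' Pipeline configuration
#'
#' Exactly one of \code{simulation} (a \code{\link{cohort_config}}) or the
#' input paths (\code{variants_path} + \code{clinical_path}) must be
#' supplied.
#'
#' @param simulation a \code{cohort_config}, or NULL when reading files.
#' @param variants_path paired tumor-normal variant TSV.
#' @param clinical_path clinical TSV.
#' @param catalog_path optional variant-catalog TSV for novelty labels.
#' @param use_counts when simulating, exercise the caller from binomial
#'   allele counts (TRUE, default) rather than exact AFs.
#' @param somatic_threshold AF-difference threshold for somatic calls.
#' @param min_depth depth floor for AF estimation from counts.
#' @param cvf_definition \code{"adjusted"} or \code{"raw"}.
#' @param functional_threshold adjusted-AF threshold for functional impact.
#' @param burden_cutoffs SNV-count cutoffs for the survival strata.
#' @param alpha familywise alpha for the Bonferroni annotation.
#' @param m_tests number of tests in the Bonferroni family.
#' @param out_dir output directory (NULL = no files written).
#' @param seed master seed for non-simulation randomness (Monte-Carlo
#'   Fisher test); the simulation uses its own config seed.
#' @param log_level one of debug, info, warn, error.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(simulation = NULL, variants_path = NULL,
                            clinical_path = NULL, catalog_path = NULL,
                            use_counts = TRUE,
                            somatic_threshold = 0.10, min_depth = 100,
                            cvf_definition = "adjusted",
                            functional_threshold = 0.70,
                            burden_cutoffs = c(1, 2),
                            alpha = 0.05, m_tests = 7,
                            out_dir = NULL, seed = 1L, log_level = "info") {
  has_sim <- !is.null(simulation)
  has_paths <- !is.null(variants_path) || !is.null(clinical_path)
  if (has_sim == has_paths) {
    stopf("config error: supply exactly one of a simulation block or input paths")
  }
  if (has_paths && (is.null(variants_path) || is.null(clinical_path))) {
    stopf("config error: both variants_path and clinical_path are required")
  }
  if (has_sim && !inherits(simulation, "cohort_config")) {
    simulation <- do.call(cohort_config, as.list(simulation))
  }
  if (somatic_threshold < 0 || somatic_threshold >= 1) {
    stopf("config error: somatic_threshold must lie in [0, 1)")
  }
  cvf_definition <- match.arg(cvf_definition, c("adjusted", "raw"))
  log_level <- match.arg(log_level, names(.log_levels))
  cfg <- as.list(environment())
  cfg$has_sim <- cfg$has_paths <- NULL
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON or YAML
#'
#' JSON is always supported; YAML requires the optional \code{yaml}
#' package.
#'
#' @param path config file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("YAML configs require the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$simulation)) {
    raw$simulation <- do.call(cohort_config, as.list(raw$simulation))
  }
  do.call(pipeline_config, raw)
}

#' Validate pipeline input tables
#'
#' Checks schema, value domains (AFs in \[0,1\], purity in (0,1\],
#' positions on the mitochondrial genome, follow-up months positive) and
#' patient-id join completeness between the variant and clinical tables.
#'
#' @param clinical clinical data.frame.
#' @param calls paired variant data.frame.
#' @param catalog optional catalog data.frame.
#' @return data.frame of issues (\code{severity}, \code{field},
#'   \code{patient_id}, \code{message}); zero rows when the inputs are
#'   well-formed.
#' @export
validate_inputs <- function(clinical, calls, catalog = NULL) {
  issues <- list()
  add <- function(severity, field, patient_id, message) {
    issues[[length(issues) + 1]] <<- data.frame(
      severity = severity, field = field,
      patient_id = as.character(patient_id), message = message,
      stringsAsFactors = FALSE)
  }
  for (col in c("patient_id", "purity")) {
    if (!(col %in% names(clinical))) {
      add("error", col, NA, sprintf("clinical table lacks column '%s'", col))
    }
  }
  if ("patient_id" %in% names(clinical)) {
    dup <- clinical$patient_id[duplicated(clinical$patient_id)]
    for (d in unique(dup)) add("error", "patient_id", d, "duplicated clinical record")
  }
  if ("purity" %in% names(clinical)) {
    bad <- which(is.na(clinical$purity) | clinical$purity <= 0 |
                   clinical$purity > 1)
    for (i in bad) {
      add("error", "purity", clinical$patient_id[i],
          sprintf("purity %s outside (0, 1]", clinical$purity[i]))
    }
  }
  if ("gleason_rp" %in% names(clinical)) {
    bad <- which(!is.na(clinical$gleason_rp) &
                   (clinical$gleason_rp < 4 | clinical$gleason_rp > 10))
    for (i in bad) {
      add("error", "gleason_rp", clinical$patient_id[i],
          sprintf("Gleason score %s outside 4-10", clinical$gleason_rp[i]))
    }
  }
  if ("follow_up_months" %in% names(clinical)) {
    bad <- which(is.na(clinical$follow_up_months) |
                   clinical$follow_up_months <= 0)
    for (i in bad) {
      add("error", "follow_up_months", clinical$patient_id[i],
          "follow-up months must be positive")
    }
  }
  for (col in c("patient_id", "position", "ref", "alt")) {
    if (!(col %in% names(calls))) {
      add("error", col, NA, sprintf("variant table lacks column '%s'", col))
    }
  }
  if (all(c("position", "patient_id") %in% names(calls)) &&
      nrow(calls) > 0) {
    bad <- which(is.na(calls$position) | calls$position < 1 |
                   calls$position > MT_GENOME_LENGTH)
    for (i in bad) {
      add("error", "position", calls$patient_id[i],
          sprintf("position %s outside 1..%d", calls$position[i],
                  MT_GENOME_LENGTH))
    }
    for (col in c("tumor_af", "normal_af")) {
      if (col %in% names(calls)) {
        bad <- which(!is.na(calls[[col]]) &
                       (calls[[col]] < 0 | calls[[col]] > 1))
        for (i in bad) {
          add("error", col, calls$patient_id[i],
              sprintf("%s = %s outside [0, 1]", col, calls[[col]][i]))
        }
      }
    }
    if ("patient_id" %in% names(clinical)) {
      orphans <- setdiff(calls$patient_id, clinical$patient_id)
      for (o in orphans) {
        add("error", "patient_id", o,
            "variant rows without matching clinical record (pairing issue)")
      }
    }
  }
  if (!is.null(catalog)) {
    ok <- catalog$context %in% c("prostate", "cancer", "disease")
    if (any(!ok)) {
      add("warn", "context", NA,
          sprintf("%d catalog rows with unknown context", sum(!ok)))
    }
  }
  if (length(issues) == 0) {
    return(data.frame(severity = character(0), field = character(0),
                      patient_id = character(0), message = character(0)))
  }
  do.call(rbind, issues)
}

# assemble the ANOVA battery; returns a data.frame of annotated tests
.association_tests <- function(clinical, profiles, alpha, m_tests) {
  d <- merge(clinical, profiles, by = "patient_id")
  g_rp <- as.integer(factor(d$gleason_cat, levels = gleason_levels()))
  g_bx <- if ("gleason_biopsy_cat" %in% names(d)) {
    as.integer(factor(d$gleason_biopsy_cat, levels = gleason_levels()))
  } else NULL
  n_syn_nc <- d$n_snv - d$n_nonsynonymous
  spec <- list(
    list(name = "gleason_rp ~ n_snv", y = g_rp, x = d$n_snv),
    list(name = "gleason_rp ~ cvf", y = g_rp, x = d$cvf),
    list(name = "gleason_biopsy ~ n_snv", y = g_bx, x = d$n_snv),
    list(name = "gleason_biopsy ~ cvf", y = g_bx, x = d$cvf),
    list(name = "gleason_rp ~ n_nonsynonymous", y = g_rp,
         x = d$n_nonsynonymous),
    list(name = "gleason_rp ~ n_syn_noncoding", y = g_rp, x = n_syn_nc),
    list(name = "gleason_rp ~ purity", y = g_rp, x = d$purity))
  thr <- bonferroni_threshold(alpha, m_tests)
  rows <- lapply(spec, function(s) {
    if (is.null(s$y)) return(NULL)
    res <- tryCatch(anova_linear(s$y, s$x), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(test = s$name, slope = NA_real_, f_statistic = NA_real_,
                 df1 = NA_integer_, df2 = NA_integer_, p_value = NA_real_,
                 bonferroni_threshold = round(thr, 4),
                 significant_bonferroni = NA,
                 note = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(test = s$name, slope = res$slope,
                 f_statistic = res$f_statistic, df1 = res$df[1],
                 df2 = res$df[2], p_value = res$p_value,
                 bonferroni_threshold = round(thr, 4),
                 significant_bonferroni = res$p_value < thr, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Run the full mutational-load pipeline
#'
#' Stages: simulate/ingest, validate, somatic calling, annotation and
#' deduplication, burden metrics, region densities and enrichment,
#' haplogroup test, burden-pathology ANOVA battery with Bonferroni
#' annotation, Kaplan-Meier/log-rank survival per burden cutoff, and
#' ROC/DeLong relapse prediction. Deterministic given the config seed(s);
#' when \code{out_dir} is set, all intermediate tables and a JSON + text
#' report are written.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return object of class \code{cohort_report}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  lv <- config$log_level
  warnings_log <- character(0)
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  # -- ingest ---------------------------------------------------------------
  log_msg("info", "ingest", "loading cohort", lv)
  cohort <- NULL
  if (!is.null(config$simulation)) {
    cohort <- simulate_cohort(config$simulation)
    clinical <- cohort$clinical
    calls_in <- if (config$use_counts) emit_allele_counts(cohort)
                else cohort$calls
    catalog <- NULL
  } else {
    calls_in <- read_paired_variants(config$variants_path)
    clinical <- read_tsv(config$clinical_path)
    catalog <- if (!is.null(config$catalog_path))
      read_catalog(config$catalog_path) else NULL
  }
  if (!is.null(config$catalog_path)) {
    catalog <- read_catalog(config$catalog_path)
  }
  if (!("gleason_cat" %in% names(clinical)) &&
      "gleason_rp" %in% names(clinical)) {
    clinical$gleason_cat <- cut(clinical$gleason_rp, c(-Inf, 6.5, 7.5, Inf),
                                labels = gleason_levels())
  }

  # -- validate -------------------------------------------------------------
  issues <- validate_inputs(clinical, calls_in, catalog)
  if (any(issues$severity == "error")) {
    stopf("validate stage failed: %d issue(s); first: %s",
          sum(issues$severity == "error"),
          issues$message[issues$severity == "error"][1])
  }

  # -- call -----------------------------------------------------------------
  log_msg("info", "call", "calling somatic variants", lv)
  called <- call_somatic_variants(calls_in,
                                  threshold = config$somatic_threshold,
                                  min_depth = config$min_depth)
  somatic <- called$somatic
  if (nrow(somatic) == 0) note("no somatic variants called")

  # -- annotate / dedup -----------------------------------------------------
  unique_variants <- deduplicate(somatic)
  unique_variants <- annotate_novelty(unique_variants, catalog)
  spectrum <- if (nrow(somatic) > 0) spectrum_summary(somatic) else NULL
  densities <- region_densities(unique_variants)
  agg <- densities$aggregates
  pick <- function(cls, col) agg[agg$region_class == cls, col]
  enrichment <- list(
    noncoding_vs_coding = tryCatch(
      region_enrichment_test(pick("noncoding_total", "n_variants"),
                             pick("noncoding_total", "length_bp"),
                             pick("protein_coding", "n_variants"),
                             pick("protein_coding", "length_bp")),
      error = function(e) { note(conditionMessage(e)); NULL }),
    dloop_trna_vs_rest = tryCatch({
      n_a <- pick("control_region", "n_variants") + pick("tRNA", "n_variants")
      l_a <- pick("control_region", "length_bp") + pick("tRNA", "length_bp")
      region_enrichment_test(n_a, l_a, nrow(unique_variants) - n_a,
                             MT_GENOME_LENGTH - l_a)
    }, error = function(e) { note(conditionMessage(e)); NULL }))

  # -- haplogroups ----------------------------------------------------------
  haplogroup_test <- NULL
  if ("haplogroup" %in% names(clinical)) {
    expected_freq <- if (!is.null(config$simulation)) {
      config$simulation$haplogroup_freqs
    } else {
      # reference European-ancestry frequencies (H/U/T/J/K + remainder)
      c(H = 0.43, U = 0.14, T = 0.09, J = 0.11, K = 0.08, other = 0.15)
    }
    obs <- table(factor(clinical$haplogroup, levels = names(expected_freq)))
    exp_counts <- round(nrow(clinical) * expected_freq)
    haplogroup_test <- fisher_exact_rxc(
      rbind(observed = as.integer(obs), expected = as.integer(exp_counts)),
      seed = substream_seed(config$seed, "haplogroup"))
  }

  # -- burden ---------------------------------------------------------------
  log_msg("info", "burden", "computing burden profiles", lv)
  profiles <- burden_profiles(somatic, clinical,
                              cvf_definition = config$cvf_definition,
                              functional_threshold = config$functional_threshold)
  summary_tbl <- if ("gleason_cat" %in% names(clinical)) {
    cohort_summary(profiles, clinical)
  } else NULL

  # -- associate ------------------------------------------------------------
  associations <- if ("gleason_cat" %in% names(clinical)) {
    .association_tests(clinical, profiles, config$alpha, config$m_tests)
  } else NULL

  # -- survive --------------------------------------------------------------
  log_msg("info", "survive", "log-rank analysis per burden cutoff", lv)
  surv_data <- merge(clinical, profiles, by = "patient_id")
  has_surv <- all(c("follow_up_months", "relapse") %in% names(surv_data))
  survival_results <- list()
  if (has_surv) {
    for (cutoff in config$burden_cutoffs) {
      grp <- dichotomize_burden(surv_data$n_snv, cutoff)
      grp <- factor(grp, levels = c("high", "low")) # HR: high vs low
      key <- sprintf("cutoff_%d", cutoff)
      if (nlevels(droplevels(grp)) < 2 || sum(surv_data$relapse) == 0) {
        note(sprintf("survival strata collapse at cutoff %d", cutoff))
        survival_results[[key]] <- NULL
        next
      }
      lr <- logrank_hr(surv_data$follow_up_months, surv_data$relapse, grp)
      km <- lapply(split(seq_len(nrow(surv_data)), grp), function(idx) {
        km_estimate(surv_data$follow_up_months[idx], surv_data$relapse[idx])
      })
      survival_results[[key]] <- list(cutoff = cutoff, logrank = lr,
                                      km_curves = km)
    }
  }

  # -- roc ------------------------------------------------------------------
  roc_results <- NULL
  delong <- NULL
  if (has_surv && length(unique(surv_data$relapse)) == 2) {
    g_code <- as.integer(factor(surv_data$gleason_cat,
                                levels = gleason_levels()))
    labels <- surv_data$relapse
    roc_results <- list(gleason = roc_auc(g_code, labels))
    roc_burden <- tryCatch(roc_auc(surv_data$n_snv, labels),
                           error = function(e) { note(conditionMessage(e)); NULL })
    roc_results$n_snv <- roc_burden
    combined <- tryCatch(
      withCallingHandlers(
        combine_predictors(g_code, surv_data$n_snv, labels),
        warning = function(w) {
          note(conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) { note(conditionMessage(e)); NULL })
    if (!is.null(combined)) {
      roc_results$combined <- roc_auc(combined$score, labels)
      delong <- delong_test(g_code, combined$score, labels)
    }
  } else if (has_surv) {
    note("ROC degenerate: only one relapse class present")
  }

  report <- list(
    parameters = config[setdiff(names(config), "simulation")],
    seed = config$seed,
    n_patients = nrow(clinical),
    validation_issues = issues,
    n_somatic_calls = nrow(somatic),
    n_unique_variants = nrow(unique_variants),
    n_excluded_low_depth = called$n_excluded_low_depth,
    n_losses = nrow(called$losses),
    summary = summary_tbl,
    spectrum = spectrum,
    novelty = if (nrow(unique_variants) > 0)
      table(unique_variants$novelty) else NULL,
    densities = densities,
    enrichment = enrichment,
    haplogroup_test = haplogroup_test,
    associations = associations,
    survival = survival_results,
    roc = roc_results,
    delong = delong,
    warnings = warnings_log,
    somatic = somatic,
    losses = called$losses,
    unique_variants = unique_variants,
    profiles = profiles,
    clinical = clinical)
  class(report) <- "cohort_report"

  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir, cohort = cohort)
  }
  report
}

#' Write a cohort report and its intermediate tables to disk
#'
#' @param report a \code{cohort_report}.
#' @param out_dir output directory (created if needed).
#' @param cohort optional \code{mito_cohort} whose truth is also written.
#' @return invisibly, the output directory.
#' @export
write_report <- function(report, out_dir, cohort = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(sprintf("mitoburden cohort report, seed %s", report$seed),
            sprintf("somatic_threshold=%s min_depth=%s cvf=%s",
                    report$parameters$somatic_threshold,
                    report$parameters$min_depth,
                    report$parameters$cvf_definition))
  write_tsv(report$profiles, file.path(out_dir, "burden_profiles.tsv"), meta)
  write_tsv(report$somatic, file.path(out_dir, "somatic_variants.tsv"), meta)
  write_tsv(report$unique_variants,
            file.path(out_dir, "unique_variants.tsv"), meta)
  write_tsv(report$losses, file.path(out_dir, "allele_losses.tsv"), meta)
  write_tsv(report$densities$regions,
            file.path(out_dir, "region_densities.tsv"), meta)
  write_tsv(report$densities$aggregates,
            file.path(out_dir, "region_aggregates.tsv"), meta)
  if (!is.null(report$summary)) {
    write_tsv(report$summary, file.path(out_dir, "cohort_summary.tsv"), meta)
  }
  if (!is.null(report$associations)) {
    write_tsv(report$associations,
              file.path(out_dir, "association_tests.tsv"), meta)
  }
  for (key in names(report$survival)) {
    sr <- report$survival[[key]]
    for (g in names(sr$km_curves)) {
      write_tsv(sr$km_curves[[g]],
                file.path(out_dir, sprintf("km_%s_%s.tsv", key, g)), meta)
    }
  }
  for (key in names(report$roc)) {
    r <- report$roc[[key]]
    if (is.null(r)) next
    write_tsv(data.frame(threshold = r$thresholds,
                         sensitivity = r$sensitivities,
                         specificity = r$specificities),
              file.path(out_dir, sprintf("roc_%s.tsv", key)),
              c(meta, sprintf("auc=%.6f", r$auc)))
  }
  if (!is.null(cohort)) {
    write_truth_json(cohort, file.path(out_dir, "truth.json"))
    write_tsv(cohort$clinical, file.path(out_dir, "clinical.tsv"), meta)
  }
  jsonlite::write_json(report_summary_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

# condensed, JSON-friendly view of the headline numbers
report_summary_list <- function(report) {
  list(
    seed = report$seed,
    n_patients = report$n_patients,
    n_somatic_calls = report$n_somatic_calls,
    n_unique_variants = report$n_unique_variants,
    spectrum = as.list(report$spectrum),
    enrichment_p = lapply(report$enrichment, function(e)
      if (is.null(e)) NULL else e$p_value),
    haplogroup_p = if (is.null(report$haplogroup_test)) NULL
                   else report$haplogroup_test$p_value,
    associations = report$associations,
    survival = lapply(report$survival, function(s) list(
      cutoff = s$cutoff, chi_square = s$logrank$chi_square,
      p_value = s$logrank$p_value, hazard_ratio = s$logrank$hazard_ratio,
      ci_low = s$logrank$ci_low, ci_high = s$logrank$ci_high)),
    auc = lapply(report$roc, function(r) if (is.null(r)) NULL else r$auc),
    delong_p = if (is.null(report$delong)) NULL else report$delong$p_value,
    warnings = report$warnings)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("== mtDNA mutational-load cohort report ==\n")
  cat(sprintf("patients: %d | somatic SNV calls: %d | unique variants: %d\n",
              x$n_patients, x$n_somatic_calls, x$n_unique_variants))
  if (!is.null(x$summary)) {
    cat("\n-- burden summary by Gleason category --\n")
    print(x$summary, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$spectrum)) {
    cat("\n-- substitution spectrum --\n")
    print(round(x$spectrum, 3))
  }
  if (!is.null(x$enrichment$noncoding_vs_coding)) {
    cat(sprintf("\nnoncoding vs protein-coding enrichment p = %.4g\n",
                x$enrichment$noncoding_vs_coding$p_value))
  }
  if (!is.null(x$enrichment$dloop_trna_vs_rest)) {
    cat(sprintf("D-loop+tRNA vs rest enrichment p = %.4g\n",
                x$enrichment$dloop_trna_vs_rest$p_value))
  }
  if (!is.null(x$haplogroup_test)) {
    cat(sprintf("haplogroup observed-vs-expected p = %.3f (MC)\n",
                x$haplogroup_test$p_value))
  }
  if (!is.null(x$associations)) {
    cat("\n-- burden-pathology ANOVA battery --\n")
    print(x$associations[, c("test", "slope", "f_statistic", "p_value",
                             "bonferroni_threshold",
                             "significant_bonferroni")],
          row.names = FALSE, digits = 3)
  }
  for (key in names(x$survival)) {
    s <- x$survival[[key]]
    cat(sprintf("\n-- survival, burden cutoff >= %d --\n", s$cutoff))
    print(s$logrank)
  }
  if (!is.null(x$roc)) {
    cat("\n-- relapse prediction (in-sample AUC) --\n")
    for (key in names(x$roc)) {
      if (!is.null(x$roc[[key]])) {
        cat(sprintf("  %-10s AUC = %.3f\n", key, x$roc[[key]]$auc))
      }
    }
    if (!is.null(x$delong)) {
      cat(sprintf("  DeLong gleason vs combined: p = %.4g\n",
                  x$delong$p_value))
    }
  }
  if (length(x$warnings)) {
    cat("\nwarnings:\n")
    cat(paste0("  - ", x$warnings, collapse = "\n"), "\n")
  }
  invisible(x)
}
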