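# Per-patient burden metrics: purity-adjusted allele frequencies,
# cumulative variant frequency (CVF), functional-impact flags, cohort
# summary tables, per-region variant densities and region-enrichment tests.

#' Purity-adjusted allele frequency
#'
#' Divides an observed allele frequency by the pathologist-estimated tumor
#' purity to approximate the allele frequency within tumor cells. The
#' result is deliberately NOT capped at 1: observed AFs can exceed the
#' purity estimate, so adjusted values above 1 are meaningful and reported
#' as-is.
#'
#' @param raw_af observed allele frequency in \[0, 1\].
#' @param purity tumor purity in (0, 1\].
#' @return adjusted allele frequency (may exceed 1).
#' @export
#' @examples
#' adjust_af(0.5, 0.5)  # 1
adjust_af <- function(raw_af, purity) {
  if (anyNA(purity) || any(purity <= 0) || any(purity > 1)) {
    stopf("purity-domain error: purity must lie in (0, 1]")
  }
  if (anyNA(raw_af) || any(raw_af < 0) || any(raw_af > 1)) {
    stopf("domain error: raw_af must lie in [0, 1]")
  }
  raw_af / purity
}

#' Cumulative variant frequency
#'
#' The per-patient sum of (by default purity-adjusted) somatic variant
#' allele frequencies; 0 for patients with no somatic SNVs.
#'
#' @param adjusted_afs numeric vector of one patient's adjusted AFs.
#' @return scalar CVF.
#' @export
compute_cvf <- function(adjusted_afs) {
  if (length(adjusted_afs) == 0) return(0)
  sum(adjusted_afs)
}

#' Flag variants able to impact mitochondrial function
#'
#' @param adjusted_af purity-adjusted allele frequency (>= 0).
#' @param threshold functional threshold (default 0.70, strict).
#' @return logical: TRUE iff \code{adjusted_af > threshold}.
#' @export
flag_functional <- function(adjusted_af, threshold = 0.70) {
  if (any(adjusted_af < 0)) stopf("domain error: adjusted_af must be >= 0")
  adjusted_af > threshold
}

#' Per-patient burden profiles
#'
#' Joins somatic calls to clinical purity and computes, for every patient
#' in the clinical table (including variant-free ones): SNV count, CVF,
#' functional-variant count and non-synonymous count.
#'
#' @param somatic annotated somatic-call table (may lack \code{effect}).
#' @param clinical clinical table with \code{patient_id} and \code{purity}.
#' @param cvf_definition \code{"adjusted"} (default) sums purity-adjusted
#'   AFs; \code{"raw"} sums observed somatic AFs.
#' @param functional_threshold threshold for \code{\link{flag_functional}}.
#' @return data.frame with one row per patient: \code{patient_id},
#'   \code{n_snv}, \code{cvf}, \code{n_functional}, \code{n_nonsynonymous},
#'   \code{mean_raw_af}, \code{mean_adjusted_af}.
#' @export
burden_profiles <- function(somatic, clinical, cvf_definition = "adjusted",
                            functional_threshold = 0.70) {
  cvf_definition <- match.arg(cvf_definition, c("adjusted", "raw"))
  if (nrow(somatic) > 0) {
    missing_ids <- setdiff(somatic$patient_id, clinical$patient_id)
    if (length(missing_ids) > 0) {
      stopf("join error: somatic calls without clinical record: %s",
            paste(missing_ids, collapse = ", "))
    }
  }
  profiles <- data.frame(patient_id = clinical$patient_id, n_snv = 0L,
                         cvf = 0, n_functional = 0L, n_nonsynonymous = 0L,
                         mean_raw_af = NA_real_, mean_adjusted_af = NA_real_,
                         stringsAsFactors = FALSE)
  if (nrow(somatic) == 0) return(profiles)
  purity <- clinical$purity[match(somatic$patient_id, clinical$patient_id)]
  raw <- somatic$tumor_af
  adj <- adjust_af(raw, purity)
  eff <- somatic$effect
  if (is.null(eff)) eff <- rep(NA_character_, nrow(somatic))
  for (i in seq_len(nrow(profiles))) {
    sel <- somatic$patient_id == profiles$patient_id[i]
    if (!any(sel)) next
    profiles$n_snv[i] <- sum(sel)
    profiles$cvf[i] <- compute_cvf(
      if (cvf_definition == "adjusted") adj[sel] else raw[sel])
    profiles$n_functional[i] <-
      sum(flag_functional(adj[sel], functional_threshold))
    profiles$n_nonsynonymous[i] <-
      sum(eff[sel] %in% c("non_synonymous", "stop_gain"))
    profiles$mean_raw_af[i] <- mean(raw[sel])
    profiles$mean_adjusted_af[i] <- mean(adj[sel])
  }
  profiles
}

#' Cohort burden summary by Gleason category
#'
#' Mirrors the standard cohort-characteristics layout: per Gleason category
#' (\code{<7}, \code{=7}, \code{>7}) and overall, reports total SNVs,
#' patients with at least one SNV, mean SNV count over ALL patients in the
#' category, non-synonymous SNV count, mean absolute and adjusted AF over
#' variants, and mean CVF over variant-carrying patients only.
#'
#' @param profiles output of \code{\link{burden_profiles}}.
#' @param clinical clinical table with \code{patient_id},
#'   \code{gleason_cat}.
#' @return data.frame with one row per category plus \code{ALL}.
#' @export
cohort_summary <- function(profiles, clinical) {
  missing_ids <- setdiff(profiles$patient_id, clinical$patient_id)
  if (length(missing_ids) > 0) {
    stopf("join error: profiles without clinical record: %s",
          paste(missing_ids, collapse = ", "))
  }
  cat_of <- clinical$gleason_cat[match(profiles$patient_id,
                                       clinical$patient_id)]
  cats <- c(gleason_levels(), "ALL")
  rows <- lapply(cats, function(cc) {
    sel <- if (cc == "ALL") rep(TRUE, nrow(profiles)) else cat_of == cc
    p <- profiles[sel, , drop = FALSE]
    carriers <- p$n_snv >= 1
    w <- p$n_snv # weights: per-variant means from per-patient means
    data.frame(
      category = cc,
      n_patients = nrow(p),
      total_snvs = sum(p$n_snv),
      patients_with_snv = sum(carriers),
      mean_snv_count = if (nrow(p)) mean(p$n_snv) else NA_real_,
      n_nonsynonymous = sum(p$n_nonsynonymous),
      mean_absolute_af = if (sum(w)) sum(p$mean_raw_af[carriers] *
                                           w[carriers]) / sum(w) else NA_real_,
      mean_adjusted_af = if (sum(w)) sum(p$mean_adjusted_af[carriers] *
                                           w[carriers]) / sum(w) else NA_real_,
      mean_cvf = if (any(carriers)) mean(p$cvf[carriers]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

region_class_levels <- function() {
  c("protein_coding", "rRNA", "tRNA", "control_region", "other_noncoding")
}

# total bases covered by at least one region record (overlaps counted once)
.covered_length <- function(map = build_region_map()) {
  covered <- logical(MT_GENOME_LENGTH)
  for (i in seq_len(nrow(map))) covered[map$start[i]:map$end[i]] <- TRUE
  sum(covered)
}

#' Variant density per region and per region class
#'
#' Counts UNIQUE variants (not per-patient calls) in every region-map
#' record and scales by region length (variants per 1000 bases). A variant
#' inside overlapping genes contributes one count to each containing region
#' but only once to class aggregates and genome-wide totals. The two
#' control-region segments are merged into a single D-loop row. Aggregates
#' cover the classes \code{protein_coding}, \code{rRNA}, \code{tRNA},
#' \code{control_region}, \code{other_noncoding} (intergenic spacers,
#' i.e. positions in no record) and \code{noncoding_total} (control region
#' + tRNA + other noncoding).
#'
#' @param unique_variants data.frame with a \code{position} column.
#' @param map region map.
#' @return list with \code{regions} and \code{aggregates} data.frames, each
#'   carrying \code{n_variants}, \code{length_bp}, \code{density_per_kb}.
#' @export
region_densities <- function(unique_variants, map = build_region_map()) {
  pos <- assert_mt_position(unique_variants$position)
  nm <- unique(map$name)
  regions <- do.call(rbind, lapply(nm, function(x) {
    segs <- map[map$name == x, ]
    inside <- vapply(pos, function(p) any(segs$start <= p & p <= segs$end),
                     logical(1))
    data.frame(name = x, region_class = segs$region_class[1],
               n_variants = sum(inside), length_bp = sum(segs$length_bp),
               stringsAsFactors = FALSE)
  }))
  regions$density_per_kb <- regions$n_variants * 1000 / regions$length_bp

  in_class <- function(cls) {
    segs <- map[map$region_class == cls, ]
    vapply(pos, function(p) any(segs$start <= p & p <= segs$end), logical(1))
  }
  in_any <- vapply(pos, function(p) any(map$start <= p & p <= map$end),
                   logical(1))
  class_len <- vapply(region_class_levels()[1:4], function(cls) {
    m <- map[map$region_class == cls, ]
    covered <- logical(MT_GENOME_LENGTH)
    for (i in seq_len(nrow(m))) covered[m$start[i]:m$end[i]] <- TRUE
    sum(covered)
  }, numeric(1))
  gap_len <- MT_GENOME_LENGTH - .covered_length(map)
  agg <- data.frame(
    region_class = c(region_class_levels(), "noncoding_total"),
    n_variants = c(sum(in_class("protein_coding")), sum(in_class("rRNA")),
                   sum(in_class("tRNA")), sum(in_class("control_region")),
                   sum(!in_any),
                   sum(in_class("tRNA") | in_class("control_region") |
                         !in_any)),
    length_bp = c(class_len, gap_len,
                  class_len[["tRNA"]] + class_len[["control_region"]] +
                    gap_len),
    stringsAsFactors = FALSE)
  agg$density_per_kb <- agg$n_variants * 1000 / agg$length_bp
  list(regions = regions, aggregates = agg)
}

#' Region-enrichment exact test
#'
#' Tests whether unique variants are enriched in one genome partition
#' relative to another by treating every base as a trial: the 2x2 table is
#' \[variants in A, variant-free bases in A; variants in B, variant-free
#' bases in B\], evaluated with the two-sided Fisher exact test.
#'
#' @param n_a,len_a variant count and base-pair length of partition A.
#' @param n_b,len_b variant count and base-pair length of partition B.
#' @return list from \code{\link{fisher_exact_2x2}} with the table used.
#' @export
region_enrichment_test <- function(n_a, len_a, n_b, len_b) {
  if (len_a <= 0 || len_b <= 0) {
    stopf("degenerate-partition error: both partitions need positive length")
  }
  if (n_a > len_a || n_b > len_b) {
    stopf("domain error: more variants than bases in a partition")
  }
  fisher_exact_2x2(n_a, len_a - n_a, n_b, len_b - n_b)
}
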