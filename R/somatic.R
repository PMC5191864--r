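# Somatic SNV identification from paired tumor-normal allele frequencies,
# substitution-spectrum classification, unique-variant deduplication and
# catalog-based novelty annotation.

#' Estimate an allele frequency from read counts
#'
#' Sites below the depth floor return NA (missing) and are excluded from
#' calling rather than treated as AF 0.
#'
#' @param alt_count alternate-allele read count.
#' @param total_count total read depth at the site.
#' @param min_depth minimum depth to report an AF (default 100).
#' @return numeric AF vector with NA where depth is insufficient.
#' @export
estimate_af <- function(alt_count, total_count, min_depth = 100) {
  if (any(alt_count < 0) || any(total_count < 0)) {
    stopf("count-consistency error: negative read counts")
  }
  if (any(alt_count > total_count)) {
    stopf("count-consistency error: alt_count exceeds total_count")
  }
  ifelse(total_count >= min_depth, alt_count / total_count, NA_real_)
}

#' Somatic call from a tumor-normal AF pair
#'
#' A variant is somatic iff the tumor allele frequency exceeds the normal
#' allele frequency by strictly more than \code{threshold} (tumor gains
#' only; losses, where the normal AF exceeds the tumor AF by more than the
#' threshold, are diagnostics, never somatic calls).
#'
#' @param tumor_af,normal_af allele frequencies in \[0, 1\]; no NAs.
#' @param threshold AF-difference threshold (default 0.10, strict).
#' @return logical vector.
#' @export
#' @examples
#' call_somatic(0.50, 0.00)       # TRUE
#' call_somatic(0.10, 0.00)       # FALSE: strict inequality
call_somatic <- function(tumor_af, normal_af, threshold = 0.10) {
  if (anyNA(tumor_af) || anyNA(normal_af)) {
    stopf("incomplete-pair error: missing allele frequency")
  }
  if (any(tumor_af < 0 | tumor_af > 1) || any(normal_af < 0 | normal_af > 1)) {
    stopf("domain error: allele frequencies must lie in [0, 1]")
  }
  tumor_af - normal_af > threshold
}

#' Pyrimidine-strand substitution class
#'
#' Purine-reference substitutions are collapsed to their reverse complement
#' so every substitution is reported with a pyrimidine reference base, one
#' of C>T, T>C, C>A, C>G, T>A, T>G; transitions are C>T and T>C.
#'
#' @param ref,alt single reference/alternate bases.
#' @return list with \code{class} and \code{is_transition}.
#' @export
classify_substitution <- function(ref, alt) {
  assert_base(ref, "ref"); assert_base(alt, "alt")
  if (any(ref == alt)) stopf("ref and alt must differ")
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, comp_base(ref), ref)
  a <- ifelse(purine, comp_base(alt), alt)
  cls <- paste0(r, ">", a)
  list(class = cls, is_transition = cls %in% c("C>T", "T>C"))
}

substitution_classes <- function() c("C>T", "T>C", "C>A", "C>G", "T>A", "T>G")

#' Call and annotate somatic SNVs over a paired variant table
#'
#' Applies \code{\link{call_somatic}} row-wise, attaches the somatic AF,
#' pyrimidine-strand substitution class, region memberships and coding
#' effect, and splits off an allele-loss diagnostics stream. Input rows may
#' carry allele frequencies directly (\code{tumor_af}, \code{normal_af}) or
#' read counts (\code{tumor_alt}, \code{tumor_depth}, \code{normal_alt},
#' \code{normal_depth}), from which AFs are estimated with the depth floor;
#' sites with a missing AF on either side are excluded and counted.
#'
#' @param calls data.frame with \code{patient_id}, \code{position},
#'   \code{ref}, \code{alt} and AF or count columns.
#' @param threshold somatic AF-difference threshold.
#' @param min_depth depth floor for AF estimation from counts.
#' @param check_reference verify ref bases against the packaged sequence
#'   when annotating effects (disable for externally-referenced data).
#' @return list with \code{somatic} (annotated calls), \code{losses}
#'   (diagnostics), \code{n_excluded_low_depth}.
#' @export
call_somatic_variants <- function(calls, threshold = 0.10, min_depth = 100,
                                  check_reference = TRUE) {
  needed <- c("patient_id", "position", "ref", "alt")
  if (!all(needed %in% names(calls))) {
    stopf("input error: calls must have columns %s",
          paste(needed, collapse = ", "))
  }
  calls$position <- assert_mt_position(calls$position)
  if (!("tumor_af" %in% names(calls)) || anyNA(calls$tumor_af)) {
    if (!all(c("tumor_alt", "tumor_depth") %in% names(calls))) {
      stopf("input error: need tumor_af or tumor_alt/tumor_depth")
    }
    calls$tumor_af <- estimate_af(calls$tumor_alt, calls$tumor_depth,
                                  min_depth)
    calls$normal_af <- estimate_af(calls$normal_alt, calls$normal_depth,
                                   min_depth)
  }
  complete <- !is.na(calls$tumor_af) & !is.na(calls$normal_af)
  n_excluded <- sum(!complete)
  calls <- calls[complete, , drop = FALSE]
  if (nrow(calls) == 0) {
    empty <- calls
    return(list(somatic = empty, losses = empty,
                n_excluded_low_depth = n_excluded))
  }
  somatic_flag <- call_somatic(calls$tumor_af, calls$normal_af, threshold)
  loss_flag <- calls$normal_af - calls$tumor_af > threshold
  somatic <- calls[somatic_flag, , drop = FALSE]
  if (nrow(somatic) > 0) {
    somatic$somatic_af <- somatic$tumor_af - somatic$normal_af
    sub <- classify_substitution(somatic$ref, somatic$alt)
    somatic$substitution_class <- sub$class
    somatic$is_transition <- sub$is_transition
    somatic$region <- locate_names(somatic$position)
    if (check_reference) {
      somatic$effect <- mapply(classify_effect, somatic$position,
                               somatic$ref, somatic$alt)
    } else {
      coding <- vapply(somatic$position, function(p) {
        any(locate(p)$region_class == "protein_coding")
      }, logical(1))
      somatic$effect <- ifelse(coding, NA_character_, "noncoding")
    }
  }
  list(somatic = somatic, losses = calls[loss_flag, , drop = FALSE],
       n_excluded_low_depth = n_excluded)
}

#' Deduplicate somatic calls into unique variants
#'
#' Unique variants are keyed by (position, ref, alt); the recurrence count
#' of a unique variant is the number of patients carrying it. Duplicate
#' (patient, position, ref, alt) rows are input errors.
#'
#' @param calls data.frame of somatic calls with \code{patient_id},
#'   \code{position}, \code{ref}, \code{alt}.
#' @return data.frame of unique variants with a \code{recurrence} column,
#'   ordered by position.
#' @export
deduplicate <- function(calls) {
  if (nrow(calls) == 0) {
    return(data.frame(position = integer(0), ref = character(0),
                      alt = character(0), recurrence = integer(0)))
  }
  pkey <- paste(calls$patient_id, calls$position, calls$ref, calls$alt)
  if (anyDuplicated(pkey)) {
    stopf("input-duplication error: duplicated (patient, position, ref, alt) rows: %s",
          paste(utils::head(pkey[duplicated(pkey)], 3), collapse = "; "))
  }
  key <- paste(calls$position, calls$ref, calls$alt)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  first <- calls[!duplicated(key), c("position", "ref", "alt")]
  first$recurrence <- agg$Freq[match(paste(first$position, first$ref,
                                           first$alt), agg$key)]
  first <- first[order(first$position, first$ref, first$alt), ]
  rownames(first) <- NULL
  first
}

novelty_levels <- function() {
  c("known_prostate", "known_cancer", "known_disease", "novel")
}

#' Annotate unique variants against a variant catalog
#'
#' Each unique variant receives the most specific catalog context it
#' matches (prostate > cancer > disease); unmatched variants are novel.
#' Malformed catalog rows are skipped with a warning and counted.
#'
#' @param unique_variants data.frame with \code{position}, \code{ref},
#'   \code{alt}.
#' @param catalog data.frame with \code{position}, \code{ref}, \code{alt},
#'   \code{context} in \{prostate, cancer, disease\}; may have zero rows.
#' @return the input with a \code{novelty} factor column; the number of
#'   skipped catalog rows is attached as attribute \code{n_skipped}.
#' @export
annotate_novelty <- function(unique_variants, catalog) {
  if (is.null(catalog) || nrow(catalog) == 0) {
    unique_variants$novelty <- factor(rep("novel", nrow(unique_variants)),
                                      levels = novelty_levels())
    attr(unique_variants, "n_skipped") <- 0L
    return(unique_variants)
  }
  ok <- !is.na(catalog$position) & catalog$position >= 1 &
    catalog$position <= MT_GENOME_LENGTH &
    catalog$ref %in% c("A", "C", "G", "T") &
    catalog$alt %in% c("A", "C", "G", "T") &
    catalog$context %in% c("prostate", "cancer", "disease")
  if (any(!ok)) {
    warnf("annotate_novelty: skipped %d malformed catalog row(s)", sum(!ok))
  }
  catalog <- catalog[ok, , drop = FALSE]
  rank_of <- c(prostate = 1, cancer = 2, disease = 3)
  vkey <- paste(unique_variants$position, unique_variants$ref,
                unique_variants$alt)
  ckey <- paste(catalog$position, catalog$ref, catalog$alt)
  lab <- vapply(vkey, function(k) {
    hits <- catalog$context[ckey == k]
    if (length(hits) == 0) return("novel")
    c("known_prostate", "known_cancer",
      "known_disease")[min(rank_of[hits])]
  }, character(1))
  unique_variants$novelty <- factor(unname(lab), levels = novelty_levels())
  attr(unique_variants, "n_skipped") <- sum(!ok)
  unique_variants
}

#' Substitution-spectrum proportions
#'
#' @param somatic data.frame of somatic variants carrying \code{ref} and
#'   \code{alt} (or a precomputed \code{substitution_class}).
#' @return named numeric vector of proportions over the six
#'   pyrimidine-strand classes (sums to 1).
#' @export
spectrum_summary <- function(somatic) {
  if (nrow(somatic) == 0) {
    stopf("empty-set error: spectrum_summary needs at least one variant")
  }
  cls <- somatic$substitution_class
  if (is.null(cls)) cls <- classify_substitution(somatic$ref, somatic$alt)$class
  counts <- table(factor(cls, levels = substitution_classes()))
  stats::setNames(as.numeric(counts) / sum(counts), substitution_classes())
}
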