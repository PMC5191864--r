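# File formats: TSV tables with commented parameter headers, minimal
# per-patient VCF 4.2 emission, VCF ingestion (via VariantAnnotation),
# variant catalogs and truth JSON.

#' Write a table as TSV with commented header lines
#'
#' @param x data.frame.
#' @param path output path.
#' @param comments character vector written as \code{# }-prefixed lines
#'   (used to record parameters and seeds).
#' @export
write_tsv <- function(x, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments) > 0) writeLines(paste0("# ", comments), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by \code{write_tsv}
#' @param path input path.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a paired tumor-normal variant table
#'
#' Expects columns \code{patient_id}, \code{position}, \code{ref},
#' \code{alt} and either AF columns (\code{tumor_af}, \code{normal_af}) or
#' count columns (\code{tumor_alt}, \code{tumor_depth}, \code{normal_alt},
#' \code{normal_depth}).
#'
#' @param path TSV path.
#' @export
read_paired_variants <- function(path) {
  x <- read_tsv(path)
  needed <- c("patient_id", "position", "ref", "alt")
  if (!all(needed %in% names(x))) {
    stopf("input error: %s lacks columns %s", path,
          paste(setdiff(needed, names(x)), collapse = ", "))
  }
  x
}

#' Read a variant catalog TSV
#'
#' Columns: \code{position}, \code{ref}, \code{alt}, \code{context}.
#' @param path TSV path.
#' @export
read_catalog <- function(path) {
  x <- read_tsv(path)
  for (col in c("position", "ref", "alt", "context")) {
    if (!(col %in% names(x))) x[[col]] <- NA
  }
  x
}

#' Write one patient pair as minimal VCF 4.2
#'
#' Emits a two-sample (TUMOR, NORMAL) VCF with FORMAT fields \code{AF} and
#' \code{AD} on the mitochondrial contig.
#'
#' @param calls rows for one patient (\code{position}, \code{ref},
#'   \code{alt}, \code{tumor_af}, \code{normal_af}, optional count
#'   columns).
#' @param patient_id sample identifier.
#' @param path output path.
#' @param seed seed recorded in the header.
#' @export
write_pair_vcf <- function(calls, patient_id, path, seed = NA) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chrM,length=%d>", MT_GENOME_LENGTH),
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    sprintf("##mitoburden_patient=%s", patient_id),
    if (!is.na(seed)) sprintf("##mitoburden_seed=%s", seed),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR", "NORMAL", sep = "\t"))
  fmt_sample <- function(af, alt, depth) {
    if (is.null(alt) || anyNA(alt)) {
      sprintf("%.6g", af)
    } else {
      sprintf("%.6g:%d,%d", af, depth - alt, alt)
    }
  }
  has_ad <- all(c("tumor_alt", "tumor_depth", "normal_alt",
                  "normal_depth") %in% names(calls))
  body <- vapply(seq_len(nrow(calls)), function(i) {
    paste("chrM", calls$position[i], ".", calls$ref[i], calls$alt[i], ".",
          "PASS", ".",
          if (has_ad) "AF:AD" else "AF",
          if (has_ad) fmt_sample(calls$tumor_af[i], calls$tumor_alt[i],
                                 calls$tumor_depth[i])
          else fmt_sample(calls$tumor_af[i], NULL, NULL),
          if (has_ad) fmt_sample(calls$normal_af[i], calls$normal_alt[i],
                                 calls$normal_depth[i])
          else fmt_sample(calls$normal_af[i], NULL, NULL),
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a paired VCF back into a variant table
#'
#' Uses VariantAnnotation to parse VCF 4.2; allele frequencies are taken
#' from the per-sample \code{AF} FORMAT field, or recomputed from \code{AD}
#' when \code{AF} is absent. Indels are parsed but flagged so downstream
#' burden statistics can exclude them.
#'
#' @param path VCF path.
#' @param patient_id patient identifier to attach (default: from the
#'   \code{##mitoburden_patient} header when present).
#' @return data.frame in \code{read_paired_variants} layout with an
#'   \code{is_snv} column.
#' @export
read_pair_vcf <- function(path, patient_id = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stopf("reading VCF requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  if (is.null(patient_id)) {
    meta_lines <- readLines(path, n = 50)
    m <- grep("^##mitoburden_patient=", meta_lines, value = TRUE)
    patient_id <- if (length(m)) sub("^##mitoburden_patient=", "", m[1])
                  else "unknown"
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- vapply(as.list(rr$ALT), function(a) as.character(a)[1], character(1))
  geno <- VariantAnnotation::geno(vcf)
  samples <- colnames(vcf)
  get_af <- function(sample) {
    if ("AF" %in% names(geno)) {
      as.numeric(geno$AF[, sample])
    } else if ("AD" %in% names(geno)) {
      vapply(geno$AD[, sample], function(ad) ad[2] / sum(ad), numeric(1))
    } else {
      stopf("input error: VCF %s has neither AF nor AD FORMAT fields", path)
    }
  }
  data.frame(patient_id = patient_id,
             position = as.integer(GenomicRanges::start(rr)),
             ref = ref, alt = alt,
             tumor_af = get_af(samples[1]),
             normal_af = get_af(samples[2]),
             is_snv = nchar(ref) == 1 & nchar(alt) == 1,
             stringsAsFactors = FALSE)
}

#' Write cohort truth as JSON
#' @param cohort a \code{mito_cohort}.
#' @param path output path.
#' @export
write_truth_json <- function(cohort, path) {
  jsonlite::write_json(
    list(seed = cohort$config$seed,
         patients = cohort$truth$patients,
         variants = cohort$truth$variants),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
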