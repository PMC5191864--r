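# Mitochondrial reference annotation: region map on rCRS coordinates,
# vertebrate mitochondrial genetic code, position lookup and single-codon
# effect classification.

.ref_cache <- new.env(parent = emptyenv())

#' Mitochondrial region map
#'
#' Returns the packaged map of all 37 mitochondrial genes (13 protein-coding,
#' 2 rRNA, 22 tRNA) plus the control region, on 1-based inclusive rCRS
#' (NC_012920) coordinates. The control region wraps the replication origin
#' and is represented as two segments (16024-16569 and 1-576) sharing the
#' name \code{D-loop}. Positions not covered by any record are intergenic
#' spacers ("other noncoding"); together with the records they tile the
#' 16,569 bp genome.
#'
#' @return A data.frame with columns \code{name}, \code{region_class}
#'   (one of \code{protein_coding}, \code{rRNA}, \code{tRNA},
#'   \code{control_region}), \code{start}, \code{end}, \code{strand}
#'   (\code{heavy}/\code{light}), \code{codon_offset} (0-2, protein-coding
#'   records only) and \code{length_bp}.
#' @export
#' @examples
#' map <- build_region_map()
#' table(map$region_class)
build_region_map <- function() {
  if (!is.null(.ref_cache$map)) return(.ref_cache$map)
  path <- system.file("extdata", "rcrs_regions.tsv", package = "mitoburden",
                      mustWork = TRUE)
  map <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  map$start <- as.integer(map$start)
  map$end <- as.integer(map$end)
  map$codon_offset <- suppressWarnings(as.integer(map$codon_offset))
  map$length_bp <- map$end - map$start + 1L
  stopifnot(all(map$start >= 1), all(map$end <= MT_GENOME_LENGTH),
            all(map$start <= map$end))
  .ref_cache$map <- map
  map
}

#' Vertebrate mitochondrial genetic code
#'
#' The full 64-codon table (NCBI translation table 2): relative to the
#' standard code, \code{TGA} codes tryptophan, \code{ATA} codes methionine
#' and \code{AGA}/\code{AGG} are stop codons, giving exactly four stops
#' (\code{TAA}, \code{TAG}, \code{AGA}, \code{AGG}).
#'
#' @return Named character vector mapping every codon to a one-letter amino
#'   acid, with \code{"*"} for stop.
#' @export
mito_genetic_code <- function() {
  if (!is.null(.ref_cache$code)) return(.ref_cache$code)
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CCWW", # TTT..TGG
    "LLLLPPPPHHQQRRRR", # CTT..CGG
    "IIMMTTTTNNKKSS**", # ATT..AGG
    "VVVVAAAADDEEGGGG"  # GTT..GGG
  ), "")[[1]]
  code <- stats::setNames(aa, codons)
  .ref_cache$code <- code
  code
}

#' Packaged mitochondrial reference sequence
#'
#' Loads the reference sequence shipped with the package. NOTE: this is a
#' synthetic stand-in for rCRS, not the NC_012920 nucleotide sequence: it
#' uses the true NC_012920 gene coordinates but computer-generated bases,
#' constrained so that every protein-coding gene carries a start codon, a
#' stop-free internal reading frame, and the documented complete or
#' incomplete terminal stop codon (see \code{\link{build_synthetic_rcrs}}).
#'
#' @param as_string if TRUE (default) return a single character string,
#'   otherwise a \code{Biostrings::DNAStringSet}.
#' @return the 16,569 bp reference sequence.
#' @export
rcrs_sequence <- function(as_string = TRUE) {
  if (is.null(.ref_cache$seq)) {
    path <- system.file("extdata", "rcrs_synthetic.fa", package = "mitoburden",
                        mustWork = TRUE)
    dss <- Biostrings::readDNAStringSet(path)
    stopifnot(length(dss) == 1, Biostrings::width(dss) == MT_GENOME_LENGTH)
    .ref_cache$seq <- dss
    .ref_cache$seq_chars <- strsplit(as.character(dss[[1]]), "")[[1]]
  }
  if (as_string) as.character(.ref_cache$seq[[1]]) else .ref_cache$seq
}

# character-vector view of the reference, cached
rcrs_chars <- function() {
  rcrs_sequence()
  .ref_cache$seq_chars
}

#' Locate mitochondrial positions in the region map
#'
#' Returns every region-map record containing a position. Positions inside
#' overlapping gene pairs (e.g. ATP8/ATP6) return one row per gene; the
#' wrapped control region is matched through either of its segments;
#' intergenic spacer positions return a zero-row data.frame.
#'
#' @param position a single 1-based rCRS position.
#' @param map region map, defaults to \code{build_region_map()}.
#' @return data.frame of matching region records (possibly zero rows).
#' @export
#' @examples
#' locate(16093)$name   # "D-loop"
locate <- function(position, map = build_region_map()) {
  if (length(position) != 1) stopf("locate() takes a single position")
  position <- assert_mt_position(position)
  map[map$start <= position & position <= map$end, , drop = FALSE]
}

# region names (comma-joined) for a vector of positions; "" for spacers
locate_names <- function(positions, map = build_region_map()) {
  vapply(positions, function(p) {
    hits <- map$name[map$start <= p & p <= map$end]
    paste(unique(hits), collapse = ",")
  }, character(1))
}

# Extract the complete codon containing `position` for one protein-coding
# record, in coding orientation. Returns NULL when the position falls in an
# incomplete terminal codon (post-transcriptionally completed stop).
codon_at <- function(rec, position, seq_chars = rcrs_chars()) {
  if (rec$strand == "heavy") {
    off <- position - rec$start - rec$codon_offset
    cstart <- rec$start + rec$codon_offset + 3L * (off %/% 3L)
    if (cstart + 2L > rec$end) return(NULL)
    idx <- cstart:(cstart + 2L)
    list(codon = seq_chars[idx], within = off %% 3L + 1L, idx = idx,
         strand = "heavy")
  } else {
    off <- rec$end - position - rec$codon_offset
    cstart <- rec$end - rec$codon_offset - 3L * (off %/% 3L)
    if (cstart - 2L < rec$start) return(NULL)
    idx <- cstart:(cstart - 2L) # descending genomic order = coding order
    list(codon = comp_base(seq_chars[idx]), within = off %% 3L + 1L,
         idx = idx, strand = "light")
  }
}

#' Classify the coding effect of a single-nucleotide substitution
#'
#' Translates the codon containing the position before and after the
#' substitution under the vertebrate mitochondrial code, strand-aware
#' (light-strand genes are read on the reverse complement). Positions
#' outside protein-coding genes classify as \code{noncoding}, as do
#' positions inside documented incomplete terminal stop codons (no complete
#' codon exists in the reference). For positions in overlapping genes the
#' most severe effect is returned (\code{stop_gain} > \code{non_synonymous}
#' > \code{synonymous}).
#'
#' @param position 1-based rCRS position.
#' @param ref_base reference base (checked against the packaged sequence).
#' @param alt_base substituted base.
#' @param map region map.
#' @param seq_chars reference sequence as a character vector.
#' @return one of \code{"synonymous"}, \code{"non_synonymous"},
#'   \code{"stop_gain"}, \code{"noncoding"}.
#' @export
classify_effect <- function(position, ref_base, alt_base,
                            map = build_region_map(),
                            seq_chars = rcrs_chars()) {
  position <- assert_mt_position(position)
  assert_base(ref_base, "ref_base")
  assert_base(alt_base, "alt_base")
  if (ref_base == alt_base) stopf("ref_base and alt_base must differ")
  if (seq_chars[position] != ref_base) {
    stopf("reference-consistency error: position %d is '%s' in the packaged reference, not '%s'",
          position, seq_chars[position], ref_base)
  }
  hits <- map[map$region_class == "protein_coding" &
                map$start <= position & position <= map$end, , drop = FALSE]
  if (nrow(hits) == 0) return("noncoding")
  code <- mito_genetic_code()
  effects <- character(0)
  for (i in seq_len(nrow(hits))) {
    cd <- codon_at(hits[i, ], position, seq_chars)
    if (is.null(cd)) next
    ref_codon <- cd$codon
    alt_codon <- ref_codon
    alt_codon[cd$within] <-
      if (cd$strand == "heavy") alt_base else comp_base(alt_base)
    aa_ref <- code[[paste(ref_codon, collapse = "")]]
    aa_alt <- code[[paste(alt_codon, collapse = "")]]
    effects <- c(effects,
      if (aa_ref == aa_alt) "synonymous"
      else if (aa_alt == "*") "stop_gain"
      else "non_synonymous")
  }
  if (length(effects) == 0) return("noncoding")
  severity <- c(stop_gain = 3, non_synonymous = 2, synonymous = 1)
  names(which.max(severity[effects]))
}

# Translate the full coding sequence of one protein-coding record (complete
# codons only; the incomplete terminal base(s), if any, are dropped).
translate_gene <- function(name, map = build_region_map(),
                           seq_chars = rcrs_chars()) {
  rec <- map[map$name == name & map$region_class == "protein_coding", ]
  if (nrow(rec) != 1) stopf("unknown protein-coding gene '%s'", name)
  chars <- seq_chars[rec$start:rec$end]
  if (rec$strand == "light") chars <- revcomp_chars(chars)
  if (rec$codon_offset > 0) chars <- chars[-seq_len(rec$codon_offset)]
  ncod <- length(chars) %/% 3
  codons <- vapply(seq_len(ncod), function(i) {
    paste(chars[(3 * i - 2):(3 * i)], collapse = "")
  }, character(1))
  unname(mito_genetic_code()[codons])
}

# Documented remainder (0/1/2 trailing bases) of each coding gene's span
# after whole codons: nonzero values are the incomplete stop codons that are
# completed by polyadenylation and are never silently "corrected".
incomplete_stop_metadata <- function(map = build_region_map()) {
  coding <- map[map$region_class == "protein_coding", ]
  data.frame(name = coding$name,
             remainder = (coding$length_bp - coding$codon_offset) %% 3L,
             stringsAsFactors = FALSE)
}
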