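# Synthetic paired tumor-normal cohort generator with known truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: Poisson per-patient somatic SNV burden with Gleason-dependent
# means, heteroplasmic allele frequencies drawn in tumor-cell-fraction
# space from a truncated Beta and multiplied by the pathologist-estimated
# purity to give observed tumor AFs, and exponential relapse times under
# burden-indexed proportional hazards with administrative censoring.

# inverse-CDF draw from Beta(shape[1], shape[2]) truncated to [lo, hi]
rbeta_trunc <- function(n, shape, lo, hi) {
  plo <- stats::pbeta(lo, shape[1], shape[2])
  phi <- stats::pbeta(hi, shape[1], shape[2])
  stats::qbeta(stats::runif(n, plo, phi), shape[1], shape[2])
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults restate the observed cohort structure: 115 patients split
#' 26/40/49 over the Gleason categories \code{<7}, \code{=7}, \code{>7};
#' per-category Poisson burden means 0.23/0.68/0.88; tumor-cell-fraction
#' allele frequencies from Beta(3, 1) truncated to [0.12, 1]; per-category
#' purity means 0.47/0.60/0.60 on the range [0.05, 0.85]; a 2.17-fold
#' relapse hazard for patients carrying at least one somatic SNV; and
#' administrative censoring drawn uniformly over 24-150 months.
#'
#' @param n_patients cohort size (>= 2).
#' @param gleason_probs probabilities of the three Gleason categories.
#' @param burden_means per-category Poisson means for the SNV count.
#' @param raw_af_shape Beta shape parameters of the tumor-cell-fraction AF.
#' @param raw_af_range truncation interval of the AF distribution.
#' @param purity_shapes list of three Beta shape pairs, one per category.
#' @param purity_range truncation interval of the purity distribution.
#' @param normal_contamination_af blood-side background AF (default 0).
#' @param baseline_hazard per-month relapse hazard of burden-free patients.
#' @param hazard_ratio hazard multiplier for patients with >= 1 SNV.
#' @param censor_window (min, max) of administrative censoring, months.
#' @param depth mean sequencing depth used by \code{emit_allele_counts}.
#' @param n_null_sites variant-free sites added by \code{emit_allele_counts}.
#' @param hotspot_fraction fraction of variant positions concentrated into
#'   the control region and tRNA genes (0 = uniform over the genome).
#' @param haplogroup_freqs named sampling frequencies for haplogroup labels.
#' @param seed master integer seed.
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 115,
                          gleason_probs = c(26, 40, 49) / 115,
                          burden_means = c(0.23, 0.68, 0.88),
                          raw_af_shape = c(3, 1),
                          raw_af_range = c(0.12, 1),
                          purity_shapes = list(c(3.6, 4.0), c(5.8, 3.9),
                                               c(5.8, 3.9)),
                          purity_range = c(0.05, 0.85),
                          normal_contamination_af = 0,
                          baseline_hazard = 0.004,
                          hazard_ratio = 2.17,
                          censor_window = c(24, 150),
                          depth = 2000,
                          n_null_sites = 50,
                          hotspot_fraction = 0,
                          haplogroup_freqs = c(H = 0.43, U = 0.14, T = 0.09,
                                               J = 0.11, K = 0.08,
                                               other = 0.15),
                          seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$gleason_probs) - 1) > 1e-9) {
    stopf("config error: gleason_probs must sum to 1")
  }
  if (length(cfg$burden_means) != 3 || any(cfg$burden_means < 0)) {
    stopf("config error: burden_means must be three nonnegative values")
  }
  if (cfg$baseline_hazard <= 0 || cfg$depth <= 0) {
    stopf("config error: rates and depths must be positive")
  }
  if (cfg$normal_contamination_af < 0 || cfg$normal_contamination_af >= 1) {
    stopf("config error: normal_contamination_af must lie in [0, 1)")
  }
  if (cfg$hotspot_fraction < 0 || cfg$hotspot_fraction > 1) {
    stopf("config error: hotspot_fraction must lie in [0, 1]")
  }
  cfg$haplogroup_freqs <- cfg$haplogroup_freqs / sum(cfg$haplogroup_freqs)
  class(cfg) <- "cohort_config"
  cfg
}

gleason_levels <- function() c("<7", "=7", ">7")

# candidate positions for the hotspot option: control region + tRNA genes
.hotspot_positions <- function(map = build_region_map()) {
  rows <- map[map$region_class %in% c("control_region", "tRNA"), ]
  unique(unlist(mapply(seq, rows$start, rows$end, SIMPLIFY = FALSE)))
}

#' Simulate a paired tumor-normal mtDNA cohort
#'
#' Per patient: draws a Gleason category, a purity, a Poisson somatic SNV
#' count, variant positions (uniform over the genome, or partially
#' concentrated into control region/tRNAs when
#' \code{hotspot_fraction > 0}; reference bases from the packaged
#' sequence, alternates uniform over the remaining bases), a
#' tumor-cell-fraction AF per variant (observed tumor AF = AF x purity),
#' and an exponential relapse time with hazard
#' \code{baseline_hazard * hazard_ratio^(n_snv >= 1)} censored at an
#' administrative time from \code{censor_window}. Deterministic given the
#' config seed.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return object of class \code{mito_cohort}: list with \code{clinical}
#'   (one row per patient), \code{calls} (paired observed AFs, one row per
#'   somatic variant), \code{truth} (list of per-patient truth data.frames:
#'   \code{patients}, \code{variants}) and the \code{config}.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  if (n < 2) stopf("degenerate-cohort error: n_patients must be >= 2")
  seq_chars <- rcrs_chars()
  bases <- c("A", "C", "G", "T")
  hotspots <- if (config$hotspot_fraction > 0) .hotspot_positions() else NULL

  withr::with_seed(substream_seed(config$seed, "cohort"), {
    pid <- sprintf("P%03d", seq_len(n))
    cat_idx <- sample.int(3, n, replace = TRUE, prob = config$gleason_probs)
    purity <- vapply(cat_idx, function(ci) {
      rbeta_trunc(1, config$purity_shapes[[ci]],
                  config$purity_range[1], config$purity_range[2])
    }, numeric(1))
    k <- stats::rpois(n, config$burden_means[cat_idx])
    gleason_rp <- ifelse(cat_idx == 1, 6,
                  ifelse(cat_idx == 2, 7,
                         sample(8:10, n, replace = TRUE,
                                prob = c(0.6, 0.3, 0.1))))
    # biopsy-core category mostly agrees with the prostatectomy category
    shift <- sample(c(0L, -1L, 1L), n, replace = TRUE,
                    prob = c(0.7, 0.15, 0.15))
    biopsy_idx <- pmin(pmax(cat_idx + shift, 1L), 3L)
    age <- pmin(pmax(round(stats::rnorm(n, 61, 6)), 46), 75)
    psa <- round(pmin(pmax(stats::rlnorm(n, log(7.5), 0.4), 2.43), 18.6), 2)
    haplogroup <- sample(names(config$haplogroup_freqs), n, replace = TRUE,
                         prob = config$haplogroup_freqs)
    rate <- config$baseline_hazard * config$hazard_ratio^(k >= 1)
    t_event <- stats::rexp(n, rate)
    c_admin <- stats::runif(n, config$censor_window[1], config$censor_window[2])
    event <- as.integer(t_event <= c_admin)
    time_months <- pmax(round(pmin(t_event, c_admin), 2), 0.01)

    variants <- vector("list", n)
    for (i in seq_len(n)) {
      if (k[i] == 0) next
      if (!is.null(hotspots)) {
        pos <- integer(0)
        while (length(pos) < k[i]) { # distinct positions within a patient
          cand <- if (stats::runif(1) < config$hotspot_fraction) {
            sample(hotspots, 1)
          } else {
            sample.int(MT_GENOME_LENGTH, 1)
          }
          pos <- union(pos, cand)
        }
      } else {
        pos <- sample.int(MT_GENOME_LENGTH, k[i])
      }
      pos <- sort(pos)
      ref <- seq_chars[pos]
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
      true_af <- rbeta_trunc(k[i], config$raw_af_shape,
                             config$raw_af_range[1], config$raw_af_range[2])
      variants[[i]] <- data.frame(
        patient_id = pid[i], position = pos, ref = ref, alt = alt,
        true_af = true_af,
        tumor_af = true_af * purity[i],
        normal_af = config$normal_contamination_af,
        stringsAsFactors = FALSE, row.names = NULL)
    }
    truth_variants <- do.call(rbind, variants[!vapply(variants, is.null,
                                                      logical(1))])
    if (is.null(truth_variants)) {
      truth_variants <- data.frame(patient_id = character(0),
                                   position = integer(0), ref = character(0),
                                   alt = character(0), true_af = numeric(0),
                                   tumor_af = numeric(0),
                                   normal_af = numeric(0))
    }
    clinical <- data.frame(
      patient_id = pid, age = age, psa = psa,
      gleason_rp = gleason_rp,
      gleason_cat = factor(gleason_levels()[cat_idx],
                           levels = gleason_levels()),
      gleason_biopsy_cat = factor(gleason_levels()[biopsy_idx],
                                  levels = gleason_levels()),
      purity = round(purity, 3),
      haplogroup = haplogroup,
      follow_up_months = time_months,
      relapse = event,
      relapse_month = ifelse(event == 1L, time_months, NA_real_),
      stringsAsFactors = FALSE)
    truth_patients <- data.frame(
      patient_id = pid, gleason_cat = gleason_levels()[cat_idx],
      purity = purity, n_snv = k,
      relapse_time = t_event, censor_time = c_admin,
      censored = 1L - event, stringsAsFactors = FALSE)

    calls <- truth_variants[, c("patient_id", "position", "ref", "alt",
                                "tumor_af", "normal_af")]
    out <- list(clinical = clinical, calls = calls,
                truth = list(patients = truth_patients,
                             variants = truth_variants),
                config = config)
    class(out) <- "mito_cohort"
    out
  })
}

#' @export
print.mito_cohort <- function(x, ...) {
  cat(sprintf("Synthetic mtDNA cohort: %d patients, %d somatic variants, seed %d\n",
              nrow(x$clinical), nrow(x$calls), x$config$seed))
  invisible(x)
}

#' Emit site-level allele counts from cohort truth
#'
#' Converts true allele frequencies into binomial read counts so the
#' somatic caller can be exercised from raw counts: per sample,
#' \code{alt_reads ~ Binomial(depth, AF)}. All truth sites are emitted,
#' plus \code{n_null_sites} variant-free sites with AF 0 in both samples
#' assigned to random patients. Deterministic given the config seed.
#'
#' @param cohort a \code{mito_cohort}.
#' @param depth sequencing depth (defaults to the config value).
#' @param n_null_sites number of null sites (defaults to the config value).
#' @return data.frame with columns \code{patient_id}, \code{position},
#'   \code{ref}, \code{alt}, \code{tumor_alt}, \code{tumor_depth},
#'   \code{normal_alt}, \code{normal_depth}, \code{is_null_site}.
#' @export
emit_allele_counts <- function(cohort, depth = NULL, n_null_sites = NULL) {
  stopifnot(inherits(cohort, "mito_cohort"))
  config <- cohort$config
  depth <- as.integer(depth %||% config$depth)
  n_null_sites <- as.integer(n_null_sites %||% config$n_null_sites)
  if (depth <= 0) stopf("config error: depth must be positive")
  tv <- cohort$truth$variants
  seq_chars <- rcrs_chars()
  bases <- c("A", "C", "G", "T")

  withr::with_seed(substream_seed(config$seed, "counts"), {
    site <- tv[, c("patient_id", "position", "ref", "alt")]
    site$true_tumor_af <- tv$tumor_af
    site$true_normal_af <- tv$normal_af
    site$is_null_site <- rep(FALSE, nrow(site))
    if (n_null_sites > 0) {
      np <- sample(cohort$clinical$patient_id, n_null_sites, replace = TRUE)
      pos <- sample.int(MT_GENOME_LENGTH, n_null_sites, replace = TRUE)
      # avoid colliding with a true variant site of the same patient
      clash <- paste(np, pos) %in% paste(tv$patient_id, tv$position)
      while (any(clash)) {
        pos[clash] <- sample.int(MT_GENOME_LENGTH, sum(clash), replace = TRUE)
        clash <- paste(np, pos) %in% paste(tv$patient_id, tv$position)
      }
      ref <- seq_chars[pos]
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
      null_site <- data.frame(patient_id = np, position = pos, ref = ref,
                              alt = alt, true_tumor_af = 0,
                              true_normal_af = 0, is_null_site = TRUE,
                              stringsAsFactors = FALSE)
      site <- rbind(site, null_site)
    }
    site$tumor_alt <- stats::rbinom(nrow(site), depth, site$true_tumor_af)
    site$tumor_depth <- depth
    site$normal_alt <- stats::rbinom(nrow(site), depth, site$true_normal_af)
    site$normal_depth <- depth
    site[order(site$patient_id, site$position),
         c("patient_id", "position", "ref", "alt", "tumor_alt",
           "tumor_depth", "normal_alt", "normal_depth", "is_null_site")]
  })
}
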