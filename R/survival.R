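# Kaplan-Meier estimation, log-rank test with Mantel-Haenszel hazard ratio,
# burden dichotomization and the biochemical-relapse event rule.

#' Kaplan-Meier product-limit estimate
#'
#' @param time_months positive follow-up or event times.
#' @param event 0/1 event indicators (1 = relapse).
#' @return data.frame with one row per distinct event time: \code{time},
#'   \code{n_risk}, \code{n_event}, \code{survival}. Survival starts at 1;
#'   censored times reduce the risk set without producing steps.
#' @export
km_estimate <- function(time_months, event) {
  time_months <- as.numeric(time_months)
  event <- as.integer(event)
  if (length(time_months) < 1) stopf("km_estimate needs at least one sample")
  if (any(is.na(time_months)) || any(time_months <= 0)) {
    stopf("domain error: times must be positive")
  }
  if (!all(event %in% c(0L, 1L))) stopf("domain error: event must be 0/1")
  times <- sort(unique(time_months[event == 1L]))
  if (length(times) == 0) {
    return(data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), survival = numeric(0)))
  }
  n_risk <- vapply(times, function(t) sum(time_months >= t), integer(1))
  n_event <- vapply(times, function(t) sum(time_months == t & event == 1L),
                    integer(1))
  data.frame(time = times, n_risk = n_risk, n_event = n_event,
             survival = cumprod(1 - n_event / n_risk))
}

#' Log-rank test with Mantel-Haenszel hazard ratio
#'
#' Standard two-group log-rank statistic over the shared distinct event
#' times. The hazard ratio is the Mantel-Haenszel one-step estimate from the
#' observed-minus-expected decomposition, \eqn{HR = \exp((O_1 - E_1)/V)},
#' with 95% CI \eqn{\exp((O_1 - E_1)/V \pm 1.96/\sqrt{V})}; group 1 is the
#' first factor level (reference is group 2).
#'
#' @param time_months positive times.
#' @param event 0/1 indicators.
#' @param group two-level factor (or coercible); the reported HR is the
#'   hazard in the first factor level relative to the second.
#' @return object of class \code{logrank_result}: list with
#'   \code{chi_square}, \code{p_value}, \code{hazard_ratio}, \code{ci_low},
#'   \code{ci_high}, \code{observed}, \code{expected}, \code{groups}.
#' @export
logrank_hr <- function(time_months, event, group) {
  time_months <- as.numeric(time_months)
  event <- as.integer(event)
  group <- factor(group)
  if (nlevels(group) != 2) {
    stopf("grouping error: exactly two non-empty groups required, got %d",
          nlevels(droplevels(group)))
  }
  if (sum(event) < 1) stopf("grouping error: at least one event required")
  if (any(time_months <= 0)) stopf("domain error: times must be positive")
  g1 <- group == levels(group)[1]
  times <- sort(unique(time_months[event == 1L]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in times) {
    at_risk <- time_months >= t
    nj <- sum(at_risk)
    n1j <- sum(at_risk & g1)
    dj <- sum(time_months == t & event == 1L)
    d1j <- sum(time_months == t & event == 1L & g1)
    O1 <- O1 + d1j
    E1 <- E1 + dj * n1j / nj
    if (nj > 1) {
      V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    }
  }
  if (V <= 0) stopf("grouping error: no usable event times for the log-rank test")
  chi <- (O1 - E1)^2 / V
  log_hr <- (O1 - E1) / V
  obs <- c(O1, sum(event) - O1)
  exp_ <- c(E1, sum(event) - E1)
  res <- list(chi_square = chi,
              p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
              hazard_ratio = exp(log_hr),
              ci_low = exp(log_hr - 1.96 / sqrt(V)),
              ci_high = exp(log_hr + 1.96 / sqrt(V)),
              observed = stats::setNames(obs, levels(group)),
              expected = stats::setNames(exp_, levels(group)),
              variance = V,
              groups = levels(group))
  class(res) <- "logrank_result"
  res
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test (%s vs %s): chi-square = %.3f, p = %.4g\n",
              x$groups[1], x$groups[2], x$chi_square, x$p_value))
  cat(sprintf("Mantel-Haenszel HR = %.3f (95%% CI %.3f - %.3f)\n",
              x$hazard_ratio, x$ci_low, x$ci_high))
  invisible(x)
}

#' Dichotomize mutational burden into survival strata
#'
#' @param n_snv per-patient somatic SNV counts.
#' @param cutoff patients with \code{n_snv >= cutoff} are "high".
#' @return factor with levels \code{low}, \code{high}.
#' @export
dichotomize_burden <- function(n_snv, cutoff = 1) {
  if (any(n_snv < 0)) stopf("domain error: n_snv must be nonnegative")
  if (cutoff < 1) stopf("domain error: cutoff must be >= 1")
  factor(ifelse(n_snv >= cutoff, "high", "low"), levels = c("low", "high"))
}

#' Classify disease relapse from clinical fields
#'
#' Applies the biochemical-recurrence rule: an event is recorded when the
#' record carries a non-curative surgery flag (event at month 1), a
#' metastasis or disease-death flag (event at the recorded month), a
#' precomputed relapse flag, or a post-surgery PSA series with two
#' consecutive values each above 0.2 ng/mL (event at the month of the
#' second confirming measurement). Otherwise the patient is censored at the
#' end of follow-up.
#'
#' @param record a list (or one-row data.frame) with any of:
#'   \code{relapse} + \code{relapse_month}; \code{psa_series} +
#'   \code{psa_months}; \code{non_curative}; \code{metastasis} /
#'   \code{disease_death} + \code{event_month}; and
#'   \code{follow_up_months}.
#' @return list with \code{event} (0/1) and \code{time_months}.
#' @export
classify_relapse <- function(record) {
  record <- as.list(record)
  fu <- record$follow_up_months
  if (isTRUE(as.logical(record$non_curative))) {
    return(list(event = 1L, time_months = 1))
  }
  if (isTRUE(as.logical(record$metastasis)) ||
      isTRUE(as.logical(record$disease_death))) {
    return(list(event = 1L, time_months = record$event_month %||% fu))
  }
  if (!is.null(record$relapse) && !is.na(record$relapse)) {
    ev <- as.integer(as.logical(record$relapse))
    tm <- if (ev == 1L) record$relapse_month %||% fu else fu
    return(list(event = ev, time_months = tm))
  }
  psa <- record$psa_series
  if (is.null(psa)) {
    stopf("insufficient-data error: record has neither a relapse flag nor a PSA series")
  }
  months <- record$psa_months %||% seq_along(psa)
  high <- psa > 0.2
  idx <- which(high[-1] & high[-length(high)])
  if (length(idx) > 0) {
    list(event = 1L, time_months = months[idx[1] + 1])
  } else {
    list(event = 0L, time_months = fu %||% months[length(months)])
  }
}
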