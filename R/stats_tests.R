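# Exact tests, ANOVA linear model and multiple-testing threshold.
# These are implemented from first principles; the test suite checks them
# against independent oracles (full enumeration, stats::lm, permutation).

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration with the "small p-values" two-sided
#' convention: the p-value is the sum of the probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (within a 1e-7 relative tolerance).
#'
#' @param a,b,c,d cell counts of the table \code{rbind(c(a, b), c(c, d))}.
#' @return list with \code{p_value}, \code{table}, \code{method}.
#' @export
#' @examples
#' fisher_exact_2x2(1, 9, 11, 3)$p_value
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells))) {
    stopf("domain error: cell counts must be nonnegative integers")
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (n == 0) stopf("domain error: all-zero table")
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- probs[support == a]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_value = min(p, 1), table = matrix(cells, 2, byrow = TRUE),
       method = "fisher.exact.2x2")
}

# log null probability of an r x c table under fixed margins
.table_logprob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Fisher's exact test for an r x c table
#'
#' 2x2 tables delegate to \code{\link{fisher_exact_2x2}}. Larger tables use
#' seeded Monte-Carlo sampling of tables with the observed margins
#' (Patefield's algorithm via \code{r2dtable}); the p-value is the
#' proportion of sampled tables whose null probability does not exceed the
#' observed one, reported together with its Monte-Carlo standard error.
#'
#' @param tab integer matrix of counts.
#' @param mc_iterations number of Monte-Carlo tables.
#' @param seed integer seed for the Monte-Carlo draw.
#' @return list with \code{p_value}, \code{mc_se} (NA for exact 2x2),
#'   \code{method}.
#' @export
fisher_exact_rxc <- function(tab, mc_iterations = 1e5, seed = 1L) {
  tab <- as.matrix(tab)
  if (anyNA(tab) || any(tab < 0) || any(tab != floor(tab))) {
    stopf("domain error: table must contain nonnegative integers")
  }
  if (sum(tab) == 0) stopf("degenerate error: all-zero table")
  if (all(dim(tab) == c(2, 2))) {
    res <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    res$mc_se <- NA_real_
    return(res)
  }
  lp_obs <- .table_logprob(tab)
  sims <- withr::with_seed(seed,
    stats::r2dtable(mc_iterations, rowSums(tab), colSums(tab)))
  lp_sim <- vapply(sims, .table_logprob, numeric(1))
  p <- mean(lp_sim <= lp_obs + 1e-7)
  list(p_value = p, mc_se = sqrt(p * (1 - p) / mc_iterations),
       method = "fisher.exact.rxc.montecarlo")
}

#' Simple linear model with ANOVA F-test
#'
#' Ordinary least squares of \code{y} on \code{x} with intercept; the
#' F statistic is MS(model)/MS(residual) on (1, n-2) degrees of freedom.
#'
#' @param y numeric response.
#' @param x numeric predictor (must not be constant).
#' @return list with \code{slope}, \code{intercept}, \code{f_statistic},
#'   \code{df}, \code{p_value}, \code{r_squared}, \code{n}.
#' @export
anova_linear <- function(y, x) {
  keep <- stats::complete.cases(y, x)
  y <- as.numeric(y[keep]); x <- as.numeric(x[keep])
  n <- length(y)
  if (n < 3) stopf("anova_linear needs n >= 3 complete observations")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stopf("rank-deficiency error: predictor x is constant")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  ss_model <- sum((fitted - mean(y))^2)
  ss_resid <- sum((y - fitted)^2)
  ss_total <- ss_model + ss_resid
  df2 <- n - 2L
  f <- if (ss_resid <= 0) Inf else (ss_model / 1) / (ss_resid / df2)
  p <- if (is.infinite(f)) 0 else stats::pf(f, 1, df2, lower.tail = FALSE)
  list(slope = slope, intercept = intercept, f_statistic = f,
       df = c(1L, df2), p_value = p,
       r_squared = if (ss_total > 0) ss_model / ss_total else NA_real_,
       n = n)
}

#' Bonferroni-corrected per-test significance threshold
#'
#' @param alpha familywise error rate, in (0, 1).
#' @param m number of tests (>= 1).
#' @return alpha / m.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 7)  # 0.00714...
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stopf("domain error: alpha must lie in (0, 1)")
  }
  if (!is.numeric(m) || m < 1 || m != floor(m)) {
    stopf("domain error: m must be a positive integer")
  }
  alpha / m
}
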