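# ROC curves, AUC by the Mann-Whitney identity, logistic score combination
# and DeLong's paired AUC comparison.

#' Empirical ROC curve and AUC
#'
#' The curve is evaluated at every distinct score threshold (predicting
#' positive when score >= threshold); the AUC is computed through the
#' Mann-Whitney identity with ties counted one half.
#'
#' @param scores numeric predictor (higher = more likely positive).
#' @param labels 0/1 outcome; both classes must be present.
#' @return object of class \code{roc_result}: list with \code{thresholds},
#'   \code{sensitivities}, \code{specificities}, \code{auc}.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (anyNA(scores) || anyNA(labels)) stopf("domain error: NA in scores/labels")
  if (!all(labels %in% c(0L, 1L))) stopf("domain error: labels must be 0/1")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    stopf("degenerate-label error: both outcome classes must be present")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0L) / n0,
                 numeric(1))
  r <- rank(scores) # midranks handle ties
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  res <- list(thresholds = thr, sensitivities = sens, specificities = spec,
              auc = auc, n_pos = n1, n_neg = n0)
  class(res) <- "roc_result"
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.3f (%d positives, %d negatives, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

#' Combine two predictors into one relapse score
#'
#' Fits an in-sample logistic regression of the outcome on the Gleason
#' grade and the somatic SNV count (IRLS, convergence tolerance 1e-8, at
#' most 100 iterations) and returns the fitted linear predictor as the
#' combined score. Under complete separation a warning is issued and the
#' score falls back to the sum of rank-standardized predictors.
#'
#' @param gleason_score numeric (ordinal category codes or raw scores).
#' @param n_snv numeric somatic SNV counts.
#' @param labels 0/1 outcome, both classes present, n >= 10.
#' @return list with \code{score}, \code{coefficients}, \code{converged},
#'   \code{separation}.
#' @export
combine_predictors <- function(gleason_score, n_snv, labels) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n < 10) stopf("combine_predictors needs at least 10 patients")
  if (length(unique(labels)) < 2) {
    stopf("degenerate-label error: both outcome classes must be present")
  }
  dat <- data.frame(y = labels, g = as.numeric(gleason_score),
                    s = as.numeric(n_snv))
  fit <- suppressWarnings(
    stats::glm(y ~ g + s, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  mu <- stats::fitted(fit)
  separated <- !fit$converged || any(mu < 1e-8) || any(mu > 1 - 1e-8)
  if (separated) {
    warnf("perfect separation detected; falling back to rank-sum combination")
    std_rank <- function(v) {
      if (length(unique(v)) == 1) return(rep(0, length(v)))
      as.numeric(scale(rank(v)))
    }
    score <- std_rank(dat$g) + std_rank(dat$s)
    return(list(score = score, coefficients = NULL, converged = FALSE,
                separation = TRUE))
  }
  list(score = as.numeric(stats::predict(fit, type = "link")),
       coefficients = stats::coef(fit), converged = fit$converged,
       separation = FALSE)
}

# placement values: for each positive, the fraction of negatives it beats
# (ties = 1/2), and vice versa
.placements <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)),
                numeric(1))
  v01 <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)),
                numeric(1))
  list(v10 = v10, v01 = v01)
}

#' DeLong's test for two paired AUCs
#'
#' Compares the AUCs of two score vectors evaluated on the same subjects,
#' using the empirical covariance of the per-subject placement values to
#' estimate the variance of the AUC difference, and a two-sided normal
#' test.
#'
#' @param scores_a,scores_b paired score vectors (same subjects, same
#'   order).
#' @param labels 0/1 outcome, both classes present.
#' @return list with \code{auc_a}, \code{auc_b}, \code{auc_diff},
#'   \code{var_a}, \code{var_b}, \code{var_diff}, \code{z}, \code{p_value}.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stopf("pairing error: scores_a, scores_b and labels must have equal length")
  }
  if (length(unique(labels)) < 2) {
    stopf("degenerate-label error: both outcome classes must be present")
  }
  pa <- .placements(scores_a, labels)
  pb <- .placements(scores_b, labels)
  m <- length(pa$v10); n <- length(pa$v01)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- auc_a - auc_b
  if (var_diff <= .Machine$double.eps) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_diff)
  }
  list(auc_a = auc_a, auc_b = auc_b, auc_diff = d,
       var_a = S[1, 1], var_b = S[2, 2], var_diff = max(var_diff, 0),
       z = z, p_value = 2 * stats::pnorm(-abs(z)))
}
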