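# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct enumeration, pairwise brute force,
# permutation and resampling.

# Fisher 2x2 two-sided p by direct enumeration over the hypergeometric
# support, probabilities from binomial coefficients.
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  p <- exp(lp)
  sum(p[p <= p[ks == a] * (1 + 1e-7)])
}

# exhaustive two-sided p for a 2 x 3 table with fixed margins
oracle_fisher_2x3 <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  logprob <- function(m) {
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) -
      lgamma(sum(m) + 1) - sum(lgamma(m + 1))
  }
  lp_obs <- logprob(tab)
  total <- 0
  for (a11 in 0:min(rs[1], cs[1])) {
    for (a12 in 0:min(rs[1] - a11, cs[2])) {
      a13 <- rs[1] - a11 - a12
      if (a13 < 0 || a13 > cs[3]) next
      m <- rbind(c(a11, a12, a13), cs - c(a11, a12, a13))
      if (any(m < 0)) next
      lp <- logprob(m)
      if (lp <= lp_obs + 1e-7) total <- total + exp(lp)
    }
  }
  total
}

# AUC by brute force over all (positive, negative) pairs, ties = 1/2
oracle_auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# permutation p-value for the two-group log-rank chi-square
oracle_logrank_permutation <- function(time, event, group, B = 4000,
                                       seed = 1) {
  obs <- mitoburden::logrank_hr(time, event, group)$chi_square
  withr::with_seed(seed, {
    perm <- replicate(B, {
      mitoburden::logrank_hr(time, event, sample(group))$chi_square
    })
  })
  mean(perm >= obs - 1e-12)
}

# jackknife variance of a single AUC (leave-one-subject-out)
oracle_auc_jackknife_var <- function(scores, labels) {
  n <- length(scores)
  auc_i <- vapply(seq_len(n), function(i) {
    oracle_auc_pairwise(scores[-i], labels[-i])
  }, numeric(1))
  (n - 1) / n * sum((auc_i - mean(auc_i))^2)
}

# small deterministic somatic-call fixture: `n` calls, one variant shared
# by `recur` patients, all others patient-private at distinct positions
make_recurrent_calls <- function(n_calls = 76, recur = 3,
                                 shared_pos = 16093) {
  n_unique_private <- n_calls - recur
  pos <- setdiff(seq(100, 100 + n_unique_private * 3, by = 3), shared_pos)
  pos <- pos[seq_len(n_unique_private)]
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n_calls)),
    position = c(rep(shared_pos, recur), pos),
    ref = "T", alt = "C",
    tumor_af = 0.5, normal_af = 0,
    stringsAsFactors = FALSE)
}

# clinical + profile fixture reproducing the reference-cohort marginal counts:
# 115 patients split 26/40/49 with per-category SNV totals 6/27/43
make_marginal_fixture <- function() {
  sizes <- c(26, 40, 49)
  totals <- c(6, 27, 43)
  carriers <- c(4, 19, 27)
  clin <- list(); profs <- list()
  pid <- 0
  for (ci in 1:3) {
    counts <- integer(sizes[ci])
    # give each carrier >= 1 and distribute the remaining SNVs round-robin
    counts[seq_len(carriers[ci])] <- 1L
    extra <- totals[ci] - carriers[ci]
    j <- 1
    while (extra > 0) {
      counts[j] <- counts[j] + 1L
      j <- j %% carriers[ci] + 1
      extra <- extra - 1
    }
    ids <- sprintf("P%03d", pid + seq_len(sizes[ci]))
    pid <- pid + sizes[ci]
    clin[[ci]] <- data.frame(patient_id = ids,
                             gleason_cat = c("<7", "=7", ">7")[ci],
                             purity = 0.5, stringsAsFactors = FALSE)
    profs[[ci]] <- data.frame(patient_id = ids, n_snv = counts,
                              cvf = counts * 0.75,
                              n_functional = 0L, n_nonsynonymous = 0L,
                              mean_raw_af = ifelse(counts > 0, 0.46, NA),
                              mean_adjusted_af = ifelse(counts > 0, 0.75, NA),
                              stringsAsFactors = FALSE)
  }
  list(clinical = do.call(rbind, clin), profiles = do.call(rbind, profs))
}
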