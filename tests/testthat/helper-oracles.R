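# Independent oracles kept outside the package so the tested code path never
# feeds the expected values.

# Two-sided Fisher p by full enumeration over all tables with the observed
# margins, using the conventional small-p definition (tables whose
# hypergeometric probability does not exceed the observed one, with the usual
# 1 + 1e-7 relative tie tolerance).
fisher_p_enum <- function(tab) {
  m <- sum(tab[1L, ])
  n <- sum(tab[2L, ])
  k <- sum(tab[, 1L])
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1L, 1L], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Analytic equal-posterior threshold between two Gaussian log-intensity
# components with mixing weight w_pos on the brighter one.
analytic_threshold <- function(mu_neg, sd_neg, mu_pos, sd_pos, w_pos) {
  f <- function(t) {
    log(1 - w_pos) + stats::dnorm(t, mu_neg, sd_neg, log = TRUE) -
      log(w_pos) - stats::dnorm(t, mu_pos, sd_pos, log = TRUE)
  }
  stats::uniroot(f, lower = mu_neg, upper = mu_pos)$root
}

# Expected seeds per ovule under the segregation-driven fertility model:
# both gametes must be euploid, and a meiosis with k bivalents out of K pairs
# yields a euploid gamete with probability (1/2)^(K - k).
expected_seed_fraction <- function(lambda, K = 5) {
  p <- 1 - exp(-lambda)
  per_gamete <- sum(stats::dbinom(0:K, K, p) * 0.5^(K - 0:K))
  per_gamete^2
}

make_counts_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(plant_id = r$plant_id, genotype = r$genotype, design = r$design,
               n_green_only = r$g, n_red_only = r$r, n_both = r$b,
               n_neither = r$n,
               n_total = r$g + r$r + r$b + r$n, stringsAsFactors = FALSE)
  }))
}
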