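check_cytology_df <- function(cells, n_chromosomes = 5L) {
  if (!is.data.frame(cells) || nrow(cells) == 0L) {
    ftl_stop("cytology table is empty", "ftl_empty_input_error")
  }
  needed <- c("genotype", "sex", "n_bivalents", "has_fragments")
  missing <- setdiff(needed, names(cells))
  if (length(missing)) {
    ftl_stop(paste("cytology table lacks columns:", paste(missing, collapse = ", ")),
             "ftl_malformed_record_error")
  }
  b <- cells$n_bivalents
  if (any(b < 0 | b > n_chromosomes | b != round(b))) {
    ftl_stop(sprintf("bivalent counts must be integers in 0..%d", n_chromosomes),
             "ftl_domain_error")
  }
  invisible(cells)
}

#' Summarise the bivalent distribution of one genotype/sex group
#'
#' Tallies the number of metaphase I cells with 0..5 bivalents and their mean,
#' the standard presentation of CO-pathway phenotypes (a wild-type meiosis
#' shows five bivalents in every cell; ZMM-deficient meioses show a spread
#' governed by residual class II crossovers).
#'
#' @param cells Data frame of cells (`genotype`, `sex`, `n_bivalents`,
#'   `has_fragments`) from a single genotype and sex.
#' @param n_chromosomes Number of chromosome pairs (default 5).
#' @return An object of class `bivalent_summary`: `genotype`, `sex`,
#'   `counts_by_bivalent` (named vector over 0..n_chromosomes), `n_cells`,
#'   `mean_bivalents`.
#' @examples
#' cells <- simulate_cytology(meiosis_params(classI_active = FALSE), 100, rng_seed = 1)
#' bivalent_summary(cells)
#' @export
bivalent_summary <- function(cells, n_chromosomes = 5L) {
  check_cytology_df(cells, n_chromosomes)
  if (length(unique(cells$genotype)) != 1L || length(unique(cells$sex)) != 1L) {
    ftl_stop("bivalent_summary expects a single genotype and sex; split first",
             "ftl_grouping_error")
  }
  tab <- tabulate(cells$n_bivalents + 1L, nbins = n_chromosomes + 1L)
  names(tab) <- as.character(0:n_chromosomes)
  structure(
    list(genotype = cells$genotype[1L], sex = cells$sex[1L],
         counts_by_bivalent = tab, n_cells = nrow(cells),
         n_chromosomes = as.integer(n_chromosomes),
         mean_bivalents = mean(cells$n_bivalents)),
    class = "bivalent_summary"
  )
}

#' @export
print.bivalent_summary <- function(x, ...) {
  cat(sprintf("<bivalent_summary> %s (%s): %d cells, mean %.2f bivalents\n",
              x$genotype, x$sex, x$n_cells, x$mean_bivalents))
  print(x$counts_by_bivalent)
  invisible(x)
}

# Welch t-test that tolerates zero-variance groups: constant equal groups give
# t = 0 / p = 1, constant groups with different means give |t| = Inf / p = 0.
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    ftl_stop("need at least 2 cells per group", "ftl_degenerate_error")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    d <- mean(a) - mean(b)
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                p_value = if (d == 0) 1 else 0,
                df = NA_real_))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

# Chi-square on two 0..K distributions, pooling bins with small expected
# counts into their neighbour (small cells are common in 0-5 bivalent tables).
pooled_chisq <- function(counts_a, counts_b, min_expected = 1) {
  tab <- rbind(counts_a, counts_b)
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  repeat {
    if (ncol(tab) < 2L) return(list(statistic = NA_real_, p_value = NA_real_,
                                    df = NA_real_))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    bad <- which(apply(expected, 2L, min) < min_expected)
    if (length(bad) == 0L) break
    j <- bad[1L]
    nb <- if (j == 1L) 2L else j - 1L
    tab[, nb] <- tab[, nb] + tab[, j]
    tab <- tab[, -j, drop = FALSE]
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Compare bivalent numbers between two genotypes
#'
#' Primary test: Welch two-sample t-test on per-cell bivalent counts (the
#' statistic's sign is mean(a) - mean(b), positive when the first group forms
#' more bivalents). Secondary: a chi-square on the pooled 0..5 distributions,
#' with bins of expected count below 1 merged into their neighbour.
#'
#' @param a,b Cytology data frames (one genotype/sex group each).
#' @param n_chromosomes Number of chromosome pairs (default 5).
#' @return An object of class `genotype_comparison` with `method = "WELCH_T"`,
#'   `statistic`, `df`, `p_value`, group means, and a `secondary` element
#'   holding the distribution chi-square.
#' @export
compare_bivalent_means <- function(a, b, n_chromosomes = 5L) {
  sa <- bivalent_summary(a, n_chromosomes)
  sb <- bivalent_summary(b, n_chromosomes)
  tt <- welch_t(a$n_bivalents, b$n_bivalents)
  chi <- pooled_chisq(sa$counts_by_bivalent, sb$counts_by_bivalent)
  structure(
    list(method = "WELCH_T",
         statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
         mean_a = sa$mean_bivalents, mean_b = sb$mean_bivalents,
         n_a = sa$n_cells, n_b = sb$n_cells,
         secondary = c(chi, list(method = "CHI2_DISTRIBUTION"))),
    class = "genotype_comparison"
  )
}

#' Compare chromosome fragmentation between two genotypes
#'
#' Two-sided Fisher exact test on the 2x2 table of fragmented versus intact
#' cells in the two groups.
#'
#' @param a,b Cytology data frames with logical `has_fragments`.
#' @return An object of class `genotype_comparison` with the 2x2 `table` and
#'   Fisher `p_value`.
#' @export
fragmentation_comparison <- function(a, b) {
  check_cytology_df(a)
  check_cytology_df(b)
  tab <- rbind(c(sum(a$has_fragments), sum(!a$has_fragments)),
               c(sum(b$has_fragments), sum(!b$has_fragments)))
  dimnames(tab) <- list(group = c("a", "b"), cells = c("fragmented", "intact"))
  ht <- stats::fisher.test(tab, alternative = "two.sided")
  structure(
    list(method = "FISHER_TWO_SIDED", table = tab, statistic = NA_real_,
         df = NA_integer_, p_value = min(1, ht$p.value)),
    class = "genotype_comparison"
  )
}

#' Estimate the class II crossover rate from a bivalent distribution
#'
#' Under the simulator's model with the obligate-CO pathway inactive, each of
#' the `K` chromosome pairs independently forms a bivalent with probability
#' \eqn{p = 1 - e^{-\lambda}}, so the bivalent count is `Binomial(K, p)` and
#' the maximum-likelihood estimate is \eqn{\hat\lambda = -\ln(1 - \hat p)}
#' with \eqn{\hat p} the mean bivalent fraction. The confidence interval is a
#' profile-likelihood interval on the binomial proportion, transformed to the
#' \eqn{\lambda} scale.
#'
#' @param summary A [bivalent_summary()].
#' @param conf_level Confidence level (default 0.95).
#' @return List with `lambda`, `ci_low`, `ci_high`, `p_bivalent`, `n_cells`.
#' @examples
#' cells <- simulate_cytology(meiosis_params(classI_active = FALSE, lambda_classII = 0.35),
#'                            500, rng_seed = 2)
#' estimate_co_rate(bivalent_summary(cells))
#' @export
estimate_co_rate <- function(summary, conf_level = 0.95) {
  if (!inherits(summary, "bivalent_summary")) {
    ftl_stop("`summary` must be a bivalent_summary", "ftl_domain_error")
  }
  K <- summary$n_chromosomes
  p_hat <- summary$mean_bivalents / K
  if (p_hat >= 1) {
    ftl_stop("all chromosome pairs form bivalents: lambda is unbounded (obligate-CO regime)",
             "ftl_domain_error")
  }
  n_trials <- summary$n_cells * K
  k_success <- sum(summary$counts_by_bivalent * as.numeric(names(summary$counts_by_bivalent)))
  loglik <- function(p) {
    k_success * log(p) + (n_trials - k_success) * log1p(-p)
  }
  crit <- stats::qchisq(conf_level, df = 1) / 2
  profile_bound <- function(lower) {
    if (k_success == 0 && lower) return(0)
    target <- function(p) {
      (if (k_success == 0) 0 else loglik(p_hat)) - loglik(p) - crit
    }
    interval <- if (lower) c(1e-12, p_hat) else c(max(p_hat, 1e-12), 1 - 1e-12)
    if (lower && p_hat <= 1e-12) return(0)
    root <- tryCatch(stats::uniroot(target, interval = interval)$root,
                     error = function(e) if (lower) 0 else 1 - 1e-12)
    root
  }
  p_lo <- profile_bound(lower = TRUE)
  p_hi <- profile_bound(lower = FALSE)
  list(lambda = if (p_hat <= 0) 0 else -log1p(-p_hat),
       ci_low = if (p_lo <= 0) 0 else -log1p(-p_lo),
       ci_high = -log1p(-p_hi),
       p_bivalent = p_hat,
       n_cells = summary$n_cells)
}

#' Compare fertility across genotypes
#'
#' The analysis unit is the plant: each plant's fertility is the mean of its
#' seeds-per-fruit counts. A one-way ANOVA on plant means is followed by
#' pairwise comparisons of each genotype against the designated control, using
#' the ANOVA's pooled error, with Sidak family-wise adjustment
#' \eqn{p_{adj} = 1 - (1 - p)^k} over the `k` comparisons (so a single
#' comparison is unadjusted).
#'
#' @param fertility Long-format fertility data frame (`plant_id`, `genotype`,
#'   `fruit_index`, `seeds`), e.g. from [simulate_fertility()], covering
#'   two or more genotypes.
#' @param control Genotype to compare the others against (default: first
#'   genotype in the data).
#' @return List with `f_statistic`, `df`, `p_anova`, `plant_means`, and
#'   `comparisons` — a data frame with one row per non-control genotype:
#'   `group`, `control`, `estimate` (group minus control plant-mean
#'   difference), `statistic`, `p_raw`, `p_adjusted`, `n_group`, `n_control`.
#' @export
compare_fertility <- function(fertility, control = NULL) {
  needed <- c("plant_id", "genotype", "seeds")
  if (!is.data.frame(fertility) || !all(needed %in% names(fertility))) {
    ftl_stop("fertility table needs columns plant_id, genotype, seeds",
             "ftl_malformed_record_error")
  }
  if (any(fertility$seeds < 0)) {
    ftl_stop("seed counts must be non-negative", "ftl_domain_error")
  }
  pm <- stats::aggregate(seeds ~ plant_id + genotype, data = fertility, FUN = mean)
  names(pm)[names(pm) == "seeds"] <- "mean_seeds"
  n_per <- table(pm$genotype)
  if (length(n_per) < 2L) {
    ftl_stop("need at least two genotypes to compare", "ftl_replication_error")
  }
  if (any(n_per < 2L)) {
    ftl_stop(sprintf("genotypes with a single plant cannot be tested: %s",
                     paste(names(n_per)[n_per < 2L], collapse = ", ")),
             "ftl_replication_error")
  }
  if (is.null(control)) control <- fertility$genotype[1L]
  if (!control %in% pm$genotype) {
    ftl_stop(sprintf("control genotype '%s' not present", control), "ftl_domain_error")
  }
  pm$genotype <- factor(pm$genotype)
  if (stats::var(pm$mean_seeds) == 0) {
    # all plants identical: no signal, no error variance
    f_stat <- 0; p_anova <- 1; mse <- 0; df_resid <- nrow(pm) - nlevels(pm$genotype)
  } else {
    fit <- stats::aov(mean_seeds ~ genotype, data = pm)
    an <- stats::anova(fit)
    f_stat <- an$`F value`[1L]
    p_anova <- an$`Pr(>F)`[1L]
    mse <- an$`Mean Sq`[2L]
    df_resid <- an$Df[2L]
  }
  others <- setdiff(levels(pm$genotype), control)
  k <- length(others)
  mean_of <- function(g) mean(pm$mean_seeds[pm$genotype == g])
  comparisons <- do.call(rbind, lapply(others, function(g) {
    n_g <- sum(pm$genotype == g); n_c <- sum(pm$genotype == control)
    est <- mean_of(g) - mean_of(control)
    se <- sqrt(mse * (1 / n_g + 1 / n_c))
    if (se == 0) {
      stat <- if (est == 0) 0 else sign(est) * Inf
      p_raw <- if (est == 0) 1 else 0
    } else {
      stat <- est / se
      p_raw <- 2 * stats::pt(abs(stat), df = df_resid, lower.tail = FALSE)
    }
    data.frame(group = g, control = control, estimate = est, statistic = stat,
               p_raw = p_raw, p_adjusted = sidak_adjust(p_raw, k),
               n_group = n_g, n_control = n_c, stringsAsFactors = FALSE)
  }))
  list(f_statistic = f_stat, df = c(length(n_per) - 1L, df_resid),
       p_anova = p_anova, plant_means = pm, comparisons = comparisons)
}

#' Sidak family-wise adjustment
#'
#' \eqn{p_{adj} = 1 - (1 - p)^k} for `k` comparisons; monotone in `p` and the
#' identity at `k = 1`.
#'
#' @param p Raw p-value(s) in `[0, 1]`.
#' @param k Number of comparisons in the family (>= 1).
#' @return Adjusted p-value(s).
#' @export
sidak_adjust <- function(p, k) {
  assert_count(k, "k", min = 1)
  if (any(p < 0 | p > 1)) ftl_stop("p-values must lie in [0, 1]", "ftl_domain_error")
  1 - (1 - p)^k
}
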