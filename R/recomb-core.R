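#' Gamete class frequencies for a cis-configured marker hemizygote
#'
#' A parent hemizygous for two dominant markers in cis produces four gamete
#' classes. With recombination fraction `r` in the marker interval, parental
#' gametes (both markers, or neither) each have frequency `(1 - r)/2` and the
#' two recombinant single-marker gametes each have frequency `r/2`.
#'
#' @param r Recombination fraction in `[0, 1]`.
#' @return Named numeric vector `c(f_GR, f_G, f_R, f_none)` summing to 1.
#' @examples
#' gamete_class_frequencies(0.2)
#' @export
gamete_class_frequencies <- function(r) {
  assert_fraction(r, "r")
  c(f_GR = (1 - r) / 2, f_G = r / 2, f_R = r / 2, f_none = (1 - r) / 2)
}

#' Expected seed-class probabilities under a cross design
#'
#' Closed-form phenotype-class probabilities for seeds carrying dominant
#' fluorescent markers. In a backcross only the scored parent's recombination
#' fraction enters: the wild-type parent contributes a marker-free gamete, so
#' seed phenotype reads the hemizygote's gamete directly
#' (single-colour classes `r/2` each, both / neither `(1 - r)/2` each).
#' In an F2 self, seed phenotype combines one female and one male gamete and
#' markers are dominant:
#' \deqn{p_{green} = p_{red} = (r_f + r_m - r_f r_m)/4, \quad
#'       p_{neither} = (1 - r_f)(1 - r_m)/4,}
#' with \eqn{p_{both}} the remainder.
#'
#' @param design A [cross_design()] or design-kind string.
#' @param r_female,r_male Sex-specific recombination fractions in `[0, 1]`.
#'   For `BC_FEMALE` only `r_female` is used; for `BC_MALE` only `r_male`.
#' @return Named numeric vector
#'   `c(p_green_only, p_red_only, p_both, p_neither)` summing to 1.
#' @seealso [enumerate_zygotes()] for the brute-force equivalent.
#' @examples
#' expected_seed_class_probs("F2_SELF", 0.2, 0.2)
#' expected_seed_class_probs("BC_FEMALE", r_female = 0.1)
#' @export
expected_seed_class_probs <- function(design, r_female = NULL, r_male = NULL) {
  design <- as_cross_design(design)
  kind <- design$design_kind
  if (kind != "BC_MALE") assert_fraction(r_female, "r_female")
  if (kind != "BC_FEMALE") assert_fraction(r_male, "r_male")
  if (kind == "F2_SELF") {
    p_single <- (r_female + r_male - r_female * r_male) / 4
    p_neither <- (1 - r_female) * (1 - r_male) / 4
    p_both <- 1 - 2 * p_single - p_neither
  } else {
    r <- if (kind == "BC_FEMALE") r_female else r_male
    p_single <- r / 2
    p_both <- (1 - r) / 2
    p_neither <- (1 - r) / 2
  }
  c(p_green_only = p_single, p_red_only = p_single,
    p_both = p_both, p_neither = p_neither)
}

#' Seed-class probabilities by exhaustive zygote enumeration
#'
#' Brute-force oracle for [expected_seed_class_probs()]: enumerates every
#' female x male gamete pairing (4 x 4 for an F2 self; 4 hemizygote gametes
#' against the single marker-free wild-type gamete for a backcross), classifies
#' each zygote's phenotype by marker dominance, and sums pairing frequencies.
#'
#' @inheritParams expected_seed_class_probs
#' @return Named numeric vector as for [expected_seed_class_probs()].
#' @export
enumerate_zygotes <- function(design, r_female = NULL, r_male = NULL) {
  design <- as_cross_design(design)
  kind <- design$design_kind
  gametes <- function(r) {
    data.frame(G = c(TRUE, TRUE, FALSE, FALSE),
               R = c(TRUE, FALSE, TRUE, FALSE),
               p = unname(gamete_class_frequencies(r)))
  }
  null_gamete <- data.frame(G = FALSE, R = FALSE, p = 1)
  female <- switch(kind,
    F2_SELF = { assert_fraction(r_female, "r_female"); gametes(r_female) },
    BC_FEMALE = { assert_fraction(r_female, "r_female"); gametes(r_female) },
    BC_MALE = null_gamete)
  male <- switch(kind,
    F2_SELF = { assert_fraction(r_male, "r_male"); gametes(r_male) },
    BC_MALE = { assert_fraction(r_male, "r_male"); gametes(r_male) },
    BC_FEMALE = null_gamete)
  probs <- c(p_green_only = 0, p_red_only = 0, p_both = 0, p_neither = 0)
  for (i in seq_len(nrow(female))) {
    for (j in seq_len(nrow(male))) {
      has_g <- female$G[i] || male$G[j]
      has_r <- female$R[i] || male$R[j]
      cls <- if (has_g && has_r) "p_both"
             else if (has_g) "p_green_only"
             else if (has_r) "p_red_only"
             else "p_neither"
      probs[cls] <- probs[cls] + female$p[i] * male$p[j]
    }
  }
  probs
}

#' Genetic distance from seed-class counts
#'
#' Applies the design-specific map-distance formula to the recombinant-seed
#' proportion \eqn{f_{obs} = (N_G + N_R)/N_T}, where \eqn{N_G} and \eqn{N_R}
#' are the green-only and red-only seed counts and \eqn{N_T} the total.
#'
#' For a backcross the recombinant proportion estimates the scored sex's
#' recombination fraction directly:
#' \deqn{cM = 100 \, (N_G + N_R)/N_T.}
#' For an F2 self, a single-colour seed arises when exactly one of the two
#' gametes is recombinant (to first order), giving expected single-colour
#' proportion \eqn{(2r - r^2)/2} under equal male and female fractions; the
#' printed inversion is
#' \deqn{cM = 100 \, (1 - [1 - 2(N_G + N_R)/N_T]^{1/2}).}
#'
#' The F2 formula assumes equal recombination in male and female meiosis. That
#' assumption is materially false for genotypes with sex-dimorphic
#' recombination, so F2 estimates always carry the warning flag
#' `"f2_assumes_equal_sex_rates"`; with unequal rates the estimator converges
#' to \eqn{100(1 - \sqrt{(1-r_f)(1-r_m)})}, a geometric-mean-type compromise.
#'
#' An observed F2 single-colour fraction above 0.5 is outside the model's range
#' and raises an error rather than producing a complex or capped value. At
#' exactly 0.5 the estimate is the boundary value 100 cM with infinite
#' standard error and CI `[0, 100]`, flagged `"f2_boundary"`.
#'
#' @param counts A [seed_counts()] object with `n_total > 0`.
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @return An object of class `recomb_estimate` with elements
#'   `recombinant_fraction` (implied gametic r), `f_obs`, `cM`, `se_cM`,
#'   `ci_low_cM`, `ci_high_cM`, `n_total`, `design`, `plant_id`, `genotype`,
#'   and `warnings` (character vector of flags).
#' @examples
#' bc <- seed_counts(50, 50, 450, 450, design = "BC_FEMALE")
#' estimate_recombination(bc)  # 10 cM
#' @export
estimate_recombination <- function(counts, conf_level = 0.95) {
  if (!inherits(counts, "seed_counts")) {
    ftl_stop("`counts` must be a seed_counts object", "ftl_domain_error")
  }
  if (counts$n_total <= 0) {
    ftl_stop("cannot estimate recombination from zero seeds", "ftl_empty_input_error")
  }
  kind <- counts$design$design_kind
  f_obs <- (counts$n_green_only + counts$n_red_only) / counts$n_total
  warnings <- character(0)
  if (kind == "F2_SELF") {
    if (f_obs > 0.5) {
      ftl_stop(sprintf(
        "observed F2 single-colour fraction %.4f exceeds 0.5: outside the model's range",
        f_obs), "ftl_out_of_model_error")
    }
    r_implied <- 1 - sqrt(1 - 2 * f_obs)
    warnings <- c(warnings, "f2_assumes_equal_sex_rates")
  } else {
    r_implied <- f_obs
  }
  cM <- 100 * r_implied
  if (kind == "F2_SELF" && f_obs == 0.5) {
    unc <- list(se_cM = Inf, ci_low_cM = 0, ci_high_cM = 100)
    warnings <- c(warnings, "f2_boundary")
  } else {
    unc <- recombination_uncertainty(f_obs, counts$n_total, counts$design,
                                     conf_level = conf_level)
  }
  structure(
    list(recombinant_fraction = r_implied,
         f_obs = f_obs,
         cM = cM,
         se_cM = unc$se_cM,
         ci_low_cM = unc$ci_low_cM,
         ci_high_cM = unc$ci_high_cM,
         n_total = counts$n_total,
         design = counts$design,
         plant_id = counts$plant_id,
         genotype = counts$genotype,
         conf_level = conf_level,
         warnings = warnings),
    class = "recomb_estimate"
  )
}

#' @export
print.recomb_estimate <- function(x, ...) {
  cat(sprintf("<recomb_estimate> %s (%s, %s)\n", x$plant_id, x$genotype,
              x$design$design_kind))
  cat(sprintf("  cM = %.3f  (se %.3f, %g%% CI [%.3f, %.3f]), f_obs = %.4f, n = %g\n",
              x$cM, x$se_cM, 100 * x$conf_level, x$ci_low_cM, x$ci_high_cM,
              x$f_obs, x$n_total))
  if (length(x$warnings)) cat("  flags:", paste(x$warnings, collapse = ", "), "\n")
  invisible(x)
}

#' Delta-method uncertainty for a map-distance estimate
#'
#' The observed recombinant-seed proportion is binomial, with standard error
#' \eqn{\sqrt{f(1-f)/n}}. For a backcross the cM estimate is a linear rescaling
#' so `se_cM = 100 * SE(f)`. For an F2 the estimate passes through the
#' square-root inversion; the delta method gives
#' \eqn{se_{cM} = 100\,SE(f)/\sqrt{1 - 2f}}. Wald intervals are clipped to
#' `[0, 100]` cM.
#'
#' @param f_obs Observed recombinant-seed proportion.
#' @param n_total Total seeds counted (> 0).
#' @param design A [cross_design()] or design-kind string.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `se_cM`, `ci_low_cM`, `ci_high_cM`.
#' @export
recombination_uncertainty <- function(f_obs, n_total, design, conf_level = 0.95) {
  design <- as_cross_design(design)
  assert_fraction(f_obs, "f_obs")
  assert_count(n_total, "n_total", min = 1)
  is_f2 <- design$design_kind == "F2_SELF"
  if (is_f2 && f_obs >= 0.5) {
    ftl_stop("F2 uncertainty is undefined for f_obs >= 0.5 (outside the model)",
             "ftl_out_of_model_error")
  }
  se_f <- sqrt(f_obs * (1 - f_obs) / n_total)
  se_cM <- if (is_f2) 100 * se_f / sqrt(1 - 2 * f_obs) else 100 * se_f
  cM <- if (is_f2) 100 * (1 - sqrt(1 - 2 * f_obs)) else 100 * f_obs
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(se_cM = se_cM,
       ci_low_cM = max(0, cM - z * se_cM),
       ci_high_cM = min(100, cM + z * se_cM))
}

#' Compare recombination between two genotypes
#'
#' Builds the 2x2 contingency table of recombinant (green-only + red-only)
#' versus non-recombinant seeds for the two genotypes and tests homogeneity of
#' the recombinant proportion, either by Pearson's chi-square (1 df, no
#' continuity correction) or by a two-sided Fisher exact test. The two-sided
#' Fisher p-value follows the conventional "small-p" definition: the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed the observed table's.
#'
#' @param counts_a,counts_b [seed_counts()] from the same cross design
#'   (pool replicates first with [pool_seed_counts()] for genotype-level tests).
#' @param method `"chi2"` or `"fisher"`.
#' @return An object of class `genotype_comparison`: `method`, `table`
#'   (2 genotypes x recombined/non-recombined), `statistic` (`NA` for Fisher),
#'   `df`, `p_value`.
#' @examples
#' a <- seed_counts(50, 50, 450, 450, design = "BC_FEMALE", genotype = "wt")
#' b <- seed_counts(90, 90, 410, 410, design = "BC_FEMALE", genotype = "mut")
#' compare_genotypes(a, b, method = "fisher")
#' @export
compare_genotypes <- function(counts_a, counts_b, method = c("chi2", "fisher")) {
  method <- match.arg(method)
  for (x in list(counts_a, counts_b)) {
    if (!inherits(x, "seed_counts")) {
      ftl_stop("both inputs must be seed_counts objects", "ftl_domain_error")
    }
    if (x$n_total <= 0) ftl_stop("counts with zero total", "ftl_empty_input_error")
  }
  if (!identical(counts_a$design$design_kind, counts_b$design$design_kind)) {
    ftl_stop("genotypes measured under different designs cannot be compared",
             "ftl_design_error")
  }
  rec <- function(x) x$n_green_only + x$n_red_only
  tab <- rbind(c(rec(counts_a), counts_a$n_total - rec(counts_a)),
               c(rec(counts_b), counts_b$n_total - rec(counts_b)))
  dimnames(tab) <- list(genotype = c(counts_a$genotype, counts_b$genotype),
                        seeds = c("recombined", "non_recombined"))
  if (any(tab != round(tab)) || any(tab < 0)) {
    ftl_stop("contingency tests require non-negative integer counts",
             "ftl_domain_error")
  }
  storage.mode(tab) <- "integer"
  if (method == "chi2") {
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
      ftl_stop("chi-square is undefined for a table with a zero margin",
               "ftl_degenerate_table_error")
    }
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    statistic <- unname(ht$statistic)
    p_value <- ht$p.value
    method_label <- "CHI2"
  } else {
    ht <- stats::fisher.test(tab, alternative = "two.sided")
    statistic <- NA_real_
    p_value <- ht$p.value
    method_label <- "FISHER_TWO_SIDED"
  }
  structure(
    list(method = method_label, table = tab, statistic = statistic,
         df = if (method == "chi2") 1L else NA_integer_,
         p_value = min(1, p_value)),
    class = "genotype_comparison"
  )
}

#' @export
print.genotype_comparison <- function(x, ...) {
  cat(sprintf("<genotype_comparison> %s\n", x$method))
  print(x$table)
  if (is.finite(x$statistic)) {
    cat(sprintf("  statistic = %.4f (df %d), p = %.4g\n", x$statistic, x$df, x$p_value))
  } else {
    cat(sprintf("  p = %.4g\n", x$p_value))
  }
  invisible(x)
}

#' Estimate recombination for every row of a seed-count table
#'
#' Convenience wrapper applying [estimate_recombination()] to each plant of a
#' seed-count data frame (as read by [read_seed_counts()]).
#'
#' @param df Data frame with columns `plant_id`, `genotype`, `design`,
#'   `n_green_only`, `n_red_only`, `n_both`, `n_neither`.
#' @param conf_level Confidence level for Wald intervals.
#' @return Data frame with one row per plant: `plant_id`, `genotype`, `design`,
#'   `f_obs`, `cM`, `se_cM`, `ci_low`, `ci_high`, `n_total`, `warnings`.
#' @export
estimate_recombination_table <- function(df, conf_level = 0.95) {
  validate_count_df(df)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    sc <- seed_counts(df$n_green_only[i], df$n_red_only[i],
                      df$n_both[i], df$n_neither[i],
                      design = df$design[i],
                      plant_id = df$plant_id[i], genotype = df$genotype[i])
    est <- estimate_recombination(sc, conf_level = conf_level)
    data.frame(plant_id = est$plant_id, genotype = est$genotype,
               design = est$design$design_kind,
               f_obs = est$f_obs, cM = est$cM, se_cM = est$se_cM,
               ci_low = est$ci_low_cM, ci_high = est$ci_high_cM,
               n_total = est$n_total,
               warnings = paste(est$warnings, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
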