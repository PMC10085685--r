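cells_df <- function(bivalents, genotype = "g", sex = "male", frags = FALSE) {
  data.frame(cell_id = sprintf("c%03d", seq_along(bivalents)),
             genotype = rep_len(genotype, length(bivalents)),
             sex = rep_len(sex, length(bivalents)),
             n_bivalents = bivalents,
             has_fragments = rep_len(frags, length(bivalents)),
             stringsAsFactors = FALSE)
}

test_that("bivalent summaries tally the 0-5 distribution and mean", {
  all5 <- bivalent_summary(cells_df(rep(5, 10)))
  expect_equal(all5$mean_bivalents, 5)
  expect_equal(unname(all5$counts_by_bivalent), c(0, 0, 0, 0, 0, 10))

  s <- bivalent_summary(cells_df(c(1, 1, 2)))
  expect_equal(unname(s$counts_by_bivalent), c(0, 2, 1, 0, 0, 0))
  expect_equal(s$mean_bivalents, 4 / 3)
  expect_equal(s$n_cells, 3L)

  mixed <- rbind(cells_df(c(1, 2), genotype = "a"), cells_df(3, genotype = "b"))
  expect_error(bivalent_summary(mixed), class = "ftl_grouping_error")
  expect_error(bivalent_summary(cells_df(integer(0))),
               class = "ftl_empty_input_error")
})

test_that("simulated bivalent means match the Poisson closed form", {
  lam <- 0.35
  cells <- simulate_cytology(meiosis_params(lambda_classII = lam,
                                            classI_active = FALSE),
                             1e4, rng_seed = 61)
  s <- bivalent_summary(cells)
  expect_lt(abs(s$mean_bivalents - 5 * (1 - exp(-lam))), 0.05)
})

test_that("bivalent mean comparison handles identical, extreme and simulated groups", {
  a <- cells_df(c(2, 3, 2, 4, 1))
  same <- compare_bivalent_means(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  lo <- cells_df(rep(0, 4))
  hi <- cells_df(rep(5, 4))
  extreme <- compare_bivalent_means(lo, hi)
  expect_lt(extreme$p_value, 1e-10)
  expect_lt(extreme$statistic, 0)  # sign follows mean(a) - mean(b)

  expect_error(compare_bivalent_means(cells_df(3), a),
               class = "ftl_degenerate_error")
})

test_that("the t-test separates zmm-like from suppressor-like rates with high power", {
  msh4 <- meiosis_params(lambda_classII = 0.35, classI_active = FALSE)
  supp <- meiosis_params(lambda_classII = 1.1, classI_active = FALSE)
  rejections <- withr::with_seed(67, {
    vapply(1:500, function(i) {
      a <- simulate_cytology(msh4, 30, rng_seed = 10000 + i)
      b <- simulate_cytology(supp, 30, rng_seed = 20000 + i)
      compare_bivalent_means(a, b)$p_value < 0.05
    }, logical(1))
  })
  expect_gte(mean(rejections), 0.9)
})

test_that("fragmentation comparison is the exact Fisher test", {
  none_a <- cells_df(rep(5, 50), frags = FALSE)
  none_b <- cells_df(rep(5, 50), frags = FALSE)
  expect_equal(fragmentation_comparison(none_a, none_b)$p_value, 1)

  frag_a <- cells_df(rep(5, 50), frags = rep(c(TRUE, FALSE), c(20, 30)))
  cmp <- fragmentation_comparison(frag_a, none_b)
  expect_equal(cmp$p_value, fisher_p_enum(cmp$table), tolerance = 1e-12)
  expect_equal(unname(cmp$table[1L, ]), c(20, 30))
})

test_that("fragmentation test detects a 40% rate against zero", {
  frag <- meiosis_params(frag_prob = 0.4)
  clean <- meiosis_params(frag_prob = 0)
  rejections <- vapply(1:500, function(i) {
    a <- simulate_cytology(frag, 60, rng_seed = 30000 + i)
    b <- simulate_cytology(clean, 60, rng_seed = 40000 + i)
    fragmentation_comparison(a, b)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
})

test_that("lambda estimation inverts the binomial-Poisson model", {
  # closed-form inversion at lambda = 1: mean bivalents 5 * (1 - exp(-1))
  k <- round(5 * (1 - exp(-1)) * 1000)
  counts <- c(rep(3, 1000 - (k - 3000)), rep(4, k - 3000))  # mean = k/1000
  est <- estimate_co_rate(bivalent_summary(cells_df(counts)))
  expect_lt(abs(est$lambda - 1), 0.002)  # rounding of k only

  zero <- estimate_co_rate(bivalent_summary(cells_df(rep(0, 20))))
  expect_identical(zero$lambda, 0)
  expect_identical(zero$ci_low, 0)
  expect_gt(zero$ci_high, 0)

  expect_error(estimate_co_rate(bivalent_summary(cells_df(rep(5, 20)))),
               class = "ftl_domain_error")
})

test_that("lambda recovery is nearly unbiased across the mutant-relevant range", {
  for (lam in c(0.2, 0.5, 1.0)) {
    cells <- simulate_cytology(meiosis_params(lambda_classII = lam,
                                              classI_active = FALSE),
                               1e4, rng_seed = 71 + round(100 * lam))
    est <- estimate_co_rate(bivalent_summary(cells))
    expect_lt(abs(est$lambda - lam) / lam, 0.02)
    expect_true(est$ci_low <= est$lambda && est$lambda <= est$ci_high)
  }
})

test_that("fertility comparison uses plant means, pooled ANOVA error and Sidak", {
  # all plants identical: no signal at all
  flat <- data.frame(plant_id = rep(sprintf("p%d", 1:6), each = 3),
                     genotype = rep(c("wt", "m1", "m2"), each = 6),
                     fruit_index = rep(1:3, 6), seeds = 30)
  fc <- compare_fertility(flat, control = "wt")
  expect_equal(fc$f_statistic, 0)
  expect_true(all(fc$comparisons$p_adjusted == 1))

  # two groups: a single comparison is unadjusted (Sidak k = 1 identity)
  two <- withr::with_seed(73, {
    rbind(simulate_fertility(meiosis_params(), genotype = "wt", rng_seed = 1),
          simulate_fertility(meiosis_params(classI_active = FALSE),
                             genotype = "msh4", rng_seed = 2))
  })
  fc2 <- compare_fertility(two, control = "wt")
  expect_equal(nrow(fc2$comparisons), 1L)
  expect_equal(fc2$comparisons$p_adjusted, fc2$comparisons$p_raw)
  expect_lt(fc2$comparisons$estimate, 0)  # zmm-like genotype is near-sterile

  single_plant <- flat[flat$plant_id != "p1", ]
  expect_error(compare_fertility(single_plant, control = "wt"),
               class = "ftl_replication_error")
})

test_that("fertility pairwise tests agree with emmeans' control contrasts", {
  fert <- withr::with_seed(79, {
    rbind(simulate_fertility(meiosis_params(), genotype = "wt", rng_seed = 3),
          simulate_fertility(meiosis_params(lambda_classII = 1.1,
                                            classI_active = FALSE),
                             genotype = "supp", rng_seed = 4),
          simulate_fertility(meiosis_params(lambda_classII = 0.35,
                                            classI_active = FALSE),
                             genotype = "msh4", rng_seed = 5))
  })
  fc <- compare_fertility(fert, control = "wt")
  pm <- fc$plant_means
  pm$genotype <- stats::relevel(factor(pm$genotype), ref = "wt")
  fit <- stats::aov(mean_seeds ~ genotype, data = pm)
  em <- emmeans::emmeans(fit, "genotype")
  ctr <- as.data.frame(emmeans::contrast(em, "trt.vs.ctrl", ref = "wt",
                                         adjust = "sidak"))
  ours <- fc$comparisons[order(fc$comparisons$group), ]
  ctr$group <- sub(" - wt", "", ctr$contrast)
  ctr <- ctr[order(ctr$group), ]
  expect_equal(ours$estimate, ctr$estimate, tolerance = 1e-8)
  expect_equal(ours$p_adjusted, ctr$p.value, tolerance = 1e-6)
})

test_that("family-wise error of the Sidak-adjusted comparisons stays near nominal", {
  fwer <- withr::with_seed(83, {
    mean(vapply(1:2000, function(i) {
      pm <- data.frame(
        plant_id = sprintf("p%d", 1:15),
        genotype = rep(c("wt", "m1", "m2"), each = 5),
        fruit_index = 1,
        seeds = round(rnorm(15, mean = 40, sd = 6)))
      fc <- compare_fertility(pm, control = "wt")
      any(fc$comparisons$p_adjusted < 0.05)
    }, logical(1)))
  })
  expect_lte(fwer, 0.06)
  expect_gt(fwer, 0.01)  # sanity: the test does reject under the null sometimes
})

test_that("Sidak adjustment is monotone and the identity at k = 1", {
  p <- seq(0, 1, by = 0.05)
  expect_equal(sidak_adjust(p, 1), p)
  adj <- sidak_adjust(p, 4)
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= p))
  expect_error(sidak_adjust(1.2, 2), class = "ftl_domain_error")
})
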