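test_that("gamete class frequencies follow the cis hemizygote model", {
  expect_equal(gamete_class_frequencies(0),
               c(f_GR = 0.5, f_G = 0, f_R = 0, f_none = 0.5))
  expect_equal(gamete_class_frequencies(0.2),
               c(f_GR = 0.4, f_G = 0.1, f_R = 0.1, f_none = 0.4))
  expect_equal(gamete_class_frequencies(1),
               c(f_GR = 0, f_G = 0.5, f_R = 0.5, f_none = 0))
  for (r in seq(0, 1, by = 0.1)) {
    f <- gamete_class_frequencies(r)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    expect_equal(unname(f["f_G"]), unname(f["f_R"]))
    expect_equal(unname(f["f_GR"]), unname(f["f_none"]))
  }
  expect_error(gamete_class_frequencies(-0.1), class = "ftl_domain_error")
  expect_error(gamete_class_frequencies(1.2), class = "ftl_domain_error")
})

test_that("closed-form seed-class probabilities match the spec'd cases", {
  expect_equal(expected_seed_class_probs("F2_SELF", 0, 0),
               c(p_green_only = 0, p_red_only = 0, p_both = 0.75, p_neither = 0.25))
  expect_equal(expected_seed_class_probs("F2_SELF", 0.2, 0.2),
               c(p_green_only = 0.09, p_red_only = 0.09, p_both = 0.66,
                 p_neither = 0.16))
  expect_equal(expected_seed_class_probs("BC_FEMALE", r_female = 0.1),
               c(p_green_only = 0.05, p_red_only = 0.05, p_both = 0.45,
                 p_neither = 0.45))
  # BC_MALE reads the male fraction, ignores the female one
  expect_equal(expected_seed_class_probs("BC_MALE", r_female = 0.9, r_male = 0.2),
               c(p_green_only = 0.1, p_red_only = 0.1, p_both = 0.4,
                 p_neither = 0.4))
  expect_error(expected_seed_class_probs("F2_SELF", 1.1, 0.1),
               class = "ftl_domain_error")
})

test_that("zygote enumeration reproduces its hand-derived cases", {
  expect_equal(unname(enumerate_zygotes("F2_SELF", 0, 0)["p_both"]), 0.75)
  expect_equal(unname(enumerate_zygotes("F2_SELF", 0.1, 0.3)["p_green_only"]),
               (0.1 + 0.3 - 0.03) / 4)
  expect_equal(unname(enumerate_zygotes("BC_MALE", r_male = 0)["p_green_only"]), 0)
})

test_that("closed form equals exhaustive zygote enumeration on a dense grid", {
  grid <- seq(0, 1, by = 0.05)
  max_dev <- 0
  for (rf in grid) {
    for (rm in grid) {
      for (kind in c("F2_SELF", "BC_FEMALE", "BC_MALE")) {
        closed <- expected_seed_class_probs(kind, rf, rm)
        brute <- enumerate_zygotes(kind, rf, rm)
        max_dev <- max(max_dev, max(abs(closed - brute)))
        expect_equal(sum(closed), 1, tolerance = 1e-12)
        expect_equal(unname(closed["p_green_only"]), unname(closed["p_red_only"]))
      }
    }
  }
  expect_lt(max_dev, 1e-12)
})

test_that("backcross and F2 estimators reproduce the printed formulas", {
  bc <- estimate_recombination(seed_counts(50, 50, 450, 450, design = "BC_FEMALE"))
  expect_equal(bc$cM, 10)
  expect_equal(bc$recombinant_fraction, 0.1)

  f2 <- estimate_recombination(seed_counts(47, 48, 700, 205, design = "F2_SELF"))
  expect_equal(f2$cM, 100 * (1 - sqrt(1 - 0.19)))
  expect_equal(f2$cM, 10, tolerance = 1e-12)
  expect_true("f2_assumes_equal_sex_rates" %in% f2$warnings)

  none <- estimate_recombination(seed_counts(0, 0, 300, 100, design = "F2_SELF"))
  expect_equal(none$cM, 0)

  boundary <- estimate_recombination(seed_counts(100, 100, 150, 50, design = "F2_SELF"))
  expect_equal(boundary$cM, 100)
  expect_true("f2_boundary" %in% boundary$warnings)
  expect_equal(boundary$se_cM, Inf)

  expect_error(estimate_recombination(seed_counts(0, 0, 0, 0, design = "BC_MALE")),
               class = "ftl_empty_input_error")
  expect_error(estimate_recombination(seed_counts(310, 300, 200, 190,
                                                  design = "F2_SELF")),
               class = "ftl_out_of_model_error")
})

test_that("F2 inversion recovers 100*r from expected counts (rounded at NT = 1e6)", {
  for (r in seq(0.01, 0.5, by = 0.01)) {
    probs <- expected_seed_class_probs("F2_SELF", r, r)
    counts <- round(probs * 1e6)
    est <- estimate_recombination(seed_counts(counts[1L], counts[2L], counts[3L],
                                              counts[4L], design = "F2_SELF"))
    expect_lt(abs(est$cM - 100 * r), 0.01)
  }
})

test_that("estimated cM is strictly increasing in the recombinant count", {
  n_total <- 1000
  for (kind in c("BC_FEMALE", "F2_SELF")) {
    rec <- seq(0, n_total / 2, by = 20)
    cms <- vapply(rec, function(k) {
      estimate_recombination(seed_counts(ceiling(k / 2), floor(k / 2),
                                         (n_total - k) / 2, (n_total - k) / 2,
                                         design = kind))$cM
    }, numeric(1))
    expect_true(all(diff(cms) > 0))
  }
})

test_that("the F2 design mixes the sexes; backcrosses separate them", {
  rf <- 0.12
  rm <- 0.04
  f2_counts <- expected_seed_class_probs("F2_SELF", rf, rm) * 4000
  f2 <- estimate_recombination(seed_counts(f2_counts[1L], f2_counts[2L],
                                           f2_counts[3L], f2_counts[4L],
                                           design = "F2_SELF"))
  expect_equal(f2$cM, 100 * (1 - sqrt((1 - rf) * (1 - rm))), tolerance = 1e-10)

  bcf_counts <- expected_seed_class_probs("BC_FEMALE", r_female = rf) * 4000
  bcf <- estimate_recombination(seed_counts(bcf_counts[1L], bcf_counts[2L],
                                            bcf_counts[3L], bcf_counts[4L],
                                            design = "BC_FEMALE"))
  expect_equal(bcf$cM, 12)
  bcm_counts <- expected_seed_class_probs("BC_MALE", r_male = rm) * 4000
  bcm <- estimate_recombination(seed_counts(bcm_counts[1L], bcm_counts[2L],
                                            bcm_counts[3L], bcm_counts[4L],
                                            design = "BC_MALE"))
  expect_equal(bcm$cM, 4)
})

test_that("delta-method uncertainty matches closed forms and a bootstrap", {
  expect_equal(recombination_uncertainty(0, 500, "BC_FEMALE")$se_cM, 0)
  expect_equal(recombination_uncertainty(0.1, 1000, "BC_FEMALE")$se_cM,
               100 * sqrt(0.1 * 0.9 / 1000))
  expect_equal(recombination_uncertainty(0.095, 1000, "F2_SELF")$se_cM,
               100 * sqrt(0.095 * 0.905 / 1000) / sqrt(0.81))
  expect_error(recombination_uncertainty(0.5, 1000, "F2_SELF"),
               class = "ftl_out_of_model_error")

  # bootstrap cross-check: sd of the estimate over multinomial resamples
  for (kind in c("BC_FEMALE", "F2_SELF")) {
    probs <- expected_seed_class_probs(kind, 0.1, 0.1)
    boot_cm <- withr::with_seed(101, {
      draws <- stats::rmultinom(2000, 1000, probs)
      apply(draws, 2L, function(d) {
        estimate_recombination(seed_counts(d[1L], d[2L], d[3L], d[4L],
                                           design = kind))$cM
      })
    })
    f_exp <- probs[["p_green_only"]] + probs[["p_red_only"]]
    se_delta <- recombination_uncertainty(f_exp, 1000, kind)$se_cM
    expect_lt(abs(sd(boot_cm) - se_delta) / se_delta, 0.05)
  }
})

test_that("Wald intervals are ordered and clipped to [0, 100] cM", {
  for (f in c(0.001, 0.05, 0.3, 0.49)) {
    for (kind in c("BC_FEMALE", "F2_SELF")) {
      u <- recombination_uncertainty(f, 200, kind)
      cm <- if (kind == "F2_SELF") 100 * (1 - sqrt(1 - 2 * f)) else 100 * f
      expect_lte(u$ci_low_cM, cm)
      expect_gte(u$ci_high_cM, cm)
      expect_gte(u$ci_low_cM, 0)
      expect_lte(u$ci_high_cM, 100)
    }
  }
})

test_that("genotype comparisons build the recombined-vs-total table correctly", {
  a <- seed_counts(50, 50, 450, 450, design = "BC_FEMALE", genotype = "wt")
  same <- seed_counts(50, 50, 450, 450, design = "BC_FEMALE", genotype = "mut")
  fis <- compare_genotypes(a, same, method = "fisher")
  expect_equal(fis$p_value, 1)
  expect_equal(unname(fis$table[, "recombined"]), c(100, 100))
  chi <- compare_genotypes(a, same, method = "chi2")
  expect_equal(chi$statistic, 0)
  expect_equal(chi$df, 1L)

  f2a <- seed_counts(50, 45, 700, 205, design = "F2_SELF")
  expect_error(compare_genotypes(a, f2a), class = "ftl_design_error")

  zero <- seed_counts(0, 0, 500, 500, design = "BC_FEMALE")
  expect_error(compare_genotypes(zero, zero, method = "chi2"),
               class = "ftl_degenerate_table_error")
  expect_equal(compare_genotypes(zero, zero, method = "fisher")$p_value, 1)
})

test_that("Fisher p equals full hypergeometric enumeration", {
  a <- seed_counts(5, 0, 50, 45, design = "BC_FEMALE")
  b <- seed_counts(12, 8, 40, 40, design = "BC_FEMALE")
  cmp <- compare_genotypes(a, b, method = "fisher")
  expect_equal(cmp$p_value, fisher_p_enum(cmp$table), tolerance = 1e-12)

  tables <- withr::with_seed(7, {
    lapply(1:200, function(i) {
      n1 <- sample(1:60, 1)
      n2 <- sample(1:60, 1)
      x1 <- sample(0:n1, 1)
      x2 <- sample(0:n2, 1)
      rbind(c(x1, n1 - x1), c(x2, n2 - x2))
    })
  })
  for (tab in tables) {
    a <- seed_counts(tab[1L, 1L], 0, tab[1L, 2L], 0, design = "BC_FEMALE")
    b <- seed_counts(tab[2L, 1L], 0, tab[2L, 2L], 0, design = "BC_FEMALE")
    cmp <- compare_genotypes(a, b, method = "fisher")
    expect_equal(cmp$p_value, fisher_p_enum(cmp$table), tolerance = 1e-12)
  }
})

test_that("pooling sums replicate counts and guards designs", {
  reps <- list(seed_counts(10, 12, 190, 188, design = "BC_MALE", genotype = "wt"),
               seed_counts(8, 9, 180, 203, design = "BC_MALE", genotype = "wt"))
  pooled <- pool_seed_counts(reps)
  expect_equal(pooled$n_green_only, 18)
  expect_equal(pooled$n_total, 800)
  expect_equal(pooled$genotype, "wt")
  mixed <- list(reps[[1L]], seed_counts(1, 1, 1, 1, design = "F2_SELF"))
  expect_error(pool_seed_counts(mixed), class = "ftl_design_error")
})

test_that("per-plant results plot builds from an estimate table", {
  df <- make_counts_df(
    list(plant_id = "w1", genotype = "wt", design = "BC_FEMALE",
         g = 50, r = 50, b = 450, n = 450),
    list(plant_id = "m1", genotype = "mut", design = "BC_FEMALE",
         g = 90, r = 85, b = 415, n = 410))
  results <- estimate_recombination_table(df)
  p <- plot_recombination(results)
  expect_s3_class(p, "ggplot")
})

test_that("trans-configured designs are rejected", {
  expect_error(cross_design("F2_SELF", configuration = "TRANS"),
               class = "ftl_domain_error")
})
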