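#' Meiotic model parameters for the simulator
#'
#' One parameter set drives every simulated input: seed segregation, cytology
#' and fertility. `r_female` / `r_male` are the sex-specific recombination
#' fractions in the scored marker interval. `lambda_classII` is the mean
#' number of interference-insensitive (class II) crossovers per chromosome pair
#' per meiosis, modelled as Poisson. When `classI_active` is `TRUE` the
#' interference-sensitive (ZMM-dependent) pathway guarantees the obligate
#' crossover, so every chromosome pair forms a bivalent; a ZMM-deficient
#' meiosis is modelled with `classI_active = FALSE`, leaving only the Poisson
#' class II events. `frag_prob` is the per-cell probability of visible
#' chromosome fragmentation at anaphase.
#'
#' Defaults model a wild-type Arabidopsis plant scored in a sub-telomeric
#' chromosome-3 FTL interval: higher male than female recombination in such
#' intervals (`r_male = 0.22`, `r_female = 0.14`), five chromosome pairs, an
#' active obligate-CO pathway, a residual class II rate of 0.35 COs per pair,
#' and no fragmentation.
#'
#' @param r_female,r_male Recombination fractions in `[0, 1]`.
#' @param n_chromosomes Number of chromosome pairs (Arabidopsis: 5).
#' @param lambda_classII Mean class II COs per chromosome pair (>= 0).
#' @param classI_active Logical; obligate-CO pathway functional?
#' @param frag_prob Per-cell fragmentation probability in `[0, 1]`.
#' @return An object of class `meiosis_params`.
#' @export
meiosis_params <- function(r_female = 0.14, r_male = 0.22,
                           n_chromosomes = 5L, lambda_classII = 0.35,
                           classI_active = TRUE, frag_prob = 0) {
  assert_fraction(r_female, "r_female")
  assert_fraction(r_male, "r_male")
  assert_count(n_chromosomes, "n_chromosomes", min = 1)
  assert_count(lambda_classII, "lambda_classII")
  assert_fraction(frag_prob, "frag_prob")
  if (!is.logical(classI_active) || length(classI_active) != 1L || is.na(classI_active)) {
    ftl_stop("`classI_active` must be TRUE or FALSE", "ftl_domain_error")
  }
  structure(
    list(r_female = r_female, r_male = r_male,
         n_chromosomes = as.integer(n_chromosomes),
         lambda_classII = lambda_classII,
         classI_active = classI_active, frag_prob = frag_prob),
    class = "meiosis_params"
  )
}

#' @export
print.meiosis_params <- function(x, ...) {
  cat(sprintf(
    "<meiosis_params> r_f %.3f | r_m %.3f | %d chrom | lambda_II %.3f | classI %s | frag %.2f\n",
    x$r_female, x$r_male, x$n_chromosomes, x$lambda_classII,
    if (x$classI_active) "on" else "off", x$frag_prob))
  invisible(x)
}

#' Two-channel seed fluorescence measurement model
#'
#' Per-channel intensities are log-normal: seeds carrying the marker draw from
#' the positive population, marker-free seeds from the autofluorescence
#' (negative) population. A per-plant multiplicative scale factor (log-normal
#' with sd `plant_effect_sd`) models illumination/exposure differences between
#' plants, and `crosstalk` is the fraction of the other channel's underlying
#' signal bleeding into a channel before scaling.
#'
#' Defaults give a positive population ~20x brighter than autofluorescence
#' (log-means 7.5 vs 4.5, log-sd 0.35 in both), i.e. a separation of about
#' 8.6 pooled log-sds — a cleanly bimodal channel, as seen in practice for
#' seed-coat fluorescent markers — with mild plant-to-plant scale noise and 2%
#' spectral crosstalk.
#'
#' @param green,red Per-channel lists with entries `log_mean_pos`,
#'   `log_sd_pos`, `log_mean_neg`, `log_sd_neg` (natural-log scale, arbitrary
#'   intensity units).
#' @param plant_effect_sd Log-scale sd of the per-plant multiplicative factor.
#' @param crosstalk Bleed-through fraction in `[0, 0.5)`.
#' @return An object of class `intensity_model`.
#' @export
intensity_model <- function(green = list(log_mean_pos = 7.5, log_sd_pos = 0.35,
                                         log_mean_neg = 4.5, log_sd_neg = 0.35),
                            red = list(log_mean_pos = 7.5, log_sd_pos = 0.35,
                                       log_mean_neg = 4.5, log_sd_neg = 0.35),
                            plant_effect_sd = 0.15, crosstalk = 0.02) {
  for (ch in list(green = green, red = red)) {
    if (!all(c("log_mean_pos", "log_sd_pos", "log_mean_neg", "log_sd_neg") %in% names(ch))) {
      ftl_stop("channel models need log_mean_pos/log_sd_pos/log_mean_neg/log_sd_neg",
               "ftl_model_error")
    }
    if (ch$log_sd_pos <= 0 || ch$log_sd_neg <= 0) {
      ftl_stop("channel log-sds must be positive", "ftl_model_error")
    }
    if (ch$log_mean_pos <= ch$log_mean_neg) {
      ftl_stop("positive population must be brighter than the negative population",
               "ftl_model_error")
    }
  }
  if (!is.numeric(plant_effect_sd) || plant_effect_sd < 0) {
    ftl_stop("`plant_effect_sd` must be >= 0", "ftl_model_error")
  }
  if (!is.numeric(crosstalk) || crosstalk < 0 || crosstalk >= 0.5) {
    ftl_stop("`crosstalk` must be in [0, 0.5)", "ftl_model_error")
  }
  structure(list(green = green, red = red,
                 plant_effect_sd = plant_effect_sd, crosstalk = crosstalk),
            class = "intensity_model")
}

#' Simulate seed-class counts for one plant
#'
#' Draws the four seed fluorescence classes from a multinomial with
#' probabilities [expected_seed_class_probs()] for the design and the
#' parameter set's sex-specific recombination fractions.
#'
#' @param design A [cross_design()] or design-kind string.
#' @param params A [meiosis_params()] object.
#' @param n_seeds Number of seeds to draw (>= 0).
#' @param rng_seed Integer seed; the draw is reproducible given
#'   (`design`, `params`, `n_seeds`, `rng_seed`). The global RNG state is left
#'   untouched.
#' @param plant_id,genotype Identifiers for the resulting counts.
#' @return A [seed_counts()] object; the seed used is recorded in
#'   `attr(, "rng_seed")`.
#' @examples
#' simulate_seed_counts("BC_FEMALE", meiosis_params(r_female = 0.1), 1000, rng_seed = 1)
#' @export
simulate_seed_counts <- function(design, params, n_seeds, rng_seed,
                                 plant_id = "sim_plant", genotype = "sim") {
  design <- as_cross_design(design)
  if (!inherits(params, "meiosis_params")) {
    ftl_stop("`params` must be a meiosis_params object", "ftl_domain_error")
  }
  assert_count(n_seeds, "n_seeds")
  probs <- expected_seed_class_probs(design, params$r_female, params$r_male)
  draw <- withr::with_seed(rng_seed, {
    if (n_seeds == 0) rep(0L, 4L) else
      as.integer(stats::rmultinom(1L, size = n_seeds, prob = probs))
  })
  out <- seed_counts(draw[1L], draw[2L], draw[3L], draw[4L],
                     design = design, plant_id = plant_id, genotype = genotype)
  attr(out, "rng_seed") <- rng_seed
  out
}

#' Simulate per-seed two-channel intensities
#'
#' Expands a `seed_counts` object into one record per seed and draws
#' measured intensities from an [intensity_model()]: the underlying channel
#' signal is log-normal from the positive population when the seed's true
#' class carries that marker, from the negative (autofluorescence) population
#' otherwise; crosstalk mixes the underlying signals and a per-plant,
#' per-channel log-normal scale factor is applied last. True classes are
#' retained for downstream accuracy checks.
#'
#' @param counts A [seed_counts()] object.
#' @param model An [intensity_model()].
#' @param rng_seed Integer seed (global RNG state untouched).
#' @return Data frame: `seed_id`, `plant_id`, `intensity_green`,
#'   `intensity_red`, `true_class` (one of `green_only`, `red_only`, `both`,
#'   `neither`).
#' @export
simulate_seed_intensities <- function(counts, model = intensity_model(), rng_seed) {
  if (!inherits(counts, "seed_counts")) {
    ftl_stop("`counts` must be a seed_counts object", "ftl_domain_error")
  }
  if (!inherits(model, "intensity_model")) {
    ftl_stop("`model` must be an intensity_model object", "ftl_model_error")
  }
  tallies <- c(counts$n_green_only, counts$n_red_only, counts$n_both,
               counts$n_neither)
  if (any(tallies != round(tallies))) {
    ftl_stop("per-seed simulation needs integer class counts", "ftl_domain_error")
  }
  classes <- rep(c("green_only", "red_only", "both", "neither"), times = tallies)
  n <- length(classes)
  withr::with_seed(rng_seed, {
    classes <- if (n) sample(classes) else classes  # shuffle scoring order
    has_g <- classes %in% c("green_only", "both")
    has_r <- classes %in% c("red_only", "both")
    draw_channel <- function(positive, ch) {
      mu <- ifelse(positive, ch$log_mean_pos, ch$log_mean_neg)
      sd <- ifelse(positive, ch$log_sd_pos, ch$log_sd_neg)
      exp(stats::rnorm(n, mu, sd))
    }
    base_g <- draw_channel(has_g, model$green)
    base_r <- draw_channel(has_r, model$red)
    scale_g <- exp(stats::rnorm(1L, 0, model$plant_effect_sd))
    scale_r <- exp(stats::rnorm(1L, 0, model$plant_effect_sd))
    data.frame(
      seed_id = if (n) sprintf("%s_s%04d", counts$plant_id, seq_len(n)) else character(0),
      plant_id = rep(counts$plant_id, n),
      intensity_green = (base_g + model$crosstalk * base_r) * scale_g,
      intensity_red = (base_r + model$crosstalk * base_g) * scale_r,
      true_class = classes,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate metaphase I cytology
#'
#' Each chromosome pair of each cell independently receives
#' `Poisson(lambda_classII)` class II crossovers; with `classI_active` the
#' obligate-CO pathway adds at least one crossover to every pair. A pair with
#' at least one crossover appears as a bivalent, otherwise as two univalents,
#' so `n_bivalents` counts pairs with >= 1 CO (and is `Binomial(n_chromosomes,
#' 1 - exp(-lambda))` when class I is inactive). Fragmentation is a
#' cell-level Bernoulli with probability `frag_prob`.
#'
#' @param params A [meiosis_params()] object.
#' @param n_cells Number of metaphase cells to draw (>= 0).
#' @param rng_seed Integer seed (global RNG state untouched).
#' @param genotype,sex Labels attached to every cell.
#' @return Data frame: `cell_id`, `genotype`, `sex`, `n_bivalents`,
#'   `has_fragments`.
#' @examples
#' simulate_cytology(meiosis_params(classI_active = FALSE), 10, rng_seed = 7)
#' @export
simulate_cytology <- function(params, n_cells, rng_seed,
                              genotype = "sim", sex = c("male", "female")) {
  if (!inherits(params, "meiosis_params")) {
    ftl_stop("`params` must be a meiosis_params object", "ftl_domain_error")
  }
  sex <- match.arg(sex)
  assert_count(n_cells, "n_cells")
  n_cells <- as.integer(n_cells)
  withr::with_seed(rng_seed, {
    if (n_cells == 0L) {
      n_biv <- integer(0)
      frag <- logical(0)
    } else {
      cos <- matrix(stats::rpois(n_cells * params$n_chromosomes,
                                 params$lambda_classII),
                    nrow = n_cells)
      bivalent <- if (params$classI_active) cos >= 0 else cos > 0
      n_biv <- as.integer(rowSums(bivalent))
      frag <- stats::runif(n_cells) < params$frag_prob
    }
    data.frame(
      cell_id = if (n_cells) sprintf("cell_%04d", seq_len(n_cells)) else character(0),
      genotype = rep(genotype, n_cells),
      sex = rep(sex, n_cells),
      n_bivalents = n_biv,
      has_fragments = frag,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate seeds-per-fruit fertility
#'
#' Links seed set to chromosome segregation: for every ovule one maternal and
#' one paternal meiosis are drawn from the cytology model. A meiosis with `u`
#' univalent pairs produces a euploid gamete with probability `(1/2)^u`
#' (each achiasmate pair segregates at random), and a seed forms only when
#' both gametes are euploid. With the obligate CO active every gamete is
#' euploid and the expected seed set equals the ovule number.
#'
#' @param params A [meiosis_params()] object (shared by both sexes here).
#' @param n_plants Number of plants (>= 1).
#' @param fruits_per_plant Fruits scored per plant (>= 1; the field-standard
#'   design scores at least five plants and ten fruits each).
#' @param ovules_per_fruit Ovules per fruit (>= 1; ~50 in Arabidopsis).
#' @param rng_seed Integer seed (global RNG state untouched).
#' @param genotype Label attached to every record.
#' @return Data frame in long format: `plant_id`, `genotype`, `fruit_index`,
#'   `seeds`.
#' @export
simulate_fertility <- function(params, n_plants = 5L, fruits_per_plant = 10L,
                               ovules_per_fruit = 50L, rng_seed,
                               genotype = "sim") {
  if (!inherits(params, "meiosis_params")) {
    ftl_stop("`params` must be a meiosis_params object", "ftl_domain_error")
  }
  assert_count(n_plants, "n_plants", min = 1)
  assert_count(fruits_per_plant, "fruits_per_plant", min = 1)
  assert_count(ovules_per_fruit, "ovules_per_fruit", min = 1)
  n_plants <- as.integer(n_plants)
  fruits_per_plant <- as.integer(fruits_per_plant)
  ovules_per_fruit <- as.integer(ovules_per_fruit)
  p_biv <- 1 - exp(-params$lambda_classII)
  withr::with_seed(rng_seed, {
    n_fruit_tot <- n_plants * fruits_per_plant
    seeds <- vapply(seq_len(n_fruit_tot), function(i) {
      if (params$classI_active) {
        # every pair gets the obligate CO: all gametes euploid
        return(ovules_per_fruit)
      }
      u_mat <- params$n_chromosomes -
        stats::rbinom(ovules_per_fruit, params$n_chromosomes, p_biv)
      u_pat <- params$n_chromosomes -
        stats::rbinom(ovules_per_fruit, params$n_chromosomes, p_biv)
      viable <- stats::runif(ovules_per_fruit) < 0.5^u_mat &
        stats::runif(ovules_per_fruit) < 0.5^u_pat
      sum(viable)
    }, integer(1))
    data.frame(
      plant_id = sprintf("%s_p%02d", genotype, rep(seq_len(n_plants),
                                                   each = fruits_per_plant)),
      genotype = rep(genotype, n_fruit_tot),
      fruit_index = rep(seq_len(fruits_per_plant), times = n_plants),
      seeds = seeds,
      stringsAsFactors = FALSE
    )
  })
}
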