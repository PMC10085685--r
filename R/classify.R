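#' Normalize per-seed intensities
#'
#' Removes multiplicative plant-to-plant scale differences (illumination,
#' exposure) before thresholds are fitted across plants, by dividing each
#' channel by a per-plant scale anchor:
#' \describe{
#'   \item{`per_plant_geomean` (default)}{the plant's geometric mean intensity
#'     in that channel. On a bimodal fluorescence channel the geometric mean
#'     moves smoothly with the positive-seed fraction, so it is a stable
#'     anchor even when positives are near one half of the seeds (as in any
#'     backcross, where the plant median sits in the near-empty gap between
#'     the two modes and jumps between them from plant to plant).}
#'   \item{`per_plant_median`}{the plant's median intensity in that channel.
#'     Stable only when one mode holds a clear majority of the seeds; retained
#'     for data where that holds and for comparability.}
#'   \item{`none`}{returns the input unchanged.}
#' }
#' Both anchors are exactly scale-equivariant: rescaling all of a plant's
#' intensities leaves its normalized values unchanged. Record order and count
#' are preserved.
#'
#' @param records Data frame with columns `seed_id`, `plant_id`,
#'   `intensity_green`, `intensity_red` (positive intensities).
#' @param method `"per_plant_geomean"`, `"per_plant_median"` or `"none"`.
#' @return Data frame of the same shape with normalized intensities.
#' @export
normalize_intensities <- function(records,
                                  method = c("per_plant_geomean",
                                             "per_plant_median", "none")) {
  method <- match.arg(method)
  check_intensity_records(records)
  if (method == "none") return(records)
  anchor <- switch(method,
    per_plant_geomean = function(x) exp(mean(log(x))),
    per_plant_median = stats::median)
  for (ch in c("intensity_green", "intensity_red")) {
    scale <- stats::ave(records[[ch]], records$plant_id, FUN = anchor)
    records[[ch]] <- records[[ch]] / scale
  }
  records
}

check_intensity_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    ftl_stop("intensity records are empty", "ftl_empty_input_error")
  }
  needed <- c("plant_id", "intensity_green", "intensity_red")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    ftl_stop(paste("records lack required columns:", paste(missing, collapse = ", ")),
             "ftl_malformed_record_error")
  }
  for (ch in c("intensity_green", "intensity_red")) {
    v <- records[[ch]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      ftl_stop(sprintf("`%s` must be finite and strictly positive", ch),
               "ftl_malformed_record_error")
    }
  }
  invisible(records)
}

# Density-valley threshold: the log-intensity at the density minimum between
# the two dominant modes. Used as fallback when the mixture fit does not
# separate the channel. Returns NA unless the valley is prominent: the minor
# mode must reach at least 10% of the major mode's density and the valley must
# dip below half the minor mode — splitting a unimodal distribution anywhere
# looks "separated" by mean-distance criteria, so unimodality is judged here,
# on the density shape.
valley_threshold <- function(x) {
  d <- stats::density(x, n = 512)
  y <- d$y
  # interior local maxima (flat-top safe: zero slopes carry the previous sign)
  s <- sign(diff(y))
  s[s == 0] <- 1
  maxima <- which(diff(s) == -2) + 1L
  if (length(maxima) < 2L) return(NA_real_)
  top2 <- maxima[order(y[maxima], decreasing = TRUE)][1:2]
  minor_height <- min(y[top2])
  if (minor_height < 0.1 * max(y[top2])) return(NA_real_)
  idx <- seq(min(top2), max(top2))
  valley_depth <- min(y[idx])
  if (valley_depth > 0.5 * minor_height) return(NA_real_)
  d$x[idx][which.min(y[idx])]
}

# Separation between the two sides of a split, in pooled-sd units.
split_separation <- function(x, thr) {
  lo <- x[x <= thr]; hi <- x[x > thr]
  if (length(lo) < 2L || length(hi) < 2L) return(0)
  pooled <- sqrt((stats::var(lo) + stats::var(hi)) / 2)
  if (!is.finite(pooled) || pooled == 0) return(Inf)
  (mean(hi) - mean(lo)) / pooled
}

#' @importFrom mclust Mclust mclustBIC
fit_channel <- function(x, channel) {
  # G chosen by BIC between 1 and 2 components: a forced 2-component fit on a
  # unimodal channel reports a deceptively large mean separation, so the
  # one-component model winning BIC is the unimodality signal.
  fit <- tryCatch(
    mclust::Mclust(x, G = 1:2, verbose = FALSE),
    error = function(e) NULL
  )
  if (!is.null(fit) && isTRUE(fit$G == 1)) fit <- NULL  # BIC prefers unimodal
  model <- NULL
  if (!is.null(fit) && !is.null(fit$parameters)) {
    mu <- fit$parameters$mean
    sd <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sd) == 1L) sd <- rep(sd, 2L)
    w <- fit$parameters$pro
    o <- order(mu)
    mu <- mu[o]; sd <- sd[o]; w <- w[o]
    pooled <- sqrt(mean(sd^2))
    sep <- if (pooled > 0) (mu[2L] - mu[1L]) / pooled else Inf
    if (is.finite(sep) && sep >= 1 && all(sd > 0)) {
      # equal-posterior point between the component means
      g <- function(t) {
        log(w[1L]) + stats::dnorm(t, mu[1L], sd[1L], log = TRUE) -
          log(w[2L]) - stats::dnorm(t, mu[2L], sd[2L], log = TRUE)
      }
      thr <- tryCatch(
        stats::uniroot(g, lower = mu[1L], upper = mu[2L])$root,
        error = function(e) mean(mu)
      )
      model <- list(threshold = thr, mean_neg = mu[1L], sd_neg = sd[1L],
                    mean_pos = mu[2L], sd_pos = sd[2L], weight_pos = w[2L],
                    separation = sep, method = "mixture_em")
    }
  }
  if (is.null(model)) {
    thr <- valley_threshold(x)
    sep <- if (is.na(thr)) 0 else split_separation(x, thr)
    if (is.na(thr) || sep < 0.5) {
      ftl_stop(sprintf(
        "channel '%s' is unimodal or too poorly separated to threshold (separation %.2f pooled-sd)",
        channel, sep), "ftl_unclassifiable_channel_error")
    }
    lo <- x[x <= thr]; hi <- x[x > thr]
    model <- list(threshold = thr,
                  mean_neg = mean(lo), sd_neg = stats::sd(lo),
                  mean_pos = mean(hi), sd_pos = stats::sd(hi),
                  weight_pos = length(hi) / length(x),
                  separation = sep, method = "density_valley")
  }
  model
}

#' Fit per-channel classification thresholds
#'
#' Fits a two-component Gaussian mixture to the natural-log intensities of
#' each channel (pooled across plants; normalize first) and places the
#' threshold at the equal-posterior point between the two component means.
#' When the mixture does not separate the channel (separation below 1
#' pooled-sd, or the fit fails), the threshold falls back to the density
#' valley between the two dominant modes. A channel whose best split has
#' separation below 0.5 pooled-sd is declared unclassifiable and raises an
#' error naming the channel.
#'
#' Thresholds are meant to be fitted per experiment batch — all plants of a
#' genotype/cross pooled after per-plant normalization — because per-plant
#' fits are unstable at a few hundred seeds.
#'
#' @param records Intensity records (see [normalize_intensities()]);
#'   at least 50 are recommended (fewer triggers a warning).
#' @param n_components Number of mixture components; only 2 is supported.
#' @return An object of class `classifier_model` with per-channel
#'   `threshold`, component means/sds, `separation` (distance between
#'   component means in pooled-sd units) and the fitting `method` used.
#' @export
fit_thresholds <- function(records, n_components = 2L) {
  check_intensity_records(records)
  if (!identical(as.integer(n_components), 2L)) {
    ftl_stop("only a 2-component mixture is supported", "ftl_domain_error")
  }
  if (nrow(records) < 50L) {
    warning("fewer than 50 seeds: threshold fit may be unstable", call. = FALSE)
  }
  channels <- list(
    green = fit_channel(log(records$intensity_green), "green"),
    red = fit_channel(log(records$intensity_red), "red")
  )
  structure(list(channels = channels, n_records = nrow(records)),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat("<classifier_model> fitted on", x$n_records, "seeds\n")
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %s: log-threshold %.3f (%s), components %.2f / %.2f, separation %.1f sd\n",
                nm, ch$threshold, ch$method, ch$mean_neg, ch$mean_pos, ch$separation))
  }
  invisible(x)
}

#' Classify seeds into the four fluorescence classes
#'
#' A seed is positive for a channel when its log intensity is at or above the
#' channel threshold (ties classify as positive), giving four classes:
#' `both`, `green_only`, `red_only`, `neither`. Per-plant class tallies
#' conserve the record count.
#'
#' @param records Intensity records, normalized the same way as the records
#'   the model was fitted on.
#' @param model A [fit_thresholds()] `classifier_model`.
#' @param design Optional [cross_design()] attached to the returned counts.
#' @return List with `labels` (character vector, one per record, in input
#'   order) and `counts` (data frame: one row per plant with the four class
#'   counts and `n_total`).
#' @export
classify_seeds <- function(records, model, design = NULL) {
  check_intensity_records(records)
  if (!inherits(model, "classifier_model")) {
    ftl_stop("`model` must come from fit_thresholds()", "ftl_domain_error")
  }
  g_pos <- log(records$intensity_green) >= model$channels$green$threshold
  r_pos <- log(records$intensity_red) >= model$channels$red$threshold
  labels <- ifelse(g_pos & r_pos, "both",
            ifelse(g_pos, "green_only",
            ifelse(r_pos, "red_only", "neither")))
  plants <- unique(records$plant_id)
  counts <- do.call(rbind, lapply(plants, function(p) {
    lab <- labels[records$plant_id == p]
    data.frame(plant_id = p,
               n_green_only = sum(lab == "green_only"),
               n_red_only = sum(lab == "red_only"),
               n_both = sum(lab == "both"),
               n_neither = sum(lab == "neither"),
               n_total = length(lab),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(design)) counts$design <- as_cross_design(design)$design_kind
  list(labels = labels, counts = counts)
}

#' Quality-control flags for seed-class counts
#'
#' Screens one plant's counts for conditions that compromise the estimators:
#' \describe{
#'   \item{`transmission_distortion`}{Backcross only: the both-colour and
#'     no-colour (parental) classes should be 1:1; a chi-square p below 0.01
#'     flags distorted marker transmission.}
#'   \item{`f2_out_of_model`}{F2 single-colour fraction above 0.5, outside the
#'     inversion formula's range.}
#'   \item{`low_count`}{Fewer than 400 seeds, the minimum scored per technical
#'     replicate in the reference protocol.}
#' }
#' QC never raises an error; it returns a (possibly empty) table of flags.
#'
#' @param counts A [seed_counts()] object.
#' @param min_seeds Low-count threshold (default 400).
#' @return Data frame with columns `flag` and `message` (zero rows when clean).
#' @export
qc_counts <- function(counts, min_seeds = 400L) {
  if (!inherits(counts, "seed_counts")) {
    ftl_stop("`counts` must be a seed_counts object", "ftl_domain_error")
  }
  flags <- list()
  kind <- counts$design$design_kind
  if (kind != "F2_SELF" && counts$n_both + counts$n_neither > 0) {
    ht <- suppressWarnings(
      stats::chisq.test(c(counts$n_both, counts$n_neither), p = c(0.5, 0.5))
    )
    if (is.finite(ht$p.value) && ht$p.value < 0.01) {
      flags <- c(flags, list(data.frame(
        flag = "transmission_distortion",
        message = sprintf(
          "backcross parental classes %g:%g deviate from 1:1 (chi-square p = %.2g)",
          counts$n_both, counts$n_neither, ht$p.value))))
    }
  }
  if (kind == "F2_SELF" && counts$n_total > 0) {
    f_obs <- (counts$n_green_only + counts$n_red_only) / counts$n_total
    if (f_obs > 0.5) {
      flags <- c(flags, list(data.frame(
        flag = "f2_out_of_model",
        message = sprintf("F2 single-colour fraction %.3f exceeds 0.5", f_obs))))
    }
  }
  if (counts$n_total < min_seeds) {
    flags <- c(flags, list(data.frame(
      flag = "low_count",
      message = sprintf("only %g seeds counted (minimum %d recommended)",
                        counts$n_total, as.integer(min_seeds)))))
  }
  if (length(flags) == 0L) {
    return(data.frame(flag = character(0), message = character(0)))
  }
  do.call(rbind, flags)
}
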