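#' Cross designs for FTL recombination scoring
#'
#' An FTL interval is scored in one of three crossing designs. In a backcross
#' the marker hemizygote is crossed to wild type and only that parent's meiosis
#' is scored: `BC_FEMALE` uses the hemizygote as the female (seed) parent and
#' measures female recombination, `BC_MALE` is the reciprocal cross measuring
#' male recombination. `F2_SELF` scores seed from a selfed hemizygote, in which
#' every seed combines one female and one male meiotic product.
#'
#' Only the cis marker configuration is supported: the hemizygous parent
#' carries both fluorescent transgenes on the same homolog, so parental
#' gametes carry both markers or neither, and recombinant gametes carry
#' exactly one.
#'
#' @param design_kind One of `"F2_SELF"`, `"BC_FEMALE"`, `"BC_MALE"`.
#' @param marker_a,marker_b Labels for the two linked dominant markers
#'   (defaults match the FTL 420 interval: GFP and dsRed on chromosome 3).
#' @param configuration Marker phase in the hemizygous parent; must be
#'   `"CIS"`. Trans-configured pairs are not supported.
#' @param interval_note Optional free-text metadata (e.g. bp coordinates).
#'
#' @return An object of class `cross_design`.
#' @examples
#' cross_design("BC_FEMALE")
#' cross_design("F2_SELF", interval_note = "Chr3 256516..5361637")
#' @export
cross_design <- function(design_kind = c("F2_SELF", "BC_FEMALE", "BC_MALE"),
                         marker_a = "GFP", marker_b = "dsRed",
                         configuration = "CIS", interval_note = NULL) {
  design_kind <- match.arg(design_kind)
  if (!identical(toupper(configuration), "CIS")) {
    ftl_stop("only the CIS marker configuration is supported (trans not implemented)",
             "ftl_domain_error")
  }
  structure(
    list(design_kind = design_kind,
         marker_a = as.character(marker_a),
         marker_b = as.character(marker_b),
         configuration = "CIS",
         interval_note = interval_note),
    class = "cross_design"
  )
}

#' Coerce a design descriptor to a `cross_design`
#'
#' Strings such as `"BC_FEMALE"` are accepted anywhere a design is expected.
#'
#' @param x A `cross_design` or a design-kind string.
#' @return A `cross_design`.
#' @export
as_cross_design <- function(x) {
  if (inherits(x, "cross_design")) return(x)
  if (is.character(x) && length(x) == 1L) return(cross_design(x))
  ftl_stop("cannot interpret `x` as a cross design", "ftl_design_error")
}

is_backcross <- function(design) {
  design$design_kind %in% c("BC_FEMALE", "BC_MALE")
}

#' @export
print.cross_design <- function(x, ...) {
  cat(sprintf("<cross_design> %s | markers %s + %s in %s\n",
              x$design_kind, x$marker_a, x$marker_b, x$configuration))
  if (!is.null(x$interval_note)) cat("  interval:", x$interval_note, "\n")
  invisible(x)
}

#' Per-plant seed-class counts
#'
#' Tallies of the four seed fluorescence classes for one plant (or one pooled
#' replicate): green-only and red-only seeds are the recombinant classes in a
#' cis-configured FTL, both-colour and colourless seeds are parental (plus, in
#' an F2, double-recombinant combinations).
#'
#' Counts may be non-integer: expected (fractional) counts are accepted so the
#' estimators can be applied to model expectations as well as observed data.
#'
#' @param n_green_only,n_red_only,n_both,n_neither Non-negative class counts.
#' @param design A [cross_design()] (or design-kind string).
#' @param plant_id,genotype Identifiers carried through to results tables.
#' @return An object of class `seed_counts` with computed `n_total`.
#' @examples
#' seed_counts(50, 50, 450, 450, design = "BC_FEMALE")
#' @export
seed_counts <- function(n_green_only, n_red_only, n_both, n_neither,
                        design, plant_id = "plant_1", genotype = "unknown") {
  design <- as_cross_design(design)
  n_green_only <- unname(n_green_only)
  n_red_only <- unname(n_red_only)
  n_both <- unname(n_both)
  n_neither <- unname(n_neither)
  for (nm in c("n_green_only", "n_red_only", "n_both", "n_neither")) {
    assert_count(get(nm), nm)
  }
  structure(
    list(n_green_only = n_green_only,
         n_red_only = n_red_only,
         n_both = n_both,
         n_neither = n_neither,
         n_total = n_green_only + n_red_only + n_both + n_neither,
         plant_id = as.character(plant_id),
         genotype = as.character(genotype),
         design = design),
    class = "seed_counts"
  )
}

#' @export
print.seed_counts <- function(x, ...) {
  cat(sprintf("<seed_counts> %s (%s, %s): G %g | R %g | GR %g | none %g (total %g)\n",
              x$plant_id, x$genotype, x$design$design_kind,
              x$n_green_only, x$n_red_only, x$n_both, x$n_neither, x$n_total))
  invisible(x)
}

#' Pool seed counts across replicates
#'
#' Sums class counts over plants of the same genotype and design. Genotype-level
#' tests are run on pooled counts (the proportion of recombinant seeds among all
#' seeds counted); per-plant counts are kept for plotting and per-plant
#' estimates.
#'
#' @param counts A list of `seed_counts`, all sharing one design kind.
#' @param plant_id,genotype Identifiers for the pooled object; genotype defaults
#'   to the shared genotype of the inputs.
#' @return A single `seed_counts` object.
#' @export
pool_seed_counts <- function(counts, plant_id = "pooled", genotype = NULL) {
  if (inherits(counts, "seed_counts")) counts <- list(counts)
  if (length(counts) == 0L) ftl_stop("no counts to pool", "ftl_empty_input_error")
  kinds <- vapply(counts, function(x) x$design$design_kind, character(1))
  if (length(unique(kinds)) != 1L) {
    ftl_stop("cannot pool counts from different designs", "ftl_design_error")
  }
  if (is.null(genotype)) {
    gts <- unique(vapply(counts, `[[`, character(1), "genotype"))
    genotype <- if (length(gts) == 1L) gts else "pooled"
  }
  tot <- function(f) sum(vapply(counts, `[[`, numeric(1), f))
  seed_counts(tot("n_green_only"), tot("n_red_only"),
              tot("n_both"), tot("n_neither"),
              design = counts[[1L]]$design,
              plant_id = plant_id, genotype = genotype)
}
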