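# CSV readers/writers for the pipeline's four table types. All writers are
# atomic (write to a temporary sibling, then rename) and prepend '#' comment
# headers carrying provenance (package version, RNG seed, config hash);
# readers skip '#' lines.

ftl_schemas <- list(
  seed_counts = list(
    required = c("plant_id", "genotype", "design", "n_green_only",
                 "n_red_only", "n_both", "n_neither"),
    optional = "n_total"),
  seed_intensities = list(
    required = c("seed_id", "plant_id", "intensity_green", "intensity_red"),
    optional = "true_class"),
  cytology = list(
    required = c("cell_id", "genotype", "sex", "n_bivalents", "has_fragments"),
    optional = character(0)),
  fertility = list(
    required = c("plant_id", "genotype", "fruit_index", "seeds"),
    optional = character(0)),
  results = list(
    required = c("plant_id", "genotype", "design", "f_obs", "cM", "se_cM",
                 "ci_low", "ci_high", "n_total", "warnings"),
    optional = character(0))
)

write_csv_atomic <- function(df, path, meta = character(0)) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, open = "wt", encoding = "UTF-8")
  ok <- FALSE
  tryCatch({
    header <- sprintf("# ftlmap %s | written %s",
                      as.character(utils::packageVersion("ftlmap")),
                      format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    meta <- meta[nzchar(meta)]
    if (length(meta)) header <- c(header, paste0("# ", meta))
    writeLines(header, con)
    utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
    ok <- TRUE
  }, finally = {
    close(con)
    if (!ok) unlink(tmp)
  })
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    ftl_stop(sprintf("could not write '%s'", path), "ftl_io_error")
  }
  invisible(path)
}

read_ftl_csv <- function(path, schema_name) {
  if (!file.exists(path)) {
    ftl_stop(sprintf("file not found: '%s'", path), "ftl_io_error")
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                    strip.white = TRUE),
    error = function(e) ftl_stop(sprintf("cannot parse '%s': %s", path,
                                         conditionMessage(e)), "ftl_io_error")
  )
  problems <- validate_df(df, schema_name)
  if (nrow(problems)) {
    first <- problems[1L, ]
    ftl_stop(sprintf("malformed %s file '%s': row %s, column %s: %s",
                     schema_name, path, first$row, first$column, first$problem),
             "ftl_malformed_record_error")
  }
  df
}

#' Read / write seed-count tables
#'
#' One row per plant: `plant_id`, `genotype`,
#' `design` (`F2_SELF`/`BC_FEMALE`/`BC_MALE`), the four class counts, and an
#' `n_total` column checked for conservation. Comma-separated, UTF-8, header
#' required; lines starting with `#` are comments.
#'
#' @param path File path.
#' @param df Data frame with the columns above (`n_total` added if absent).
#' @param meta Character vector of provenance lines for the comment header.
#' @return `read_seed_counts` returns the validated data frame;
#'   `write_seed_counts` returns `path` invisibly.
#' @export
read_seed_counts <- function(path) read_ftl_csv(path, "seed_counts")

#' @rdname read_seed_counts
#' @export
write_seed_counts <- function(df, path, meta = character(0)) {
  if (!"n_total" %in% names(df)) {
    df$n_total <- df$n_green_only + df$n_red_only + df$n_both + df$n_neither
  }
  validate_count_df(df)
  write_csv_atomic(df, path, meta)
}

#' Read / write per-seed intensity tables
#'
#' One row per seed: `seed_id`, `plant_id`, `intensity_green`,
#' `intensity_red`, and optionally `true_class` (simulated data only).
#' Intensities must be strictly positive; non-positive values are rejected at
#' parse time.
#'
#' @inheritParams read_seed_counts
#' @export
read_seed_intensities <- function(path) read_ftl_csv(path, "seed_intensities")

#' @rdname read_seed_intensities
#' @export
write_seed_intensities <- function(df, path, meta = character(0)) {
  check_intensity_records(df)
  write_csv_atomic(df, path, meta)
}

#' Read / write cytology tables
#'
#' One row per metaphase cell: `cell_id`, `genotype`, `sex`, `n_bivalents`
#' (0-5), `has_fragments` (TRUE/FALSE).
#'
#' @inheritParams read_seed_counts
#' @export
read_cytology <- function(path) {
  df <- read_ftl_csv(path, "cytology")
  df$has_fragments <- as.logical(df$has_fragments)
  df
}

#' @rdname read_cytology
#' @export
write_cytology <- function(df, path, meta = character(0)) {
  check_cytology_df(df)
  write_csv_atomic(df, path, meta)
}

#' Read / write fertility tables
#'
#' Long format, one row per fruit: `plant_id`, `genotype`, `fruit_index`,
#' `seeds` (non-negative).
#'
#' @inheritParams read_seed_counts
#' @export
read_fertility <- function(path) read_ftl_csv(path, "fertility")

#' @rdname read_fertility
#' @export
write_fertility <- function(df, path, meta = character(0)) {
  write_csv_atomic(df, path, meta)
}

#' Write a per-plant results table
#'
#' Columns: `plant_id`, `genotype`, `design`, `f_obs`, `cM`, `se_cM`,
#' `ci_low`, `ci_high`, `n_total`, `warnings` (semicolon-separated flags).
#'
#' @inheritParams read_seed_counts
#' @export
write_results <- function(df, path, meta = character(0)) {
  write_csv_atomic(df, path, meta)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- read_ftl_csv(path, "results")
  df$warnings <- as.character(df$warnings)
  df
}

validate_count_df <- function(df) {
  problems <- validate_df(df, "seed_counts")
  if (nrow(problems)) {
    first <- problems[1L, ]
    ftl_stop(sprintf("invalid seed-count table: row %s, column %s: %s",
                     first$row, first$column, first$problem),
             "ftl_malformed_record_error")
  }
  invisible(df)
}

#' Validate a pipeline CSV against its schema
#'
#' Checks the header, column types and table invariants (non-negative integer
#' counts, class-total conservation, strictly positive intensities, bivalent
#' range, known design kinds) and returns a machine-readable list of
#' violations rather than raising.
#'
#' @param path File path (must exist and be readable).
#' @param schema_name One of `"seed_counts"`, `"seed_intensities"`,
#'   `"cytology"`, `"fertility"`, `"results"`.
#' @return Data frame with columns `row` (data row index, `NA` for file-level
#'   problems), `column`, `problem`; zero rows for a well-formed file.
#' @export
validate_csv <- function(path, schema_name) {
  if (!schema_name %in% names(ftl_schemas)) {
    ftl_stop(sprintf("unknown schema '%s'", schema_name), "ftl_config_error")
  }
  if (!file.exists(path)) {
    ftl_stop(sprintf("file not found: '%s'", path), "ftl_io_error")
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                    strip.white = TRUE),
    error = function(e) NULL
  )
  if (is.null(df)) {
    return(data.frame(row = NA_integer_, column = NA_character_,
                      problem = "file cannot be parsed as CSV",
                      stringsAsFactors = FALSE))
  }
  validate_df(df, schema_name)
}

validate_df <- function(df, schema_name) {
  schema <- ftl_schemas[[schema_name]]
  problems <- list()
  note <- function(row, column, problem) {
    problems[[length(problems) + 1L]] <<- data.frame(
      row = row, column = column, problem = problem, stringsAsFactors = FALSE)
  }
  missing <- setdiff(schema$required, names(df))
  for (m in missing) note(NA_integer_, m, "required column missing")
  if (length(missing)) return(do.call(rbind, problems))
  empty_ok <- data.frame(row = integer(0), column = character(0),
                         problem = character(0), stringsAsFactors = FALSE)
  # a header-only file is structurally valid (emptiness is the caller's call)
  if (nrow(df) == 0L) return(empty_ok)

  bad_rows <- function(ok) which(!ok)
  check_numeric <- function(col, predicate, msg) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      note(NA_integer_, col, "column is not numeric")
      return()
    }
    for (i in bad_rows(predicate(v))) note(i, col, msg)
  }
  if (schema_name == "seed_counts") {
    for (col in c("n_green_only", "n_red_only", "n_both", "n_neither")) {
      check_numeric(col, function(v) is.finite(v) & v >= 0 & v == round(v),
                    "count must be a non-negative integer")
    }
    bad_design <- !df$design %in% c("F2_SELF", "BC_FEMALE", "BC_MALE")
    for (i in which(bad_design)) note(i, "design", "unknown design kind")
    if ("n_total" %in% names(df) && is.numeric(df$n_total) &&
        all(vapply(c("n_green_only", "n_red_only", "n_both", "n_neither"),
                   function(col) is.numeric(df[[col]]), logical(1)))) {
      sums <- df$n_green_only + df$n_red_only + df$n_both + df$n_neither
      for (i in which(df$n_total != sums)) {
        note(i, "n_total", "total does not equal the sum of the four classes")
      }
    }
  } else if (schema_name == "seed_intensities") {
    for (col in c("intensity_green", "intensity_red")) {
      check_numeric(col, function(v) is.finite(v) & v > 0,
                    "intensity must be finite and strictly positive")
    }
  } else if (schema_name == "cytology") {
    check_numeric("n_bivalents", function(v) is.finite(v) & v >= 0 & v <= 5 & v == round(v),
                  "bivalent count must be an integer in 0..5")
    frag <- df$has_fragments
    coerced <- if (is.logical(frag)) frag else as.logical(frag)
    for (i in which(is.na(coerced))) note(i, "has_fragments", "not interpretable as TRUE/FALSE")
    bad_sex <- !df$sex %in% c("male", "female")
    for (i in which(bad_sex)) note(i, "sex", "sex must be male or female")
  } else if (schema_name == "fertility") {
    check_numeric("seeds", function(v) is.finite(v) & v >= 0 & v == round(v),
                  "seed count must be a non-negative integer")
  } else if (schema_name == "results") {
    check_numeric("cM", function(v) is.finite(v) & v >= 0 & v <= 100,
                  "cM must lie in [0, 100]")
  }
  if (length(problems) == 0L) return(empty_ok)
  do.call(rbind, problems)
}
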