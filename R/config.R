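# Run configuration: a flat key-value YAML file per subcommand. Unknown keys
# are rejected so typos fail loudly instead of silently using a default.

cli_config_keys <- list(
  simulate = c("seed", "out_dir", "design", "genotype", "n_plants", "n_seeds",
               "r_female", "r_male", "n_chromosomes", "lambda_classII",
               "classI_active", "frag_prob", "n_cells", "sex",
               "n_fertility_plants", "fruits_per_plant", "ovules_per_fruit",
               "write_intensities", "plant_effect_sd", "crosstalk"),
  classify = c("seed", "input", "out_dir", "normalization", "design"),
  estimate = c("seed", "input", "input_type", "out_dir", "normalization",
               "method", "control", "pool_replicates", "conf_level", "design"),
  compare = c("seed", "input", "out_dir", "method", "control",
              "pool_replicates"),
  cyto = c("seed", "cytology", "fertility", "out_dir", "control",
           "n_chromosomes"),
  validate = c("input", "schema")
)

cli_config_defaults <- list(
  simulate = list(seed = 1L, out_dir = ".", design = "BC_FEMALE",
                  genotype = "sim", n_plants = 3L, n_seeds = 1000L,
                  r_female = 0.14, r_male = 0.22, n_chromosomes = 5L,
                  lambda_classII = 0.35, classI_active = TRUE, frag_prob = 0,
                  n_cells = 50L, sex = "male", n_fertility_plants = 5L,
                  fruits_per_plant = 10L, ovules_per_fruit = 50L,
                  write_intensities = TRUE, plant_effect_sd = 0.15,
                  crosstalk = 0.02),
  classify = list(seed = 1L, out_dir = ".", normalization = "per_plant_geomean",
                  design = NULL),
  estimate = list(seed = 1L, out_dir = ".", input_type = "auto",
                  normalization = "per_plant_geomean", method = "chi2",
                  control = NULL, pool_replicates = TRUE, conf_level = 0.95,
                  design = NULL),
  compare = list(seed = 1L, out_dir = ".", method = "chi2", control = NULL,
                 pool_replicates = TRUE),
  cyto = list(seed = 1L, out_dir = ".", control = NULL, n_chromosomes = 5L,
              fertility = NULL),
  validate = list()
)

#' Read and validate a run configuration
#'
#' Configurations are flat YAML key-value files. Keys not recognised by the
#' subcommand are rejected; omitted keys take documented defaults. `overrides`
#' (typically command-line flags) take precedence over the file.
#'
#' @param path Path to a YAML config file, or `NULL` for defaults only.
#' @param subcommand One of `simulate`, `classify`, `estimate`, `compare`,
#'   `cyto`, `validate`.
#' @param overrides Named list overriding file values.
#' @return Named list of class `ftl_run_config` with a `subcommand` attribute.
#' @export
read_run_config <- function(path = NULL, subcommand, overrides = list()) {
  if (!subcommand %in% names(cli_config_keys)) {
    ftl_stop(sprintf("unknown subcommand '%s'", subcommand), "ftl_config_error")
  }
  cfg <- cli_config_defaults[[subcommand]]
  from_file <- if (is.null(path)) list() else {
    if (!file.exists(path)) {
      ftl_stop(sprintf("config file not found: '%s'", path), "ftl_io_error")
    }
    yaml::read_yaml(path)
  }
  for (src in list(from_file, overrides)) {
    if (length(src) == 0L) next
    unknown <- setdiff(names(src), cli_config_keys[[subcommand]])
    if (length(unknown)) {
      ftl_stop(sprintf("unknown config key(s) for '%s': %s", subcommand,
                       paste(unknown, collapse = ", ")), "ftl_config_error")
    }
    cfg[names(src)] <- src
  }
  structure(cfg, subcommand = subcommand, class = "ftl_run_config")
}

#' Hash of a run configuration
#'
#' MD5 of the canonical (alphabetically keyed) YAML rendering, embedded in
#' every output file's comment header so a result can be traced to the exact
#' configuration and seed that produced it.
#'
#' @param config A named list / `ftl_run_config`.
#' @return Lower-case hex string.
#' @export
config_hash <- function(config) {
  plain <- unclass(config)
  attributes(plain) <- list(names = names(plain))
  plain <- plain[order(names(plain))]
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(plain), tmp)
  unname(tools::md5sum(tmp))
}

provenance_meta <- function(config) {
  c(sprintf("seed=%s", config$seed),
    sprintf("config_md5=%s", config_hash(config)))
}
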