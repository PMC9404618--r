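# Plain-text interfaces: the fixed-header trial CSV and the YAML form of the
# simulation config. Missing values are encoded as empty CSV fields.

#' Write a trial dataset to CSV
#'
#' Fixed header `patient_id, site_id, arm, sepsis, surgical, ckd, death90,
#' krt_free_days, hosp_free_days, survivor, krt_dep90, rehosp90`; missing
#' values become empty fields.
#'
#' @param data Trial `data.frame` (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  validate_trial_dataset(data)
  utils::write.csv(data[TRIAL_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial dataset from CSV
#'
#' @param path CSV path with the fixed trial header.
#' @return A validated trial `data.frame`.
#' @export
read_trial_csv <- function(path) {
  data <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character",
                                         site_id = "character"))
  missing_cols <- setdiff(TRIAL_COLUMNS, names(data))
  if (length(missing_cols)) {
    stop_invalid("path", paste("CSV lacks column(s):",
                               paste(missing_cols, collapse = ", ")))
  }
  validate_trial_dataset(data)
  data
}

#' Serialize a simulation config to YAML
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
sim_config_to_yaml <- function(config, path) {
  if (!inherits(config, "sim_config")) stop_invalid("config", "must be a sim_config")
  x <- unclass(config)
  x$zoib_params_by_arm <- lapply(x$zoib_params_by_arm, function(pp) {
    lapply(pp, unclass)
  })
  x$p_krt_dep_by_arm <- as.list(x$p_krt_dep_by_arm)
  x$p_rehosp_by_arm <- as.list(x$p_rehosp_by_arm)
  x$miss_krt_free_by_arm <- as.list(x$miss_krt_free_by_arm)
  x$miss_hosp_free_by_arm <- as.list(x$miss_hosp_free_by_arm)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a simulation config from YAML
#'
#' Unknown keys are rejected so that typos in a config file fail loudly
#' instead of silently falling back to defaults.
#'
#' @param path YAML path produced by [sim_config_to_yaml()] or hand-written
#'   with the same keys.
#' @return A validated [sim_config()].
#' @export
sim_config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  known <- setdiff(names(formals(sim_config)), "...")
  known <- c(known, "beta0")
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop_invalid("path", paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  if (!is.null(x$zoib_params_by_arm)) {
    x$zoib_params_by_arm <- lapply(x$zoib_params_by_arm, function(pp) {
      lapply(pp, function(p) do.call(zoib_params, p))
    })
  }
  for (nm in c("p_krt_dep_by_arm", "p_rehosp_by_arm",
               "miss_krt_free_by_arm", "miss_hosp_free_by_arm")) {
    if (!is.null(x[[nm]])) x[[nm]] <- unlist(x[[nm]])
  }
  do.call(sim_config, x)
}
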