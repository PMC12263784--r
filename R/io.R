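# File round-trips: delimited series tables, JSON sidecars, model
# checkpoints and YAML run configurations.

#' Write and read series tables
#'
#' Comma-separated with a header row, `t` column first, `NaN` for missing
#' entries. The write/read round-trip is lossless for finite values and for
#' the missingness mask.
#'
#' @param df data frame whose first column is `t`.
#' @param path file path.
#' @return `read_series_csv()` returns the data frame; `write_series_csv()`
#'   returns `path` invisibly.
#' @export
write_series_csv <- function(df, path) {
  stopifnot(is.data.frame(df), names(df)[1] == "t")
  utils::write.csv(df, path, row.names = FALSE, na = "NaN")
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, na.strings = c("NaN", "NA"))
  if (names(df)[1] != "t") stop("series file must have `t` as first column")
  df
}

#' Write and read a JSON sidecar
#'
#' Records the generating specification and seeds next to a data artifact.
#'
#' @param x a list of settings (scalars unboxed).
#' @param path file path.
#' @return `read_sidecar_json()` returns the list.
#' @export
write_sidecar_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_sidecar_json
#' @export
read_sidecar_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Save and load model checkpoints
#'
#' Serialises a fitted model (either family; the class tag distinguishes
#' them) so that load followed by predict is bitwise-identical to
#' predicting before saving.
#'
#' @param model a `dlfm_model`.
#' @param path checkpoint file path.
#' @return `load_checkpoint()` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "dlfm_model"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dlfm_model")) stop("not a model checkpoint: ", path)
  model
}

#' Read and validate a run configuration
#'
#' YAML configuration for a fitting run. Required fields: `family`
#' (`"rff"`/`"vip"`) plus family-specific size fields; all counts must be
#' positive. Unknown fields are rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config configuration list (as parsed from YAML).
#' @export
validate_run_config <- function(config) {
  allowed <- c("family", "layers", "q", "n_rf", "inducing", "basis",
               "iterations", "lr", "batch", "mc_train", "samples", "seed",
               "local_reparam", "test_reparam", "resample_basis")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$family) || !config$family %in% c("rff", "vip")) {
    stop("config `family` must be \"rff\" or \"vip\"")
  }
  defaults <- list(layers = 2L, q = 1L, n_rf = 100L, inducing = 100L,
                   basis = 256L, iterations = 2000L, lr = 0.01,
                   batch = 128L, mc_train = 1L, samples = 100L, seed = 1L,
                   local_reparam = TRUE, test_reparam = TRUE,
                   resample_basis = TRUE)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  counts <- c("layers", "q", "n_rf", "inducing", "basis", "iterations",
              "batch", "mc_train", "samples")
  for (nm in counts) {
    v <- config[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      stop("config `", nm, "` must be a positive integer")
    }
    config[[nm]] <- as.integer(v)
  }
  if (!is.numeric(config$lr) || config$lr <= 0) {
    stop("config `lr` must be positive")
  }
  config
}
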