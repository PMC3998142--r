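# Run configuration: a single bundled YAML file supplies every default;
# the CLI (or the caller of run_pipeline) overrides individual keys.

#' Built-in default configuration
#'
#' Reads the configuration file bundled with the package. Keys:
#' `input` (FASTA path), `seq_type` (`"p"`/`"n"`), `formats`,
#' `output_base`, `analyses` (`NULL` = all libraries in the data
#' directory), `chunk_size`, `mode`, `max_workers`, `max_direct_workers`,
#' `retry_limit`, `min_orf_length`, `disable_precalc`, `lookup`, `date`
#' (`NULL` = today), `data_dir`.
#'
#' @param path Optional path to a user configuration file overriding the
#'   bundled one.
#' @return Named list of configuration values.
#' @export
load_config <- function(path = NULL) {
  defaults <- yaml::read_yaml(system.file("config", "sigscan.yml",
                                          package = "sigscan"))
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    defaults[names(user)] <- user
  }
  defaults
}

#' @rdname load_config
#' @export
default_config <- function() load_config()

# Fill unset keys from the bundled defaults and normalize types.
merge_config <- function(config) {
  defaults <- load_config()
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  if (is.null(config$input)) stop("config: 'input' FASTA is required",
                                  call. = FALSE)
  if (is.null(config$output_base)) {
    config$output_base <- sub("\\.[^.]*$", "", config$input)
  }
  if (is.null(config$data_dir)) stop("config: 'data_dir' is required",
                                     call. = FALSE)
  if (is.null(config$date)) config$date <- as.character(Sys.Date())
  config$chunk_size <- as.integer(config$chunk_size)
  config$formats <- tolower(unlist(config$formats))
  config
}
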