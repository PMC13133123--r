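#' Load a named codec preset
#'
#' Standardized parameter sets targeting code rates of 0.50, 1.00 and
#' 1.50 bit per nt at L = 150 nt ship with the package
#' (`inst/extdata/codec_presets.yaml`); the achieved rate is within 5%
#' of the target.
#'
#' @param codec `"rs"`, `"fountain"` or `"baseline"`.
#' @param rate Preset name suffix, e.g. `"0.50"`, `"1.00"`, `"1.50"`
#'   (or `"max"` for the baseline).
#' @return A codec object.
#' @export
#' @examples
#' cdc <- codec_preset("rs", "0.50")
codec_preset <- function(codec = c("rs", "fountain", "baseline"),
                         rate = "1.00") {
  codec <- match.arg(codec)
  path <- system.file("extdata", "codec_presets.yaml",
                      package = "oligobench", mustWork = TRUE)
  presets <- yaml::read_yaml(path)
  key <- paste0("rate_", rate)
  p <- presets[[codec]][[key]]
  if (is.null(p)) {
    stop(sprintf("no preset '%s' for codec '%s' (available: %s)",
                 key, codec,
                 paste(names(presets[[codec]]), collapse = ", ")))
  }
  switch(codec,
         rs = rs_codec(L = p$L, inner_parity = p$inner_parity,
                       outer_n = p$outer_n, outer_k = p$outer_k),
         fountain = fountain_codec(L = p$L, epsilon = p$epsilon,
                                   parity_bytes = p$parity_bytes),
         baseline = baseline_codec(L = p$L))
}

#' Read a run configuration
#'
#' A YAML (or JSON) file with a `seed`, optional `limits`
#' (`wall_s`, `mem_bytes`) and named parameter blocks for the pipeline
#' stages.  Identical configurations (including the seed) give
#' bit-identical pipeline outputs.
#'
#' @param path Path to a YAML/JSON configuration file.
#' @return A named list with defaults filled in (`seed`, `limits`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  lim <- cfg$limits %||% list()
  cfg$limits <- resource_limits(
    wall_s = lim$wall_s %||% 3600,
    mem_bytes = lim$mem_bytes %||% (8 * 1024^3))
  cfg
}

# timestamped plain-text stage logging (stderr), toggled by option
ob_log <- function(stage, fmt, ...) {
  if (isTRUE(getOption("oligobench.verbose", FALSE))) {
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%OS2"),
                    stage, sprintf(fmt, ...)))
  }
  invisible(NULL)
}
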