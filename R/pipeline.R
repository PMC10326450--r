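#' Run the full scoring pipeline from a configuration
#'
#' Ties the modules into one reproducible run: read the dataset, build the
#' graph and bin stack, score every gene, adjust p values, and write the
#' result tables. The configuration (including the master seed) is
#' serialized verbatim to `<prefix>.config.json`, so a run can be replayed
#' from its config file alone.
#'
#' @param config named list (or path to a JSON config) with entries:
#'   `input` (path), `mode` (`table`/`mtx`/`gaussian`), optional I/O paths
#'   (`coords`, `features`, `barcodes`, `sd`), `out` (output prefix), and
#'   any of the [spatinfo()] options (`graph`, `walk_k`, `bin_sizes`,
#'   `uncertainty`, `max_iters`, `learning_rate`, `eval_rounds`, `seed`,
#'   ...). Unknown entries are rejected.
#' @return Invisibly, the `spatinfo` fit.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  required <- c("input", "out")
  missing_ <- setdiff(required, names(config))
  if (length(missing_)) stop("config missing: ", paste(missing_, collapse = ", "))
  known <- c(required, "mode", "coords", "features", "barcodes", "sd",
             "coord_cols", "transpose", "saliency_genes",
             "graph", "graph_params", "walk_k", "bin_sizes", "uncertainty",
             "max_iters", "learning_rate", "convergence_window",
             "convergence_rtol", "early_stop", "eval_rounds", "allow_negative_weights", "seed",
             "verbose")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  if (!file.exists(config$input))
    stop(sprintf("input file not found: %s", config$input))

  ds <- read_spatial_dataset(config$input,
                             mode = if (is.null(config$mode)) "table" else config$mode,
                             coords_path = config$coords,
                             features_path = config$features,
                             barcodes_path = config$barcodes,
                             sd_path = config$sd,
                             coord_cols = if (is.null(config$coord_cols))
                               c("x", "y") else config$coord_cols,
                             transpose = isTRUE(config$transpose))
  fit_args <- config[intersect(names(config),
                               setdiff(known, c(required, "mode", "coords",
                                                "features", "barcodes", "sd",
                                                "coord_cols", "transpose",
                                                "saliency_genes")))]
  fit <- do.call(spatinfo, c(list(object = ds), fit_args))
  write_spatinfo_results(fit, config$out,
                         saliency_genes = config$saliency_genes)
  jsonlite::write_json(config, paste0(config$out, ".config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}
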