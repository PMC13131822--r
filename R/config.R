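# YAML run configuration for the command-line surface.

.config_schema <- list(
  binning = c("interval_bp", "scope", "impute", "gc"),
  ingestion = c("alpha_clust", "cluster_adjust", "weight_cap",
                "pseudocount", "window_bp"),
  model = c("K", "flavor", "spectra_adjust", "l1_penalty",
            "strand_uniform_pf", "strand_dev_pf", "tree_nrounds",
            "tree_eta", "tree_depth", "tree_min_child", "alpha_init"),
  inference = c("max_epochs", "tol", "tol_window", "e_inner", "e_tol",
                "spectra_every", "batch_fraction", "sv_kappa", "sv_delay",
                "update_alpha", "seed"))

#' Read and validate a run configuration
#'
#' The YAML may contain sections `binning`, `ingestion`, `model`,
#' `inference` plus free keys `feature_class` and `heldout_chrom`. Unknown
#' keys raise an error naming their path. Values can be overridden through
#' environment variables named `MUTOPIA_<SECTION>_<KEY>`.
#'
#' @param path Path to the YAML file.
#' @return Validated nested configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (sec in names(cfg)) {
    if (sec %in% c("feature_class", "heldout_chrom")) next
    if (!sec %in% names(.config_schema))
      stop("unknown config section: ", sec)
    bad <- setdiff(names(cfg[[sec]]), .config_schema[[sec]])
    if (length(bad))
      stop("unknown config key: ", sec, ".", bad[1])
  }
  for (sec in names(.config_schema)) {
    for (key in .config_schema[[sec]]) {
      ev <- Sys.getenv(toupper(paste("MUTOPIA", sec, key, sep = "_")), "")
      if (nzchar(ev)) {
        val <- utils::type.convert(ev, as.is = TRUE)
        if (is.null(cfg[[sec]])) cfg[[sec]] <- list()
        cfg[[sec]][[key]] <- val
      }
    }
  }
  cfg
}

#' Build a [mutopia_config()] from a run configuration
#' @param cfg Output of [read_config()].
#' @return A config list for [fit_mutopia()].
#' @export
config_to_fit <- function(cfg) {
  args <- c(cfg$model %||% list(), cfg$inference %||% list())
  do.call(mutopia_config, args)
}

#' Write a run manifest
#'
#' Records the subcommand, package version, seed, input paths and their
#' md5 sums next to the outputs of a run.
#' @param path Output JSON path.
#' @param command Subcommand name.
#' @param seed Seed used.
#' @param inputs Character vector of input file paths.
#' @export
write_manifest <- function(path, command, seed, inputs = character(0)) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(list(command = command,
                            package_version =
                              as.character(utils::packageVersion("mutopia")),
                            seed = seed, time = format(Sys.time()),
                            inputs = hashes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
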