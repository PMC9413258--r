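#' Pipeline configuration files
#'
#' The tunable parameters of the whole pipeline can be carried in a single
#' YAML file: `preprocess.tug` / `preprocess.6mwt` (filter specs),
#' `segmentation` (thresholds and de-bouncing), `features` (stride-length
#' constant, entropy epochs, harmonic count) and `model` (split fractions,
#' tuning budget). Missing entries fall back to the package defaults, so a
#' config file only needs to state what it changes.
#'
#' @param path file path of a YAML config.
#' @param config a configuration list as returned by [default_config()].
#' @return [default_config()] and [read_config()] return a configuration
#'   list with `preprocess` entries as [filter_spec()] and `segmentation`
#'   as [threshold_spec()].
#' @export
default_config <- function() {
  list(
    preprocess = list(tug = tug_filter_spec(), `6mwt` = sixmwt_filter_spec()),
    segmentation = threshold_spec(),
    features = list(k_height = 0.83, apen_epoch_s = 30, n_harmonics = 20),
    model = list(train_frac = 0.70, val_frac = 0.10, test_frac = 0.20,
                 n_trials = 50)
  )
}

#' @rdname default_config
#' @export
write_config <- function(config, path) {
  plain <- rapply(config, unclass, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_gaitage(paste0("no such file: ", path), "format")
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_into <- function(base, new) {
    for (nm in names(new)) {
      if (is.list(base[[nm]]) && is.list(new[[nm]])) {
        base[[nm]] <- merge_into(base[[nm]], new[[nm]])
      } else {
        base[[nm]] <- new[[nm]]
      }
    }
    base
  }
  cfg <- merge_into(rapply(cfg, unclass, how = "replace"), user)
  cfg$preprocess$tug <- do.call(filter_spec, cfg$preprocess$tug)
  cfg$preprocess$`6mwt` <- do.call(filter_spec, cfg$preprocess$`6mwt`)
  cfg$segmentation <- do.call(threshold_spec, cfg$segmentation)
  cfg
}
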