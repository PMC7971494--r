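#' Save or load a draw archive
#'
#' A fitted model is archived as a single serialized container holding the
#' draw arrays (`Gamma`, `Omega`, `Psi`, `B`, optionally `Z`), the data and a
#' `meta` block echoing the sampler configuration, its hash and the seed, so
#' every archive is reproducible from its own metadata.
#'
#' @param fit an `mgcgm` fit.
#' @param path archive path (`.rds`).
#' @return `save_fit_archive` returns the path invisibly; `load_fit_archive`
#'   returns the `mgcgm` object with the `meta` block attached.
#' @export
save_fit_archive <- function(fit, path) {
  stopifnot(inherits(fit, "mgcgm"))
  fit$meta <- list(seed = fit$settings$seed,
                   config_hash = config_hash(fit$settings),
                   settings = fit$settings,
                   created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_fit_archive
#' @export
load_fit_archive <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "mgcgm")) stop("not an mgcgm archive")
  fit
}

#' Hash of a sampler configuration
#'
#' @param settings a settings list as stored in an `mgcgm` fit.
#' @return md5 hex string.
#' @export
config_hash <- function(settings) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(settings[order(names(settings))], tf)
  unname(tools::md5sum(tf))
}
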