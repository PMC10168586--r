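# Run-level configuration, artifact serialisation and run manifests.

#' Load (or default) a run configuration
#'
#' A run configuration is a small structured document selecting the
#' model variant and the experimental knobs.  Recognised fields:
#' `model` ("complete"/"simplified"), `D_d`, `epsilon`, `n`, `opto`
#' (mapping with `kind` and optional `kappa`), `seed`, `duration`,
#' `warmup`.  Missing fields are filled with defaults and recorded, so
#' the resolved configuration fully reproduces the run.
#'
#' @param path Path to a YAML run configuration, or `NULL` for the
#'   defaults.
#' @return An object of class `bg_run_config` (named list, fully
#'   resolved).
#' @export
load_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  defaults <- list(model = "complete", D_d = 1, epsilon = 0.75, n = 1,
                   opto = NULL, seed = 1, duration = 10000, warmup = 500)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown run-configuration field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (!cfg$model %in% c("complete", "simplified"))
    stop("model must be 'complete' or 'simplified'")
  stopifnot(cfg$D_d > 0, cfg$epsilon >= 0, cfg$epsilon <= 1, cfg$n >= 1,
            cfg$duration > 0, cfg$warmup >= 0)
  if (!is.null(cfg$opto)) {
    if (is.null(cfg$opto$kind)) stop("opto block requires a 'kind' field")
    kappa <- if (is.null(cfg$opto$kappa)) 1 else cfg$opto$kappa
    cfg$opto <- opto_perturbation(cfg$opto$kind, kappa = kappa)
  }
  structure(cfg[names(defaults)], class = "bg_run_config")
}

#' Write a run configuration
#'
#' @param config A `bg_run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
dump_run_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$opto)) x$opto <- list(kind = x$opto$kind, kappa = x$opto$kappa)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Build the network selected by a run configuration
#'
#' @param config A [load_run_config()] object.
#' @return A [bg_network()].
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "bg_run_config"))
  if (config$model == "complete")
    build_complete_model(D_d = config$D_d, n = config$n, opto = config$opto,
                         opto_seed = config$seed)
  else {
    net <- build_simplified_model(config$epsilon, D_d = config$D_d,
                                  n = config$n)
    if (!is.null(config$opto)) net <- apply_opto(net, config$opto,
                                                 seed = config$seed)
    net
  }
}

#' Execute a run configuration
#'
#' @param config A [load_run_config()] object.
#' @return A `bg_raster`.
#' @export
run_config <- function(config) {
  run_simulation(build_model(config), duration = config$duration,
                 warmup = config$warmup, seed = config$seed)
}

#' Write the artifacts of a run
#'
#' Serialises a raster (sparse TSV), per-population rates and spectral
#' scalars (CSV, deterministic column order), optional extra tables, and
#' a manifest (resolved configuration, master seed, package version,
#' wall time, file inventory with MD5 checksums) sufficient to reproduce
#' and verify the run.
#'
#' @param raster A `bg_raster`.
#' @param outdir Output directory (created if missing).
#' @param config Optional `bg_run_config` recorded in the manifest.
#' @param tables Optional named list of data frames written as
#'   `<name>.csv`.
#' @param band Analysis band for the spectral scalars.
#' @return Invisibly, the manifest as a list.
#' @export
write_outputs <- function(raster, outdir, config = NULL, tables = list(),
                          band = c(8, 24)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  write_raster(raster, file.path(outdir, "raster.tsv"))
  scal <- do.call(rbind, lapply(names(raster$observers), function(p) {
    series <- bin_rates(raster, p)
    nseg <- min(2000, length(series$rate)) # short runs: single segment
    s <- welch_psd(series, nperseg = nseg, noverlap = nseg %/% 2)
    data.frame(population = p, rate_hz = unname(raster$rates[p]),
               mean_f_hz = mean_frequency(s, band),
               mean_beta_psd = mean_beta_psd(s, band))
  }))
  utils::write.csv(scal, file.path(outdir, "spectral_scalars.csv"),
                   row.names = FALSE, quote = FALSE)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(outdir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  files <- c("raster.tsv", "spectral_scalars.csv",
             if (length(tables)) paste0(names(tables), ".csv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("bgbeta")),
    seed = raster$seed, duration = raster$duration, warmup = raster$warmup,
    h = raster$h,
    config = if (!is.null(config)) {
      x <- unclass(config)
      if (!is.null(x$opto)) x$opto <- list(kind = x$opto$kind,
                                           kappa = x$opto$kappa)
      x[!vapply(x, is.null, logical(1))]
    },
    wall_time_s = as.numeric(Sys.time() - t0, units = "secs"),
    files = lapply(stats::setNames(files, files), function(f)
      list(md5 = unname(tools::md5sum(file.path(outdir, f))))))
  manifest <- manifest[!vapply(manifest, is.null, logical(1))]
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}

#' Verify the checksums of a run directory
#'
#' @param outdir Directory previously written by [write_outputs()].
#' @return `TRUE` if all checksums match; otherwise a character vector
#'   of mismatching files.
#' @export
verify_manifest <- function(outdir) {
  manifest <- yaml::read_yaml(file.path(outdir, "manifest.yaml"))
  bad <- character(0)
  for (f in names(manifest$files)) {
    cur <- unname(tools::md5sum(file.path(outdir, f)))
    if (is.na(cur) || !identical(cur, manifest$files[[f]]$md5))
      bad <- c(bad, f)
  }
  if (length(bad)) bad else TRUE
}
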