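#' Canonical model configuration
#'
#' The reference parameterisation of the Complete Model ships with the
#' package as a structured YAML document so that every population size,
#' neuron parameter and connectivity entry is data rather than code.
#' `bg_config()` loads and validates it (or a user-supplied file of the
#' same schema).
#'
#' @param path Path to a model configuration YAML file.  Defaults to the
#'   canonical Complete Model configuration installed with the package.
#' @return A list with elements `populations` (named list of per-population
#'   parameter records), `connections` (data frame: source, target, p,
#'   delay, type, weight), and `rate_windows` (named list of target firing
#'   rate intervals in Hz).
#' @export
bg_config <- function(path = system.file("extdata", "complete_model.yaml",
                                         package = "bgbeta")) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$populations) || is.null(cfg$connections))
    stop("configuration must contain 'populations' and 'connections'")
  con <- do.call(rbind, lapply(cfg$connections, function(x)
    data.frame(source = x$source, target = x$target, p = x$p,
               delay = x$delay, type = x$type, weight = x$weight,
               stringsAsFactors = FALSE)))
  pops <- names(cfg$populations)
  bad <- setdiff(unique(c(con$source, con$target)), c(pops, "ext"))
  if (length(bad))
    stop("connections refer to unknown population(s): ",
         paste(bad, collapse = ", "))
  if (any(con$p < 0 | con$p > 1)) stop("connection probability outside [0,1]")
  if (any(con$delay < 0)) stop("negative delay in connectivity table")
  if (any(con$weight < 0)) stop("negative synaptic weight in connectivity table")
  cfg$connections <- con
  cfg
}

#' Population sizes of the reference network
#'
#' @return Named integer vector of reference population sizes.
#' @export
bg_population_sizes <- function() {
  cfg <- bg_config()
  vapply(cfg$populations, function(p) as.integer(p$size), integer(1))
}

#' Connectivity table of the reference network
#'
#' Returns the full connectivity specification (19 internal pathways plus
#' the 6 external-drive rows, one per population).
#'
#' @return Data frame with columns source, target, p, delay, type
#'   (`"E"`/`"I"`), weight.
#' @export
bg_connectivity <- function() bg_config()$connections

#' Target firing-rate calibration windows
#'
#' The empirically motivated per-population mean-rate windows used to
#' calibrate the external drives: FSN 10-20 Hz, D1/D2 0.5-2.5 Hz,
#' GPe-TI 40-60 Hz, GPe-TA 5-15 Hz, STN 12-20 Hz.
#'
#' @return Named list of length-2 numeric vectors (Hz).
#' @export
bg_rate_windows <- function() bg_config()$rate_windows
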