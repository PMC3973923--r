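#' Readers and writers for the package's file formats
#'
#' CSV is the canonical interchange format; every file carries its units
#' in the header and the column names are part of the contract:
#' \describe{
#'   \item{trace}{`t_ms,V_mV,Iinj_pA`}
#'   \item{control signals}{`t_ms,I_pA,G_nS` plus optional `VI_mV`}
#'   \item{features}{`cycle,t_ms,Vsubthr_mV,Vpulse_mV,qc`}
#'   \item{estimates}{`t_ms,I_pA,G_nS,GE_nS,GI_nS,status`}
#' }
#' Calibration surfaces travel as JSON with named coefficients, form,
#' domain, residual RMS and units.
#'
#' @param x object to write
#' @param path file path
#' @return readers return the reconstructed object; writers return `path`
#'   invisibly
#' @name firingclamp-io
NULL

check_columns <- function(df, need, what, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed ", what, " file '", path, "': missing column(s) ",
         paste(miss, collapse = ", "))
}

#' @rdname firingclamp-io
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "voltage_trace"))
  df <- data.frame(t_ms = trace_times(x), V_mV = x$V, Iinj_pA = x$I_inj)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname firingclamp-io
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  check_columns(df, c("t_ms", "V_mV", "Iinj_pA"), "trace", path)
  dt <- df$t_ms[2] - df$t_ms[1]
  voltage_trace(dt, df$V_mV, df$Iinj_pA, t0_ms = df$t_ms[1])
}

#' @rdname firingclamp-io
#' @export
write_controls <- function(x, path) {
  stopifnot(inherits(x, "control_signals"))
  df <- data.frame(t_ms = (seq_along(x$I) - 1) * x$dt, I_pA = x$I,
                   G_nS = x$G)
  if (!is.null(x$VI)) df$VI_mV <- x$VI
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname firingclamp-io
#' @export
read_controls <- function(path) {
  df <- read.csv(path)
  check_columns(df, c("t_ms", "I_pA", "G_nS"), "control-signals", path)
  dt <- df$t_ms[2] - df$t_ms[1]
  control_signals(dt, df$I_pA, df$G_nS,
                  VI_mV = if ("VI_mV" %in% names(df)) df$VI_mV else NULL)
}

#' @rdname firingclamp-io
#' @export
write_features <- function(x, path) {
  write.csv(as.data.frame(x)[c("cycle", "t_ms", "Vsubthr_mV", "Vpulse_mV",
                               "qc")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname firingclamp-io
#' @export
read_features <- function(path) {
  df <- read.csv(path)
  check_columns(df, c("cycle", "t_ms", "Vsubthr_mV", "Vpulse_mV", "qc"),
                "feature", path)
  probe_features(df)
}

#' @rdname firingclamp-io
#' @export
write_surface <- function(x, path) {
  stopifnot(inherits(x, "calibration_surface"))
  obj <- list(format = "firingclamp calibration surface",
              units = list(I = "pA", G = "nS", V = "mV"),
              form = x$form, pulse_feature = x$pulse_feature,
              subthr = as.list(x$subthr), pulse = as.list(x$pulse),
              domain = x$domain,
              residual_rms_mV = as.list(x$residual_rms_mV),
              n_points = x$n_points)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname firingclamp-io
#' @export
read_surface <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("form", "subthr", "pulse", "domain"))
    if (is.null(obj[[f]]))
      stop("malformed surface file '", path, "': missing field '", f, "'")
  calibration_surface(unlist(obj$subthr), unlist(obj$pulse),
                      domain = list(I_pA = obj$domain$I_pA,
                                    G_nS = obj$domain$G_nS),
                      form = obj$form,
                      residual_rms_mV = unlist(obj$residual_rms_mV),
                      n_points = obj$n_points,
                      pulse_feature = if (is.null(obj$pulse_feature))
                        "difference" else obj$pulse_feature)
}

#' @rdname firingclamp-io
#' @export
write_estimates <- function(x, path) {
  write.csv(as.data.frame(x)[c("t_ms", "I_pA", "G_nS", "GE_nS", "GI_nS",
                               "status")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname firingclamp-io
#' @export
read_estimates <- function(path) {
  df <- read.csv(path)
  check_columns(df, c("t_ms", "I_pA", "G_nS", "GE_nS", "GI_nS", "status"),
                "estimate", path)
  class(df) <- c("estimate_series", "data.frame")
  df
}

#' Read a run configuration file
#'
#' YAML configuration with `neuron`, `protocol`, `calibration`,
#' `reversal`, and `run` blocks; every numeric key carries its unit in
#' its name, and unknown keys are rejected so silent typos cannot change
#' a run.
#'
#' @param path YAML file
#' @return `list(neuron = neuron_params, protocol = meander_config,
#'   reversal = reversal_spec, calibration = list, run = list)`
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known_blocks <- c("neuron", "protocol", "calibration", "reversal", "run")
  unknown <- setdiff(names(cfg), known_blocks)
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  take <- function(block, builder, formals_of) {
    if (is.null(cfg[[block]])) return(builder())
    allowed <- names(formals(formals_of))
    bad <- setdiff(names(cfg[[block]]), allowed)
    if (length(bad))
      stop("unknown key(s) in '", block, "': ", paste(bad, collapse = ", "))
    do.call(builder, cfg[[block]])
  }
  list(neuron = take("neuron", neuron_params, neuron_params),
       protocol = take("protocol", meander_config, meander_config),
       reversal = take("reversal", reversal_spec, reversal_spec),
       calibration = cfg$calibration, run = cfg$run)
}
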