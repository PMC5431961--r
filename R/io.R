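#' Read an LFP signal from disk
#'
#' CSV dialect: two columns `time_s, amplitude_mV` (uniform sampling is
#' checked), or a single `amplitude_mV` column accompanied by a JSON
#' sidecar `<path>.json` with at least `fs` (and optionally `t0`).  EDF
#' files are read with the bundled minimal EDF reader (continuous signals,
#' 16-bit).
#'
#' @param path File path.
#' @param format `"csv"` or `"edf"`; default guessed from the extension.
#' @param channel Channel index for multi-channel EDF files (default 1).
#' @return An [lfp_signal()].
#' @export
read_signal <- function(path, format = NULL, channel = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- format %||% guess_format(path)
  switch(format,
         csv = read_signal_csv(path),
         edf = read_edf(path, channel = channel),
         stop("unknown format: ", format))
}

#' Write an LFP signal to disk
#'
#' @param sig An [lfp_signal()].
#' @param path Output path.
#' @param format `"csv"` (two-column `time_s, amplitude_mV`) or `"edf"`
#'   (16-bit, quantized over the signal's range); default from the
#'   extension.
#' @return `path`, invisibly.
#' @export
write_signal <- function(sig, path, format = NULL) {
  stopifnot(inherits(sig, "lfp_signal"))
  format <- format %||% guess_format(path)
  switch(format,
         csv = {
           df <- data.frame(time_s = signal_times(sig),
                            amplitude_mV = sig$samples)
           write.csv(df, path, row.names = FALSE)
         },
         edf = write_edf(sig, path),
         stop("unknown format: ", format))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = "csv", tsv = "csv", txt = "csv", edf = "edf",
         stop("cannot guess signal format from extension '", ext, "'"))
}

read_signal_csv <- function(path) {
  df <- tryCatch(read.csv(path), error = function(e)
    stop("unparseable CSV ", path, ": ", conditionMessage(e)))
  if (nrow(df) < 2) stop("truncated signal file: ", path)
  if (ncol(df) >= 2) {
    t <- df[[1]]
    v <- df[[2]]
    if (any(!is.finite(t)) || any(!is.finite(v)))
      stop("non-finite values in ", path)
    dts <- diff(t)
    if (any(abs(dts - dts[1]) > 1e-6 * dts[1] + 1e-12))
      stop("non-uniform sampling in ", path)
    lfp_signal(v, fs = 1 / dts[1], t0 = t[1])
  } else {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("single-column CSV needs a JSON sidecar with fs: ", sidecar)
    meta <- jsonlite::read_json(sidecar)
    if (is.null(meta$fs)) stop("sidecar ", sidecar, " lacks 'fs'")
    lfp_signal(df[[1]], fs = meta$fs, t0 = meta$t0 %||% 0)
  }
}

#' Export a discharge schedule or event table as CSV
#'
#' @param x An [hpd_schedule()] or `event_table`.
#' @param path Output path; schedules write `onset_s, offset_s`, event
#'   tables additionally `n_peaks`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  if (inherits(x, "event_table")) {
    df <- data.frame(onset_s = x$onset, offset_s = x$offset,
                     n_peaks = lengths(x$peaks))
  } else if (inherits(x, "hpd_schedule")) {
    df <- data.frame(onset_s = x$onset, offset_s = x$offset)
  } else stop("unsupported object of class ", class(x)[1])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' Structured YAML configuration with named presets; every model, INMF,
#' circuit, detection and protocol parameter is addressable.  Unknown keys
#' are rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("preset", "model", "inmf", "circuit", "triplet", "protocol",
             "detection", "seed", "duration", "out_dir")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  structure(cfg, class = c("run_config", "list"))
}

#' Write a run configuration
#'
#' @param cfg A list / `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# resolve a run_config into concrete objects with defaults filled in
resolve_config <- function(cfg) {
  preset <- model_preset(cfg$preset %||% "hpd_regime")
  params <- preset$params
  if (!is.null(cfg$model)) {
    allowed <- c("A", "B", "G", "tau_exc", "tau_slow", "tau_fast",
                 "noise_mean", "noise_sd", "fs", "lfp_invert")
    bad <- setdiff(names(cfg$model), allowed)
    if (length(bad)) stop("unknown model keys: ", paste(bad, collapse = ", "))
    args <- modifyList(params[allowed[allowed %in% names(params)]],
                       cfg$model)
    params <- do.call(model_params, args)
  }
  inmf <- inmf_config(K = preset$K)
  if (!is.null(cfg$inmf)) {
    inmf <- inmf_config(
      law_hpd = if (!is.null(cfg$inmf$law_hpd))
        gamma_law(cfg$inmf$law_hpd$a, cfg$inmf$law_hpd$b) else inmf$law_hpd,
      law_bkg = if (!is.null(cfg$inmf$law_bkg))
        gamma_law(cfg$inmf$law_bkg$a, cfg$inmf$law_bkg$b) else inmf$law_bkg,
      K = cfg$inmf$K %||% inmf$K)
  }
  circuit <- if (is.null(cfg$circuit)) interface_circuit()
             else do.call(interface_circuit, cfg$circuit)
  triplet <- if (is.null(cfg$triplet)) NULL
             else if (is.character(cfg$triplet)) triplet_preset(cfg$triplet)
             else do.call(coupling_triplet, as.list(cfg$triplet))
  list(params = params, inmf = inmf, circuit = circuit, triplet = triplet,
       seed = cfg$seed %||% 1, duration = cfg$duration %||% 400)
}
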