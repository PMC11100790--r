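#' Read a grayscale multi-page TIFF stack
#'
#' @param path file path.
#' @return 3-D array ordered `(plane, row, col)`. Integer-valued pages are
#'   returned on their native scale (e.g. 0..65535 for 16-bit).
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
    stop("unsupported format: multi-channel/RGB TIFF (expect grayscale)")
  d <- dim(pages[[1]])
  out <- array(0, dim = c(length(pages), d))
  for (i in seq_along(pages)) out[i, , ] <- pages[[i]]
  out
}

#' Write a grayscale multi-page TIFF stack
#'
#' Values are stored as unsigned integers of the requested depth; the stack
#' must lie within `[0, 2^bits - 1]`. 16-bit integer data round-trips
#' bit-exactly through [read_stack()].
#'
#' @param stack 3-D array `(plane, row, col)` or a matrix (single plane).
#' @param path output path.
#' @param bits bits per sample (8, 16 or 32).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(1L, dim(stack)))
  stopifnot(length(dim(stack)) == 3L, bits %in% c(8L, 16L, 32L))
  full <- 2^bits - 1
  if (any(stack < 0) || any(stack > full))
    stop(sprintf("values must lie in [0, %d] for %d-bit storage", full, bits))
  pages <- lapply(seq_len(dim(stack)[1]), function(i) stack[i, , ] / full)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  reduce = FALSE)
  invisible(path)
}

#' Read a schema-checked CSV table
#'
#' @param path file path.
#' @param required character vector of column names that must be present.
#' @return data.frame.
#' @export
read_table <- function(path, required = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("table has no data rows: ", path)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  df
}

#' Write a CSV table at full floating precision
#'
#' Numeric columns are serialized with 17 significant digits (C locale
#' decimal point), so a write-read round trip reproduces doubles exactly.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a YAML run configuration
#'
#' @param path YAML file.
#' @param allowed character vector of permitted top-level keys; unknown keys
#'   are rejected.
#' @return named list.
#' @export
read_run_config <- function(path, allowed) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg
}

#' Bundle stage results into a reproducible envelope
#'
#' @param stage stage name.
#' @param config configuration list echoed into the envelope.
#' @param seed seed used by the stage.
#' @param outputs named list of result values and/or file references.
#' @param timestamp include a wall-clock timestamp (set `FALSE` for
#'   byte-reproducible envelopes).
#' @return list of class `result_envelope`.
#' @export
result_envelope <- function(stage, config, seed, outputs, timestamp = TRUE) {
  env <- list(stage = stage,
              package_version = as.character(utils::packageVersion("glycoprobe")),
              config = config, seed = seed, outputs = outputs)
  if (timestamp) env$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  structure(env, class = "result_envelope")
}

#' @rdname result_envelope
#' @param env a `result_envelope`.
#' @param path output JSON path.
#' @export
write_envelope <- function(env, path) {
  jsonlite::write_json(unclass(env), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write / read a two-state dye model as config plus spectra CSVs
#'
#' The YAML config names per-state spectrum CSV files (relative to its own
#' directory) together with `epsilon_peak` and `phi`.
#'
#' @param model a [two_state_dye()].
#' @param dir output directory (created if needed).
#' @param name base name for the config and CSV files.
#' @return path of the YAML config, invisibly (`write`); a
#'   [two_state_dye()] (`read`).
#' @export
write_dye_model <- function(model, dir, name = "dye") {
  stopifnot(inherits(model, "two_state_dye"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list()
  for (state in c("unbound", "bound")) {
    st <- model[[state]]
    afile <- sprintf("%s_%s_absorbance.csv", name, state)
    efile <- sprintf("%s_%s_emission.csv", name, state)
    write_spectrum_csv(st$absorbance, file.path(dir, afile))
    write_spectrum_csv(st$emission, file.path(dir, efile))
    cfg[[state]] <- list(epsilon_peak = st$epsilon_peak, phi = st$phi,
                         absorbance_csv = afile, emission_csv = efile)
  }
  path <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_dye_model
#' @param path YAML config written by `write_dye_model`.
#' @export
read_dye_model <- function(path) {
  cfg <- read_run_config(path, allowed = c("unbound", "bound"))
  dir <- dirname(path)
  states <- lapply(cfg, function(st)
    dye_state(st$epsilon_peak, st$phi,
              read_spectrum_csv(file.path(dir, st$absorbance_csv), "absorbance"),
              read_spectrum_csv(file.path(dir, st$emission_csv), "emission")))
  two_state_dye(states$unbound, states$bound)
}
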