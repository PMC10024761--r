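# Plain-text containers: a delimited sample matrix plus a JSON sidecar
# carrying rate, labels and units, and CSV tables for events and reports.

#' Write a recording to delimited text with a JSON sidecar
#'
#' Samples go to `<prefix>.tsv` (one row per time point, one column per
#' channel) and metadata to `<prefix>.json`
#' (`{rate_hz, channel_labels, units, t0, ...}`). For MEA recordings the
#' region map is written to `<prefix>_regions.csv`.
#'
#' @param rec A `laminar_recording`, `mea_recording` or `current_trace`.
#' @param prefix Output path prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  if (inherits(rec, "laminar_recording")) {
    mat <- t(rec$samples)
    meta <- list(kind = "laminar", rate_hz = rec$rate_hz,
                 channel_labels = rec$channel_labels, units = "uV",
                 t0 = 0.0, session_id = rec$session_id,
                 genotype = rec$genotype)
  } else if (inherits(rec, "mea_recording")) {
    mat <- t(rec$traces)
    meta <- list(kind = "mea", rate_hz = rec$rate_hz, units = "uV",
                 t0 = 0.0, slice_id = rec$slice_id,
                 genotype = rec$genotype)
    utils::write.csv(rec$region_map, paste0(prefix, "_regions.csv"),
                     row.names = FALSE)
  } else if (inherits(rec, "current_trace")) {
    mat <- matrix(rec$samples, ncol = 1)
    meta <- list(kind = "current", rate_hz = rec$rate_hz, units = "pA",
                 t0 = 0.0, holding_mv = rec$holding_mv,
                 polarity = rec$polarity, cell_id = rec$cell_id)
  } else {
    stop_config("rec", "unsupported recording class")
  }
  utils::write.table(mat, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix Path prefix used when writing.
#' @return The reconstructed recording object.
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  mat <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(mat) <- NULL
  if (meta$kind == "laminar") {
    laminar_recording(t(mat), meta$rate_hz, meta$channel_labels,
                      session_id = meta$session_id,
                      genotype = meta$genotype)
  } else if (meta$kind == "mea") {
    region_map <- utils::read.csv(paste0(prefix, "_regions.csv"),
                                  stringsAsFactors = FALSE)
    mea_recording(t(mat), meta$rate_hz, region_map,
                  slice_id = meta$slice_id, genotype = meta$genotype)
  } else if (meta$kind == "current") {
    current_trace(mat[, 1], meta$rate_hz, holding_mv = meta$holding_mv,
                  polarity = meta$polarity, cell_id = meta$cell_id)
  } else {
    stop("unknown recording kind in sidecar", call. = FALSE)
  }
}
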