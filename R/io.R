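## Interchange format: a delimited numeric matrix (rows = samples, columns =
## electrodes, header row of channel ids) plus a JSON sidecar holding all
## metadata. No vendor binary formats are parsed; exports from acquisition
## software are expected to be converted to this open layout.

.unitToMv <- c(V = 1000, mV = 1, uV = 0.001, "µV" = 0.001)

#' Load a grid EMG recording from a signal file and metadata sidecar
#'
#' Reads a delimited (TSV/CSV) numeric matrix of samples x electrodes and a
#' JSON sidecar describing the acquisition. Signal values are converted to
#' mV from the unit the sidecar declares (`"V"`, `"mV"`, or `"uV"`).
#'
#' The sidecar is a JSON object with keys `fs_hz`, `unit`, `n_rows`,
#' `n_cols`, `missing` (array of `[row, col]`), `ied_mm`, `mode`,
#' `channel_map` (array of `[row, col]`, one per signal column, in column
#' order), and optionally `speed_label`, `bad_channels`, `torque_file`
#' (path relative to the sidecar) and `torque_fs_hz`.
#'
#' @param signalPath path to the delimited signal matrix.
#' @param sidecarPath path to the JSON sidecar.
#' @return A validated [GridRecording-class] with signals in mV.
#' @seealso [saveRecording()]
#' @export
loadRecording <- function(signalPath, sidecarPath) {
  meta <- jsonlite::fromJSON(sidecarPath, simplifyVector = TRUE)
  sep <- if (grepl("\\.csv$", signalPath, ignore.case = TRUE)) "," else "\t"
  sig <- utils::read.table(signalPath, header = TRUE, sep = sep,
                           check.names = FALSE)
  sig <- as.matrix(sig)
  cmap <- meta$channel_map
  if (is.list(cmap)) cmap <- do.call(rbind, cmap)
  cmap <- matrix(as.integer(cmap), ncol = 2L)
  if (ncol(sig) != nrow(cmap))
    stop(sprintf("signal file has %d channel column(s) but the sidecar channel map has %d entr(ies)",
                 ncol(sig), nrow(cmap)))
  unit <- as.character(meta$unit %||% "mV")
  if (!unit %in% names(.unitToMv))
    stop(sprintf("unknown signal unit '%s' (expected V, mV or uV)", unit))
  bad <- !is.finite(sig)
  if (any(bad)) {
    chs <- which(apply(bad, 2L, any))
    stop("non-finite samples in channel(s): ", paste(chs, collapse = ", "))
  }
  sig <- t(sig) * .unitToMv[[unit]]     # -> channels x samples, mV
  miss <- meta$missing
  if (is.list(miss)) miss <- do.call(rbind, miss)
  geom <- GridGeometry(nRows = meta$n_rows, nCols = meta$n_cols,
                       missing = miss, iedMm = meta$ied_mm %||% 8)
  rownames(cmap) <- rownames(sig)
  torque <- numeric(); torqueFs <- 100
  if (!is.null(meta$torque_file)) {
    tpath <- file.path(dirname(sidecarPath), meta$torque_file)
    torque <- utils::read.table(tpath, header = FALSE)[[1L]]
    torqueFs <- meta$torque_fs_hz %||% 100
  }
  GridRecording(sig, fsHz = meta$fs_hz, geometry = geom, positions = cmap,
                mode = meta$mode %||% "monopolar",
                torque = torque, torqueFsHz = torqueFs,
                speedLabel = as.character(meta$speed_label %||% NA),
                badChannels = as.integer(meta$bad_channels %||% integer()))
}

#' Save a grid EMG recording to the open interchange format
#'
#' Writes the signal matrix as a TSV (samples x electrodes, header of
#' channel ids, mV, 15 significant digits so a load/save round-trip agrees
#' to better than 1e-9 mV), a JSON sidecar with all metadata, and - if a
#' torque trace is present - a one-column torque TSV next to the sidecar.
#'
#' @param rec a valid [GridRecording-class].
#' @param signalPath output path for the signal TSV.
#' @param sidecarPath output path for the JSON sidecar.
#' @return invisibly, the sidecar path.
#' @seealso [loadRecording()]
#' @export
saveRecording <- function(rec, signalPath, sidecarPath) {
  stopifnot(is(rec, "GridRecording"))
  validObject(rec)
  sig <- t(rec@signals)
  ids <- rownames(rec@positions)
  if (is.null(ids)) ids <- paste0("ch", seq_len(nChannels(rec)))
  con <- file(signalPath, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste(ids, collapse = "\t"), con)
  utils::write.table(format(sig, digits = 15, scientific = TRUE, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- list(
    fs_hz = rec@fsHz, unit = "mV",
    n_rows = rec@geometry@nRows, n_cols = rec@geometry@nCols,
    missing = unname(rec@geometry@missing),
    ied_mm = rec@geometry@iedMm, mode = rec@mode,
    channel_map = unname(rec@positions),
    speed_label = rec@speedLabel,
    bad_channels = rec@badChannels
  )
  if (length(rec@torque)) {
    tfile <- paste0(sub("\\.json$", "", basename(sidecarPath)), "_torque.tsv")
    utils::write.table(
      format(rec@torque, digits = 15, scientific = TRUE, trim = TRUE),
      file.path(dirname(sidecarPath), tfile),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    meta$torque_file <- tfile
    meta$torque_fs_hz <- rec@torqueFsHz
  }
  jsonlite::write_json(meta, sidecarPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecarPath)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
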