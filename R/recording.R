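#' Construct a grid EMG recording
#'
#' @param signals numeric matrix, channels x samples, in mV.
#' @param fsHz sampling rate in Hz (typical grid amplifiers sample at 1024).
#' @param geometry a [GridGeometry-class]; defaults to the 13 x 5 /
#'   64-electrode layout.
#' @param positions channels x 2 (row, col) integer matrix mapping each
#'   channel to its occupied grid position; defaults to
#'   [defaultChannelMap()] order.
#' @param mode `"monopolar"` or `"single_differential"`.
#' @param torque optional torque trace in Nm.
#' @param torqueFsHz sampling rate of the torque trace (dynamometers
#'   commonly log at 100 Hz).
#' @param speedLabel condition tag, e.g. `"60"`, `"90"`, `"120"` (deg/s)
#'   or `"0"` for an isometric MVC.
#' @param badChannels channel indices to exclude from every analysis.
#'
#' @return A validated [GridRecording-class].
#' @examples
#' g <- GridGeometry()
#' sig <- matrix(rnorm(nElectrodes(g) * 1024, sd = 0.05), nElectrodes(g))
#' rec <- GridRecording(sig, fsHz = 1024, geometry = g)
#' nChannels(rec)
#' @export
GridRecording <- function(signals, fsHz = 1024, geometry = GridGeometry(),
                          positions = defaultChannelMap(geometry),
                          mode = c("monopolar", "single_differential"),
                          torque = numeric(), torqueFsHz = 100,
                          speedLabel = NA_character_,
                          badChannels = integer()) {
  mode <- match.arg(mode)
  storage.mode(positions) <- "integer"
  new("GridRecording", signals = as.matrix(signals), fsHz = as.numeric(fsHz),
      geometry = geometry, positions = positions, mode = mode,
      torque = as.numeric(torque), torqueFsHz = as.numeric(torqueFsHz),
      speedLabel = as.character(speedLabel),
      badChannels = as.integer(badChannels))
}

#' Accessors for GridRecording objects
#'
#' `nChannels`/`nSamples` give the signal matrix dimensions;
#' `samplingRate` the EMG rate in Hz; `signalMatrix` the channels x samples
#' matrix in mV; `channelPositions` the channel -> (row, col) map;
#' `recordingMode` `"monopolar"` or `"single_differential"`;
#' `torqueTrace`/`torqueRate` the optional dynamometer channel.
#'
#' @param x a [GridRecording-class].
#' @name GridRecording-accessors
#' @aliases nChannels nSamples samplingRate gridGeometry signalMatrix
#'   channelPositions recordingMode speedLabel torqueTrace torqueRate
NULL

#' @rdname GridRecording-accessors
#' @export
setMethod("nChannels", "GridRecording", function(x) nrow(x@signals))

#' @rdname GridRecording-accessors
#' @export
setMethod("nSamples", "GridRecording", function(x) ncol(x@signals))

#' @rdname GridRecording-accessors
#' @export
setMethod("samplingRate", "GridRecording", function(x) x@fsHz)

#' @rdname GridRecording-accessors
#' @export
setMethod("gridGeometry", "GridRecording", function(x) x@geometry)

#' @rdname GridRecording-accessors
#' @export
setMethod("signalMatrix", "GridRecording", function(x) x@signals)

#' @rdname GridRecording-accessors
#' @export
setMethod("channelPositions", "GridRecording", function(x) x@positions)

#' @rdname GridRecording-accessors
#' @export
setMethod("recordingMode", "GridRecording", function(x) x@mode)

#' @rdname GridRecording-accessors
#' @export
setMethod("speedLabel", "GridRecording", function(x) x@speedLabel)

#' @rdname GridRecording-accessors
#' @export
setMethod("torqueTrace", "GridRecording", function(x) x@torque)

#' @rdname GridRecording-accessors
#' @export
setMethod("torqueRate", "GridRecording", function(x) x@torqueFsHz)

setMethod("show", "GridRecording", function(object) {
  cat(sprintf("GridRecording: %d channel(s) x %d sample(s) at %g Hz (%s)\n",
              nChannels(object), nSamples(object), object@fsHz, object@mode))
  cat(sprintf("  duration %.2f s; grid %d x %d; speed label %s\n",
              nSamples(object) / object@fsHz, object@geometry@nRows,
              object@geometry@nCols, object@speedLabel))
  if (length(object@torque))
    cat(sprintf("  torque: %d sample(s) at %g Hz, peak %.1f Nm\n",
                length(object@torque), object@torqueFsHz, max(object@torque)))
  if (length(object@badChannels))
    cat("  bad channels:", paste(object@badChannels, collapse = ", "), "\n")
})

#' Scatter per-channel values onto the grid
#'
#' Places a value-per-channel vector at each channel's (row, col) position;
#' unoccupied positions become NA.
#'
#' @param values numeric vector, one value per channel.
#' @param geometry a [GridGeometry-class].
#' @param positions channels x 2 position matrix.
#' @return numeric nRows x nCols matrix.
#' @keywords internal
gridScatter <- function(values, geometry, positions) {
  m <- matrix(NA_real_, geometry@nRows, geometry@nCols)
  m[positions] <- values
  m
}

#' Gather a grid matrix back into channel order
#'
#' Inverse of [gridScatter()].
#' @inheritParams gridScatter
#' @param m numeric nRows x nCols matrix.
#' @return numeric vector in channel order.
#' @keywords internal
gridGather <- function(m, positions) {
  m[positions]
}

#' View a recording window as a grid-shaped sample stack
#'
#' Rearranges a sample window of the recording into a rows x cols x samples
#' array with each channel's samples at its grid position, plus a validity
#' mask marking occupied positions not flagged bad.
#'
#' @param rec a [GridRecording-class].
#' @param sampleWindow integer length 2, (start, end) sample indices
#'   (1-based, inclusive).
#' @return list with elements `values` (nRows x nCols x nSamples array,
#'   NA at invalid positions) and `valid` (logical nRows x nCols matrix).
#' @examples
#' rec <- simulateRecording(simulationConfig(durationS = 1, seed = 1))$recording
#' gv <- toGridView(rec, c(1, 256))
#' dim(gv$values)
#' @export
toGridView <- function(rec, sampleWindow) {
  stopifnot(is(rec, "GridRecording"))
  sampleWindow <- as.integer(sampleWindow)
  if (length(sampleWindow) != 2L || sampleWindow[1L] < 1L ||
      sampleWindow[2L] > nSamples(rec) || sampleWindow[1L] > sampleWindow[2L])
    stop("sampleWindow must be a non-empty (start, end) range inside the recording")
  idx <- seq.int(sampleWindow[1L], sampleWindow[2L])
  g <- rec@geometry
  valid <- occupancyMask(g)
  if (length(rec@badChannels))
    valid[rec@positions[rec@badChannels, , drop = FALSE]] <- FALSE
  out <- array(NA_real_, dim = c(g@nRows, g@nCols, length(idx)))
  keep <- setdiff(seq_len(nChannels(rec)), rec@badChannels)
  for (ch in keep)
    out[rec@positions[ch, 1L], rec@positions[ch, 2L], ] <- rec@signals[ch, idx]
  list(values = out, valid = valid)
}

#' Mask of analysable grid positions for a recording
#'
#' Occupied positions minus bad channels.
#' @param rec a [GridRecording-class].
#' @return logical nRows x nCols matrix.
#' @keywords internal
recordingValidMask <- function(rec) {
  valid <- occupancyMask(rec@geometry)
  if (length(rec@badChannels))
    valid[rec@positions[rec@badChannels, , drop = FALSE]] <- FALSE
  valid
}
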