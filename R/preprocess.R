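#' Zero-phase band-pass filter a grid recording
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass to every
#' channel. The 20-400 Hz default is the conventional surface-EMG analysis
#' band: below 20 Hz movement artefact dominates, above 400 Hz there is
#' essentially no myoelectric power at these sampling rates. Forward-
#' backward application doubles the effective order and removes phase
#' distortion, so envelope timing (and hence barycentre trajectories) is
#' preserved.
#'
#' @param rec a [GridRecording-class].
#' @param lowHz,highHz band edges in Hz; must satisfy
#'   `0 < lowHz < highHz < samplingRate(rec) / 2`.
#' @param order Butterworth order of the underlying one-pass design.
#' @return A [GridRecording-class] with filtered signals and unchanged
#'   metadata.
#' @examples
#' rec <- simulateRecording(simulationConfig(durationS = 1, seed = 1))$recording
#' filt <- bandpassFilter(rec)
#' @export
bandpassFilter <- function(rec, lowHz = 20, highHz = 400, order = 4) {
  stopifnot(is(rec, "GridRecording"))
  nyq <- rec@fsHz / 2
  if (!(lowHz > 0 && lowHz < highHz && highHz < nyq))
    stop(sprintf("band edges must satisfy 0 < low < high < Nyquist (%g Hz)", nyq))
  bf <- signal::butter(order, c(lowHz, highHz) / nyq, type = "pass")
  out <- rec
  out@signals <- t(apply(rec@signals, 1L,
                         function(x) signal::filtfilt(bf, x)))
  out
}

#' Derive single-differential channels along the fiber axis
#'
#' Subtracts each channel from its neighbour one row further along the
#' muscle-fiber (row) axis in the same column: the differential channel at
#' (i, j) is signal(i, j) - signal(i + 1, j). Components common to all
#' electrodes cancel. Pairs that touch a missing or bad electrode are
#' dropped, so the default 64-electrode 13 x 5 grid yields 59 differential
#' channels on a 12 x 5 grid.
#'
#' @param rec a monopolar [GridRecording-class].
#' @return A [GridRecording-class] with mode `"single_differential"` and a
#'   geometry of `nRows - 1` rows; positions of dropped pairs appear as
#'   missing positions.
#' @export
toSingleDifferential <- function(rec) {
  stopifnot(is(rec, "GridRecording"))
  if (rec@mode != "monopolar")
    stop("recording is already single differential")
  g <- rec@geometry
  valid <- recordingValidMask(rec)
  chanAt <- matrix(NA_integer_, g@nRows, g@nCols)
  chanAt[rec@positions] <- seq_len(nChannels(rec))
  pos <- list(); sigs <- list(); k <- 0L
  for (j in seq_len(g@nCols)) {
    for (i in seq_len(g@nRows - 1L)) {
      if (valid[i, j] && valid[i + 1L, j]) {
        k <- k + 1L
        pos[[k]] <- c(i, j)
        sigs[[k]] <- rec@signals[chanAt[i, j], ] -
          rec@signals[chanAt[i + 1L, j], ]
      }
    }
  }
  if (k == 0L) stop("no adjacent electrode pairs available")
  pos <- do.call(rbind, pos)
  all <- cbind(rep(seq_len(g@nRows - 1L), times = g@nCols),
               rep(seq_len(g@nCols), each = g@nRows - 1L))
  occ <- paste(pos[, 1L], pos[, 2L])
  miss <- all[!(paste(all[, 1L], all[, 2L]) %in% occ), , drop = FALSE]
  gdiff <- GridGeometry(nRows = g@nRows - 1L, nCols = g@nCols,
                        missing = miss, iedMm = g@iedMm)
  rownames(pos) <- paste0("sd", seq_len(k))
  GridRecording(do.call(rbind, sigs), fsHz = rec@fsHz, geometry = gdiff,
                positions = pos, mode = "single_differential",
                torque = rec@torque, torqueFsHz = rec@torqueFsHz,
                speedLabel = rec@speedLabel)
}

#' Detect the contraction segment of a recording
#'
#' Finds the first and last crossings of a threshold fraction of the peak
#' of a smoothed effort signal: the torque trace when available (the usual
#' choice for isokinetic dynamometry), otherwise the grid-mean rectified
#' EMG envelope. Smoothing is a 100 ms moving average.
#'
#' @param rec a [GridRecording-class].
#' @param source `"torque"` or `"emg_envelope"`.
#' @param thresholdFrac fraction of the smoothed peak defining onset/offset.
#' @param minDurationS segments shorter than this are rejected.
#' @return A [ContractionSegment-class] in EMG sample indices.
#' @export
segmentContraction <- function(rec, source = c("torque", "emg_envelope"),
                               thresholdFrac = 0.1, minDurationS = 0.25) {
  stopifnot(is(rec, "GridRecording"))
  source <- match.arg(source)
  if (source == "torque") {
    if (!length(rec@torque)) stop("no torque trace in this recording")
    env <- rec@torque
    fsEnv <- rec@torqueFsHz
  } else {
    env <- colMeans(abs(rec@signals))
    fsEnv <- rec@fsHz
  }
  w <- max(1L, round(0.1 * fsEnv))
  env <- stats::filter(env, rep(1 / w, w), sides = 2L)
  env[is.na(env)] <- 0
  env <- as.numeric(env)
  thr <- thresholdFrac * max(env)
  above <- which(env >= thr)
  if (max(env) <= 0 || length(above) == 0L)
    stop("no contraction detected")
  # nearest-sample conversion from the envelope rate to EMG samples
  start <- max(1L, as.integer(round((above[1L] - 1L) * rec@fsHz / fsEnv)) + 1L)
  end <- min(nSamples(rec),
             as.integer(round((above[length(above)] - 1L) * rec@fsHz / fsEnv)) + 1L)
  if ((end - start + 1L) / rec@fsHz < minDurationS)
    stop("detected contraction is shorter than the minimum duration")
  new("ContractionSegment", startSample = start, endSample = end,
      method = if (source == "torque") "torque-threshold" else "envelope-threshold")
}

setMethod("show", "ContractionSegment", function(object) {
  cat(sprintf("ContractionSegment: samples %d-%d (%s)\n",
              object@startSample, object@endSample, object@method))
})

.rmsWindowMap <- function(rec, startSample, endSample) {
  idx <- seq.int(startSample, endSample)
  v <- sqrt(rowMeans(rec@signals[, idx, drop = FALSE]^2))
  valid <- recordingValidMask(rec)
  vals <- matrix(NA_real_, rec@geometry@nRows, rec@geometry@nCols)
  keep <- setdiff(seq_len(nChannels(rec)), rec@badChannels)
  vals[rec@positions[keep, , drop = FALSE]] <- v[keep]
  new("ActivationMap", values = vals, validMask = valid,
      window = c(startSample - 1L, endSample) / rec@fsHz, mode = rec@mode)
}

#' RMS activation maps over consecutive windows
#'
#' Tiles the contraction segment with analysis windows and computes one
#' activation map per window: the map value at (i, j) is the RMS amplitude
#' of the channel at that grid position within the window. The 0.25 s
#' default suits trajectory analysis of short dynamic contractions;
#' `windowS = 1` reproduces the coarser interval mapping used for long
#' holds.
#'
#' @param rec a [GridRecording-class] (typically band-pass filtered).
#' @param seg a [ContractionSegment-class].
#' @param windowS window length in seconds.
#' @param overlapFrac fractional overlap between consecutive windows in
#'   `[0, 1)`; 0 means windows tile the segment without gaps.
#' @return list of [ActivationMap-class], ordered in time; the number of
#'   maps is `floor((duration - window) / step) + 1`.
#' @export
windowedMaps <- function(rec, seg, windowS = 0.25, overlapFrac = 0) {
  stopifnot(is(rec, "GridRecording"), is(seg, "ContractionSegment"))
  wlen <- as.integer(round(windowS * rec@fsHz))
  seglen <- seg@endSample - seg@startSample + 1L
  if (wlen > seglen)
    stop("analysis window is longer than the contraction segment")
  if (overlapFrac < 0 || overlapFrac >= 1)
    stop("overlapFrac must be in [0, 1)")
  step <- max(1L, as.integer(round(wlen * (1 - overlapFrac))))
  starts <- seq.int(seg@startSample, seg@endSample - wlen + 1L, by = step)
  lapply(starts, function(s) .rmsWindowMap(rec, s, s + wlen - 1L))
}

#' Activation map of the contraction-midpoint epoch
#'
#' Computes one activation map from a short epoch centred at the midpoint
#' of the contraction, the standard reference window for feature
#' extraction (250 ms by default).
#'
#' @inheritParams windowedMaps
#' @param epochS epoch length in seconds.
#' @return An [ActivationMap-class].
#' @export
midpointEpoch <- function(rec, seg, epochS = 0.25) {
  stopifnot(is(rec, "GridRecording"), is(seg, "ContractionSegment"))
  elen <- as.integer(round(epochS * rec@fsHz))
  seglen <- seg@endSample - seg@startSample + 1L
  if (elen > seglen)
    stop("epoch is longer than the contraction segment")
  mid <- (seg@startSample + seg@endSample) / 2
  start <- as.integer(round(mid - elen / 2))
  .rmsWindowMap(rec, start, start + elen - 1L)
}
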