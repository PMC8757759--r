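#' @import methods
NULL

#' Electrode grid geometry
#'
#' Describes the physical layout of a 2D surface-EMG electrode grid: the
#' number of rows (the long, muscle-fiber axis), the number of columns, any
#' grid positions that carry no electrode, and the inter-electrode distance.
#' The default is the 13 x 5 layout with one absent corner electrode used by
#' common 64-channel semi-disposable arrays.
#'
#' Grid indices are 1-based. Row index i runs along the fiber direction
#' (cranial-caudal on a thigh muscle), column index j across it.
#'
#' @slot nRows integer, number of electrode rows (fiber axis).
#' @slot nCols integer, number of electrode columns.
#' @slot missing integer matrix with columns (row, col); grid positions with
#'   no electrode. May have zero rows.
#' @slot iedMm numeric, inter-electrode distance in millimetres.
#'
#' @seealso [GridGeometry()] for the user constructor.
#' @exportClass GridGeometry
setClass("GridGeometry",
  representation(
    nRows = "integer",
    nCols = "integer",
    missing = "matrix",
    iedMm = "numeric"
  )
)

setValidity("GridGeometry", function(object) {
  msg <- character()
  if (length(object@nRows) != 1L || object@nRows < 1L)
    msg <- c(msg, "nRows must be a single positive integer")
  if (length(object@nCols) != 1L || object@nCols < 1L)
    msg <- c(msg, "nCols must be a single positive integer")
  if (ncol(object@missing) != 2L)
    msg <- c(msg, "missing must be a two-column (row, col) matrix")
  if (nrow(object@missing) > 0L) {
    r <- object@missing[, 1L]; cc <- object@missing[, 2L]
    if (any(r < 1L | r > object@nRows | cc < 1L | cc > object@nCols))
      msg <- c(msg, "missing positions must lie inside the grid")
    if (anyDuplicated(paste(r, cc)))
      msg <- c(msg, "missing positions must be unique")
  }
  if (length(object@iedMm) != 1L || !is.finite(object@iedMm) ||
      object@iedMm <= 0)
    msg <- c(msg, "iedMm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Multichannel grid EMG recording
#'
#' Container for a multichannel surface-EMG recording from an electrode
#' grid: a channels x samples signal matrix in millivolts, the sampling
#' rate, the grid geometry, the mapping from channel index to grid position,
#' the recording mode (monopolar or single differential), and an optional
#' torque trace recorded at its own (typically much lower) rate.
#'
#' @slot signals numeric matrix, channels x samples, in mV.
#' @slot fsHz numeric, EMG sampling rate in Hz.
#' @slot geometry a [GridGeometry-class] object.
#' @slot positions integer matrix, channels x 2 (row, col); the bijection
#'   between channel index and occupied grid position. Row names are channel
#'   identifiers.
#' @slot mode character, `"monopolar"` or `"single_differential"`.
#' @slot torque numeric, optional torque trace in Nm (length 0 if absent).
#' @slot torqueFsHz numeric, sampling rate of the torque trace in Hz.
#' @slot speedLabel character, condition tag, e.g. `"60"` for 60 deg/s.
#' @slot badChannels integer, indices of channels flagged unusable.
#'
#' @seealso [GridRecording()], [loadRecording()], [simulateRecording()]
#' @exportClass GridRecording
setClass("GridRecording",
  representation(
    signals = "matrix",
    fsHz = "numeric",
    geometry = "GridGeometry",
    positions = "matrix",
    mode = "character",
    torque = "numeric",
    torqueFsHz = "numeric",
    speedLabel = "character",
    badChannels = "integer"
  )
)

setValidity("GridRecording", function(object) {
  msg <- character()
  g <- object@geometry
  nOcc <- g@nRows * g@nCols - nrow(g@missing)
  if (nrow(object@signals) != nrow(object@positions))
    msg <- c(msg, sprintf("signal matrix has %d channels but channel map has %d",
                          nrow(object@signals), nrow(object@positions)))
  if (nrow(object@positions) != nOcc)
    msg <- c(msg, sprintf("channel map has %d entries; geometry has %d occupied positions",
                          nrow(object@positions), nOcc))
  if (ncol(object@positions) == 2L && nrow(object@positions) > 0L) {
    key <- paste(object@positions[, 1L], object@positions[, 2L])
    if (anyDuplicated(key))
      msg <- c(msg, "two channels map to the same grid position")
    if (nrow(g@missing) > 0L &&
        any(key %in% paste(g@missing[, 1L], g@missing[, 2L])))
      msg <- c(msg, "a channel is mapped onto a missing grid position")
    if (any(object@positions[, 1L] < 1L | object@positions[, 1L] > g@nRows |
            object@positions[, 2L] < 1L | object@positions[, 2L] > g@nCols))
      msg <- c(msg, "channel positions must lie inside the grid")
  }
  if (anyNA(object@signals) || any(!is.finite(object@signals)))
    msg <- c(msg, "signal matrix contains non-finite values")
  if (length(object@fsHz) != 1L || object@fsHz <= 0)
    msg <- c(msg, "fsHz must be a single positive number")
  if (!object@mode %in% c("monopolar", "single_differential"))
    msg <- c(msg, "mode must be 'monopolar' or 'single_differential'")
  if (length(object@torque) > 0L &&
      (length(object@torqueFsHz) != 1L || object@torqueFsHz <= 0))
    msg <- c(msg, "torqueFsHz must be positive when a torque trace is present")
  if (length(msg)) msg else TRUE
})

#' Contraction segment
#'
#' Sample-index bounds of one contraction inside a [GridRecording-class],
#' together with the detection method that produced them.
#'
#' @slot startSample integer, first sample of the contraction (1-based).
#' @slot endSample integer, last sample of the contraction.
#' @slot method character, one of `"torque-threshold"`,
#'   `"envelope-threshold"`, `"manual"`.
#'
#' @seealso [segmentContraction()]
#' @exportClass ContractionSegment
setClass("ContractionSegment",
  representation(
    startSample = "integer",
    endSample = "integer",
    method = "character"
  )
)

setValidity("ContractionSegment", function(object) {
  msg <- character()
  if (object@startSample < 1L)
    msg <- c(msg, "startSample must be >= 1")
  if (object@endSample <= object@startSample)
    msg <- c(msg, "endSample must exceed startSample")
  if (!object@method %in% c("torque-threshold", "envelope-threshold", "manual"))
    msg <- c(msg, "unknown segmentation method")
  if (length(msg)) msg else TRUE
})

#' RMS activation map
#'
#' The spatial representation of muscle activity over one time window: a
#' rows x cols matrix whose entry at (i, j) is the RMS amplitude (mV) of the
#' channel at grid position (i, j), with a validity mask marking positions
#' that carry an electrode and were not flagged bad. Invalid positions hold
#' NA and are excluded from every downstream feature.
#'
#' @slot values numeric matrix, rows x cols, RMS in mV; NA where invalid.
#' @slot validMask logical matrix, rows x cols.
#' @slot window numeric length 2, (start, end) of the window in seconds
#'   relative to the recording start.
#' @slot mode character, mode of the signals the map was computed from.
#'
#' @seealso [windowedMaps()], [midpointEpoch()], [cogPoint()]
#' @exportClass ActivationMap
setClass("ActivationMap",
  representation(
    values = "matrix",
    validMask = "matrix",
    window = "numeric",
    mode = "character"
  )
)

setValidity("ActivationMap", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@validMask)))
    msg <- c(msg, "values and validMask must have identical dimensions")
  v <- object@values[object@validMask]
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "valid positions must hold finite values")
  else if (any(v < 0))
    msg <- c(msg, "RMS values must be non-negative")
  if (length(object@window) != 2L || object@window[1L] >= object@window[2L])
    msg <- c(msg, "window must be (start, end) with start < end")
  if (length(msg)) msg else TRUE
})

#' Centre-of-gravity trajectory
#'
#' Time series of activation-map barycentre coordinates over a contraction:
#' one (x, y) pair per analysis window, where x is the coordinate along the
#' fiber (row) axis and y across the columns, both in electrode-index units.
#' Per-axis mean, variance, standard deviation and min-max range summarise
#' the trajectory for reporting.
#'
#' @slot timesS numeric, window centres in seconds.
#' @slot xs,ys numeric, barycentre coordinate series (index units).
#'
#' @seealso [cogTrajectory()], [trajSummary()]
#' @exportClass CoGTrajectory
setClass("CoGTrajectory",
  representation(
    timesS = "numeric",
    xs = "numeric",
    ys = "numeric"
  )
)

setValidity("CoGTrajectory", function(object) {
  msg <- character()
  n <- length(object@timesS)
  if (length(object@xs) != n || length(object@ys) != n)
    msg <- c(msg, "timesS, xs and ys must have equal length")
  if (n > 1L && any(diff(object@timesS) <= 0))
    msg <- c(msg, "window times must be strictly increasing")
  if (length(msg)) msg else TRUE
})
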