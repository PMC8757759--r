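#' Accessors for ActivationMap objects
#'
#' `mapValues` returns the rows x cols RMS matrix (NA where invalid),
#' `validMask` the logical mask of analysable positions, `mapWindow` the
#' (start, end) time window in seconds and `nValidChannels` the channel
#' count N entering the spatial features.
#'
#' @param x an [ActivationMap-class].
#' @name ActivationMap-accessors
#' @aliases mapValues validMask mapWindow nValidChannels
NULL

#' @rdname ActivationMap-accessors
#' @export
setMethod("mapValues", "ActivationMap", function(x) x@values)

#' @rdname ActivationMap-accessors
#' @export
setMethod("validMask", "ActivationMap", function(x) x@validMask)

#' @rdname ActivationMap-accessors
#' @export
setMethod("mapWindow", "ActivationMap", function(x) x@window)

#' @rdname ActivationMap-accessors
#' @export
setMethod("nValidChannels", "ActivationMap", function(x) sum(x@validMask))

setMethod("show", "ActivationMap", function(object) {
  v <- object@values[object@validMask]
  cat(sprintf("ActivationMap: %d x %d grid, %d valid channel(s), window %.3f-%.3f s (%s)\n",
              nrow(object@values), ncol(object@values), sum(object@validMask),
              object@window[1L], object@window[2L], object@mode))
  cat(sprintf("  RMS range %.4g-%.4g mV, mean %.4g mV\n",
              min(v), max(v), mean(v)))
})

.validValues <- function(map) {
  stopifnot(is(map, "ActivationMap"))
  map@values[map@validMask]
}

#' Map intensity
#'
#' The common logarithm of the mean of the activation map:
#' `I = log10( (1/N) * sum(HM_ij) )` over the N valid positions. The log
#' compresses the non-linear EMG-amplitude/force relation; with map values
#' in mV, a map averaging 0.1 mV has intensity -1.
#'
#' @param map an [ActivationMap-class].
#' @return intensity in log10-mV units.
#' @export
mapIntensity <- function(map) {
  v <- .validValues(map)
  m <- mean(v)
  if (m <= 0) stop("map mean is zero; intensity is undefined")
  log10(m)
}

#' Differential intensity
#'
#' Log-scale amplitude of the single-differential map: consecutive-channel
#' differences along the fiber axis are RMS'd per pair and `DI` is the
#' common logarithm of their mean. Aggregating by the mean before the log
#' mirrors the structure of [mapIntensity()], keeping the two features
#' commensurable; per-pair values are a map, not a scalar, so some
#' aggregation convention is unavoidable.
#'
#' @param diffMap an [ActivationMap-class] computed from a
#'   single-differential recording.
#' @return differential intensity in log10-mV units.
#' @export
differentialIntensity <- function(diffMap) {
  if (diffMap@mode != "single_differential")
    stop("differential intensity requires a single-differential map")
  v <- .validValues(diffMap)
  m <- mean(v)
  if (m <= 0) stop("no differential activity (common-mode-only recording?)")
  log10(m)
}

#' Modified entropy of an activation map
#'
#' Shannon entropy (bits) of the normalised squared-RMS distribution across
#' channels: with `q_i = HM_i^2 / sum_k HM_k^2` over the N valid channels,
#' `E = -sum q_i log2 q_i` (zero terms contribute zero). E is maximal,
#' `log2(N)`, when all channels carry the same RMS, and 0 when a single
#' channel carries everything; low entropy therefore signals a spatially
#' heterogeneous (localised) activation pattern.
#'
#' @param map an [ActivationMap-class].
#' @return entropy in bits, in `[0, log2(N)]`.
#' @export
modifiedEntropy <- function(map) {
  v <- .validValues(map)
  s <- sum(v^2)
  if (s <= 0) stop("all-zero map; entropy is undefined")
  q <- v^2 / s
  q <- q[q > 0]
  -sum(q * log2(q))
}

#' Spatial coefficient of variation
#'
#' `CoV = 100 * SD / mean` of the valid channel RMS values, in percent.
#' The complementary heterogeneity index to [modifiedEntropy()]: a uniform
#' map has CoV 0; localisation raises CoV and lowers entropy.
#'
#' @param map an [ActivationMap-class].
#' @return CoV in percent.
#' @export
spatialCoV <- function(map) {
  v <- .validValues(map)
  m <- mean(v)
  if (m <= 0) stop("map mean is zero; CoV is undefined")
  100 * stats::sd(v) / m
}

#' Mean RMS of an activation map
#'
#' Arithmetic mean of the valid channel RMS values, in mV. Identical to
#' `10^mapIntensity(map)` by construction.
#'
#' @param map an [ActivationMap-class].
#' @return mean RMS in mV.
#' @export
meanRMS <- function(map) {
  mean(.validValues(map))
}

## Hann-windowed periodogram median frequency of a single epoch.
## Convention for the discrete spectrum: the smallest frequency at which
## cumulative power reaches half the total over [0, fs/2].
.medianFreq <- function(x, fsHz) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq.int(0L, n - 1L) / (n - 1L))
  X <- stats::fft((x - mean(x)) * w)
  half <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(half)])^2
  tot <- sum(p)
  if (tot <= 0) return(NA_real_)
  f <- (seq_len(half) - 1L) * fsHz / n
  # half-power ties (to within window-leakage rounding) resolve to the
  # lower frequency
  f[which(cumsum(p) >= tot * (0.5 - 1e-6))[1L]]
}

#' Median frequency of epoch signals
#'
#' The frequency that divides the power spectrum of the epoch into two
#' equal halves, computed per channel from a Hann-windowed periodogram and
#' averaged over channels. On the discrete spectrum the median is taken as
#' the smallest frequency bin at which cumulative power reaches half the
#' total; silent channels are excluded from the average.
#'
#' @param rec a [GridRecording-class].
#' @param seg optional [ContractionSegment-class]; if supplied with
#'   `epochS`, the epoch centred at the segment midpoint is analysed,
#'   otherwise the whole segment (or recording) is used.
#' @param epochS epoch length in seconds (NULL for the full segment).
#' @return mean per-channel median frequency in Hz.
#' @export
medianFrequency <- function(rec, seg = NULL, epochS = 0.25) {
  stopifnot(is(rec, "GridRecording"))
  if (is.null(seg)) {
    idx <- seq_len(nSamples(rec))
  } else if (is.null(epochS)) {
    idx <- seq.int(seg@startSample, seg@endSample)
  } else {
    elen <- as.integer(round(epochS * rec@fsHz))
    mid <- (seg@startSample + seg@endSample) / 2
    start <- as.integer(round(mid - elen / 2))
    idx <- seq.int(start, start + elen - 1L)
  }
  if (length(idx) < 128L)
    stop("epoch must contain at least 128 samples")
  keep <- setdiff(seq_len(nChannels(rec)), rec@badChannels)
  fm <- vapply(keep, function(ch) {
    x <- rec@signals[ch, idx]
    if (sqrt(mean(x^2)) < 1e-12) NA_real_ else .medianFreq(x, rec@fsHz)
  }, numeric(1))
  fm <- fm[is.finite(fm)]
  if (!length(fm)) stop("all channels silent; median frequency is undefined")
  mean(fm)
}

#' Spatial feature set of one contraction
#'
#' Computes the six standard scalar features from the contraction-midpoint
#' epoch of a monopolar grid recording:
#' \describe{
#'   \item{entropy, cov}{heterogeneity of the 59-channel (default grid)
#'     single-differential activation map, in bits and percent;}
#'   \item{intensity, mean_rms}{amplitude of the monopolar map, in log10-mV
#'     and mV (`intensity == log10(mean_rms)` exactly);}
#'   \item{differential_intensity}{log10 of the mean differential RMS;}
#'   \item{median_frequency}{mean per-channel spectral median of the
#'     monopolar epoch, Hz.}
#' }
#' Heterogeneity features use the differential map because adjacent-
#' electrode differences cancel far-field crosstalk that would otherwise
#' flatten the topography; amplitude features use the monopolar map so
#' intensity and differential intensity remain distinct measurements.
#'
#' @param rec a monopolar [GridRecording-class], already band-pass
#'   filtered (or filter with `filterFirst = TRUE`).
#' @param seg a [ContractionSegment-class]; autodetected from torque (or
#'   the EMG envelope) when NULL.
#' @param epochS feature epoch length in seconds.
#' @param filterFirst apply the default 20-400 Hz band-pass first.
#' @return one-row `data.frame` with columns `entropy`, `cov`,
#'   `intensity`, `differential_intensity`, `mean_rms`,
#'   `median_frequency`.
#' @export
featureSet <- function(rec, seg = NULL, epochS = 0.25, filterFirst = FALSE) {
  stopifnot(is(rec, "GridRecording"))
  if (rec@mode != "monopolar")
    stop("featureSet expects a monopolar recording")
  if (filterFirst) rec <- bandpassFilter(rec)
  if (is.null(seg)) {
    src <- if (length(rec@torque)) "torque" else "emg_envelope"
    seg <- segmentContraction(rec, source = src)
  }
  mono <- midpointEpoch(rec, seg, epochS = epochS)
  diffRec <- toSingleDifferential(rec)
  diffMap <- midpointEpoch(diffRec, seg, epochS = epochS)
  data.frame(
    entropy = modifiedEntropy(diffMap),
    cov = spatialCoV(diffMap),
    intensity = mapIntensity(mono),
    differential_intensity = differentialIntensity(diffMap),
    mean_rms = meanRMS(mono),
    median_frequency = medianFrequency(rec, seg, epochS = epochS)
  )
}
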