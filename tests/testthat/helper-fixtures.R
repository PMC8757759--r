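# Shared fixtures: small, fast simulation configs and analytic map builders.

# short trial (2 s) that still contains a full trapezoidal contraction
quickConfig <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(durationS = 2, onsetS = 0.1, rampS = 0.25, plateauS = 1.3,
         seed = seed),
    list(...))
  do.call(simulationConfig, args)
}

# map with the default differential-grid channel count (59 valid positions)
# holding the given values, in gridScatter order
map59 <- function(values) {
  g <- GridGeometry(nRows = 12, nCols = 5,
                    missing = matrix(c(1L, 1L), 1L))
  m <- matrix(NA_real_, 12, 5)
  m[cbind(rep(1:12, 5), rep(1:5, each = 12))[-1L, ]] <- values
  activationMapFromMatrix(m, mode = "single_differential")
}

# monopolar sine-carrier recording with per-channel amplitudes
sineRecording <- function(amps, freqHz = 100, fsHz = 1024, durationS = 1,
                          geometry = GridGeometry()) {
  n <- fsHz * durationS
  t <- (seq_len(n) - 1L) / fsHz
  sig <- outer(amps, sin(2 * pi * freqHz * t))
  GridRecording(sig, fsHz = fsHz, geometry = geometry)
}
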