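#' Centre of gravity (barycentre) of an activation map
#'
#' The amplitude-weighted mean grid coordinate of the map:
#' `CoG = sum(HM_ij * (i, j)) / sum(HM_ij)` over valid positions, with x
#' the row coordinate along the muscle-fiber axis and y the column
#' coordinate across it, both in 1-based electrode-index units. Weighting
#' is linear in the map amplitudes. Multiply by the inter-electrode
#' distance to convert to mm.
#'
#' @param map an [ActivationMap-class] with at least one positive value.
#' @return named numeric `c(x = , y = )` in electrode-index units.
#' @examples
#' m <- matrix(1, 13, 5)
#' map <- activationMapFromMatrix(m)
#' cogPoint(map)   # (7, 3): centroid of a uniform symmetric grid
#' @export
cogPoint <- function(map) {
  stopifnot(is(map, "ActivationMap"))
  w <- map@values
  w[!map@validMask] <- 0
  tot <- sum(w)
  if (tot <= 0) stop("all-zero map; centre of gravity is undefined")
  rows <- matrix(seq_len(nrow(w)), nrow(w), ncol(w))
  cols <- matrix(seq_len(ncol(w)), nrow(w), ncol(w), byrow = TRUE)
  c(x = sum(w * rows) / tot, y = sum(w * cols) / tot)
}

#' Wrap a plain matrix as an activation map
#'
#' Convenience constructor for analytic work and testing: the matrix is
#' taken as the map values, NA entries become invalid positions, and the
#' window defaults to (0, 1) s.
#'
#' @param m numeric rows x cols matrix of RMS values (NA = invalid).
#' @param window numeric length-2 time window in seconds.
#' @param mode signal mode label for the map.
#' @return An [ActivationMap-class].
#' @export
activationMapFromMatrix <- function(m, window = c(0, 1),
                                    mode = "monopolar") {
  new("ActivationMap", values = m, validMask = !is.na(m),
      window = as.numeric(window), mode = mode)
}

#' Single-map CoG under a reference-window rule
#'
#' Point-based CoG estimation reduces the contraction to one reference map.
#' Three rules are supported: `"midpoint"` (the map whose window centre is
#' closest to the midpoint of the mapped interval, the convention for
#' isometric holds), `"peak_intensity"` (the map with the greatest total
#' RMS, the convention for dynamic efforts), and `"peak_torque"` (the map
#' whose window contains the torque peak).
#'
#' @param maps list of [ActivationMap-class] in time order.
#' @param rule reference selection rule.
#' @param torque optional torque trace (needed for `"peak_torque"`).
#' @param torqueFsHz sampling rate of `torque` in Hz.
#' @return named numeric `c(x = , y = )` with attribute `"window"` giving
#'   the selected map's index.
#' @export
cogReference <- function(maps, rule = c("peak_intensity", "midpoint",
                                        "peak_torque"),
                         torque = NULL, torqueFsHz = 100) {
  rule <- match.arg(rule)
  stopifnot(length(maps) >= 1L)
  centers <- vapply(maps, function(m) mean(m@window), numeric(1))
  idx <- switch(rule,
    peak_intensity = which.max(vapply(maps, function(m)
      sum(m@values[m@validMask]), numeric(1))),
    midpoint = which.min(abs(centers - mean(range(centers)))),
    peak_torque = {
      if (is.null(torque) || !length(torque))
        stop("peak_torque rule requires a torque trace")
      tPeak <- (which.max(torque) - 1L) / torqueFsHz
      which.min(abs(centers - tPeak))
    })
  out <- cogPoint(maps[[idx]])
  attr(out, "window") <- idx
  out
}

#' CoG trajectory over a contraction
#'
#' Computes the barycentre of every windowed activation map from the start
#' to the end of the contraction, giving the time course of the spatial
#' focus of activity. Windows whose map is all-zero are skipped with a
#' warning. Use [trajSummary()] for the per-axis mean, variance, SD and
#' min-max range reported per contraction trial.
#'
#' @param maps list of at least two [ActivationMap-class] in time order.
#' @return A [CoGTrajectory-class].
#' @export
cogTrajectory <- function(maps) {
  stopifnot(length(maps) >= 2L)
  keep <- vapply(maps, function(m) sum(m@values[m@validMask]) > 0, logical(1))
  if (any(!keep))
    warning(sprintf("%d all-zero window(s) skipped", sum(!keep)))
  maps <- maps[keep]
  if (length(maps) == 0L) stop("every window was all-zero")
  pts <- vapply(maps, cogPoint, numeric(2))
  new("CoGTrajectory",
      timesS = vapply(maps, function(m) mean(m@window), numeric(1)),
      xs = unname(pts[1L, ]), ys = unname(pts[2L, ]))
}

#' Accessors for CoGTrajectory objects
#'
#' @param x a [CoGTrajectory-class].
#' @param ... unused.
#' @name CoGTrajectory-accessors
#' @aliases trajTimes trajX trajY trajSummary
NULL

#' @rdname CoGTrajectory-accessors
#' @export
setMethod("trajTimes", "CoGTrajectory", function(x) x@timesS)

#' @rdname CoGTrajectory-accessors
#' @export
setMethod("trajX", "CoGTrajectory", function(x) x@xs)

#' @rdname CoGTrajectory-accessors
#' @export
setMethod("trajY", "CoGTrajectory", function(x) x@ys)

#' @describeIn CoGTrajectory-accessors one-row data.frame with per-axis
#'   mean, variance, standard deviation and min-max range
#'   (`cogx_mean`, `cogy_mean`, `cogx_var`, `cogy_var`, `cogx_sd`,
#'   `cogy_sd`, `cogx_range`, `cogy_range`). Variance and SD are 0 for a
#'   constant series.
#' @export
setMethod("trajSummary", "CoGTrajectory", function(x, ...) {
  rng <- function(v) diff(range(v))
  vr <- function(v) if (length(v) > 1L) stats::var(v) else 0
  data.frame(
    cogx_mean = mean(x@xs), cogy_mean = mean(x@ys),
    cogx_var = vr(x@xs), cogy_var = vr(x@ys),
    cogx_sd = sqrt(vr(x@xs)), cogy_sd = sqrt(vr(x@ys)),
    cogx_range = rng(x@xs), cogy_range = rng(x@ys)
  )
})

setMethod("show", "CoGTrajectory", function(object) {
  s <- trajSummary(object)
  cat(sprintf("CoGTrajectory: %d window(s), %.3f-%.3f s\n",
              length(object@timesS), min(object@timesS), max(object@timesS)))
  cat(sprintf("  x: mean %.3f, var %.4f, range %.3f | y: mean %.3f, var %.4f, range %.3f\n",
              s$cogx_mean, s$cogx_var, s$cogx_range,
              s$cogy_mean, s$cogy_var, s$cogy_range))
})

#' Agreement between point-based and trajectory-based CoG
#'
#' Pearson product-moment correlation, per axis, between single-reference
#' CoG estimates and the matched trajectory means across trials, optionally
#' within speed groups. Zero variance in either series leaves r undefined
#' (NA) for that axis/group.
#'
#' @param points data.frame with columns `x`, `y` (one row per trial).
#' @param trajMeans data.frame with columns `x`, `y`: matched trajectory
#'   mean coordinates.
#' @param group optional factor of trial groups (e.g. speed condition).
#' @return data.frame with columns `group`, `axis`, `r`, `r2`, `p`, `n`.
#' @export
compareCoGMethods <- function(points, trajMeans, group = NULL) {
  stopifnot(nrow(points) == nrow(trajMeans))
  if (is.null(group)) group <- rep("all", nrow(points))
  res <- list()
  for (gl in unique(group)) {
    sel <- group == gl
    if (sum(sel) < 3L)
      stop("at least 3 matched trials per group are required")
    for (ax in c("x", "y")) {
      a <- points[[ax]][sel]; b <- trajMeans[[ax]][sel]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        res[[length(res) + 1L]] <- data.frame(
          group = gl, axis = ax, r = NA_real_, r2 = NA_real_,
          p = NA_real_, n = sum(sel))
      } else {
        ct <- stats::cor.test(a, b, method = "pearson")
        res[[length(res) + 1L]] <- data.frame(
          group = gl, axis = ax, r = unname(ct$estimate),
          r2 = unname(ct$estimate)^2, p = ct$p.value, n = sum(sel))
      }
    }
  }
  do.call(rbind, res)
}
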