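#' Construct an electrode grid geometry
#'
#' @param nRows,nCols grid dimensions. The row axis is the long,
#'   muscle-fiber axis of the array; the default 13 x 5 layout matches
#'   common 64-channel semi-disposable grids.
#' @param missing grid positions carrying no electrode, as a two-column
#'   (row, col) matrix or a list of length-2 vectors. The default single
#'   missing corner at (1, 1) gives 64 electrodes on the 13 x 5 grid; the
#'   absent corner is array-specific and should be set to match the
#'   hardware in use.
#' @param iedMm inter-electrode distance in mm.
#'
#' @return A [GridGeometry-class] object.
#' @examples
#' g <- GridGeometry()            # 13 x 5, one corner absent, 64 electrodes
#' nElectrodes(g)
#' @export
GridGeometry <- function(nRows = 13, nCols = 5,
                         missing = matrix(c(1L, 1L), nrow = 1L),
                         iedMm = 8) {
  if (is.list(missing))
    missing <- do.call(rbind, lapply(missing, as.integer))
  if (is.null(missing) || length(missing) == 0L)
    missing <- matrix(integer(), ncol = 2L)
  missing <- matrix(as.integer(missing), ncol = 2L,
                    dimnames = list(NULL, c("row", "col")))
  new("GridGeometry", nRows = as.integer(nRows), nCols = as.integer(nCols),
      missing = missing, iedMm = as.numeric(iedMm))
}

#' Number of electrodes on a grid
#'
#' Occupied positions: `nRows * nCols` minus the missing positions.
#'
#' @param geometry a [GridGeometry-class].
#' @return integer electrode count.
#' @export
nElectrodes <- function(geometry) {
  geometry@nRows * geometry@nCols - nrow(geometry@missing)
}

#' Default channel map for a grid geometry
#'
#' Enumerates the occupied grid positions in column-major order (rows fastest
#' within a column), the conventional channel ordering for grid arrays.
#'
#' @param geometry a [GridGeometry-class].
#' @return integer matrix, electrodes x 2 (row, col), with row names
#'   `"ch1"`, `"ch2"`, ...
#' @export
defaultChannelMap <- function(geometry) {
  rows <- rep(seq_len(geometry@nRows), times = geometry@nCols)
  cols <- rep(seq_len(geometry@nCols), each = geometry@nRows)
  pos <- cbind(row = rows, col = cols)
  if (nrow(geometry@missing) > 0L) {
    miss <- paste(geometry@missing[, 1L], geometry@missing[, 2L])
    pos <- pos[!(paste(pos[, 1L], pos[, 2L]) %in% miss), , drop = FALSE]
  }
  rownames(pos) <- paste0("ch", seq_len(nrow(pos)))
  pos
}

#' Logical occupancy mask of a grid
#'
#' @param geometry a [GridGeometry-class].
#' @return logical nRows x nCols matrix, TRUE where an electrode exists.
#' @keywords internal
occupancyMask <- function(geometry) {
  m <- matrix(TRUE, geometry@nRows, geometry@nCols)
  if (nrow(geometry@missing) > 0L)
    m[geometry@missing] <- FALSE
  m
}

setMethod("show", "GridGeometry", function(object) {
  cat(sprintf("GridGeometry: %d x %d grid, %d electrode(s), IED %.1f mm\n",
              object@nRows, object@nCols, nElectrodes(object), object@iedMm))
  if (nrow(object@missing) > 0L)
    cat("  missing positions:",
        paste(sprintf("(%d,%d)", object@missing[, 1L], object@missing[, 2L]),
              collapse = " "), "\n")
})
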