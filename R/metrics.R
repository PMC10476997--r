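## Dose/LET-volume histograms, dose statistics and difference maps.

.maskValues <- function(grid, mask) {
  stopifnot(is(grid, "VoxelGrid"))
  m <- if (is(mask, "VoxelGrid")) mask@values != 0 else mask
  if (!any(m)) stop("empty mask")
  grid@values[m]
}

#' Cumulative dose- or LET-volume histogram
#'
#' `V(d)` is the fraction of structure voxels with value >= d, evaluated
#' on a regular edge grid of width `binWidth` from 0 to just above the
#' maximum value.
#'
#' @param grid a [VoxelGrid-class] of nonnegative values (Gy or keV/um).
#' @param mask structure mask (logical array or 0/1 [VoxelGrid-class]).
#' @param binWidth histogram bin width (default 0.01).
#' @return A [CumulativeHistogram-class].
#' @examples
#' g <- voxelGrid(array(c(1, 3), c(2, 1, 1)))
#' h <- dvh(g, array(TRUE, c(2, 1, 1)), binWidth = 0.5)
#' histVolume(h)[histEdges(h) == 2]  # 0.5
#' @export
dvh <- function(grid, mask, binWidth = 0.01) {
  vals <- .maskValues(grid, mask)
  if (any(vals < 0)) stop("cumulative histograms require nonnegative values")
  edges <- seq(0, max(vals) + binWidth, by = binWidth)
  vol <- vapply(edges, function(e) mean(vals >= e), numeric(1))
  new("CumulativeHistogram", edges = edges, volume = vol)
}

#' Dose at a volume fraction (D_q)
#'
#' The largest histogram edge still covering at least the fraction `q` of
#' the structure (>=-threshold convention, no interpolation): `D50%` is
#' `doseAtVolume(h, 0.5)`. With the default 0.01 Gy bin width the result
#' is bit-stable.
#'
#' @param h a [CumulativeHistogram-class].
#' @param q volume fraction in (0, 1).
#' @return dose (or LET) at the requested volume fraction.
#' @export
doseAtVolume <- function(h, q) {
  stopifnot(is(h, "CumulativeHistogram"))
  if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
  ok <- h@volume >= q
  if (!any(ok)) return(0)
  max(h@edges[ok])
}

#' @rdname doseAtVolume
#' @param grid a [VoxelGrid-class].
#' @param mask structure mask.
#' @export
meanDose <- function(grid, mask) mean(.maskValues(grid, mask))

#' @rdname doseAtVolume
#' @export
maxDose <- function(grid, mask) max(.maskValues(grid, mask))

#' Voxelwise difference of two grids
#'
#' @param a,b aligned [VoxelGrid-class] objects.
#' @return a [VoxelGrid-class] holding `a - b`.
#' @export
differenceMap <- function(a, b) {
  stopifnot(is(a, "VoxelGrid"), is(b, "VoxelGrid"))
  if (!identical(dim(a@values), dim(b@values)) ||
      !isTRUE(all.equal(a@spacing, b@spacing)) ||
      !isTRUE(all.equal(a@origin, b@origin)))
    stop("alignment error: grids differ in dims, spacing or origin")
  out <- a
  out@values <- a@values - b@values
  out
}
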