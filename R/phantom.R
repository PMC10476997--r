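## Fixture generation: slabbed-oxygenation water phantom, patient-like
## synthetic pO2 fields, PET-uptake conversion.

#' Build the slabbed-oxygenation water phantom
#'
#' Produces a water-equivalent density grid, a cubic target mask at the
#' requested depth, and a pO2 grid in which the target interior is divided
#' into equal-thickness slabs along the beam (z) axis carrying the
#' specified pO2 sequence, with normoxic background elsewhere. The lateral
#' axes are centered on the beam axis (with the default even lateral voxel
#' counts the axis runs along the boundary of the four innermost voxel
#' columns, see [centralAxisMask()]); the beam entry face is at depth 0.
#'
#' Generation is pure: the same specification yields identical output.
#'
#' @param spec a [phantomSpec()].
#' @return list with [VoxelGrid-class] elements `density` (1 everywhere),
#'   `target` (0/1 mask), `po2` (mmHg) and `slabIndex` (integer slab
#'   membership inside the target, 0 outside).
#' @examples
#' ph <- makeWaterPhantom(phantomSpec())
#' sum(gridValues(ph$target))  # 8000 voxels = (40 mm / 2 mm)^3
#' @export
makeWaterPhantom <- function(spec = phantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  dims <- spec@dims
  h <- spec@spacing
  origin <- c(-(dims[1] - 1) / 2 * h[1], -(dims[2] - 1) / 2 * h[2], h[3] / 2)
  xc <- origin[1] + (seq_len(dims[1]) - 1) * h[1]
  yc <- origin[2] + (seq_len(dims[2]) - 1) * h[2]
  zc <- origin[3] + (seq_len(dims[3]) - 1) * h[3]   # depth of voxel center
  half <- spec@targetSize / 2
  z0 <- spec@targetDepth
  z1 <- spec@targetDepth + spec@targetSize
  if (z1 > dims[3] * h[3] || half > min(abs(range(xc)), abs(range(yc))) + h[1] / 2)
    stop("configuration error: target extends outside the grid")
  inX <- abs(xc) < half
  inY <- abs(yc) < half
  inZ <- zc > z0 & zc < z1
  mask <- outer(outer(inX, inY, `&`), inZ, `&`)
  if (!any(mask)) stop("configuration error: empty target")

  nSlab <- length(spec@slabPo2)
  slabTh <- spec@targetSize / nSlab
  slabOfZ <- pmin(nSlab, pmax(1L, floor((zc - z0) / slabTh) + 1L))
  slabArr <- array(rep(slabOfZ, each = dims[1] * dims[2]), dims)
  slabArr[!mask] <- 0L

  po2 <- array(spec@backgroundPo2, dims)
  po2[mask] <- spec@slabPo2[slabArr[mask]]

  mk <- function(vals) voxelGrid(vals, h, origin)
  list(density = mk(array(1, dims)),
       target = mk(array(as.numeric(mask), dims)),
       po2 = mk(po2),
       slabIndex = mk(slabArr))
}

#' Voxel columns nearest the beam axis
#'
#' Selects the lateral voxel columns whose centers are nearest the beam
#' (z) axis: the central column of an odd lateral grid, or the four
#' innermost columns of an even one. Used for central-axis depth profiles
#' of dose and LETd.
#'
#' @param grid a [VoxelGrid-class].
#' @return logical 3-D array selecting the central columns.
#' @export
centralAxisMask <- function(grid) {
  stopifnot(is(grid, "VoxelGrid"))
  dims <- dim(grid@values)
  nearAxis <- function(ax) {
    cc <- abs(axisCoords(grid, ax))
    cc < min(cc) + 1e-9
  }
  outer(outer(nearAxis(1), nearAxis(2), `&`), rep(TRUE, dims[3]), `&`)
}

#' Voxels of one target slab
#'
#' @param phantom output of [makeWaterPhantom()].
#' @param slab slab number; by default the most hypoxic slab (lowest pO2).
#' @return logical 3-D array selecting the slab's voxels.
#' @export
slabMask <- function(phantom, slab = NULL) {
  si <- gridValues(phantom$slabIndex)
  if (is.null(slab)) {
    po2 <- gridValues(phantom$po2)
    inT <- si > 0
    slab <- si[inT][which.min(po2[inT])]
  }
  si == slab
}

## Internal: separable Gaussian smoothing of a 3-D array, edge-replicated.
.smoothGaussian3d <- function(arr, sdVox) {
  for (ax in 1:3) {
    s <- sdVox[ax]
    if (s <= 0) next
    halfw <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-halfw, halfw), 0, s)
    k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    d <- dim(a)
    m <- matrix(a, d[1], d[2] * d[3])
    padded <- rbind(m[rep(1L, halfw), , drop = FALSE], m,
                    m[rep(d[1], halfw), , drop = FALSE])
    sm <- stats::filter(padded, k, sides = 2)
    m <- matrix(sm[(halfw + 1L):(halfw + d[1]), ], d[1], d[2] * d[3])
    arr <- aperm(array(m, d), order(perm))
  }
  arr
}

#' Generate a patient-like synthetic pO2 case
#'
#' Draws a spatially correlated Gaussian random field, smooths it to the
#' requested correlation length, and rescales it so that the requested
#' fraction of PTV voxels falls below the 60 mmHg hypoxia threshold
#' (matched through the PTV quantile of the field, so the realized
#' fraction is exact up to ties). A spherical PTV at the grid center and a
#' laterally adjacent spherical OAR are generated alongside. Deterministic
#' per seed.
#'
#' @param spec a [syntheticCaseSpec()].
#' @return list with [VoxelGrid-class] elements `po2`, `ptv` and `oar`
#'   (0/1 masks).
#' @examples
#' case <- makeSyntheticCase(syntheticCaseSpec(seed = 7, hypoxicFraction = 0.95))
#' mean(gridValues(case$po2)[gridValues(case$ptv) != 0] < 60)
#' @export
makeSyntheticCase <- function(spec) {
  stopifnot(is(spec, "SyntheticCaseSpec"))
  lo <- spec@po2Range[1]
  hi <- spec@po2Range[2]
  f <- spec@hypoxicFraction
  if (f > 0 && lo >= 60)
    stop("unattainable hypoxic fraction: pO2 range has no values below 60 mmHg")
  if (f < 1 && hi <= 60)
    stop("unattainable hypoxic fraction: pO2 range has no values above 60 mmHg")
  dims <- spec@dims
  h <- spec@spacing
  origin <- -(dims - 1) / 2 * h
  mk <- function(vals) voxelGrid(vals, h, origin)

  coords <- lapply(1:3, function(ax) origin[ax] + (seq_len(dims[ax]) - 1) * h[ax])
  dist2 <- function(center) {
    dx2 <- (coords[[1]] - center[1])^2
    dy2 <- (coords[[2]] - center[2])^2
    dz2 <- (coords[[3]] - center[3])^2
    outer(outer(dx2, dy2, `+`), dz2, `+`)
  }
  extent <- dims * h
  rPtv <- 0.22 * min(extent)
  ptv <- dist2(c(0, 0, 0)) < rPtv^2
  oar <- dist2(c(rPtv + 0.6 * rPtv, 0, 0)) < (0.6 * rPtv)^2

  set.seed(spec@seed)
  field <- array(stats::rnorm(prod(dims)), dims)
  field <- .smoothGaussian3d(field, spec@correlationLength / h)

  fp <- field[ptv]
  q <- if (f <= 0) min(fp) - 1 else if (f >= 1) max(fp) + 1 else
    stats::quantile(fp, f, type = 1, names = FALSE)
  dev <- field - q
  sUp <- if (any(dev > 0)) (hi - 60) / max(dev) else 1
  sDn <- if (any(dev < 0)) (60 - lo) / max(-dev) else 1
  po2 <- array(pmin(hi, pmax(lo, 60 + min(sUp, sDn) * dev)), dims)

  realized <- mean(po2[ptv] < 60)
  if (abs(realized - f) > 0.02)
    stop(sprintf("unattainable hypoxic fraction: requested %.3f, realized %.3f",
                 f, realized))
  list(po2 = mk(po2), ptv = mk(array(as.numeric(ptv), dims)),
       oar = mk(array(as.numeric(oar), dims)))
}

#' Convert PET tracer uptake to pO2
#'
#' Piecewise-linear interpolation of a monotone calibration table, clamped
#' at the table ends. The calibration curve itself is a pluggable input
#' (two-column table: uptake, pO2 in mmHg).
#'
#' @param uptake a [VoxelGrid-class] or numeric vector of uptake values.
#' @param calibration data.frame whose first two columns are uptake and
#'   pO2 (mmHg); uptake must be strictly increasing.
#' @return pO2 in the same container as `uptake`.
#' @examples
#' cal <- data.frame(uptake = c(0, 1, 2), po2_mmHg = c(100, 40, 5))
#' uptakeToPo2(c(0.5, 1.5, 9), cal)
#' @export
uptakeToPo2 <- function(uptake, calibration) {
  if (ncol(calibration) < 2L)
    stop("configuration error: calibration table needs two columns")
  u <- as.numeric(calibration[[1]])
  p <- as.numeric(calibration[[2]])
  if (any(diff(u) <= 0))
    stop("configuration error: calibration uptake values must be strictly increasing")
  conv <- function(x) {
    if (length(u) == 1L) return(rep(p, length(x)))
    stats::approx(u, p, xout = x, rule = 2)$y
  }
  if (is(uptake, "VoxelGrid")) {
    out <- uptake
    out@values <- array(conv(as.vector(uptake@values)), dim(uptake@values))
    out
  } else conv(uptake)
}
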