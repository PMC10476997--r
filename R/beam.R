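## Analytical pencil-beam dose and LETd engine.
##
## Pristine Bragg curves follow a power-law depth-dose parametrization
## (range-energy exponent p = 1.77) convolved with a Gaussian range
## straggling kernel (straggling plus delivery energy spread); lateral
## spread is a depth-growing Gaussian. The LETd depth curve rises
## monotonically from an entrance value of ~1.5 keV/um through ~6-7 at the
## peak to a distal-falloff band of ~8-15 keV/um, matching the voxel-scale
## depth-LETd morphology of Monte Carlo proton pencil beams. All constants
## live in beamConfig() and are ordinary machine-calibration inputs.

.engineCache <- new.env(parent = emptyenv())

#' Pencil-beam engine configuration
#'
#' Machine and engine constants of the analytical dose/LET engine.
#' Depth-dose shape: for residual range t = range - z the unconvolved
#' curve is `t^(1/p - 1) + entranceCoef * t^(1/p)` with p = 1.77, then
#' convolved with a Gaussian of width `rangeSigmaFrac * range` (range
#' straggling plus delivery energy spread). LETd depth curve:
#' `letEntrance + letK / (max(range + letOffset - z, 0) + letT0)`, capped
#' at `letCap`. Lateral spread:
#' `sigma(z) = sqrt(sigma0^2 + (sigmaGrowth * z)^2)`.
#'
#' @param powerExponent range-energy power-law exponent p.
#' @param entranceCoef plateau term coefficient (sets the entrance-to-peak
#'   dose ratio, ~0.3 at default).
#' @param rangeSigmaFrac Gaussian range-straggling sigma as a fraction of
#'   range.
#' @param distalMargin mm beyond the range after which the dose is treated
#'   as zero (< 1% of peak by construction).
#' @param letEntrance,letK,letT0,letOffset,letCap LETd curve constants
#'   (keV/um and mm).
#' @param sigma0 lateral sigma at the surface, mm.
#' @param sigmaGrowth lateral sigma growth per mm depth.
#' @param fineStep internal depth sampling step, mm.
#' @param lateralCutoffSigma lateral support truncation, in sigmas.
#' @param doseRelCutoff per-spot relative dose threshold below which
#'   influence entries are dropped.
#' @param rangeLimits machine range limits, mm.
#' @return A list with class `"beamConfig"`.
#' @export
beamConfig <- function(powerExponent = 1.77, entranceCoef = 0.0047,
                       rangeSigmaFrac = 0.022, distalMargin = 10,
                       letEntrance = 1.1, letK = 40, letT0 = 3,
                       letOffset = 4, letCap = 15,
                       sigma0 = 2.2, sigmaGrowth = 0.035,
                       fineStep = 0.25, lateralCutoffSigma = 3,
                       doseRelCutoff = 1e-4, rangeLimits = c(10, 320)) {
  structure(list(powerExponent = powerExponent, entranceCoef = entranceCoef,
                 rangeSigmaFrac = rangeSigmaFrac, distalMargin = distalMargin,
                 letEntrance = letEntrance, letK = letK, letT0 = letT0,
                 letOffset = letOffset, letCap = letCap, sigma0 = sigma0,
                 sigmaGrowth = sigmaGrowth, fineStep = fineStep,
                 lateralCutoffSigma = lateralCutoffSigma,
                 doseRelCutoff = doseRelCutoff, rangeLimits = rangeLimits),
            class = "beamConfig")
}

## Internal: pristine depth-dose/LET profile on a fine grid, peak dose
## normalized to 1. Cached per (range, config).
.pristineProfile <- function(range, config) {
  key <- paste0("r", format(range, digits = 12), "|",
                paste(unlist(config[c("powerExponent", "entranceCoef",
                                      "rangeSigmaFrac", "distalMargin",
                                      "letEntrance", "letK", "letT0",
                                      "letOffset", "letCap", "fineStep")]),
                      collapse = ","))
  hit <- .engineCache[[key]]
  if (!is.null(hit)) return(hit)
  h <- config$fineStep
  zf <- seq(0, range + config$distalMargin + 4, by = h)
  t <- range - zf
  q <- 1 / config$powerExponent
  raw <- ifelse(t > 0, t^(q - 1) + config$entranceCoef * t^q, 0)
  sigma <- max(0.3, config$rangeSigmaFrac * range)
  xk <- seq(-4 * sigma, 4 * sigma, by = h)
  kern <- stats::dnorm(xk, 0, sigma)
  kern <- kern / sum(kern)
  pad <- (length(kern) - 1L) %/% 2L
  padded <- c(rep(raw[1], pad), raw, rep(0, pad))
  conv <- stats::filter(padded, kern, sides = 2)
  prof <- as.numeric(conv[(pad + 1L):(pad + length(zf))])
  prof[is.na(prof)] <- 0
  prof <- prof / max(prof)
  ## re-anchor so the convolved peak sits at the nominal range, extending
  ## the entrance plateau back to the surface
  zf <- zf + (range - zf[which.max(prof)])
  if (zf[1] > 0) {
    pre <- seq(0, zf[1] - h / 2, by = h)
    zf <- c(pre, zf)
    prof <- c(rep(prof[1], length(pre)), prof)
  }
  letd <- pmin(config$letCap,
               config$letEntrance +
                 config$letK / (pmax(range + config$letOffset - zf, 0) +
                                  config$letT0))
  res <- list(z = zf, dose = prof, letd = letd)
  .engineCache[[key]] <- res
  res
}

#' Pristine Bragg depth-dose curve
#'
#' Relative dose (peak = 1) of a single pencil beam of nominal range
#' `range` at water depth `z`. The curve has a low entrance plateau, a
#' single peak within one voxel of the range, and a steep distal falloff
#' reaching below 1% of the peak within `distalMargin` of the range.
#'
#' @param range nominal range, mm water.
#' @param z depth(s), mm; nonnegative. Depths beyond the computed grid
#'   return 0.
#' @param config a [beamConfig()] list.
#' @return relative dose, same length as `z`.
#' @examples
#' z <- seq(0, 100, by = 0.5)
#' d <- depthDose(80, z)
#' z[which.max(d)]  # peak near 80 mm
#' @export
depthDose <- function(range, z, config = beamConfig()) {
  if (any(z < 0)) stop("'z' must be nonnegative")
  if (range < config$rangeLimits[1] || range > config$rangeLimits[2])
    stop("range outside machine limits")
  p <- .pristineProfile(range, config)
  stats::approx(p$z, p$dose, xout = z, yleft = p$dose[1], yright = 0)$y
}

#' Depth curve of the dose-averaged LET of a pencil beam
#'
#' Monotonically nondecreasing from an entrance value of ~1.5 keV/um
#' through ~6-7 keV/um at the peak to a distal-edge band of ~8-15 keV/um
#' (capped at `letCap`), continuous in depth.
#'
#' @inheritParams depthDose
#' @return LETd in keV/um, same length as `z`.
#' @examples
#' depthLetd(80, c(5, 79, 82))
#' @export
depthLetd <- function(range, z, config = beamConfig()) {
  if (any(z < 0)) stop("'z' must be nonnegative")
  pmin(config$letCap,
       config$letEntrance +
         config$letK / (pmax(range + config$letOffset - z, 0) +
                          config$letT0))
}

## Internal: axis mapping of a field direction.
## Returns depth axis, sign, and the two lateral grid axes (beam-frame x, y).
.fieldAxes <- function(direction) {
  ax <- match(substr(direction, 1, 1), c("x", "y", "z"))
  sgn <- if (substr(direction, 2, 2) == "+") 1 else -1
  lat <- setdiff(1:3, ax)
  list(depthAxis = ax, sign = sgn, latAxes = lat)
}

## Internal: depth of each voxel center along a field, and entry-face
## coordinate. The beam enters at the grid face.
.voxelDepths <- function(grid, direction) {
  fa <- .fieldAxes(direction)
  n <- dim(grid@values)[fa$depthAxis]
  h <- grid@spacing[fa$depthAxis]
  centers <- grid@origin[fa$depthAxis] + (seq_len(n) - 1) * h
  if (fa$sign > 0) {
    face <- grid@origin[fa$depthAxis] - h / 2
    depths <- centers - face
  } else {
    face <- grid@origin[fa$depthAxis] + (n - 1) * h + h / 2
    depths <- face - centers
  }
  list(depths = depths, h = h, axes = fa)
}

## Internal: voxel-averaged depth dose and LET-dose for one (range,
## direction) on a grid: mean pristine dose and mean dose*LET within each
## depth voxel.
.depthVoxelProfiles <- function(range, depths, h, config) {
  p <- .pristineProfile(range, config)
  lo <- depths - h / 2
  bin <- findInterval(p$z, c(lo, depths[length(depths)] + h / 2))
  keep <- bin >= 1L & bin <= length(depths)
  dz <- nz <- numeric(length(depths))
  if (any(keep)) {
    sums <- rowsum(cbind(p$dose[keep], p$dose[keep] * p$letd[keep],
                         rep(1, sum(keep))), bin[keep])
    idx <- as.integer(rownames(sums))
    dz[idx] <- sums[, 1] / sums[, 3]
    nz[idx] <- sums[, 2] / sums[, 3]
  }
  list(dose = dz, letDose = nz)
}

#' Build per-spot influence data on a grid
#'
#' Computes the sparse per-unit-weight dose (`d_ij`) and LET-times-dose
#' (`n_ij = L_ij d_ij`) contributions of every plan spot to every grid
#' voxel: the pristine depth-dose/LET profile is averaged within depth
#' voxels and multiplied by Gaussian lateral factors integrated over the
#' voxel cross-section. Deterministic given the configuration. Spots whose
#' lateral position falls outside the grid contribute nothing and are
#' reported via a message.
#'
#' @param plan a [ProtonPlan-class].
#' @param grid a [VoxelGrid-class] defining the geometry.
#' @param config a [beamConfig()] list.
#' @return An [InfluenceData-class] object with voxels in array linear
#'   order of `grid`.
#' @export
buildInfluence <- function(plan, grid, config = beamConfig()) {
  stopifnot(is(plan, "ProtonPlan"), is(grid, "VoxelGrid"))
  dims <- dim(grid@values)
  nVox <- prod(dims)
  spots <- plan@spots
  nSpot <- nrow(spots)
  iList <- vector("list", nSpot)
  xList <- vector("list", nSpot)
  nList <- vector("list", nSpot)
  outside <- character()

  ## strides for linear indexing
  stride <- c(1L, dims[1], dims[1] * dims[2])

  for (fid in names(plan@fields)) {
    fld <- plan@fields[[fid]]
    vd <- .voxelDepths(grid, fld$direction)
    ax <- vd$axes
    nz <- length(vd$depths)
    ## work in increasing-depth order; map back to grid indices below
    depthsOrd <- if (ax$sign > 0) vd$depths else rev(vd$depths)
    sigmaZ <- sqrt(config$sigma0^2 + (config$sigmaGrowth * depthsOrd)^2)

    ## lateral geometry of the two beam-frame axes
    latInfo <- lapply(ax$latAxes, function(a) {
      n <- dims[a]
      hh <- grid@spacing[a]
      centers <- grid@origin[a] + (seq_len(n) - 1) * hh
      list(n = n, h = hh, centers = centers,
           lo = centers - hh / 2, hi = centers + hh / 2)
    })

    ## caches within this field: depth profiles per range, lateral factor
    ## matrices per (axis, offset)
    depthCache <- new.env(parent = emptyenv())
    latCache <- new.env(parent = emptyenv())

    latFactors <- function(axisIdx, pos) {
      key <- paste0(axisIdx, "@", format(pos, digits = 12))
      hit <- latCache[[key]]
      if (!is.null(hit)) return(hit)
      li <- latInfo[[axisIdx]]
      ## n_lat x n_depth matrix of integrated Gaussian factors
      g <- vapply(seq_len(nz), function(iz) {
        s <- sigmaZ[iz]
        stats::pnorm((li$hi - pos) / s) - stats::pnorm((li$lo - pos) / s)
      }, numeric(li$n))
      keep <- which(rowSums(g) > 0 &
                      abs(li$centers - pos) <=
                        config$lateralCutoffSigma * max(sigmaZ) + li$h)
      res <- list(g = g[keep, , drop = FALSE], idx = keep)
      latCache[[key]] <- res
      res
    }

    sIdx <- which(spots$field_id == fid)
    for (s in sIdx) {
      rng <- spots$range_mm[s]
      if (rng < config$rangeLimits[1] || rng > config$rangeLimits[2])
        stop("spot range outside machine limits: ", rng, " mm")
      rkey <- format(rng, digits = 12)
      dp <- depthCache[[rkey]]
      if (is.null(dp)) {
        dp <- .depthVoxelProfiles(rng, depthsOrd, vd$h, config)
        depthCache[[rkey]] <- dp
      }
      gx <- latFactors(1L, spots$x_mm[s])
      gy <- latFactors(2L, spots$y_mm[s])
      if (length(gx$idx) == 0L || length(gy$idx) == 0L) {
        outside <- c(outside, sprintf("spot %d (field %s)", s, fid))
        next
      }
      nx <- length(gx$idx)
      ny <- length(gy$idx)
      ## dose(lat1, lat2, depth) = depth profile x lateral factors
      mxz <- gx$g * rep(dp$dose, each = nx)        # nx x nz
      arr <- array(0, c(nx, ny, nz))
      for (iz in seq_len(nz)) {
        if (dp$dose[iz] <= 0) next
        arr[, , iz] <- outer(mxz[, iz], gy$g[, iz])
      }
      cutoff <- config$doseRelCutoff * max(arr)
      sel <- which(arr > cutoff)
      if (length(sel) == 0L) {
        outside <- c(outside, sprintf("spot %d (field %s)", s, fid))
        next
      }
      sub <- arrayInd(sel, c(nx, ny, nz))
      ## map (lat1, lat2, depth) to grid axis subscripts
      subGrid <- matrix(0L, nrow(sub), 3L)
      subGrid[, ax$latAxes[1]] <- gx$idx[sub[, 1]]
      subGrid[, ax$latAxes[2]] <- gy$idx[sub[, 2]]
      dIdx <- if (ax$sign > 0) sub[, 3] else (nz + 1L - sub[, 3])
      subGrid[, ax$depthAxis] <- dIdx
      lin <- 1L + (subGrid[, 1] - 1L) * stride[1] +
        (subGrid[, 2] - 1L) * stride[2] + (subGrid[, 3] - 1L) * stride[3]
      dVals <- arr[sel]
      ## LET-dose shares the lateral factors: n = dose * (letDose/dose)
      ratio <- ifelse(dp$dose > 0, dp$letDose / pmax(dp$dose, 1e-300), 0)
      nVals <- dVals * ratio[sub[, 3]]
      iList[[s]] <- lin
      xList[[s]] <- dVals
      nList[[s]] <- nVals
    }
  }
  if (length(outside))
    message("spots contributing nothing to the grid: ",
            paste(outside, collapse = ", "))
  counts <- lengths(iList)
  j <- rep.int(seq_len(nSpot), counts)
  i <- unlist(iList, use.names = FALSE)
  xd <- unlist(xList, use.names = FALSE)
  xn <- unlist(nList, use.names = FALSE)
  if (is.null(i)) {
    i <- integer()
    xd <- xn <- numeric()
  }
  doseM <- Matrix::sparseMatrix(i = i, j = j, x = xd, dims = c(nVox, nSpot))
  letM <- Matrix::sparseMatrix(i = i, j = j, x = xn, dims = c(nVox, nSpot))
  new("InfluenceData", dose = doseM, letDose = letM,
      gridDims = as.integer(dims))
}

#' Build the initial spread-out Bragg peak plan
#'
#' Lays a lateral spot lattice covering the target cross-section (plus one
#' spot-spacing margin) and energy layers spanning its depth extent, then
#' optimizes the spot weights so that 1.1 times the physical dose matches
#' the prescription uniformly in the target: the standard clinical
#' constant-RBE first approximation of the plan, produced with the same
#' dose-difference optimizer with the OER disabled.
#'
#' @param targetMask a [VoxelGrid-class] 0/1 target mask (also defines the
#'   geometry).
#' @param fields list of [beamField()] descriptions.
#' @param prescription prescription, Gy(RBE).
#' @param config a [beamConfig()] list.
#' @param optimConfig an [optimizerConfig()] for the initial-weight
#'   optimization.
#' @return list with elements `plan` (the optimized [ProtonPlan-class]),
#'   `influence` (the [InfluenceData-class], reusable for subsequent
#'   optimization) and `fit` (the [PlanOptimization-class] of the
#'   constant-RBE run).
#' @export
initSobpPlan <- function(targetMask, fields, prescription,
                         config = beamConfig(),
                         optimConfig = optimizerConfig()) {
  stopifnot(is(targetMask, "VoxelGrid"))
  mask <- targetMask@values != 0
  if (!any(mask)) stop("nonempty target required")
  if (is.null(names(fields)) || any(!nzchar(names(fields))))
    names(fields) <- vapply(fields, `[[`, "", "id")
  dims <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)

  spotRows <- list()
  for (fld in fields) {
    vd <- .voxelDepths(targetMask, fld$direction)
    ax <- vd$axes
    ## depth extent of the target along this field (voxel faces)
    dDepth <- vd$depths[idx[, ax$depthAxis]]
    dmin <- min(dDepth) - vd$h / 2
    dmax <- max(dDepth) + vd$h / 2
    if (dmax - dmin < fld$layerSpacing)
      stop("configuration error: target thinner than one layer spacing ",
           "along field ", fld$id)
    ranges <- seq(dmin + 1, dmax + 2.5, by = fld$layerSpacing)
    ## lateral lattice centered on the target cross-section
    latPos <- lapply(1:2, function(k) {
      a <- ax$latAxes[k]
      centers <- targetMask@origin[a] + (idx[, a] - 1) * targetMask@spacing[a]
      mid <- (min(centers) + max(centers)) / 2
      half <- (max(centers) - min(centers)) / 2
      kk <- ceiling(half / fld$spotSpacing)
      mid + fld$spotSpacing * (-kk:kk)
    })
    lat <- expand.grid(x_mm = latPos[[1]], y_mm = latPos[[2]])
    for (r in ranges)
      spotRows[[length(spotRows) + 1L]] <-
        data.frame(field_id = fld$id, range_mm = r, x_mm = lat$x_mm,
                   y_mm = lat$y_mm, weight = 1)
  }
  spots <- do.call(rbind, spotRows)
  plan <- protonPlan(spots, fields, prescription)
  influence <- buildInfluence(plan, targetMask, config)

  ## scale the uniform start so the mean target dose is near the physical
  ## prescription, then flatten with the optimizer (constant RBE, OER off)
  unitDose <- as.numeric(influence@dose[as.vector(mask), , drop = FALSE] %*%
                           spotWeights(plan))
  scale <- (prescription / 1.1) / mean(unitDose)
  spotWeights(plan) <- spotWeights(plan) * scale
  po2 <- targetMask
  po2@values <- array(160, dims)
  fit <- optimizePlan(plan, influence, po2,
                      objectives = list(objective(mask, "uniform_target",
                                                  prescription)),
                      model = rbeModel("constant_1p1"),
                      tissue = tissueParams(),
                      config = optimConfig, oerOn = FALSE)
  list(plan = optimizedPlan(fit), influence = influence, fit = fit)
}
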