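## ROWD: mixed-field LETd accumulation and the RBE-and-OER weighted dose.

#' Dose-averaged LET from influence data
#'
#' Accumulates the per-voxel dose-averaged LET of the mixed field delivered
#' by a weighted spot set:
#' `LETd_i = sum_j w_j n_ij / sum_j w_j d_ij` with `n_ij = L_ij d_ij`.
#' Voxels receiving zero dose get LETd 0 by convention.
#'
#' @param weights nonnegative spot weights, one per influence column.
#' @param influence an [InfluenceData-class] object.
#' @return numeric vector of LETd (keV/um) per voxel, in grid linear order.
#' @export
letdFromInfluence <- function(weights, influence) {
  stopifnot(is(influence, "InfluenceData"))
  if (any(weights < 0)) stop("spot weights must be nonnegative")
  if (length(weights) != ncol(influence@dose))
    stop("need one weight per spot")
  d <- as.numeric(influence@dose %*% weights)
  n <- as.numeric(influence@letDose %*% weights)
  ifelse(d > 0, n / d, 0)
}

## Internal: per-voxel alphaX/betaX vectors from a TissueParams or a list of
## list(mask=, params=) assignments applied in order (later wins).
.tissueVectors <- function(tissue, nVox) {
  if (is(tissue, "TissueParams"))
    return(list(alphaX = rep(tissue@alphaX, nVox),
                betaX = rep(tissue@betaX, nVox)))
  aX <- rep(NA_real_, nVox)
  bX <- rep(NA_real_, nVox)
  for (entry in tissue) {
    m <- if (is(entry$mask, "VoxelGrid")) entry$mask@values != 0 else entry$mask
    aX[as.vector(m)] <- entry$params@alphaX
    bX[as.vector(m)] <- entry$params@betaX
  }
  if (anyNA(aX))
    stop("tissue map does not cover every voxel")
  list(alphaX = aX, betaX = bX)
}

#' RBE-and-OER weighted dose (ROWD)
#'
#' Converts a mixed proton field into a photon-equivalent dose that
#' accounts simultaneously for LET-driven RBE and hypoxia-driven
#' radioresistance. Per voxel, with hypoxic parameters
#' `alphaH = alphaRBE / OER` and `betaH = betaRBE / OER^2` evaluated at the
#' voxel LETd and pO2,
#'
#' `ROWD = (D / Dp) * ( sqrt( (alphaX / (2 betaX))^2 +
#'          (alphaH Dp + betaH Dp^2) / betaX ) - alphaX / (2 betaX) )`
#'
#' i.e. the photon dose producing the same linear-quadratic effect as the
#' proton dose `Dp`, rescaled by the total-to-proton dose ratio. Voxels
#' with `Dp = 0` return 0.
#'
#' @param doses a [DoseSet-class] (total dose, proton dose, LETd grids).
#' @param po2 a [VoxelGrid-class] of oxygen pressures, mmHg.
#' @param tissue a [TissueParams-class] applied to all voxels, or a list of
#'   `list(mask =, params =)` entries resolving tissue per voxel.
#' @param model an [RbeModel-class] object.
#' @param params an [OerModelParams-class] object.
#' @param oerOn logical; if `FALSE` the OER is held at 1 (pure RBE
#'   weighting).
#' @return a [VoxelGrid-class] of ROWD values, Gy(RBE).
#' @examples
#' g <- voxelGrid(array(2, c(2, 2, 2)), spacing = 2)
#' l <- voxelGrid(array(3, c(2, 2, 2)), spacing = 2)
#' p <- voxelGrid(array(160, c(2, 2, 2)), spacing = 2)
#' ds <- doseSet(g, l)
#' computeRowd(ds, p, tissueParams(), rbeModel("constant_1p1"))
#' @export
computeRowd <- function(doses, po2, tissue, model, params = oerParams(),
                        oerOn = TRUE) {
  stopifnot(is(doses, "DoseSet"), is(po2, "VoxelGrid"))
  dims <- dim(doses@dProton@values)
  if (!identical(dims, dim(po2@values)))
    stop("shape error: pO2 grid is not aligned with the dose grids")
  dp <- as.vector(doses@dProton@values)
  dt <- as.vector(doses@dTotal@values)
  L <- as.vector(doses@letd@values)
  p <- as.vector(po2@values)
  tv <- .tissueVectors(tissue, length(dp))
  if (any(tv$betaX <= 0)) stop("configuration error: betaX must be > 0")
  o <- if (oerOn) oer(L, p, params) else rep(1, length(dp))
  out <- rowdClosedForm(dp, dt, L, o, tv$alphaX, tv$betaX, model, tissue)
  res <- doses@dProton
  res@values <- array(out, dims)
  res
}

## Internal closed form shared by computeRowd and the optimizer: all inputs
## are per-voxel vectors except model/tissue. For a tissue map the aerobic
## RBE parameters must be evaluated per voxel, so tissue may be a list; the
## alphaX/betaX vectors are passed in precomputed.
rowdClosedForm <- function(dp, dt, letd, oerValue, alphaX, betaX, model,
                           tissue) {
  if (is(tissue, "TissueParams")) {
    rb <- rbeParamsAerobic(model, letd, tissue)
  } else {
    rb <- list(alpha = rep(NA_real_, length(dp)),
               beta = rep(NA_real_, length(dp)))
    for (entry in tissue) {
      m <- if (is(entry$mask, "VoxelGrid")) entry$mask@values != 0 else entry$mask
      m <- as.vector(m)
      sub <- rbeParamsAerobic(model, letd[m], entry$params)
      rb$alpha[m] <- sub$alpha
      rb$beta[m] <- sub$beta
    }
  }
  h <- hypoxicParams(rb$alpha, rb$beta, oerValue)
  k <- alphaX / (2 * betaX)
  eff <- h$alpha * dp + h$beta * dp^2
  out <- ifelse(dp > 0,
                (dt / pmax(dp, .Machine$double.xmin)) *
                  (sqrt(k^2 + eff / betaX) - k),
                0)
  out
}

#' Sensitivity of the ROWD to pO2 and LET
#'
#' Central finite differences of the ROWD with respect to the voxel oxygen
#' pressure and the voxel LETd, holding the physical dose fixed. Normoxic
#' voxels (both perturbed pressures at or above the normoxia threshold)
#' have zero pO2 sensitivity because the OER is clamped there.
#'
#' @param doses a [DoseSet-class].
#' @param po2 a [VoxelGrid-class] of oxygen pressures, mmHg.
#' @param tissue a [TissueParams-class] (or tissue map, see
#'   [computeRowd()]).
#' @param model an [RbeModel-class].
#' @param params an [OerModelParams-class].
#' @param deltaP pO2 step, mmHg (> 0).
#' @param deltaL LETd step, keV/um (> 0).
#' @return list of two [VoxelGrid-class] objects: `dRowdDpo2` (Gy(RBE) per
#'   mmHg) and `dRowdDletd` (Gy(RBE) per keV/um).
#' @export
rowdSensitivity <- function(doses, po2, tissue, model, params = oerParams(),
                            deltaP = 1, deltaL = 0.1) {
  if (deltaP <= 0 || deltaL <= 0) stop("perturbation steps must be positive")
  shift <- function(grid, d) { grid@values <- grid@values + d; grid }
  clampP <- function(grid) { grid@values <- pmax(grid@values, 0); grid }
  clampL <- function(ds, d) {
    ds@letd@values <- pmax(ds@letd@values + d, 0)
    ds
  }
  rp <- computeRowd(doses, clampP(shift(po2, deltaP)), tissue, model, params)
  rm_ <- computeRowd(doses, clampP(shift(po2, -deltaP)), tissue, model, params)
  dP <- rp
  dP@values <- (rp@values - rm_@values) / (2 * deltaP)
  lp <- computeRowd(clampL(doses, deltaL), po2, tissue, model, params)
  lm_ <- computeRowd(clampL(doses, -deltaL), po2, tissue, model, params)
  dL <- lp
  dL@values <- (lp@values - lm_@values) / (2 * deltaL)
  list(dRowdDpo2 = dP, dRowdDletd = dL)
}
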