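## Iterative dose-difference spot-weight optimization of the ROWD.

.checkObjectives <- function(objectives) {
  kinds <- vapply(objectives, function(o) o@kind, "")
  if (sum(kinds == "uniform_target") != 1L)
    stop("configuration error: exactly one uniform_target objective required")
  tgt <- objectives[[which(kinds == "uniform_target")]]
  if (!any(tgt@mask))
    stop("configuration error: empty target mask")
  invisible(kinds)
}

#' Objective cost of a ROWD distribution
#'
#' Mean squared deviation of ROWD from the prescription over the target,
#' plus one-sided quadratic penalties for maximum constraints:
#' `cost = mean_target (R - P)^2 +
#'         sum_constraints w * mean(max(0, R - level)^2)`.
#'
#' @param rowd a [VoxelGrid-class] of ROWD values, or a numeric vector in
#'   grid linear order.
#' @param objectives list of [objective()] objects; exactly one
#'   `uniform_target`.
#' @return scalar cost, >= 0.
#' @export
planCost <- function(rowd, objectives) {
  .checkObjectives(objectives)
  r <- if (is(rowd, "VoxelGrid")) as.vector(rowd@values) else as.numeric(rowd)
  cost <- 0
  for (o in objectives) {
    m <- as.vector(o@mask)
    if (o@kind == "uniform_target") {
      cost <- cost + mean((r[m] - o@level)^2)
    } else {
      cost <- cost + o@penaltyWeight * mean(pmax(0, r[m] - o@level)^2)
    }
  }
  cost
}

#' One dose-difference weight update
#'
#' Multiplicative update of every spot weight towards the prescription:
#' `w_j <- max(minWeight, w_j * (sum_i d_ij P_i^eff / sum_i d_ij R_i)^damping)`
#' where the sums run over objective voxels, `P^eff` is the prescription on
#' target voxels and the constraint level on voxels currently violating a
#' maximum constraint (non-violated constraint voxels and voxels outside
#' all objectives are ignored), and `R` is the current ROWD. Spots with a
#' zero denominator keep their weight (a warning is issued).
#'
#' @param weights current spot weights, >= 0.
#' @param influence an [InfluenceData-class].
#' @param objectives list of [objective()] objects.
#' @param rowd current ROWD as a [VoxelGrid-class] or numeric vector in
#'   grid linear order.
#' @param config an [optimizerConfig()].
#' @return updated weight vector.
#' @export
optimStep <- function(weights, influence, objectives, rowd,
                      config = optimizerConfig()) {
  if (any(weights < 0)) stop("weights must be >= 0")
  .checkObjectives(objectives)
  r <- if (is(rowd, "VoxelGrid")) as.vector(rowd@values) else as.numeric(rowd)
  sel <- .objectiveSelection(objectives, r)
  .updateWeights(weights, influence@dose[sel$idx, , drop = FALSE],
                 sel$pEff, r[sel$idx], config)
}

## Internal: voxel selection for the update. Target voxels take precedence
## over constraint voxels; only violated constraint voxels participate.
.objectiveSelection <- function(objectives, r) {
  kinds <- vapply(objectives, function(o) o@kind, "")
  tgt <- objectives[[which(kinds == "uniform_target")]]
  tIdx <- which(as.vector(tgt@mask))
  idx <- tIdx
  pEff <- rep(tgt@level, length(tIdx))
  for (o in objectives[kinds == "max_constraint"]) {
    cIdx <- setdiff(which(as.vector(o@mask) & r > o@level), tIdx)
    idx <- c(idx, cIdx)
    pEff <- c(pEff, rep(o@level, length(cIdx)))
  }
  list(idx = idx, pEff = pEff)
}

.updateWeights <- function(weights, doseSub, pEff, rSub, config) {
  num <- as.numeric(Matrix::crossprod(doseSub, pEff))
  den <- as.numeric(Matrix::crossprod(doseSub, rSub))
  ratio <- rep(1, length(weights))
  ok <- den > 0
  if (any(!ok & num > 0))
    warning("spots with zero accumulated ROWD kept their weight")
  ratio[ok] <- num[ok] / den[ok]
  pmax(config@minWeight, weights * ratio^config@damping)
}

#' Optimize spot weights for homogeneous ROWD
#'
#' Alternating recompute/update loop: per iteration the ROWD of the
#' current weights is evaluated on the objective voxels (LETd and the
#' radiobiological parameters are refreshed every `letRefreshEvery`
#' iterations, dose every iteration) and all spot weights receive the
#' multiplicative dose-difference update of [optimStep()]. Iterations stop
#' when the relative cost change falls below `relTol` or at `maxIters`.
#' Fully deterministic for a fixed configuration. A plain
#' projected-gradient variant of the weight update (same cost, exact ROWD
#' dose derivative, backtracking line search) is available via
#' `optimizerConfig(method = "gradient")`.
#'
#' @param plan initial [ProtonPlan-class] (e.g. from [initSobpPlan()]).
#' @param influence an [InfluenceData-class] for `plan` on the grid.
#' @param po2 a [VoxelGrid-class] of oxygen pressures, mmHg.
#' @param objectives list of [objective()] objects; exactly one
#'   `uniform_target`.
#' @param model an [RbeModel-class].
#' @param tissue a [TissueParams-class] (or tissue map, see
#'   [computeRowd()]).
#' @param config an [optimizerConfig()].
#' @param params an [OerModelParams-class].
#' @param oerOn include the OER (`FALSE` gives pure RBE-weighted
#'   optimization).
#' @param secondaryFraction constant secondary-dose fraction (default 0).
#' @return A [PlanOptimization-class]: optimized plan, convergence log
#'   (iteration, cost, D50 of target ROWD, maximum constraint violation),
#'   and final ROWD / total dose / LETd grids.
#' @export
optimizePlan <- function(plan, influence, po2, objectives, model, tissue,
                         config = optimizerConfig(), params = oerParams(),
                         oerOn = TRUE, secondaryFraction = 0) {
  stopifnot(is(plan, "ProtonPlan"), is(influence, "InfluenceData"),
            is(po2, "VoxelGrid"))
  .checkObjectives(objectives)
  dims <- dim(po2@values)
  if (!identical(as.integer(dims), influence@gridDims))
    stop("shape error: influence grid does not match the pO2 grid")
  kinds <- vapply(objectives, function(o) o@kind, "")
  tgt <- objectives[[which(kinds == "uniform_target")]]
  tIdxFull <- which(as.vector(tgt@mask))
  objVox <- sort(unique(unlist(lapply(objectives,
                                      function(o) which(as.vector(o@mask))))))
  A <- influence@dose[objVox, , drop = FALSE]
  N <- influence@letDose[objVox, , drop = FALSE]
  pObj <- as.vector(po2@values)[objVox]
  tv <- .tissueVectors(tissue, prod(dims))
  if (any(tv$betaX <= 0)) stop("configuration error: betaX must be > 0")
  aXObj <- tv$alphaX[objVox]
  bXObj <- tv$betaX[objVox]
  tInObj <- match(tIdxFull, objVox)
  objLocal <- lapply(objectives, function(o)
    list(kind = o@kind, level = o@level, pw = o@penaltyWeight,
         idx = match(which(as.vector(o@mask)), objVox)))

  w <- spotWeights(plan)
  scal <- 1 / (1 - secondaryFraction)
  kObj <- aXObj / (2 * bXObj)
  hPars <- NULL
  logRows <- vector("list", config@maxIters)
  prevCost <- NA_real_

  ## ROWD on the objective voxels with the current (frozen) hypoxic
  ## parameters, and the objective cost of such a distribution
  rowdOf <- function(dpObj) {
    dtObj <- dpObj * scal
    eff <- hPars$alpha * dpObj + hPars$beta * dpObj^2
    ifelse(dpObj > 0,
           (dtObj / pmax(dpObj, .Machine$double.xmin)) *
             (sqrt(kObj^2 + eff / bXObj) - kObj), 0)
  }
  costOf <- function(r) {
    cost <- 0
    for (o in objLocal) {
      if (o$kind == "uniform_target") {
        cost <- cost + mean((r[o$idx] - o$level)^2)
      } else {
        cost <- cost + o$pw * mean(pmax(0, r[o$idx] - o$level)^2)
      }
    }
    cost
  }

  for (it in seq_len(config@maxIters)) {
    dpObj <- as.numeric(A %*% w)
    if (it == 1L || (it - 1L) %% config@letRefreshEvery == 0L) {
      nObj <- as.numeric(N %*% w)
      letObj <- ifelse(dpObj > 0, nObj / dpObj, 0)
      oObj <- if (oerOn) oer(letObj, pObj, params) else rep(1, length(pObj))
      hPars <- .aerobicThenHypoxic(model, letObj, tissue, objVox, dims, oObj)
    }
    r <- rowdOf(dpObj)
    cost <- costOf(r)
    maxViol <- 0
    for (o in objLocal)
      if (o$kind == "max_constraint")
        maxViol <- max(maxViol, 0, r[o$idx] - o$level)
    if (!is.finite(cost))
      stop("optimization aborted: non-finite cost at iteration ", it,
           " (", sum(!is.finite(r)), " non-finite ROWD voxels, ",
           "weight range [", min(w), ", ", max(w), "])")
    logRows[[it]] <- data.frame(iteration = it, cost = cost,
                                d50_target = stats::median(r[tInObj]),
                                max_violation = maxViol)
    if (it > 1L && abs(cost - prevCost) < config@relTol * max(prevCost,
                                                              1e-12))
      break
    prevCost <- cost

    if (config@method == "gradient") {
      ## plain projected gradient descent with backtracking on the cost,
      ## ROWD linearized through its exact dose derivative
      slope <- ifelse(dpObj > 0,
                      scal * (hPars$alpha + 2 * hPars$beta * dpObj) /
                        (2 * bXObj * sqrt(kObj^2 +
                          (hPars$alpha * dpObj + hPars$beta * dpObj^2) /
                            bXObj)),
                      scal * hPars$alpha / aXObj)
      resid <- numeric(length(r))
      for (o in objLocal) {
        if (o$kind == "uniform_target") {
          resid[o$idx] <- resid[o$idx] +
            2 * (r[o$idx] - o$level) / length(o$idx)
        } else {
          resid[o$idx] <- resid[o$idx] +
            2 * o$pw * pmax(0, r[o$idx] - o$level) / length(o$idx)
        }
      }
      g <- as.numeric(Matrix::crossprod(A, resid * slope))
      gmax <- max(abs(g))
      if (gmax == 0) break
      step <- 0.5 * max(w, 1e-12) / gmax
      for (bt in seq_len(25)) {
        wTry <- pmax(config@minWeight, w - step * g)
        if (costOf(rowdOf(as.numeric(A %*% wTry))) < cost) break
        step <- step / 2
      }
      w <- wTry
    } else {
      ## effective prescription: target level on target voxels, constraint
      ## level on currently violated constraint voxels
      idx <- tInObj
      pEff <- rep(tgt@level, length(tInObj))
      for (o in objLocal) {
        if (o$kind == "uniform_target") next
        cIdx <- setdiff(o$idx[r[o$idx] > o$level], tInObj)
        idx <- c(idx, cIdx)
        pEff <- c(pEff, rep(o$level, length(cIdx)))
      }
      w <- .updateWeights(w, A[idx, , drop = FALSE], pEff, r[idx], config)
    }
  }

  spotWeights(plan) <- w
  log <- do.call(rbind, logRows[!vapply(logRows, is.null, TRUE)])
  ## final full-grid evaluation
  dpFull <- as.numeric(influence@dose %*% w)
  letFull <- letdFromInfluence(w, influence)
  mk <- function(vals) voxelGrid(array(vals, dims), po2@spacing, po2@origin)
  doses <- doseSet(mk(dpFull), mk(letFull), secondaryFraction)
  rowd <- computeRowd(doses, po2, tissue, model, params, oerOn = oerOn)
  new("PlanOptimization", plan = plan, log = log, rowd = rowd,
      dose = doses@dTotal, letd = doses@letd)
}

## Internal: hypoxic (alphaH, betaH) on the objective voxels, honoring a
## per-voxel tissue map.
.aerobicThenHypoxic <- function(model, letObj, tissue, objVox, dims, oObj) {
  if (is(tissue, "TissueParams")) {
    rb <- rbeParamsAerobic(model, letObj, tissue)
  } else {
    rb <- list(alpha = rep(NA_real_, length(letObj)),
               beta = rep(NA_real_, length(letObj)))
    for (entry in tissue) {
      m <- if (is(entry$mask, "VoxelGrid")) entry$mask@values != 0 else entry$mask
      mm <- which(as.vector(m))
      loc <- which(objVox %in% mm)
      if (!length(loc)) next
      sub <- rbeParamsAerobic(model, letObj[loc], entry$params)
      rb$alpha[loc] <- sub$alpha
      rb$beta[loc] <- sub$beta
    }
  }
  hypoxicParams(rb$alpha, rb$beta, oObj)
}
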