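#' @import methods
NULL

## ---------------------------------------------------------------------------
## VoxelGrid: axis-aligned 3-D scalar field
## ---------------------------------------------------------------------------

#' VoxelGrid: an axis-aligned 3-D scalar field
#'
#' The basic spatial container of the package: a 3-D array of voxel values
#' together with voxel spacing (mm per axis) and the world coordinate of the
#' first voxel center (mm, RAS convention). Doses (Gy), dose-averaged LET
#' (keV/um), partial oxygen pressure maps (mmHg), ROWD (Gy(RBE)) and binary
#' structure masks are all stored as `VoxelGrid` objects and must share
#' geometry before they can be combined.
#'
#' @slot values numeric 3-D array of voxel values.
#' @slot spacing numeric(3), voxel size in mm per axis; strictly positive.
#' @slot origin numeric(3), world coordinates (mm) of the center of voxel
#'   `[1, 1, 1]`.
#'
#' @seealso [voxelGrid()], [gridValues()], [readGrid()]
#' @export
setClass("VoxelGrid",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(values = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive finite numbers (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be 3 finite numbers (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelGrid
#'
#' @param values numeric 3-D array (or a vector with `dims` supplied).
#' @param spacing voxel size in mm, length 1 (isotropic) or 3.
#' @param origin world position (mm) of the first voxel center, length 3.
#' @param dims optional integer(3) used to reshape `values`.
#' @return A [VoxelGrid-class] object.
#' @examples
#' g <- voxelGrid(array(1, c(4, 4, 4)), spacing = 2)
#' gridDims(g)
#' @export
voxelGrid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      dims = NULL) {
  if (!is.null(dims)) values <- array(values, dim = dims)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("VoxelGrid", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

## ---------------------------------------------------------------------------
## OerModelParams: constants of the OER model
## ---------------------------------------------------------------------------

#' Parameters of the oxygen enhancement ratio model
#'
#' Fitted constants of the LET- and pO2-dependent linear-quadratic
#' radiosensitivity model underlying the OER, plus the reference pressure
#' and evaluation conventions. The alpha parameter is
#' `((a1 + a2*L)*p + (a3 + a4*L)*K) / (p + K)` and the beta parameter
#' `(b1*p + b2*K) / (p + K)`, saturation forms that interpolate between the
#' anoxic (p = 0) and fully aerobic (p -> Inf) fit constants with
#' half-saturation pressure `K`. The OER is the ratio of doses at 10% cell
#' survival at pressure `p` versus the aerobic reference pressure `pA`.
#'
#' @slot a1,a2,a3,a4 alpha-model constants; `a1`, `a3` in 1/Gy, `a2`, `a4`
#'   in um/(Gy keV) (multiply LET in keV/um).
#' @slot b1,b2 beta-model constants (as printed, 1/Gy).
#' @slot K half-saturation oxygen pressure, mmHg.
#' @slot pA aerobic reference pressure, mmHg.
#' @slot survivalLevel survival fraction at which the OER is taken.
#' @slot normoxiaThreshold pressure (mmHg) at and above which tissue is
#'   treated as normoxic with OER forced to exactly 1.
#' @slot betaConvention `"sqrt"` reads the b-constants as sqrt(beta) and
#'   squares the expression (consistent with their printed 1/Gy units);
#'   `"linear"` uses the b-expression directly as beta.
#' @slot clampFloorOne if `TRUE`, the OER is floored at 1 everywhere.
#' @seealso [oerParams()], [oer()]
#' @export
setClass("OerModelParams",
  representation(a1 = "numeric", a2 = "numeric", a3 = "numeric",
                 a4 = "numeric", b1 = "numeric", b2 = "numeric",
                 K = "numeric", pA = "numeric", survivalLevel = "numeric",
                 normoxiaThreshold = "numeric", betaConvention = "character",
                 clampFloorOne = "logical"))

setValidity("OerModelParams", function(object) {
  msg <- character()
  cst <- c(a1 = object@a1, a2 = object@a2, a3 = object@a3, a4 = object@a4,
           b1 = object@b1, b2 = object@b2, K = object@K, pA = object@pA)
  if (any(lengths(list(object@a1, object@a2, object@a3, object@a4,
                       object@b1, object@b2, object@K, object@pA)) != 1L) ||
      any(!is.finite(cst)) || any(cst <= 0))
    msg <- c(msg, "all model constants must be single positive numbers")
  else if (object@pA <= object@K)
    msg <- c(msg, "'pA' must exceed the half-saturation pressure 'K'")
  if (length(object@survivalLevel) != 1L ||
      !is.finite(object@survivalLevel) ||
      object@survivalLevel <= 0 || object@survivalLevel >= 1)
    msg <- c(msg, "'survivalLevel' must lie in (0, 1)")
  if (length(object@normoxiaThreshold) != 1L ||
      !is.finite(object@normoxiaThreshold) ||
      object@normoxiaThreshold < object@pA)
    msg <- c(msg, "'normoxiaThreshold' must be >= 'pA'")
  if (!object@betaConvention %in% c("linear", "sqrt"))
    msg <- c(msg, "'betaConvention' must be \"linear\" or \"sqrt\"")
  if (length(msg)) msg else TRUE
})

#' Construct OER model parameters
#'
#' Defaults are the in-vitro proton fit: `a1 = 0.10` 1/Gy, `a2 = 0.0010`
#' um/(Gy keV), `a3 = 0.010` 1/Gy, `a4 = 0.0100` um/(Gy keV), `b1 = 0.765`,
#' `b2 = 0.273`, `K = 3` mmHg, reference pressure `pA = 30` mmHg, OER taken
#' at 10% survival, and 60 mmHg as the normoxia threshold.
#'
#' The b-constants carry units of 1/Gy, i.e. they parametrize sqrt(beta)
#' (beta itself is 1/Gy^2), so the default convention is `"sqrt"`; the
#' `"linear"` convention (the b-expression used directly as beta) is kept
#' available behind the flag.
#'
#' @param a1,a2,a3,a4,b1,b2,K,pA,survivalLevel,normoxiaThreshold model
#'   constants, see [OerModelParams-class].
#' @param betaConvention `"sqrt"` (default) or `"linear"`.
#' @param clampFloorOne floor the OER at 1 (default `TRUE`).
#' @return An [OerModelParams-class] object.
#' @examples
#' p <- oerParams()
#' oer(2, 2.5, p)
#' @export
oerParams <- function(a1 = 0.10, a2 = 0.0010, a3 = 0.010, a4 = 0.0100,
                      b1 = 0.765, b2 = 0.273, K = 3, pA = 30,
                      survivalLevel = 0.1, normoxiaThreshold = 60,
                      betaConvention = c("sqrt", "linear"),
                      clampFloorOne = TRUE) {
  betaConvention <- match.arg(betaConvention)
  new("OerModelParams", a1 = a1, a2 = a2, a3 = a3, a4 = a4, b1 = b1,
      b2 = b2, K = K, pA = pA, survivalLevel = survivalLevel,
      normoxiaThreshold = normoxiaThreshold,
      betaConvention = betaConvention, clampFloorOne = clampFloorOne)
}

## ---------------------------------------------------------------------------
## TissueParams: aerobic photon radiosensitivity
## ---------------------------------------------------------------------------

#' Aerobic photon radiosensitivity of a structure
#'
#' Linear-quadratic photon parameters alpha_x (1/Gy) and beta_x (1/Gy^2) of
#' a structure under full oxygenation; their ratio (alpha/beta)_x in Gy is
#' exposed through [alphaBetaRatio()].
#'
#' @slot alphaX photon alpha, 1/Gy; > 0.
#' @slot betaX photon beta, 1/Gy^2; > 0.
#' @slot label structure name.
#' @seealso [tissueParams()]
#' @export
setClass("TissueParams",
  representation(alphaX = "numeric", betaX = "numeric", label = "character"))

setValidity("TissueParams", function(object) {
  if (length(object@alphaX) != 1L || !is.finite(object@alphaX) ||
      object@alphaX <= 0) return("'alphaX' must be a single positive number")
  if (length(object@betaX) != 1L || !is.finite(object@betaX) ||
      object@betaX <= 0) return("'betaX' must be a single positive number")
  TRUE
})

#' Construct tissue radiosensitivity parameters
#'
#' Defaults describe a target with (alpha/beta)_x = 10 Gy. For organs at
#' risk a ratio of 3 Gy is conventional, e.g.
#' `tissueParams(0.105, 0.035, "OAR")`.
#'
#' @param alphaX photon alpha, 1/Gy.
#' @param betaX photon beta, 1/Gy^2.
#' @param label structure name.
#' @return A [TissueParams-class] object.
#' @examples
#' alphaBetaRatio(tissueParams())
#' @export
tissueParams <- function(alphaX = 0.10, betaX = 0.010, label = "target") {
  new("TissueParams", alphaX = alphaX, betaX = betaX, label = label)
}

## ---------------------------------------------------------------------------
## RbeModel: RBE model specification
## ---------------------------------------------------------------------------

#' RBE model specification
#'
#' Identifies how aerobic proton radiosensitivity parameters are produced
#' from dose-averaged LET and tissue photon parameters. `constant_1p1`
#' scales alpha by 1.1 and beta by 1.1^2 independent of LET; the variable
#' models (`MCN`, `ROR_approx`) use RBEmax affine-increasing in
#' LETd/(alpha/beta)_x and RBEmin affine in sqrt((alpha/beta)_x)*LETd, with
#' coefficients loaded from a versioned JSON file (see [rbeModel()]).
#'
#' @slot kind one of `"constant_1p1"`, `"MCN"`, `"ROR_approx"`.
#' @slot alphaCoeffs numeric(2): RBEmax intercept and slope (per
#'   LETd/(alpha/beta)_x). Empty for `constant_1p1`.
#' @slot betaCoeffs numeric(2): RBEmin intercept and slope (per
#'   sqrt((alpha/beta)_x)*LETd). Empty for `constant_1p1`.
#' @slot provenance free-text description of the coefficient set.
#' @export
setClass("RbeModel",
  representation(kind = "character", alphaCoeffs = "numeric",
                 betaCoeffs = "numeric", provenance = "character"))

setValidity("RbeModel", function(object) {
  if (!object@kind %in% c("constant_1p1", "MCN", "ROR_approx"))
    return("unknown RBE model kind")
  if (object@kind != "constant_1p1" &&
      (length(object@alphaCoeffs) != 2L || length(object@betaCoeffs) != 2L))
    return("variable RBE models need 2 alpha and 2 beta coefficients")
  TRUE
})

## ---------------------------------------------------------------------------
## DoseSet: mixed-field physical dose description
## ---------------------------------------------------------------------------

#' Mixed-field physical dose description of a delivered field
#'
#' Bundles the grids entering the ROWD computation: total physical dose `D`
#' (protons plus secondary particles), proton physical dose `Dp`, and the
#' dose-averaged LET grid. The analytical engine transports primaries only,
#' so by default `D = Dp`; a constant `secondaryFraction` s produces
#' `D = Dp / (1 - s)` to exercise the mixed-field branch.
#'
#' @slot dTotal total physical dose grid, Gy.
#' @slot dProton proton physical dose grid, Gy.
#' @slot letd dose-averaged LET grid, keV/um.
#' @slot secondaryFraction fraction of total dose from secondaries, in
#'   `[0, 1)`.
#' @seealso [doseSet()], [computeRowd()]
#' @export
setClass("DoseSet",
  representation(dTotal = "VoxelGrid", dProton = "VoxelGrid",
                 letd = "VoxelGrid", secondaryFraction = "numeric"))

setValidity("DoseSet", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(dim(object@dTotal@values),
                        dim(object@dProton@values))) ||
      !isTRUE(all.equal(dim(object@dTotal@values), dim(object@letd@values))))
    msg <- c(msg, "dose and LET grids must share dimensions")
  if (length(object@secondaryFraction) != 1L ||
      object@secondaryFraction < 0 || object@secondaryFraction >= 1)
    msg <- c(msg, "'secondaryFraction' must lie in [0, 1)")
  if (any(object@dProton@values < 0))
    msg <- c(msg, "proton dose must be nonnegative")
  if (any(object@dProton@values > object@dTotal@values + 1e-9))
    msg <- c(msg, "proton dose cannot exceed total dose")
  if (length(msg)) msg else TRUE
})

#' Construct a DoseSet
#'
#' @param dProton proton physical dose [VoxelGrid-class], Gy.
#' @param letd dose-averaged LET [VoxelGrid-class], keV/um.
#' @param secondaryFraction constant secondary-particle dose fraction s;
#'   total dose is `dProton / (1 - s)`. Default 0.
#' @return A [DoseSet-class] object.
#' @export
doseSet <- function(dProton, letd, secondaryFraction = 0) {
  dTotal <- dProton
  dTotal@values <- dProton@values / (1 - secondaryFraction)
  new("DoseSet", dTotal = dTotal, dProton = dProton, letd = letd,
      secondaryFraction = secondaryFraction)
}

## ---------------------------------------------------------------------------
## Plan / InfluenceData
## ---------------------------------------------------------------------------

#' A pencil-beam treatment plan
#'
#' Spots are rows of a data frame with columns `field_id`, `range_mm`
#' (nominal range in water), `x_mm`, `y_mm` (lateral position in the beam
#' frame) and `weight` (nonnegative fluence units). Fields are axis-aligned
#' beam descriptions (see [beamField()]).
#'
#' @slot spots data.frame of spots.
#' @slot fields named list of field descriptions.
#' @slot prescription prescribed dose level, Gy(RBE).
#' @seealso [protonPlan()], [initSobpPlan()]
#' @export
setClass("ProtonPlan",
  representation(spots = "data.frame", fields = "list",
                 prescription = "numeric"))

setValidity("ProtonPlan", function(object) {
  need <- c("field_id", "range_mm", "x_mm", "y_mm", "weight")
  if (!all(need %in% names(object@spots)))
    return(paste("spot table must have columns:", paste(need, collapse = ", ")))
  if (any(object@spots$weight < 0)) return("spot weights must be >= 0")
  if (any(!object@spots$field_id %in% names(object@fields)))
    return("every spot must reference a declared field")
  if (length(object@prescription) != 1L || object@prescription <= 0)
    return("'prescription' must be a single positive dose, Gy(RBE)")
  TRUE
})

#' Construct a plan
#'
#' @param spots data.frame with columns `field_id`, `range_mm`, `x_mm`,
#'   `y_mm`, `weight`.
#' @param fields named list of fields from [beamField()].
#' @param prescription prescription level, Gy(RBE).
#' @return A [ProtonPlan-class] object.
#' @export
protonPlan <- function(spots, fields, prescription) {
  spots$field_id <- as.character(spots$field_id)
  new("ProtonPlan", spots = spots, fields = fields,
      prescription = prescription)
}

#' Describe an axis-aligned treatment field
#'
#' @param id field identifier.
#' @param direction beam direction, one of `"x+"`, `"x-"`, `"y+"`, `"y-"`,
#'   `"z+"`, `"z-"`; the beam enters at the corresponding grid face.
#' @param spotSpacing lateral spot lattice spacing, mm.
#' @param layerSpacing energy-layer spacing expressed as range step, mm.
#' @return A list with class `"beamFieldSpec"`.
#' @export
beamField <- function(id, direction = "z+", spotSpacing = 5,
                      layerSpacing = 4) {
  if (!direction %in% c("x+", "x-", "y+", "y-", "z+", "z-"))
    stop("'direction' must be one of x+/x-/y+/y-/z+/z-")
  if (spotSpacing <= 0 || layerSpacing <= 0)
    stop("spot and layer spacings must be positive")
  structure(list(id = as.character(id), direction = direction,
                 spotSpacing = spotSpacing, layerSpacing = layerSpacing),
            class = "beamFieldSpec")
}

#' Per-spot, per-voxel influence data
#'
#' Sparse matrices of per-unit-weight contributions: `dose` holds d_ij (Gy
#' per unit weight of spot j in voxel i) and `letDose` holds n_ij =
#' L_ij * d_ij (keV/um * Gy per unit weight). The sparsity pattern of
#' `letDose` is contained in that of `dose`. Voxels are stored in array
#' linear order of the grid the influence was computed on.
#'
#' @slot dose sparse dgCMatrix, voxels x spots.
#' @slot letDose sparse dgCMatrix, voxels x spots.
#' @slot gridDims integer(3) voxel counts of the underlying grid.
#' @seealso [buildInfluence()], [letdFromInfluence()]
#' @export
setClass("InfluenceData",
  representation(dose = "Matrix", letDose = "Matrix", gridDims = "integer"))

setValidity("InfluenceData", function(object) {
  msg <- character()
  if (!identical(dim(object@dose), dim(object@letDose)))
    msg <- c(msg, "'dose' and 'letDose' must have identical shape")
  if (length(object@gridDims) != 3L || prod(object@gridDims) != nrow(object@dose))
    msg <- c(msg, "'gridDims' must multiply to the number of voxel rows")
  if (length(object@dose@x) && min(object@dose@x) < 0)
    msg <- c(msg, "influence dose entries must be nonnegative")
  if (length(object@letDose@x) && min(object@letDose@x) < 0)
    msg <- c(msg, "influence LET-dose entries must be nonnegative")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Objective / OptimizerConfig
## ---------------------------------------------------------------------------

#' An optimization objective
#'
#' Either the (single) uniform target objective, penalizing squared
#' deviation of ROWD from `level` over the mask, or a one-sided maximum
#' constraint penalizing ROWD above `level`.
#'
#' @slot mask logical 3-D array selecting the structure's voxels.
#' @slot kind `"uniform_target"` or `"max_constraint"`.
#' @slot level objective dose level, Gy(RBE).
#' @slot penaltyWeight nonnegative weight of constraint objectives.
#' @seealso [objective()], [planCost()]
#' @export
setClass("Objective",
  representation(mask = "array", kind = "character", level = "numeric",
                 penaltyWeight = "numeric"))

setValidity("Objective", function(object) {
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    return("'mask' must be a logical 3-D array")
  if (!object@kind %in% c("uniform_target", "max_constraint"))
    return("'kind' must be uniform_target or max_constraint")
  if (length(object@level) != 1L || object@level <= 0)
    return("'level' must be a single positive dose")
  if (object@penaltyWeight < 0) return("'penaltyWeight' must be >= 0")
  TRUE
})

#' Construct an objective
#'
#' @param mask logical 3-D array, or a [VoxelGrid-class] mask of 0/1 values.
#' @param kind `"uniform_target"` or `"max_constraint"`.
#' @param level dose level, Gy(RBE).
#' @param penaltyWeight weight of a constraint term (ignored for the target
#'   objective). Default 1.
#' @return An [Objective-class] object.
#' @export
objective <- function(mask, kind = c("uniform_target", "max_constraint"),
                      level, penaltyWeight = 1) {
  kind <- match.arg(kind)
  if (is(mask, "VoxelGrid")) mask <- mask@values != 0
  new("Objective", mask = mask, kind = kind, level = level,
      penaltyWeight = penaltyWeight)
}

#' Optimizer loop controls
#'
#' @slot method `"dose_difference"` (default) for the multiplicative
#'   dose-difference update, or `"gradient"` for plain projected gradient
#'   descent with backtracking on the same cost.
#' @slot maxIters maximum number of weight updates.
#' @slot relTol relative cost-change stopping tolerance.
#' @slot damping exponent in (0, 1] applied to the multiplicative update.
#' @slot minWeight weight floor (>= 0).
#' @slot letRefreshEvery iterations between re-evaluations of LETd and the
#'   radiobiological parameters (dose itself is refreshed every iteration).
#' @slot seed integer seed recorded with the run; the optimizer itself is
#'   deterministic.
#' @seealso [optimizerConfig()], [optimizePlan()]
#' @export
setClass("OptimizerConfig",
  representation(method = "character", maxIters = "integer",
                 relTol = "numeric", damping = "numeric",
                 minWeight = "numeric", letRefreshEvery = "integer",
                 seed = "integer"))

setValidity("OptimizerConfig", function(object) {
  if (!object@method %in% c("dose_difference", "gradient"))
    return("'method' must be dose_difference or gradient")
  if (object@maxIters < 1L) return("'maxIters' must be >= 1")
  if (object@relTol <= 0) return("'relTol' must be > 0")
  if (object@damping <= 0 || object@damping > 1)
    return("'damping' must lie in (0, 1]")
  if (object@minWeight < 0) return("'minWeight' must be >= 0")
  if (object@letRefreshEvery < 1L) return("'letRefreshEvery' must be >= 1")
  TRUE
})

#' Construct optimizer controls
#'
#' @param maxIters maximum iterations (default 200).
#' @param relTol relative cost-change stopping tolerance (default 1e-5).
#' @param damping update exponent in (0, 1] (default 0.7).
#' @param minWeight weight floor (default 0).
#' @param letRefreshEvery iterations between LETd/radiobiology refreshes
#'   (default 1, i.e. every iteration).
#' @param seed integer seed recorded with the run.
#' @param method `"dose_difference"` (default) or `"gradient"`.
#' @return An [OptimizerConfig-class] object.
#' @export
optimizerConfig <- function(maxIters = 200L, relTol = 1e-5, damping = 0.7,
                            minWeight = 0, letRefreshEvery = 1L,
                            seed = 1L,
                            method = c("dose_difference", "gradient")) {
  new("OptimizerConfig", method = match.arg(method),
      maxIters = as.integer(maxIters), relTol = relTol,
      damping = damping, minWeight = minWeight,
      letRefreshEvery = as.integer(letRefreshEvery), seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## PlanOptimization: optimizer output bundle
## ---------------------------------------------------------------------------

#' Result of a plan optimization
#'
#' @slot plan the optimized [ProtonPlan-class].
#' @slot log data.frame convergence log (iteration, cost, D50 of the target
#'   ROWD, maximum constraint violation).
#' @slot rowd final ROWD grid, Gy(RBE).
#' @slot dose final total physical dose grid, Gy.
#' @slot letd final dose-averaged LET grid, keV/um.
#' @seealso [optimizePlan()]
#' @export
setClass("PlanOptimization",
  representation(plan = "ProtonPlan", log = "data.frame", rowd = "VoxelGrid",
                 dose = "VoxelGrid", letd = "VoxelGrid"))

## ---------------------------------------------------------------------------
## CumulativeHistogram
## ---------------------------------------------------------------------------

#' Cumulative dose- or LET-volume histogram
#'
#' `volume[k]` is the fraction of structure voxels with value greater than
#' or equal to `edges[k]`; it starts at 1 at zero dose and is nonincreasing.
#'
#' @slot edges numeric bin edges (Gy or keV/um), increasing from 0.
#' @slot volume numeric volume fractions in `[0, 1]`, nonincreasing.
#' @seealso [dvh()], [doseAtVolume()]
#' @export
setClass("CumulativeHistogram",
  representation(edges = "numeric", volume = "numeric"))

setValidity("CumulativeHistogram", function(object) {
  if (length(object@edges) != length(object@volume))
    return("'edges' and 'volume' must have equal length")
  if (is.unsorted(object@edges)) return("'edges' must be increasing")
  if (any(diff(object@volume) > 1e-12)) return("'volume' must be nonincreasing")
  if (object@volume[1] != 1) return("'volume' must start at 1")
  TRUE
})

## ---------------------------------------------------------------------------
## PhantomSpec / SyntheticCaseSpec
## ---------------------------------------------------------------------------

#' Water phantom specification
#'
#' Describes the slabbed-oxygenation water phantom: a cubic target at a
#' given depth whose interior is divided into equal-thickness slabs along
#' the beam (z) axis, each slab with its own pO2 value, embedded in a
#' normoxic water background.
#'
#' @slot dims integer(3) voxel counts.
#' @slot spacing numeric(3) voxel size, mm.
#' @slot targetSize target cube edge length, mm.
#' @slot targetDepth depth of the proximal target face along +z, mm.
#' @slot slabPo2 numeric pO2 per slab (mmHg), proximal to distal; the slabs
#'   partition the target along the beam axis.
#' @slot backgroundPo2 pO2 outside the target, mmHg.
#' @seealso [phantomSpec()], [makeWaterPhantom()]
#' @export
setClass("PhantomSpec",
  representation(dims = "integer", spacing = "numeric",
                 targetSize = "numeric", targetDepth = "numeric",
                 slabPo2 = "numeric", backgroundPo2 = "numeric"))

setValidity("PhantomSpec", function(object) {
  if (any(object@spacing <= 0)) return("voxel spacing must be positive")
  if (length(object@slabPo2) < 1L) return("at least one slab is required")
  if (any(object@slabPo2 < 0 | object@slabPo2 > 160))
    return("slab pO2 values must lie in [0, 160] mmHg")
  if (object@targetSize <= 0 || object@targetDepth < 0)
    return("target size must be positive and depth nonnegative")
  TRUE
})

#' Construct a water phantom specification
#'
#' Defaults reproduce the slabbed phantom used throughout the package: a
#' 4x4x4 cm^3 target at 8 cm depth on a 2 mm grid, divided into seven
#' equal-thickness slabs along the beam axis carrying seven distinct
#' log-spaced pO2 values spanning 2.5 to 30 mmHg with the most hypoxic
#' slab centered in depth, in normoxic water.
#'
#' @param dims voxel counts (default `c(30, 30, 80)`, chosen so the target
#'   cross-section is an exact whole number of voxels).
#' @param spacing voxel size mm (default 2, isotropic).
#' @param targetSize target cube edge, mm (default 40).
#' @param targetDepth proximal target depth, mm (default 80).
#' @param slabPo2 per-slab pO2 values, mmHg, proximal to distal; the
#'   default is the seven log-spaced values `2.5 * 12^(k/6)` arranged so
#'   the minimum (2.5 mmHg) sits in the central slab.
#' @param backgroundPo2 background pO2, mmHg (default 160).
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(dims = c(30L, 30L, 80L), spacing = c(2, 2, 2),
                        targetSize = 40, targetDepth = 80,
                        slabPo2 = defaultSlabPo2(),
                        backgroundPo2 = 160) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("PhantomSpec", dims = as.integer(dims), spacing = as.numeric(spacing),
      targetSize = targetSize, targetDepth = targetDepth,
      slabPo2 = slabPo2, backgroundPo2 = backgroundPo2)
}

#' @rdname phantomSpec
#' @export
defaultSlabPo2 <- function() {
  v <- 2.5 * 12^((0:6) / 6)     # seven distinct values on [2.5, 30]
  v[c(7, 5, 3, 1, 2, 4, 6)]     # minimum centered, hypoxia graded inward
}

#' Synthetic patient-like pO2 case specification
#'
#' @slot seed integer RNG seed (mandatory for reproducibility).
#' @slot hypoxicFraction requested fraction of PTV voxels below 60 mmHg.
#' @slot correlationLength spatial smoothing length of the random field, mm.
#' @slot po2Range attainable pO2 range, mmHg.
#' @slot dims integer(3) voxel counts.
#' @slot spacing numeric(3) voxel size, mm.
#' @seealso [syntheticCaseSpec()], [makeSyntheticCase()]
#' @export
setClass("SyntheticCaseSpec",
  representation(seed = "integer", hypoxicFraction = "numeric",
                 correlationLength = "numeric", po2Range = "numeric",
                 dims = "integer", spacing = "numeric"))

setValidity("SyntheticCaseSpec", function(object) {
  if (length(object@seed) != 1L || is.na(object@seed))
    return("'seed' is mandatory")
  if (object@hypoxicFraction < 0 || object@hypoxicFraction > 1)
    return("'hypoxicFraction' must lie in [0, 1]")
  if (object@correlationLength <= 0)
    return("'correlationLength' must be positive")
  if (length(object@po2Range) != 2L || diff(object@po2Range) <= 0 ||
      any(object@po2Range < 0))
    return("'po2Range' must be an increasing nonnegative pair")
  TRUE
})

#' Construct a synthetic-case specification
#'
#' @param seed integer RNG seed.
#' @param hypoxicFraction requested fraction of PTV voxels below 60 mmHg.
#' @param correlationLength smoothing length, mm (default 10).
#' @param po2Range attainable pO2 range, mmHg (default `c(0, 160)`).
#' @param dims voxel counts (default `c(30, 30, 80)`).
#' @param spacing voxel size, mm (default 2, isotropic).
#' @return A [SyntheticCaseSpec-class] object.
#' @export
syntheticCaseSpec <- function(seed, hypoxicFraction,
                              correlationLength = 10,
                              po2Range = c(0, 160),
                              dims = c(30L, 30L, 80L), spacing = c(2, 2, 2)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("SyntheticCaseSpec", seed = as.integer(seed),
      hypoxicFraction = hypoxicFraction,
      correlationLength = correlationLength, po2Range = as.numeric(po2Range),
      dims = as.integer(dims), spacing = as.numeric(spacing))
}
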