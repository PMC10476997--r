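## Accessor generics, methods and show() methods.

#' @rdname VoxelGrid-class
#' @param object,x a [VoxelGrid-class] (or other package object).
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname VoxelGrid-class
#' @export
setMethod("gridValues", "VoxelGrid", function(x) x@values)

#' @rdname VoxelGrid-class
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname VoxelGrid-class
#' @export
setMethod("gridSpacing", "VoxelGrid", function(x) x@spacing)

#' @rdname VoxelGrid-class
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname VoxelGrid-class
#' @export
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)

#' @rdname VoxelGrid-class
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @rdname VoxelGrid-class
#' @export
setMethod("gridDims", "VoxelGrid", function(x) dim(x@values))

#' World coordinates of voxel centers along one axis
#'
#' @param x a [VoxelGrid-class].
#' @param axis 1, 2 or 3.
#' @return numeric vector of voxel-center coordinates, mm.
#' @export
axisCoords <- function(x, axis) {
  stopifnot(is(x, "VoxelGrid"), axis %in% 1:3)
  x@origin[axis] + (seq_len(dim(x@values)[axis]) - 1L) * x@spacing[axis]
}

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelGrid: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  cat(sprintf("  origin (mm): %s\n",
              paste(format(object@origin, digits = 4), collapse = ", ")))
  v <- range(object@values)
  cat(sprintf("  values: [%g, %g]\n", v[1], v[2]))
})

#' @rdname TissueParams-class
#' @param x a [TissueParams-class].
#' @export
setGeneric("alphaBetaRatio", function(x) standardGeneric("alphaBetaRatio"))

#' @rdname TissueParams-class
#' @export
setMethod("alphaBetaRatio", "TissueParams", function(x) x@alphaX / x@betaX)

setMethod("show", "TissueParams", function(object) {
  cat(sprintf(
    "TissueParams '%s': alphaX = %g 1/Gy, betaX = %g 1/Gy^2, (a/b)x = %g Gy\n",
    object@label, object@alphaX, object@betaX, alphaBetaRatio(object)))
})

setMethod("show", "OerModelParams", function(object) {
  cat("OER model parameters\n")
  cat(sprintf("  a1..a4: %g, %g, %g, %g; b1, b2: %g, %g\n", object@a1,
              object@a2, object@a3, object@a4, object@b1, object@b2))
  cat(sprintf("  K = %g mmHg, reference pA = %g mmHg, OER at %g%% survival\n",
              object@K, object@pA, 100 * object@survivalLevel))
  cat(sprintf("  normoxic at >= %g mmHg; beta convention '%s'; floor at 1: %s\n",
              object@normoxiaThreshold, object@betaConvention,
              object@clampFloorOne))
})

setMethod("show", "RbeModel", function(object) {
  cat(sprintf("RbeModel '%s'", object@kind))
  if (object@kind != "constant_1p1")
    cat(sprintf(": RBEmax = %g + %g * LETd/(a/b)x, RBEmin = %g + %g * sqrt((a/b)x)*LETd",
                object@alphaCoeffs[1], object@alphaCoeffs[2],
                object@betaCoeffs[1], object@betaCoeffs[2]))
  cat("\n")
  if (length(object@provenance) && nzchar(object@provenance))
    cat("  ", object@provenance, "\n", sep = "")
})

#' @rdname ProtonPlan-class
#' @param x a [ProtonPlan-class].
#' @export
setGeneric("planSpots", function(x) standardGeneric("planSpots"))

#' @rdname ProtonPlan-class
#' @export
setMethod("planSpots", "ProtonPlan", function(x) x@spots)

#' @rdname ProtonPlan-class
#' @export
setGeneric("planFields", function(x) standardGeneric("planFields"))

#' @rdname ProtonPlan-class
#' @export
setMethod("planFields", "ProtonPlan", function(x) x@fields)

#' @rdname ProtonPlan-class
#' @export
setGeneric("planPrescription", function(x) standardGeneric("planPrescription"))

#' @rdname ProtonPlan-class
#' @export
setMethod("planPrescription", "ProtonPlan", function(x) x@prescription)

#' @rdname ProtonPlan-class
#' @param value replacement spot weights, one per spot.
#' @export
setGeneric("spotWeights", function(x) standardGeneric("spotWeights"))

#' @rdname ProtonPlan-class
#' @export
setMethod("spotWeights", "ProtonPlan", function(x) x@spots$weight)

#' @rdname ProtonPlan-class
#' @export
setGeneric("spotWeights<-", function(x, value) standardGeneric("spotWeights<-"))

#' @rdname ProtonPlan-class
#' @export
setReplaceMethod("spotWeights", "ProtonPlan", function(x, value) {
  if (length(value) != nrow(x@spots))
    stop("need one weight per spot")
  if (any(value < 0)) stop("spot weights must be >= 0")
  x@spots$weight <- value
  validObject(x)
  x
})

setMethod("show", "ProtonPlan", function(object) {
  cat(sprintf("ProtonPlan: %d spots in %d field(s), prescription %g Gy(RBE)\n",
              nrow(object@spots), length(object@fields),
              object@prescription))
  for (f in object@fields)
    cat(sprintf("  field '%s': direction %s, spot spacing %g mm, layer spacing %g mm\n",
                f$id, f$direction, f$spotSpacing, f$layerSpacing))
})

#' @rdname InfluenceData-class
#' @param x an [InfluenceData-class].
#' @export
setGeneric("influenceDose", function(x) standardGeneric("influenceDose"))

#' @rdname InfluenceData-class
#' @export
setMethod("influenceDose", "InfluenceData", function(x) x@dose)

#' @rdname InfluenceData-class
#' @export
setGeneric("influenceLetDose", function(x) standardGeneric("influenceLetDose"))

#' @rdname InfluenceData-class
#' @export
setMethod("influenceLetDose", "InfluenceData", function(x) x@letDose)

setMethod("show", "InfluenceData", function(object) {
  cat(sprintf("InfluenceData: %d voxels x %d spots, %d nonzero dose entries\n",
              nrow(object@dose), ncol(object@dose),
              length(object@dose@x)))
})

#' @rdname PlanOptimization-class
#' @param x a [PlanOptimization-class].
#' @export
setGeneric("optimizedPlan", function(x) standardGeneric("optimizedPlan"))

#' @rdname PlanOptimization-class
#' @export
setMethod("optimizedPlan", "PlanOptimization", function(x) x@plan)

#' @rdname PlanOptimization-class
#' @export
setGeneric("convergenceLog", function(x) standardGeneric("convergenceLog"))

#' @rdname PlanOptimization-class
#' @export
setMethod("convergenceLog", "PlanOptimization", function(x) x@log)

#' @rdname PlanOptimization-class
#' @export
setGeneric("rowdGrid", function(x) standardGeneric("rowdGrid"))

#' @rdname PlanOptimization-class
#' @export
setMethod("rowdGrid", "PlanOptimization", function(x) x@rowd)

#' @rdname PlanOptimization-class
#' @export
setGeneric("doseGrid", function(x) standardGeneric("doseGrid"))

#' @rdname PlanOptimization-class
#' @export
setMethod("doseGrid", "PlanOptimization", function(x) x@dose)

#' @rdname PlanOptimization-class
#' @export
setGeneric("letdGrid", function(x) standardGeneric("letdGrid"))

#' @rdname PlanOptimization-class
#' @export
setMethod("letdGrid", "PlanOptimization", function(x) x@letd)

setMethod("show", "PlanOptimization", function(object) {
  n <- nrow(object@log)
  cat(sprintf("PlanOptimization: %d iterations, final cost %.3e\n",
              n, object@log$cost[n]))
  cat(sprintf("  target D50 = %.3f Gy(RBE), max constraint violation %.3f\n",
              object@log$d50_target[n], object@log$max_violation[n]))
})

#' @rdname CumulativeHistogram-class
#' @param x a [CumulativeHistogram-class].
#' @export
setGeneric("histEdges", function(x) standardGeneric("histEdges"))

#' @rdname CumulativeHistogram-class
#' @export
setMethod("histEdges", "CumulativeHistogram", function(x) x@edges)

#' @rdname CumulativeHistogram-class
#' @export
setGeneric("histVolume", function(x) standardGeneric("histVolume"))

#' @rdname CumulativeHistogram-class
#' @export
setMethod("histVolume", "CumulativeHistogram", function(x) x@volume)

setMethod("show", "CumulativeHistogram", function(object) {
  cat(sprintf("CumulativeHistogram: %d bins over [%g, %g]\n",
              length(object@edges), min(object@edges), max(object@edges)))
})
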