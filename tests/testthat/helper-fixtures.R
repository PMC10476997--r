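# Shared fixtures. The slabbed water phantom at full scale (the study
# geometry) is expensive to optimize, so the four plan variants are built
# lazily once per session and reused across test files.

.fixtureEnv <- new.env(parent = emptyenv())

# small slabbed phantom for fast unit tests: 24 mm target at 40 mm depth
smallPhantomSpec <- function(slabPo2 = defaultSlabPo2()) {
  phantomSpec(dims = c(16L, 16L, 50L), targetSize = 24, targetDepth = 40,
              slabPo2 = slabPo2)
}

# z-symmetric small phantom (target centered in depth) for opposing-field
# symmetry checks: grid 100 mm deep, target 24 mm at depth 38 mm
symmetricPhantomSpec <- function() {
  phantomSpec(dims = c(16L, 16L, 50L), targetSize = 24, targetDepth = 38)
}

smallPhantomCase <- function() {
  hit <- .fixtureEnv$small
  if (!is.null(hit)) return(hit)
  ph <- makeWaterPhantom(smallPhantomSpec())
  init <- initSobpPlan(ph$target, list(f1 = beamField("f1", "z+")), 2)
  res <- list(phantom = ph, init = init,
              objectives = list(objective(ph$target, "uniform_target", 2)))
  .fixtureEnv$small <- res
  res
}

# full-scale study phantom with single and opposing fields and the four
# optimized plan variants; built once
studyPhantomCase <- function() {
  hit <- .fixtureEnv$study
  if (!is.null(hit)) return(hit)
  ph <- makeWaterPhantom(phantomSpec())
  obj <- list(objective(ph$target, "uniform_target", 2))
  tis <- tissueParams()
  initS <- initSobpPlan(ph$target, list(f1 = beamField("f1", "z+")), 2)
  initO <- initSobpPlan(ph$target, list(f1 = beamField("f1", "z+"),
                                        f2 = beamField("f2", "z-")), 2)
  opt <- function(init, kind)
    optimizePlan(init$plan, init$influence, ph$po2, obj,
                 model = rbeModel(kind), tissue = tis, oerOn = TRUE)
  res <- list(
    phantom = ph, objectives = obj,
    refSingle = initS$fit, refOpposing = initO$fit,
    rbe11OerSingle = opt(initS, "constant_1p1"),
    rbe11OerOpposing = opt(initO, "constant_1p1"),
    rorOerSingle = opt(initS, "ROR_approx"),
    rorOerOpposing = opt(initO, "ROR_approx"))
  .fixtureEnv$study <- res
  res
}

# single-spot, single-voxel toy influence for closed-form optimizer checks
unitInfluence <- function(d = 0.5, letd = 4) {
  new("InfluenceData",
      dose = Matrix::sparseMatrix(i = 1L, j = 1L, x = d, dims = c(1L, 1L)),
      letDose = Matrix::sparseMatrix(i = 1L, j = 1L, x = letd * d,
                                     dims = c(1L, 1L)),
      gridDims = c(1L, 1L, 1L))
}

unitGrid <- function(value) voxelGrid(array(value, c(1, 1, 1)))

unitPlan <- function(weight = 1, prescription = 2) {
  protonPlan(data.frame(field_id = "f1", range_mm = 80, x_mm = 0, y_mm = 0,
                        weight = weight),
             list(f1 = beamField("f1", "z+")), prescription)
}

# an RBE model with RBEmax = RBEmin = 1: proton parameters equal photon
# parameters, so the ROWD collapses to the physical dose at OER = 1
identityRbeModel <- function() {
  new("RbeModel", kind = "MCN", alphaCoeffs = c(1, 0), betaCoeffs = c(1, 0),
      provenance = "identity (test)")
}
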