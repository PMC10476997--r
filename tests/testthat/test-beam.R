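test_that("pristine depth-dose has Bragg-curve morphology", {
  z <- seq(0, 110, by = 0.25)
  d <- depthDose(80, z)
  peak <- max(d)
  # peak within one 2 mm voxel of the nominal range
  expect_lt(abs(z[which.max(d)] - 80), 2)
  # distal falloff: < 1% of peak beyond the distal margin, and far beyond
  expect_lt(depthDose(80, 80 + beamConfig()$distalMargin), 0.01 * peak)
  expect_lt(depthDose(80, 120), 0.01 * peak)
  # entrance-to-peak ratio in the published pristine-curve band
  expect_gt(d[1] / peak, 0.2)
  expect_lt(d[1] / peak, 0.5)
  expect_error(depthDose(80, -1), "nonnegative")
  expect_error(depthDose(5, 10), "machine limits")
})

test_that("depth-LET curve rises monotonically into the distal band", {
  z <- seq(0, 88, by = 0.5)
  L <- depthLetd(80, z)
  expect_true(all(diff(L) >= 0))
  expect_gte(depthLetd(80, 0), 0)
  expect_lt(depthLetd(80, 5), depthLetd(80, 79))
  # distal-edge values within the configured calibration band
  distal <- depthLetd(80, 80 + c(2, 3, 4))
  expect_true(all(distal >= 8 & distal <= 15))
  # entrance on the 1-2 keV/um scale
  expect_lt(depthLetd(80, 0), 2)
})

test_that("influence is linear: zero plan and superposition", {
  grid <- voxelGrid(array(0, c(10, 10, 40)), spacing = 2,
                    origin = c(-9, -9, 1))
  fields <- list(f1 = beamField("f1", "z+"))
  mkPlan <- function(spots) protonPlan(spots, fields, 2)
  s1 <- data.frame(field_id = "f1", range_mm = 50, x_mm = 0, y_mm = 0,
                   weight = 1)
  s2 <- data.frame(field_id = "f1", range_mm = 40, x_mm = 4, y_mm = 0,
                   weight = 1)
  infBoth <- buildInfluence(mkPlan(rbind(s1, s2)), grid)
  inf1 <- buildInfluence(mkPlan(s1), grid)
  inf2 <- buildInfluence(mkPlan(s2), grid)
  # zero weights -> zero dose
  expect_equal(max(abs(influenceDose(infBoth) %*% c(0, 0))), 0)
  # dose of the 2-spot plan equals the sum of the single-spot doses
  both <- as.numeric(influenceDose(infBoth) %*% c(1, 1))
  apart <- as.numeric(influenceDose(inf1) %*% 1) +
    as.numeric(influenceDose(inf2) %*% 1)
  expect_equal(both, apart, tolerance = 1e-12)
  # integral dose scales linearly in a single spot weight
  expect_equal(sum(influenceDose(infBoth) %*% c(3, 1)),
               3 * sum(inf1@dose) + sum(inf2@dose), tolerance = 1e-10)
})

test_that("translating a spot by a voxel multiple translates its dose", {
  grid <- voxelGrid(array(0, c(12, 12, 40)), spacing = 2,
                    origin = c(-11, -11, 1))
  fields <- list(f1 = beamField("f1", "z+"))
  plan <- protonPlan(data.frame(field_id = "f1", range_mm = 50,
                                x_mm = c(-2, 2), y_mm = 0, weight = 1),
                     fields, 2)
  inf <- buildInfluence(plan, grid)
  a <- array(as.numeric(influenceDose(inf)[, 1]), c(12, 12, 40))
  b <- array(as.numeric(influenceDose(inf)[, 2]), c(12, 12, 40))
  # shift by 4 mm = 2 voxels along x; compare interior
  expect_equal(a[1:9, , ], b[3:11, , ], tolerance = 1e-10)
})

test_that("spots outside the grid contribute nothing", {
  grid <- voxelGrid(array(0, c(8, 8, 30)), spacing = 2, origin = c(-7, -7, 1))
  plan <- protonPlan(data.frame(field_id = "f1", range_mm = 40,
                                x_mm = 500, y_mm = 0, weight = 1),
                     list(f1 = beamField("f1", "z+")), 2)
  expect_message(inf <- buildInfluence(plan, grid), "contributing nothing")
  expect_equal(length(inf@dose@x), 0L)
})

test_that("initial SOBP plan flattens the constant-RBE dose", {
  cs <- smallPhantomCase()
  tm <- gridValues(cs$phantom$target) != 0
  expect_true(all(spotWeights(optimizedPlan(cs$init$fit)) >= 0))
  d <- gridValues(doseGrid(cs$init$fit))[tm]
  rbe <- 1.1 * d
  # D95 of the RBE-weighted dose within 5% of the 2 Gy(RBE) prescription
  expect_lt(abs(stats::quantile(rbe, 0.05, names = FALSE) - 2) / 2, 0.05)
  # physical-dose inhomogeneity (D5 - D95) / mean < 10%
  inhom <- (stats::quantile(d, 0.95, names = FALSE) -
              stats::quantile(d, 0.05, names = FALSE)) / mean(d)
  expect_lt(inhom, 0.10)
})

test_that("opposing fields on a depth-symmetric phantom get symmetric weights", {
  ph <- makeWaterPhantom(symmetricPhantomSpec())
  init <- initSobpPlan(ph$target, list(f1 = beamField("f1", "z+"),
                                       f2 = beamField("f2", "z-")), 2)
  sp <- planSpots(optimizedPlan(init$fit))
  w1 <- sum(sp$weight[sp$field_id == "f1"])
  w2 <- sum(sp$weight[sp$field_id == "f2"])
  expect_lt(abs(w1 - w2) / w1, 0.01)
})

test_that("a target thinner than one layer spacing is rejected", {
  thin <- voxelGrid(array(0, c(8, 8, 30)), spacing = 2, origin = c(-7, -7, 1))
  vals <- gridValues(thin)
  vals[3:6, 3:6, 10] <- 1   # 2 mm slab
  thin@values <- vals
  expect_error(initSobpPlan(thin, list(f1 = beamField("f1", "z+")), 2),
               "thinner")
})
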