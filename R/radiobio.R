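## Radiobiological models: OER, aerobic RBE parameters, hypoxic parameters.

#' LET- and pO2-dependent alpha of the OER model
#'
#' Evaluates the linear radiosensitivity parameter
#' `alpha(L, p) = ((a1 + a2*L)*p + (a3 + a4*L)*K) / (p + K)`,
#' a saturation form interpolating between the anoxic constants
#' (`a3 + a4*L` at p = 0) and the aerobic constants (`a1 + a2*L` as
#' p -> Inf) with half-saturation pressure `K`.
#'
#' @param letd dose-averaged LET, keV/um; nonnegative, vectorized.
#' @param po2 partial oxygen pressure, mmHg; nonnegative, vectorized.
#' @param params an [OerModelParams-class] object.
#' @return alpha in 1/Gy, recycled to the common length.
#' @examples
#' alphaOer(10, 0)  # anoxic limit: a3 + a4 * 10
#' @export
alphaOer <- function(letd, po2, params = oerParams()) {
  .checkLetPo2(letd, po2)
  ((params@a1 + params@a2 * letd) * po2 +
     (params@a3 + params@a4 * letd) * params@K) / (po2 + params@K)
}

#' pO2-dependent beta of the OER model
#'
#' Evaluates `(b1*p + b2*K) / (p + K)`. With `betaConvention = "linear"`
#' (the default) the expression is used directly as beta (1/Gy^2); with
#' `"sqrt"` the b-constants are read as sqrt(beta) and the expression is
#' squared.
#'
#' @param po2 partial oxygen pressure, mmHg; nonnegative, vectorized.
#' @param params an [OerModelParams-class] object.
#' @return beta in 1/Gy^2.
#' @examples
#' betaOer(0)      # anoxic limit: b2
#' betaOer(1e6)    # aerobic limit: ~b1
#' @export
betaOer <- function(po2, params = oerParams()) {
  if (any(po2 < 0)) stop("'po2' must be nonnegative")
  b <- (params@b1 * po2 + params@b2 * params@K) / (po2 + params@K)
  if (params@betaConvention == "sqrt") b^2 else b
}

#' Oxygen enhancement ratio
#'
#' The OER at LET `letd` and oxygen pressure `po2` is the ratio of doses at
#' the model's survival level (default 10%) between pressure `po2` and the
#' aerobic reference pressure `pA`:
#' `OER = D10(letd, po2) / D10(letd, pA)` with
#' `D10 = (sqrt(alpha^2 - 4 beta ln s) - alpha) / (2 beta)`, which equals
#' the closed form
#' `[sqrt(a_h^2 - 4 b_h ln s) - a_h] / [sqrt(a_a^2 - 4 b_a ln s) - a_a] *
#'  b_a / b_h` where subscripts denote evaluation at `po2` and `pA`.
#' Pressures at or above the normoxia threshold (60 mmHg by default) return
#' exactly 1, and with `clampFloorOne` the result is floored at 1
#' everywhere (raw values between `pA` and the threshold fall marginally
#' below 1).
#'
#' @param letd dose-averaged LET, keV/um; nonnegative, vectorized.
#' @param po2 partial oxygen pressure, mmHg; nonnegative, vectorized.
#' @param params an [OerModelParams-class] object.
#' @return dimensionless OER, recycled to the common length.
#' @examples
#' oer(2, 2.5)                    # severely hypoxic
#' oer(5, 30)                     # reference pressure: exactly 1
#' oer(0, 120)                    # normoxic rule: exactly 1
#' @export
oer <- function(letd, po2, params = oerParams()) {
  .checkLetPo2(letd, po2)
  n <- max(length(letd), length(po2))
  letd <- rep_len(letd, n)
  po2 <- rep_len(po2, n)
  lnS <- log(params@survivalLevel)
  d10 <- function(a, b) (sqrt(a^2 - 4 * b * lnS) - a) / (2 * b)
  res <- d10(alphaOer(letd, po2, params), betaOer(po2, params)) /
    d10(alphaOer(letd, params@pA, params), betaOer(params@pA, params))
  res[po2 >= params@normoxiaThreshold] <- 1
  if (params@clampFloorOne) res <- pmax(res, 1)
  res
}

.checkLetPo2 <- function(letd, po2) {
  if (any(letd < 0)) stop("'letd' must be nonnegative")
  if (any(po2 < 0)) stop("'po2' must be nonnegative")
  invisible(TRUE)
}

#' Load an RBE model specification
#'
#' For the variable models the RBEmax/RBEmin coefficients are read from a
#' versioned JSON coefficient file (the packaged default ships the
#' published McNamara linear-in-LETd fit and a dose-averaged-LET
#' approximation of the Rorvik model with unscaled beta). The constant
#' model needs no coefficients.
#'
#' @param kind `"constant_1p1"`, `"MCN"` or `"ROR_approx"`.
#' @param coefficientFile path to a coefficient JSON; defaults to the file
#'   shipped with the package.
#' @return An [RbeModel-class] object.
#' @examples
#' rbeModel("MCN")
#' @export
rbeModel <- function(kind = c("constant_1p1", "MCN", "ROR_approx"),
                     coefficientFile = NULL) {
  kind <- match.arg(kind)
  if (kind == "constant_1p1")
    return(new("RbeModel", kind = kind, alphaCoeffs = numeric(),
               betaCoeffs = numeric(),
               provenance = "clinical constant RBE of 1.1"))
  if (is.null(coefficientFile))
    coefficientFile <- system.file("extdata", "rbe_coefficients.json",
                                   package = "rowdplan", mustWork = TRUE)
  spec <- jsonlite::fromJSON(coefficientFile, simplifyVector = TRUE)
  key <- sub("_approx$", "", kind)
  if (is.null(spec$models[[key]]))
    stop("configuration error: no coefficient set for model '", kind,
         "' in ", coefficientFile)
  m <- spec$models[[key]]
  new("RbeModel", kind = kind,
      alphaCoeffs = c(m$alpha_coeffs$intercept, m$alpha_coeffs$slope),
      betaCoeffs = c(m$beta_coeffs$intercept, m$beta_coeffs$slope),
      provenance = as.character(m$provenance))
}

#' Aerobic proton radiosensitivity parameters for an RBE model
#'
#' Produces (alphaRBE, betaRBE) under full oxygenation. The constant model
#' gives `alphaRBE = 1.1 * alphaX` and `betaRBE = 1.1^2 * betaX`. The
#' variable models use
#' `alphaRBE = alphaX * RBEmax` with `RBEmax = c0 + c1 * LETd/(a/b)x`, and
#' `betaRBE = betaX * RBEmin^2` with `RBEmin = d0 + d1 * sqrt((a/b)x) *
#' LETd` (floored at 0).
#'
#' @param model an [RbeModel-class] object.
#' @param letd dose-averaged LET, keV/um; nonnegative, vectorized.
#' @param tissue a [TissueParams-class] object.
#' @return list with numeric components `alpha` (1/Gy) and `beta` (1/Gy^2),
#'   each the length of `letd`.
#' @examples
#' rbeParamsAerobic(rbeModel("constant_1p1"), 7, tissueParams())
#' @export
rbeParamsAerobic <- function(model, letd, tissue) {
  stopifnot(is(model, "RbeModel"), is(tissue, "TissueParams"))
  if (any(letd < 0)) stop("'letd' must be nonnegative")
  if (model@kind == "constant_1p1") {
    n <- length(letd)
    return(list(alpha = rep_len(1.1 * tissue@alphaX, n),
                beta = rep_len(1.1^2 * tissue@betaX, n)))
  }
  abx <- alphaBetaRatio(tissue)
  rbeMax <- model@alphaCoeffs[1] + model@alphaCoeffs[2] * letd / abx
  rbeMin <- pmax(0, model@betaCoeffs[1] +
                   model@betaCoeffs[2] * sqrt(abx) * letd)
  list(alpha = tissue@alphaX * rbeMax, beta = tissue@betaX * rbeMin^2)
}

#' Hypoxic proton radiosensitivity parameters
#'
#' Scales the aerobic RBE-model parameters by the OER:
#' `alphaH = alphaRBE / OER` and `betaH = betaRBE / OER^2`.
#'
#' @param alphaRbe aerobic alpha, 1/Gy.
#' @param betaRbe aerobic beta, 1/Gy^2.
#' @param oerValue OER value(s), > 0.
#' @return list with components `alpha` and `beta`.
#' @examples
#' hypoxicParams(0.11, 0.0121, 2)
#' @export
hypoxicParams <- function(alphaRbe, betaRbe, oerValue) {
  if (any(oerValue <= 0)) stop("'oerValue' must be positive")
  list(alpha = alphaRbe / oerValue, beta = betaRbe / oerValue^2)
}
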