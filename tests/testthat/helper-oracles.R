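# Independent straight-line re-implementations used as oracles. These
# deliberately repeat the model arithmetic rather than calling package
# internals.

oracleConsts <- list(a1 = 0.10, a2 = 0.0010, a3 = 0.010, a4 = 0.0100,
                     b1 = 0.765, b2 = 0.273, K = 3, pA = 30, s = 0.1)

oracleAlpha <- function(L, p, cs = oracleConsts) {
  ((cs$a1 + cs$a2 * L) * p + (cs$a3 + cs$a4 * L) * cs$K) / (p + cs$K)
}

oracleBeta <- function(p, convention = "sqrt", cs = oracleConsts) {
  b <- (cs$b1 * p + cs$b2 * cs$K) / (p + cs$K)
  if (convention == "sqrt") b * b else b
}

# dose at survival level s from the LQ closed form
oracleD10 <- function(a, b, s = 0.1) (sqrt(a^2 - 4 * b * log(s)) - a) / (2 * b)

oracleOer <- function(L, p, convention = "sqrt", cs = oracleConsts) {
  oracleD10(oracleAlpha(L, p, cs), oracleBeta(p, convention, cs), cs$s) /
    oracleD10(oracleAlpha(L, cs$pA, cs), oracleBeta(cs$pA, convention, cs),
              cs$s)
}

# photon-equivalent dose of a proton dose dp with hypoxic parameters
# (aH, bH), photon parameters (aX, bX) and total/proton ratio dt/dp
oracleRowdVox <- function(dp, dt, aH, bH, aX, bX) {
  if (dp == 0) return(0)
  k <- aX / (2 * bX)
  (dt / dp) * (sqrt(k^2 + (aH * dp + bH * dp^2) / bX) - k)
}

# plain bisection on [lo, hi] to a root of f, independent of any package
# solver
oracleBisect <- function(f, lo, hi, iters = 200) {
  flo <- f(lo)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# brute-force double-loop dose-averaged LET
oracleLetd <- function(w, dMat, nMat) {
  nVox <- nrow(dMat)
  out <- numeric(nVox)
  for (i in seq_len(nVox)) {
    num <- 0
    den <- 0
    for (j in seq_along(w)) {
      num <- num + w[j] * nMat[i, j]
      den <- den + w[j] * dMat[i, j]
    }
    out[i] <- if (den > 0) num / den else 0
  }
  out
}

# brute-force objective cost
oracleCost <- function(r, targetIdx, P, constraints = list()) {
  cost <- mean((r[targetIdx] - P)^2)
  for (cn in constraints) {
    v <- pmax(0, r[cn$idx] - cn$level)
    cost <- cost + cn$pw * mean(v^2)
  }
  cost
}
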