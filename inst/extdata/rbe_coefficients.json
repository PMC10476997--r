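{
  "schema": "rowdplan-rbe-coefficients/1",
  "note": "RBEmax = intercept + slope * LETd / (alpha/beta)x ; RBEmin = intercept + slope * sqrt((alpha/beta)x) * LETd, LETd in keV/um, (alpha/beta)x in Gy",
  "models": {
    "MCN": {
      "alpha_coeffs": { "intercept": 0.99064, "slope": 0.35605 },
      "beta_coeffs": { "intercept": 1.1012, "slope": -0.0038703 },
      "provenance": "McNamara phenomenological proton RBE fit (linear in dose-averaged LET), published cell-line library constants"
    },
    "ROR": {
      "alpha_coeffs": { "intercept": 1.0, "slope": 0.645 },
      "beta_coeffs": { "intercept": 1.0, "slope": 0.0 },
      "provenance": "Rorvik-family model reduced to dose-averaged LET (ROR_approx): RBEmax linear in LETd/(a/b)x, beta unscaled (RBEmin = 1); an approximation of the full LET-spectrum weighting"
    }
  }
}
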