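{
  "comment": "Second-order model of the bundled study, natural units (g/100 ml). Intercept follows the coefficient table (-0.1801), which reproduces the printed center-point prediction 1.698545; the regression-equation text prints the sign flipped.",
  "factors": ["yeast_extract", "dextrose", "starch", "ammonium_carbonate"],
  "units": "natural",
  "coefficients": {
    "(Intercept)": -0.1801,
    "yeast_extract": 2.8746,
    "dextrose": 0.4696,
    "starch": 1.35105,
    "ammonium_carbonate": -32.5579,
    "yeast_extract^2": 0.4879,
    "dextrose^2": -0.112,
    "starch^2": 0.01418,
    "ammonium_carbonate^2": -302.301,
    "yeast_extract:dextrose": -0.0125,
    "yeast_extract:starch": -1.95938,
    "yeast_extract:ammonium_carbonate": 48.37499,
    "dextrose:starch": -1.175,
    "dextrose:ammonium_carbonate": 65.4999,
    "starch:ammonium_carbonate": 16.0625
  }
}
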