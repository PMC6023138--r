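# shared fixtures: the four fitted survival-curve parameter pairs of the
# two-arm trial (X = capecitabine, XELOX = capecitabine + oxaliplatin)
x_pfs <- llogis_params(-3.0531, 2.1872)
x_os <- llogis_params(-3.2726, 1.4703)
xelox_pfs <- llogis_params(-3.9836, 1.6494)
xelox_os <- llogis_params(-4.5714, 1.4960)

# a config whose parameter ranges are all collapsed to the point value
# (degenerate distributions -> deterministic PSA)
degenerate_config <- function() {
  cfg <- default_config()
  cfg$parameters$low <- cfg$parameters$value
  cfg$parameters$high <- cfg$parameters$value
  validate_config(cfg)
}

# random valid log-logistic parameters for property-style loops
random_llogis <- function() {
  llogis_params(theta = stats::runif(1, -6, 1), kappa = stats::runif(1, 0.3, 3))
}
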