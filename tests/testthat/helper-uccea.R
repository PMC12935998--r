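# Shared fixtures: the two base-case configurations and their cohort
# traces (the N+GC build warns about the anticipated far-tail PFS/OS
# crossing, so builds are wrapped in suppressWarnings here).
CFG_US <- suppressWarnings(default_config("us"))
CFG_CN <- suppressWarnings(default_config("china"))
TRACES_US <- suppressWarnings(config_traces(CFG_US))
TRACES_CN <- suppressWarnings(config_traces(CFG_CN))

run_cea_quiet <- function(cfg, traces = NULL) {
  suppressWarnings(run_cea(cfg, traces = traces))
}

# Table 1 survival models
MODEL_EVP_PFS <- parametric_model("lognormal", c(meanlog = 2.6709, sdlog = 1.4649))
MODEL_EVP_OS  <- parametric_model("loglogistic", c(shape = 1.3124, scale = 32.1285))
MODEL_NGC_PFS <- parametric_model("gengamma", c(mu = 1.9794, sigma = 1.1635, Q = -0.6043))
MODEL_NGC_OS  <- parametric_model("lognormal", c(meanlog = 3.1474, sdlog = 1.2350))

# random in-domain parameter draws per family, for property loops
random_params <- function(family) {
  switch(family,
    exponential = c(rate = stats::runif(1, 0.01, 0.5)),
    weibull     = c(shape = stats::runif(1, 0.5, 3), scale = stats::runif(1, 5, 60)),
    gompertz    = c(shape = stats::runif(1, -0.05, 0.1), rate = stats::runif(1, 0.01, 0.2)),
    lognormal   = c(meanlog = stats::runif(1, 1, 4), sdlog = stats::runif(1, 0.3, 1.6)),
    loglogistic = c(shape = stats::runif(1, 0.8, 3), scale = stats::runif(1, 5, 60)),
    gengamma    = c(mu = stats::runif(1, 1, 4), sigma = stats::runif(1, 0.4, 1.5),
                    Q = stats::runif(1, -1, 1)))
}
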