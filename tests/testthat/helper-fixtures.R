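# Shared fixtures: short constructors for the models used throughout, and a
# small synthetic trial for reconstruction/fitting tests.

ll_model <- function(shape, rate) {
  surv_model("loglogistic", c(shape = shape, rate = rate))
}

ln_model <- function(meanlog, sdlog) {
  surv_model("lognormal", c(meanlog = meanlog, sdlog = sdlog))
}

# one representative, valid parameter set per family
family_examples <- function() {
  list(
    exponential = surv_model("exponential", c(rate = 0.02)),
    weibull = surv_model("weibull", c(shape = 1.3, scale = 60)),
    gamma = surv_model("gamma", c(shape = 2, rate = 0.03)),
    lognormal = ln_model(3.5, 1.0),
    gompertz = surv_model("gompertz", c(shape = 0.01, rate = 0.005)),
    loglogistic = ll_model(1.6742, 0.0095),
    gengamma = surv_model("gengamma", c(mu = 3.5, sigma = 0.9, Q = 0.5))
  )
}

# simulated censored sample from a model: administrative censoring at the
# given survival quantile (cens_q = 0.8 -> ~20% censored)
censored_sample <- function(model, n, cens_q = 0.8, seed = 42) {
  times <- sample_times(model, n, seed = seed)
  cens <- quantile_at(model, cens_q)
  pseudo_ipd(pmin(times, cens), as.integer(times <= cens))
}

# deterministic zero-cost regimen for accrual edge cases
free_regimen <- function(name = "free") {
  regimen(name, list(regimen_component("placebo", 0, "flat", 1, 21, 0,
                                       infusion_hours = 0, share = 1)))
}

zero_cost_econ <- function(...) {
  args <- list(ct_scan_cost = 0, follow_up_cost = 0, bsc_cost_per_cycle = 0,
               terminal_care_cost = 0, admin_first_hour = 0,
               admin_addl_hour = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(econ_inputs, args)
}
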