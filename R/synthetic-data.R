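# Synthetic trial machinery and built-in scenario fixtures.
#
# Everything the pipeline consumes can be generated here without any
# download: event/censoring times from known parametric truth, digitized KM
# coordinates with at-risk tables (emulating graph digitization), and the
# full published model-input configuration for each analysis scenario.

#' Known parametric truth for a synthetic two-arm trial
#'
#' Defaults emulate the source trial's conditions: 373 vs 184 patients,
#' roughly two years of uniform accrual inside a 160-week study window
#' (administrative censoring at window end minus entry time), weekly
#' digitization grid, at-risk tables every 13 weeks.
#'
#' @param os_tdxd,pfs_tdxd,os_chemo,pfs_chemo [surv_model()]s for each
#'   endpoint and arm (defaults: the full-cohort scenario models).
#' @param n_tdxd,n_chemo Patients per arm.
#' @param accrual_weeks Uniform accrual window (weeks).
#' @param study_weeks Total study duration (weeks); per-subject
#'   administrative censoring time is `study_weeks - entry`.
#' @param grid_step Digitization grid step (weeks).
#' @param at_risk_interval Spacing of the numbers-at-risk table (weeks).
#' @param seed Integer seed for all randomness downstream.
#' @return Object of class `trial_truth`.
#' @export
trial_truth <- function(os_tdxd = surv_model("loglogistic", c(shape = 1.6742, rate = 0.0095)),
                        pfs_tdxd = surv_model("lognormal", c(meanlog = 3.7343, sdlog = 1.1400)),
                        os_chemo = surv_model("loglogistic", c(shape = 1.7826, rate = 0.0136)),
                        pfs_chemo = surv_model("lognormal", c(meanlog = 3.0558, sdlog = 1.0395)),
                        n_tdxd = 373, n_chemo = 184,
                        accrual_weeks = 104, study_weeks = 160,
                        grid_step = 1, at_risk_interval = 13,
                        seed = 1L) {
  check_that(n_tdxd >= 10 && n_chemo >= 10, "need at least 10 patients per arm")
  check_that(grid_step > 0 && at_risk_interval > 0, "grids must be positive")
  check_that(accrual_weeks >= 0 && study_weeks > accrual_weeks,
             "study window must exceed the accrual window")
  structure(list(models = list(
    tdxd = list(os = os_tdxd, pfs = pfs_tdxd),
    chemo = list(os = os_chemo, pfs = pfs_chemo)),
    n = c(tdxd = n_tdxd, chemo = n_chemo),
    accrual_weeks = accrual_weeks, study_weeks = study_weeks,
    grid_step = grid_step, at_risk_interval = at_risk_interval,
    seed = as.integer(seed)), class = "trial_truth")
}

#' Simulate per-arm pseudo-IPD from known truth
#'
#' OS times are drawn from the arm's OS model; a latent progression time is
#' drawn independently from the PFS model and clamped so the PFS event time
#' is `min(progression, death)`. Censoring is administrative:
#' `study_weeks - entry`, entry uniform over the accrual window.
#'
#' @param truth A [trial_truth()].
#' @return Named list (`tdxd`, `chemo`), each with [pseudo_ipd()] elements
#'   `os` and `pfs`.
#' @export
simulate_trial <- function(truth) {
  check_that(inherits(truth, "trial_truth"), "need a trial_truth")
  with_local_seed(truth$seed, {
    out <- list()
    for (arm in names(truth$models)) {
      n <- truth$n[[arm]]
      entry <- stats::runif(n, 0, truth$accrual_weeks)
      cens <- pmax(truth$study_weeks - entry, 1e-3)
      t_os <- quantile_at(truth$models[[arm]]$os, stats::runif(n))
      t_prog <- quantile_at(truth$models[[arm]]$pfs, stats::runif(n))
      t_pfs <- pmin(t_prog, t_os)
      os_event <- as.integer(t_os <= cens)
      pfs_event <- as.integer(t_pfs <= cens)
      out[[arm]] <- list(
        os = pseudo_ipd(pmin(t_os, cens), os_event),
        pfs = pseudo_ipd(pmin(t_pfs, cens), pfs_event))
    }
    out
  })
}

#' Digitize a KM curve onto a grid (emulating a plot digitizer)
#'
#' Evaluates the product-limit estimate on a regular grid, optionally adds
#' uniform jitter (default +/- 0.002 survival, the typical magnitude of
#' plot-digitizer noise), and records exact at-risk counts at interval
#' boundaries.
#'
#' @param ipd A [pseudo_ipd()].
#' @param grid_step Grid spacing in weeks.
#' @param at_risk_interval Spacing of the at-risk table in weeks.
#' @param jitter Half-width of the uniform digitization noise (0 = exact).
#' @param seed Optional seed for the jitter.
#' @return A [digitized_curve()].
#' @export
digitize_km <- function(ipd, grid_step = 1, at_risk_interval = 13,
                        jitter = 0.002, seed = NULL) {
  ipd <- as_pseudo_ipd(ipd)
  km <- km_estimate(ipd)
  t_max <- max(ipd$time_weeks)
  grid <- seq(0, t_max, by = grid_step)
  s <- km_survival_at(km, grid)
  if (jitter > 0) {
    noise <- if (is.null(seed)) stats::runif(length(s), -jitter, jitter)
             else with_local_seed(seed, stats::runif(length(s), -jitter, jitter))
    s <- pmin(pmax(s + noise, 0), 1)
    s[1] <- 1
  }
  risk_t <- seq(0, t_max, by = at_risk_interval)
  n_risk <- vapply(risk_t, function(a) sum(ipd$time_weeks >= a - 1e-9), 0L)
  digitized_curve(points = data.frame(time_weeks = grid, survival = s),
                  at_risk = data.frame(time_weeks = risk_t, n_risk = n_risk),
                  total_events = sum(ipd$event))
}

# printed survival-model parameters per scenario (weekly time scale)
.scenario_models <- list(
  all = list(
    tdxd = list(os = list(family = "loglogistic", params = list(shape = 1.6742, rate = 0.0095)),
                pfs = list(family = "lognormal", params = list(meanlog = 3.7343, sdlog = 1.1400))),
    chemo = list(os = list(family = "loglogistic", params = list(shape = 1.7826, rate = 0.0136)),
                 pfs = list(family = "lognormal", params = list(meanlog = 3.0558, sdlog = 1.0395)))),
  hr_positive = list(
    tdxd = list(os = list(family = "loglogistic", params = list(shape = 1.79219, rate = 0.0093)),
                pfs = list(family = "lognormal", params = list(meanlog = 3.77703, sdlog = 1.12199))),
    chemo = list(os = list(family = "loglogistic", params = list(shape = 1.72949, rate = 0.0125)),
                 pfs = list(family = "lognormal", params = list(meanlog = 3.11192, sdlog = 1.04968)))),
  hr_negative = list(
    tdxd = list(os = list(family = "loglogistic", params = list(shape = 1.3437, rate = 0.0120)),
                pfs = list(family = "lognormal", params = list(meanlog = 3.48501, sdlog = 1.21098))),
    chemo = list(os = list(family = "lognormal", params = list(meanlog = 3.692111, sdlog = 0.837671)),
                 pfs = list(family = "lognormal", params = list(meanlog = 2.731798, sdlog = 0.889911))))
)

#' Default T-DXd regimen (5.4 mg/kg q3w IV)
#' @return A [regimen()].
#' @export
default_tdxd_regimen <- function() {
  regimen("trastuzumab_deruxtecan",
          list(regimen_component("trastuzumab_deruxtecan", dose = 5.4,
                                 dose_rule = "per_kg", n_admin_per_cycle = 1,
                                 cycle_length_days = 21, price_per_mg = 29.68,
                                 infusion_hours = 2, share = 1)),
          ae_cost_onetime = 4586, ae_disutility_onetime = 0.027)
}

#' Default physician's-choice chemotherapy basket
#'
#' Market shares are the trial's treatment distribution; dosing schedules are
#' package defaults for each agent (standard single-agent regimens), as the
#' shares but not the schedules are published. Capecitabine is oral (no
#' administration fee).
#' @return A [regimen()].
#' @export
default_chemo_regimen <- function() {
  regimen("chemotherapy", list(
    regimen_component("eribulin", 1.4, "per_m2", 2, 21, 1294, 2, 0.511),
    regimen_component("capecitabine", 1250, "per_m2", 28, 21, 0.0027, 0, 0.201),
    regimen_component("nab_paclitaxel", 100, "per_m2", 3, 28, 14.19, 2, 0.103),
    regimen_component("gemcitabine", 1000, "per_m2", 2, 21, 0.0199, 2, 0.103),
    regimen_component("paclitaxel", 80, "per_m2", 3, 21, 0.128, 2, 0.082)),
    ae_cost_onetime = 5896, ae_disutility_onetime = 0.023)
}

#' Built-in scenario configuration (published model inputs)
#'
#' Returns the complete pipeline configuration for one of the three analysis
#' cohorts, embedding the published survival-model parameters, 2021 USD unit
#' costs, utilities, sensitivity distributions and patient characteristics.
#'
#' @param scenario 1/`"all"` (full HER2-low cohort), 2/`"hr_positive"`
#'   (hormone-receptor-positive), or 3/`"hr_negative"`.
#' @param seed Seed stored in the config (flows to all stochastic analyses).
#' @return A validated `run_config`.
#' @examples
#' cfg <- scenario_config("all")
#' res <- run_base_case(cfg)
#' res$comparisons
#' @export
scenario_config <- function(scenario = c("all", "hr_positive", "hr_negative"),
                            seed = 1L) {
  if (is.numeric(scenario)) {
    check_that(scenario %in% 1:3, "scenario must be 1, 2, 3 or a label")
    scenario <- c("all", "hr_positive", "hr_negative")[scenario]
  }
  scenario <- match.arg(scenario)
  suppressMessages(as_run_config(list(
    scenario = scenario,
    seed = as.integer(seed),
    grid = list(cycle_length = 1, horizon = 520, discount_rate = 0.03),
    survival = .scenario_models[[scenario]],
    patient = list(body_surface_area = 1.82, body_weight = 74),
    econ = unclass(econ_inputs()),
    regimens = list(tdxd = unclass_regimen(default_tdxd_regimen()),
                    chemo = unclass_regimen(default_chemo_regimen())),
    wtp = c(50000, 100000),
    hr_pfs_tdxd = 1,
    param_specs = default_param_specs())))
}

#' Run the full synthetic pipeline end-to-end
#'
#' simulate -> digitize -> reconstruct -> fit -> partitioned survival ->
#' economics, entirely from known parametric truth. Used for validation: the
#' reconstructed-and-refitted analysis should recover the truth-model
#' economics.
#'
#' @param truth A [trial_truth()].
#' @param families Survival families to fit at the refit stage (default: the
#'   truth families plus Weibull as a competitor).
#' @param config Economic configuration to apply (default: full-cohort
#'   scenario inputs, survival replaced by the refitted models).
#' @return List: `fits` (per arm/endpoint ranked fits), `config_refit`,
#'   `base_case` (the [run_base_case()] result on refitted curves), and
#'   `curves`/`ipd` intermediates.
#' @export
run_synthetic_pipeline <- function(truth = trial_truth(),
                                   families = c("weibull", "lognormal", "loglogistic"),
                                   config = scenario_config("all")) {
  ipd_true <- simulate_trial(truth)
  curves <- list(); ipd_rec <- list(); fits <- list(); best <- list()
  for (arm in names(ipd_true)) {
    for (ep in c("os", "pfs")) {
      key <- paste(arm, ep, sep = "_")
      curves[[key]] <- digitize_km(ipd_true[[arm]][[ep]],
                                   grid_step = truth$grid_step,
                                   at_risk_interval = truth$at_risk_interval,
                                   jitter = 0.002, seed = truth$seed + 17L)
      ipd_rec[[key]] <- reconstruct_ipd(curves[[key]])
      fits[[key]] <- fit_all_families(ipd_rec[[key]], families = families,
                                      n_starts = 2L)
      best[[key]] <- fits[[key]][[1]]$model
    }
  }
  cfg <- config
  cfg$survival <- list(
    tdxd = list(os = model_to_spec(best$tdxd_os), pfs = model_to_spec(best$tdxd_pfs)),
    chemo = list(os = model_to_spec(best$chemo_os), pfs = model_to_spec(best$chemo_pfs)))
  cfg <- suppressMessages(as_run_config(unclass(cfg)))
  list(fits = fits, config_refit = cfg,
       base_case = run_base_case(cfg),
       curves = curves, ipd = ipd_rec)
}
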