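# Sensitivity machinery: one-way sweeps (tornado), probabilistic sensitivity
# analysis with CEAC, threshold price search, and hazard-ratio subgroups.
#
# Parameter uncertainty follows the published table: gamma for costs, beta
# for utilities/disutilities, normal for body measures, with gamma/beta
# hyperparameters moment-matched from mean and 95% CI (SE = (hi - lo)/3.92).
# Survival-model parameters are point estimates there (no distribution) and
# are held fixed in the PSA.

#' One uncertain parameter
#'
#' @param name Canonical parameter name (see [default_param_specs()]).
#' @param base Base-case value.
#' @param low,high One-way sweep bounds (95% CI where published, otherwise
#'   +/- 20%).
#' @param dist `"gamma"`, `"beta"`, `"normal"` or `"fixed"` (fixed parameters
#'   are swept one-way but never drawn in the PSA).
#' @return Object of class `param_spec`.
#' @export
param_spec <- function(name, base, low, high,
                       dist = c("gamma", "beta", "normal", "fixed")) {
  dist <- match.arg(dist)
  check_that(low <= base && base <= high, "'%s': need low <= base <= high", name)
  if (dist == "beta") {
    check_that(base >= 0 && high <= 1, "'%s': beta is for [0, 1] quantities", name)
  }
  structure(list(name = name, base = base, low = low, high = high, dist = dist),
            class = "param_spec")
}

#' Default uncertain-parameter table
#'
#' All published cost/utility/characteristic inputs with their 95% CIs, plus
#' a hazard-ratio multiplier on the T-DXd PFS curve swept +/- 20% (no CI is
#' published for it; it stays fixed in the PSA along with all survival
#' parameters).
#'
#' @return List of `param_spec`s (as plain lists, config-serializable).
#' @export
default_param_specs <- function() {
  tab <- list(
    list("price_trastuzumab_deruxtecan", 29.68, 23.74, 35.62, "gamma"),
    list("price_capecitabine", 0.0027, 0.0022, 0.0033, "gamma"),
    list("price_eribulin", 1294, 1035, 1552, "gamma"),
    list("price_gemcitabine", 0.0199, 0.0159, 0.0239, "gamma"),
    list("price_paclitaxel", 0.128, 0.102, 0.154, "gamma"),
    list("price_nab_paclitaxel", 14.19, 11.35, 17.02, "gamma"),
    list("terminal_care_cost", 20409, 16327, 24491, "gamma"),
    list("ct_scan_cost", 135, 58, 256, "gamma"),
    list("bsc_cost_per_cycle", 472, 377, 566, "gamma"),
    list("ae_cost_tdxd", 4586, 3669, 5503, "gamma"),
    list("ae_cost_chemo", 5896, 4717, 7076, "gamma"),
    list("admin_first_hour", 159, 130, 206, "gamma"),
    list("admin_addl_hour", 34, 28, 42, "gamma"),
    list("follow_up_cost", 251, 223, 318, "gamma"),
    list("utility_pf", 0.830, 0.664, 0.935, "beta"),
    list("utility_pd", 0.443, 0.354, 0.532, "beta"),
    list("ae_disutility_tdxd", 0.027, 0.022, 0.033, "beta"),
    list("ae_disutility_chemo", 0.023, 0.018, 0.028, "beta"),
    list("body_surface_area", 1.82, 1.44, 2.16, "normal"),
    list("body_weight", 74, 59, 90, "normal"),
    list("hr_pfs_tdxd", 1, 0.8, 1.2, "fixed"))
  lapply(tab, function(r) {
    unclass(param_spec(r[[1]], r[[2]], r[[3]], r[[4]], r[[5]]))
  })
}

#' Set one canonical parameter in a config
#'
#' Maps canonical sensitivity-parameter names onto the nested config fields:
#' `price_<drug>` to regimen components, `ae_cost_/ae_disutility_<arm>` to the
#' regimen, utilities/unit costs to the econ block, body measures to the
#' patient block, `hr_pfs_tdxd` and `discount_rate` to their own fields.
#'
#' @param config A `run_config`.
#' @param name Canonical parameter name.
#' @param value New value.
#' @return The modified config.
#' @export
set_config_param <- function(config, name, value) {
  check_that(is_number(value), "value for '%s' must be a single number", name)
  econ_fields <- c("utility_pf", "utility_pd", "ct_scan_cost", "follow_up_cost",
                   "scan_interval_weeks", "bsc_cost_per_cycle",
                   "terminal_care_cost", "admin_first_hour", "admin_addl_hour")
  if (name %in% econ_fields) {
    config$econ[[name]] <- value
  } else if (name %in% c("body_surface_area", "body_weight")) {
    config$patient[[name]] <- value
  } else if (name == "discount_rate") {
    config$grid$discount_rate <- value
  } else if (name == "hr_pfs_tdxd") {
    config$hr_pfs_tdxd <- value
  } else if (grepl("^price_", name)) {
    drug <- sub("^price_", "", name)
    found <- FALSE
    for (arm in names(config$regimens)) {
      for (i in seq_along(config$regimens[[arm]]$components)) {
        if (config$regimens[[arm]]$components[[i]]$drug == drug) {
          config$regimens[[arm]]$components[[i]]$price_per_mg <- value
          found <- TRUE
        }
      }
    }
    check_that(found, "no regimen component for drug '%s'", drug)
  } else if (grepl("^ae_(cost|disutility)_", name)) {
    arm <- sub("^ae_(cost|disutility)_", "", name)
    field <- if (grepl("^ae_cost_", name)) "ae_cost_onetime" else "ae_disutility_onetime"
    check_that(arm %in% names(config$regimens), "unknown arm '%s' in '%s'", arm, name)
    config$regimens[[arm]][[field]] <- value
  } else {
    stop(sprintf("unknown parameter name '%s'", name), call. = FALSE)
  }
  config
}

.icer_of <- function(config, wtp, traces = NULL) {
  pipe <- run_pipeline(config, traces = traces)
  compare_strategies(pipe$strategies$tdxd, pipe$strategies$chemo, wtp)$icer_per_qaly
}

#' One-way deterministic sensitivity sweep (tornado)
#'
#' Re-runs the full pipeline with each parameter at its low and high bound
#' (all others at base) and reports the ICER range, sorted by spread.
#' A sweep value that violates a type invariant flags the row (`flagged`,
#' with the message) instead of silently dropping it.
#'
#' @param config A `run_config`.
#' @param specs List of [param_spec()]s (default: the config's own).
#' @param wtp Threshold used for the reported ICER (informational; the ICER
#'   itself does not depend on it).
#' @return Data frame: `param`, `icer_low`, `icer_high`, `spread`, `flagged`,
#'   `note`, sorted by `spread` descending.
#' @export
one_way_sweep <- function(config, specs = NULL, wtp = 100000) {
  config <- as_run_config(config)
  if (is.null(specs)) specs <- config$param_specs
  base_icer <- .icer_of(config, wtp)
  check_that(is.finite(base_icer), "base case has no defined ICER")
  rows <- lapply(specs, function(sp) {
    one <- function(v) {
      tryCatch(list(icer = .icer_of(set_config_param(config, sp$name, v), wtp),
                    err = NA_character_),
               error = function(e) list(icer = NA_real_, err = conditionMessage(e)))
    }
    lo <- one(sp$low); hi <- one(sp$high)
    data.frame(param = sp$name, base = sp$base, low = sp$low, high = sp$high,
               icer_low = lo$icer, icer_high = hi$icer,
               spread = abs(hi$icer - lo$icer),
               flagged = is.na(lo$icer) || is.na(hi$icer),
               note = paste(stats::na.omit(c(lo$err, hi$err)), collapse = "; "))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread, out$param), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  out
}

#' Threshold price search
#'
#' Finds the per-mg price of a drug at which the base-case ICER equals the
#' willingness-to-pay threshold, by root bracketing to within $1/QALY.
#'
#' @param config A `run_config`.
#' @param wtp Target willingness-to-pay, USD/QALY.
#' @param price_bounds Search bracket for the per-mg price.
#' @param drug Drug whose price is varied (default T-DXd).
#' @return List of class `threshold_result`: `price` (USD/mg, `NA` when no
#'   crossing exists in the bracket), `icer_at_price`, `wtp`, `converged`.
#' @export
threshold_price <- function(config, wtp, price_bounds = c(0.01, 200),
                            drug = "trastuzumab_deruxtecan") {
  config <- as_run_config(config)
  check_that(is_number(wtp) && wtp > 0, "wtp must be > 0")
  traces <- pipeline_traces(config)
  f <- function(p) .icer_of(set_config_param(config, paste0("price_", drug), p),
                            wtp, traces = traces) - wtp
  f_lo <- f(price_bounds[1]); f_hi <- f(price_bounds[2])
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo * f_hi > 0) {
    return(structure(list(price = NA_real_, icer_at_price = NA_real_,
                          wtp = wtp, converged = FALSE,
                          note = "ICER does not cross the threshold inside the price bounds"),
                     class = "threshold_result"))
  }
  root <- stats::uniroot(f, price_bounds, tol = 1e-7)
  icer <- root$f.root + wtp
  structure(list(price = root$root, icer_at_price = icer, wtp = wtp,
                 converged = abs(icer - wtp) <= 1, note = "ok"),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (is.na(x$price)) {
    cat(sprintf("<threshold_result> no solution: %s\n", x$note))
  } else {
    cat(sprintf("<threshold_result> price $%.4f/mg gives ICER $%.2f/QALY (target $%s)\n",
                x$price, x$icer_at_price, format(x$wtp, big.mark = ",")))
  }
  invisible(x)
}

# moment-matched distribution draws; SE from the 95% CI width
.draw_param <- function(sp, n) {
  se <- (sp$high - sp$low) / 3.92
  if (sp$dist == "fixed" || se <= 0) return(rep(sp$base, n))
  m <- sp$base
  switch(sp$dist,
    gamma = stats::rgamma(n, shape = (m / se)^2, rate = m / se^2),
    beta = {
      v <- se^2
      check_that(v < m * (1 - m), "'%s': CI too wide for a beta distribution", sp$name)
      a <- m * (m * (1 - m) / v - 1)
      stats::rbeta(n, a, a * (1 - m) / m)
    },
    normal = stats::rnorm(n, m, se))
}

#' Probabilistic sensitivity analysis
#'
#' Draws every non-fixed parameter from its assigned distribution
#' (moment-matched to mean and 95% CI), re-runs the cost/QALY accrual for
#' both arms each iteration, and records incremental cost and effect.
#' Survival parameters are fixed, so the state traces are computed once.
#' Negative draws for positive-support normal parameters are redrawn (count
#' reported in the `redraws` attribute).
#'
#' @param config A `run_config`.
#' @param n_iter Number of Monte Carlo iterations (the published analysis
#'   uses 10,000).
#' @param seed Integer seed (default: the config's).
#' @return Data frame of class `psa_samples`: `iter`, `delta_cost`,
#'   `delta_effect`; attributes `base` (deterministic comparison) and
#'   `redraws`.
#' @export
sample_psa <- function(config, n_iter = 10000, seed = NULL) {
  config <- as_run_config(config)
  check_that(is_number(n_iter) && n_iter >= 1, "n_iter must be >= 1")
  if (is.null(seed)) seed <- config$seed
  specs <- config$param_specs
  traces <- pipeline_traces(config)
  grid <- do.call(time_grid, config$grid)

  redraws <- 0L
  draws <- with_local_seed(seed, {
    m <- lapply(specs, function(sp) {
      x <- .draw_param(sp, n_iter)
      if (sp$dist == "normal" && sp$base > 0) {
        bad <- which(x <= 0)
        while (length(bad)) {
          redraws <<- redraws + length(bad)
          x[bad] <- .draw_param(sp, length(bad))
          bad <- which(x[bad] <= 0)
        }
      }
      x
    })
    names(m) <- vapply(specs, `[[`, "", "name")
    m
  })
  if (redraws > 0) message(sprintf("PSA: %d out-of-support draws redrawn", redraws))

  dc <- de <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    cfg_i <- config
    for (nm in names(draws)) {
      if (specs[[match(nm, names(draws))]]$dist != "fixed") {
        cfg_i <- set_config_param(cfg_i, nm, draws[[nm]][i])
      }
    }
    econ_i <- do.call(econ_inputs, cfg_i$econ)
    pt_i <- do.call(patient, cfg_i$patient)
    regs_i <- lapply(cfg_i$regimens, regimen_from_spec)
    a <- accrue_strategy(traces$tdxd, regs_i$tdxd, econ_i, pt_i)
    b <- accrue_strategy(traces$chemo, regs_i$chemo, econ_i, pt_i)
    dc[i] <- a$cost_total - b$cost_total
    de[i] <- a$qaly - b$qaly
  }
  base_pipe <- run_pipeline(config, traces = traces)
  out <- data.frame(iter = seq_len(n_iter), delta_cost = dc, delta_effect = de)
  structure(out, class = c("psa_samples", "data.frame"),
            base = compare_strategies(base_pipe$strategies$tdxd,
                                      base_pipe$strategies$chemo,
                                      config$wtp[length(config$wtp)]),
            redraws = redraws)
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the intervention is cost-effective at each
#' willingness-to-pay value: the fraction of PSA iterations with positive
#' incremental net monetary benefit `dE * lambda - dC > 0`.
#'
#' @param samples PSA samples from [sample_psa()] (or any data frame with
#'   `delta_cost`, `delta_effect`).
#' @param wtp_grid Thresholds to evaluate (default $0-200,000 by $2,000).
#' @return Data frame `wtp`, `probability`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 200000, by = 2000)) {
  check_that(is.data.frame(samples) && nrow(samples) > 0 &&
               all(c("delta_cost", "delta_effect") %in% names(samples)),
             "samples must contain delta_cost and delta_effect")
  prob <- vapply(wtp_grid, function(l)
    mean(samples$delta_effect * l - samples$delta_cost > 0), 0)
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Proportional-hazards transform of a survival curve
#'
#' Returns a curve with `S'(t) = S(t)^hr`, evaluable with [survival_at()]
#' and sampleable with [sample_times()] (used to derive subgroup PFS curves
#' from the comparator curve).
#'
#' @param model A survival model.
#' @param hr Hazard ratio (> 0).
#' @return Object of class `ph_model`.
#' @export
apply_hazard_ratio <- function(model, hr) {
  check_that(is_number(hr) && hr > 0, "hr must be > 0")
  structure(list(base = model, hr = hr), class = "ph_model")
}

#' @export
survival_at.ph_model <- function(model, t) {
  survival_at(model$base, t)^model$hr
}

#' @export
quantile_at.ph_model <- function(model, p) {
  # S'(t) = u  <=>  S(t) = u^(1/hr)
  quantile_at(model$base, 1 - (1 - p)^(1 / model$hr))
}

#' Published subgroup hazard ratios for PFS
#'
#' The trial's unstratified T-DXd-vs-chemotherapy PFS hazard ratios by
#' subgroup, with 95% CIs.
#'
#' @return Data frame `label`, `hr`, `hr_low`, `hr_high`.
#' @export
subgroup_specs <- function() {
  utils::read.csv(text = "label,hr,hr_low,hr_high
prior_cdk46i_yes,0.55,0.42,0.73
prior_cdk46i_no,0.42,0.28,0.64
ihc_1plus,0.48,0.35,0.64
ihc_2plus_ish_neg,0.55,0.38,0.80
prior_chemo_lines_1,0.54,0.40,0.73
prior_chemo_lines_ge2,0.47,0.33,0.68
age_lt_65,0.51,0.39,0.67
age_ge_65,0.47,0.29,0.77
race_white,0.64,0.44,0.91
race_asian,0.40,0.28,0.56
race_other,0.83,0.41,1.69
region_asia,0.41,0.28,0.58
region_europe_israel,0.62,0.43,0.89
region_north_america,0.54,0.30,0.97
ecog_0,0.56,0.40,0.77
ecog_1,0.45,0.32,0.64
visceral_disease_yes,0.54,0.42,0.69
visceral_disease_no,0.23,0.09,0.55", stringsAsFactors = FALSE)
}

#' Hazard-ratio subgroup analysis
#'
#' Replaces the T-DXd PFS curve by the proportional-hazards transform of the
#' comparator (chemotherapy) PFS curve at the subgroup's hazard ratio, leaves
#' both OS curves unchanged, and re-runs the pipeline.
#'
#' @param config A `run_config`.
#' @param hr PFS hazard ratio (T-DXd vs chemotherapy).
#' @param label Subgroup label for the output row.
#' @param wtp Threshold for the net-benefit columns.
#' @return One-row data frame: `label`, `hr`, `delta_cost`, `delta_qaly`,
#'   `icer`, `inhb`, `inmb`.
#' @export
subgroup_analysis <- function(config, hr, label = "subgroup", wtp = 100000) {
  config <- as_run_config(config)
  chemo_pfs <- model_from_spec(config$survival$chemo$pfs)
  config$survival$tdxd$pfs <- apply_hazard_ratio(chemo_pfs, hr)
  pipe <- run_pipeline(config)
  cc <- compare_strategies(pipe$strategies$tdxd, pipe$strategies$chemo, wtp)
  data.frame(label = label, hr = hr,
             delta_cost = cc$delta_cost, delta_qaly = cc$delta_effect,
             icer = cc$icer_per_qaly, inhb = cc$inhb, inmb = cc$inmb)
}

#' Run all published subgroups
#'
#' @param config A `run_config` (typically the hormone-receptor-positive
#'   scenario, whose cohort the subgroups refine).
#' @param specs Data frame like [subgroup_specs()].
#' @param wtp Net-benefit threshold.
#' @return Data frame with one [subgroup_analysis()] row per subgroup.
#' @export
subgroup_table <- function(config, specs = subgroup_specs(), wtp = 100000) {
  do.call(rbind, lapply(seq_len(nrow(specs)), function(i)
    subgroup_analysis(config, specs$hr[i], specs$label[i], wtp)))
}
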