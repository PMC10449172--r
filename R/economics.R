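# Cost and QALY accrual over a state trace, and incremental comparison.
#
# Accrual rules (all flows discounted with the trace's per-cycle weights):
#  - drug + administration: accrue while progression-free (treat-to-
#    progression, no maximum-cycles cap), prorated per week from each
#    component's dosing cycle;
#  - CT monitoring + follow-up fee: discrete events on a fixed schedule
#    (default every 6 weeks) while alive;
#  - best supportive care: per model cycle while progressed;
#  - adverse-event cost and disutility: one-time at model entry;
#  - terminal care: one-time at death, weighted by the per-cycle increment of
#    the dead state.
# Life-years are reported undiscounted; QALYs discounted.

#' Patient characteristics used for dosing
#'
#' @param body_surface_area Body surface area in m2 (default 1.82).
#' @param body_weight Weight in kg (default 74).
#' @return Object of class `patient`.
#' @export
patient <- function(body_surface_area = 1.82, body_weight = 74) {
  check_that(is_number(body_surface_area) && body_surface_area > 0, "BSA must be > 0")
  check_that(is_number(body_weight) && body_weight > 0, "weight must be > 0")
  structure(list(body_surface_area = body_surface_area,
                 body_weight = body_weight), class = "patient")
}

#' One drug component of a regimen
#'
#' @param drug Drug name.
#' @param dose Dose per administration in mg per unit of `dose_rule`.
#' @param dose_rule `"per_kg"`, `"per_m2"` or `"flat"` (mg as given).
#' @param n_admin_per_cycle Administrations per dosing cycle.
#' @param cycle_length_days Dosing cycle length in days (21-day cycles for
#'   most agents here).
#' @param price_per_mg Price in USD per mg.
#' @param infusion_hours Infusion chair time in hours; 0 marks an oral drug
#'   (no administration fee). An IV component incurs the first-hour fee plus
#'   additional-hour fees for time beyond one hour.
#' @param share Market-share weight within a basket (shares of a regimen's
#'   components must sum to 1 across drugs; a single-drug regimen uses 1).
#' @return Object of class `regimen_component`.
#' @export
regimen_component <- function(drug, dose, dose_rule = c("per_kg", "per_m2", "flat"),
                              n_admin_per_cycle, cycle_length_days,
                              price_per_mg, infusion_hours = 2, share = 1) {
  dose_rule <- match.arg(dose_rule)
  for (v in list(dose, n_admin_per_cycle, cycle_length_days, price_per_mg,
                 infusion_hours, share)) {
    check_that(is_number(v) && v >= 0, "component '%s': numeric fields must be >= 0", drug)
  }
  check_that(cycle_length_days > 0, "component '%s': cycle length must be > 0", drug)
  structure(list(drug = drug, dose = dose, dose_rule = dose_rule,
                 n_admin_per_cycle = n_admin_per_cycle,
                 cycle_length_days = cycle_length_days,
                 price_per_mg = price_per_mg,
                 infusion_hours = infusion_hours, share = share),
            class = "regimen_component")
}

#' Treatment regimen (single drug or market-share basket)
#'
#' @param name Regimen label.
#' @param components List of [regimen_component()]s; shares must sum to 1.
#' @param ae_cost_onetime Aggregate grade >= 3 adverse-event management cost,
#'   USD, applied once at model entry.
#' @param ae_disutility_onetime Aggregate adverse-event disutility (QALY),
#'   applied once at model entry.
#' @return Object of class `regimen`.
#' @export
regimen <- function(name, components, ae_cost_onetime = 0,
                    ae_disutility_onetime = 0) {
  check_that(length(components) >= 1 &&
               all(vapply(components, inherits, TRUE, "regimen_component")),
             "components must be regimen_component objects")
  shares <- vapply(components, function(x) x$share, 0)
  check_that(abs(sum(shares) - 1) < 1e-6,
             "market shares of regimen '%s' must sum to 1 (got %.4f)", name, sum(shares))
  check_that(is_number(ae_cost_onetime) && ae_cost_onetime >= 0, "AE cost must be >= 0")
  check_that(is_number(ae_disutility_onetime) && ae_disutility_onetime >= 0,
             "AE disutility must be >= 0")
  structure(list(name = name, components = components,
                 ae_cost_onetime = ae_cost_onetime,
                 ae_disutility_onetime = ae_disutility_onetime),
            class = "regimen")
}

#' Cost, utility and schedule inputs
#'
#' Defaults are the published 2021 USD inputs of the analysis.
#'
#' @param utility_pf Utility per year in the progression-free state.
#' @param utility_pd Utility per year after progression.
#' @param ct_scan_cost USD per CT scan.
#' @param follow_up_cost USD physician follow-up fee per monitoring event.
#' @param scan_interval_weeks Monitoring interval in weeks while alive
#'   (frequency is a package default: the source gives unit costs only).
#' @param bsc_cost_per_cycle USD best-supportive-care cost per model cycle in
#'   the progressed state.
#' @param terminal_care_cost USD one-time terminal-care cost at death.
#' @param admin_first_hour,admin_addl_hour USD infusion administration fees.
#' @return Object of class `econ_inputs`.
#' @export
econ_inputs <- function(utility_pf = 0.830, utility_pd = 0.443,
                        ct_scan_cost = 135, follow_up_cost = 251,
                        scan_interval_weeks = 6,
                        bsc_cost_per_cycle = 472,
                        terminal_care_cost = 20409,
                        admin_first_hour = 159, admin_addl_hour = 34) {
  check_that(is_number(utility_pf) && utility_pf >= 0 && utility_pf <= 1,
             "utility_pf must be in [0, 1]")
  check_that(is_number(utility_pd) && utility_pd >= 0 && utility_pd <= 1,
             "utility_pd must be in [0, 1]")
  check_that(utility_pf >= utility_pd, "utility_pf must be >= utility_pd")
  for (v in list(ct_scan_cost, follow_up_cost, bsc_cost_per_cycle,
                 terminal_care_cost, admin_first_hour, admin_addl_hour)) {
    check_that(is_number(v) && v >= 0, "costs must be >= 0")
  }
  check_that(is_number(scan_interval_weeks) && scan_interval_weeks > 0,
             "scan_interval_weeks must be > 0")
  structure(list(utility_pf = utility_pf, utility_pd = utility_pd,
                 ct_scan_cost = ct_scan_cost, follow_up_cost = follow_up_cost,
                 scan_interval_weeks = scan_interval_weeks,
                 bsc_cost_per_cycle = bsc_cost_per_cycle,
                 terminal_care_cost = terminal_care_cost,
                 admin_first_hour = admin_first_hour,
                 admin_addl_hour = admin_addl_hour),
            class = "econ_inputs")
}

#' Drug cost of one administration
#'
#' Resolves the dose via the component's rule (per kg, per m2, or flat mg)
#' and multiplies by the per-mg price. No vial rounding or wastage: prices
#' are per mg.
#'
#' @param component A [regimen_component()].
#' @param pt A [patient()].
#' @return USD.
#' @examples
#' tdxd <- regimen_component("trastuzumab_deruxtecan", 5.4, "per_kg",
#'                           1, 21, 29.68)
#' drug_cost_per_admin(tdxd, patient())  # 5.4 * 74 * 29.68 = 11860.13
#' @export
drug_cost_per_admin <- function(component, pt = patient()) {
  check_that(inherits(component, "regimen_component"), "need a regimen_component")
  mult <- switch(component$dose_rule,
                 per_kg = pt$body_weight,
                 per_m2 = pt$body_surface_area,
                 flat = 1)
  component$dose * mult * component$price_per_mg
}

# share-weighted USD per week of drug acquisition for a regimen
drug_cost_per_week <- function(reg, pt) {
  sum(vapply(reg$components, function(cp) {
    cp$share * drug_cost_per_admin(cp, pt) * cp$n_admin_per_cycle * 7 / cp$cycle_length_days
  }, 0))
}

# share-weighted USD per week of administration fees
admin_cost_per_week <- function(reg, econ) {
  sum(vapply(reg$components, function(cp) {
    if (cp$infusion_hours <= 0) return(0)  # oral
    fee <- econ$admin_first_hour + econ$admin_addl_hour * max(0, cp$infusion_hours - 1)
    cp$share * fee * cp$n_admin_per_cycle * 7 / cp$cycle_length_days
  }, 0))
}

#' Frequency-weighted adverse-event burden
#'
#' Aggregates itemized grade >= 3 adverse events into the one-time per-arm
#' cost and disutility the model applies at entry.
#'
#' @param events Data frame with columns `frequency` (in `[0, 1]`),
#'   `cost` (USD) and `disutility` (QALY); may be empty.
#' @return Named numeric: `cost`, `disutility`.
#' @export
aggregate_ae_burden <- function(events) {
  if (is.null(events) || nrow(events) == 0) return(c(cost = 0, disutility = 0))
  check_that(all(c("frequency", "cost", "disutility") %in% names(events)),
             "events needs columns frequency, cost, disutility")
  check_that(all(events$frequency >= 0 & events$frequency <= 1),
             "frequencies must lie in [0, 1]")
  c(cost = sum(events$frequency * events$cost),
    disutility = sum(events$frequency * events$disutility))
}

#' Accrue costs and QALYs for one strategy over a trace
#'
#' @param trace A [build_trace()] result.
#' @param reg The strategy's [regimen()].
#' @param econ An [econ_inputs()].
#' @param pt A [patient()] (dosing).
#' @return Object of class `strategy_result`: life-years (`ly_pf`,
#'   `ly_total`, undiscounted), discounted `qaly`, discounted cost components
#'   (`cost_drug`, `cost_admin`, `cost_monitoring`, `cost_bsc`, `cost_ae`,
#'   `cost_terminal`) and `cost_total`.
#' @export
accrue_strategy <- function(trace, reg, econ, pt = patient()) {
  check_that(inherits(trace, "state_trace"), "trace must be a state_trace")
  check_that(inherits(reg, "regimen"), "reg must be a regimen")
  check_that(inherits(econ, "econ_inputs"), "econ must be econ_inputs")
  grid <- attr(trace, "grid")
  t <- trace$time_weeks
  w <- trace$discount_weight
  alive <- trace$pf + trace$pd

  ly_pf <- trapz(t, trace$pf) / 52
  ly_total <- trapz(t, alive) / 52
  qaly <- trapz(t, (econ$utility_pf * trace$pf + econ$utility_pd * trace$pd) * w) / 52 -
    reg$ae_disutility_onetime

  pf_wk_disc <- trapz(t, trace$pf * w)       # discounted person-weeks on treatment
  pd_wk_disc <- trapz(t, trace$pd * w)

  cost_drug <- drug_cost_per_week(reg, pt) * pf_wk_disc
  cost_admin <- admin_cost_per_week(reg, econ) * pf_wk_disc
  cost_bsc <- econ$bsc_cost_per_cycle / grid$cycle_length * pd_wk_disc

  scan_t <- seq(econ$scan_interval_weeks, grid$horizon, by = econ$scan_interval_weeks)
  if (length(scan_t)) {
    alive_at <- stats::approx(t, alive, xout = scan_t, rule = 2)$y
    cost_monitoring <- sum((econ$ct_scan_cost + econ$follow_up_cost) * alive_at *
                             discount_weight(scan_t, grid$discount_rate))
  } else cost_monitoring <- 0

  cost_ae <- reg$ae_cost_onetime
  cost_terminal <- sum(diff(trace$dead) * econ$terminal_care_cost * w[-1])

  cost_total <- cost_drug + cost_admin + cost_monitoring + cost_bsc +
    cost_ae + cost_terminal

  structure(list(strategy = reg$name,
                 ly_pf = ly_pf, ly_total = ly_total, qaly = qaly,
                 cost_drug = cost_drug, cost_admin = cost_admin,
                 cost_monitoring = cost_monitoring, cost_bsc = cost_bsc,
                 cost_ae = cost_ae, cost_terminal = cost_terminal,
                 cost_total = cost_total),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s\n", x$strategy))
  cat(sprintf("  LY (PF / total): %.3f / %.3f   QALY: %.3f\n",
              x$ly_pf, x$ly_total, x$qaly))
  cat(sprintf("  cost total: $%s (drug %s, admin %s, monitor %s, BSC %s, AE %s, terminal %s)\n",
              format(round(x$cost_total), big.mark = ","),
              format(round(x$cost_drug), big.mark = ","),
              format(round(x$cost_admin), big.mark = ","),
              format(round(x$cost_monitoring), big.mark = ","),
              format(round(x$cost_bsc), big.mark = ","),
              format(round(x$cost_ae), big.mark = ","),
              format(round(x$cost_terminal), big.mark = ",")))
  invisible(x)
}

#' Incremental comparison of two strategies
#'
#' Computes incremental cost, effect, ICERs and the net-benefit measures
#' `INHB = dE - dC / lambda` (QALYs) and `INMB = dE * lambda - dC` (USD) at a
#' willingness-to-pay threshold.
#'
#' @param a,b `strategy_result`s; increments are `a - b` (intervention minus
#'   comparator).
#' @param wtp Willingness-to-pay threshold, USD per QALY (> 0).
#' @return Object of class `ce_comparison` with `delta_cost`, `delta_effect`,
#'   `delta_ly`, `icer_per_qaly`, `icer_per_ly`, `inhb`, `inmb`,
#'   `wtp_lambda` and a `dominance` label (`"icer"`, `"a_dominant"`,
#'   `"b_dominant"`, or `"equal_effect"` when the ICER is undefined).
#' @examples
#' # net-benefit identities from printed increments
#' a <- list(qaly = 0.817, ly_total = 0, cost_total = 67602)
#' b <- list(qaly = 0, ly_total = 0, cost_total = 0)
#' class(a) <- class(b) <- "strategy_result"
#' compare_strategies(a, b, wtp = 1e5)[c("inhb", "inmb")]
#' @export
compare_strategies <- function(a, b, wtp = 100000) {
  check_that(inherits(a, "strategy_result") && inherits(b, "strategy_result"),
             "a and b must be strategy_result objects")
  check_that(is_number(wtp) && wtp > 0, "wtp must be > 0")
  dc <- a$cost_total - b$cost_total
  de <- a$qaly - b$qaly
  dly <- (a$ly_total %||% 0) - (b$ly_total %||% 0)
  dominance <- if (de > 0 && dc <= 0) "a_dominant"
    else if (de < 0 && dc >= 0) "b_dominant"
    else if (de == 0) "equal_effect"
    else "icer"
  structure(list(delta_cost = dc, delta_effect = de, delta_ly = dly,
                 icer_per_qaly = if (de != 0) dc / de else NA_real_,
                 icer_per_ly = if (dly != 0) dc / dly else NA_real_,
                 inhb = de - dc / wtp,
                 inmb = de * wtp - dc,
                 wtp_lambda = wtp, dominance = dominance),
            class = "ce_comparison")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.ce_comparison <- function(x, ...) {
  cat(sprintf("<ce_comparison> dC = $%s, dE = %.3f QALY, dLY = %.3f\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_effect, x$delta_ly))
  if (x$dominance == "icer") {
    cat(sprintf("  ICER: $%s/QALY ($%s/LY)\n",
                format(round(x$icer_per_qaly), big.mark = ","),
                format(round(x$icer_per_ly), big.mark = ",")))
  } else cat(sprintf("  dominance: %s\n", x$dominance))
  cat(sprintf("  at lambda $%s/QALY: INHB %.3f QALY, INMB $%s\n",
              format(x$wtp_lambda, big.mark = ","), x$inhb,
              format(round(x$inmb), big.mark = ",")))
  invisible(x)
}
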