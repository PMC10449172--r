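# Run configuration: schema, YAML/JSON I/O, base-case driver, provenance.
#
# A run_config is a plain nested list (so it serializes 1:1 to YAML/JSON)
# with class "run_config". Heavier S3 objects (surv_model, regimen, ...) are
# built from it on demand.

.config_top_keys <- c("scenario", "seed", "grid", "survival", "patient",
                      "econ", "regimens", "wtp", "param_specs", "hr_pfs_tdxd")

#' Validate and normalize a run configuration
#'
#' Fills defaults (reported via `message()`), validates the schema, and
#' returns a `run_config`. Required shape: `survival$tdxd`/`survival$chemo`
#' each with `os`/`pfs` model specs (`family` + named `params`), regimen
#' definitions with a price for every drug, positive WTP thresholds.
#'
#' @param x Named list (e.g. parsed YAML) or `run_config`.
#' @return A validated `run_config`.
#' @export
as_run_config <- function(x) {
  check_that(is.list(x), "config must be a list")
  unknown <- setdiff(names(x), .config_top_keys)
  if (length(unknown)) {
    warning(sprintf("ignoring unknown config keys: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
    x[unknown] <- NULL
  }
  defaults <- list(scenario = "custom", seed = 1L,
                   grid = list(cycle_length = 1, horizon = 520, discount_rate = 0.03),
                   patient = list(body_surface_area = 1.82, body_weight = 74),
                   econ = unclass(econ_inputs()),
                   wtp = c(50000, 100000),
                   hr_pfs_tdxd = 1,
                   param_specs = default_param_specs())
  for (k in names(defaults)) {
    if (is.null(x[[k]])) {
      x[[k]] <- defaults[[k]]
      message(sprintf("config: '%s' not given, using default", k))
    }
  }
  check_that(!is.null(x$survival), "config field 'survival' is required")
  for (arm in c("tdxd", "chemo")) {
    check_that(!is.null(x$survival[[arm]]),
               "config field 'survival$%s' is required", arm)
    for (ep in c("os", "pfs")) {
      spec <- x$survival[[arm]][[ep]]
      check_that(!is.null(spec), "config field 'survival$%s$%s' is required", arm, ep)
      model_from_spec(spec)  # validates family/params
    }
  }
  if (is.null(x$regimens)) {
    x$regimens <- list(tdxd = unclass_regimen(default_tdxd_regimen()),
                       chemo = unclass_regimen(default_chemo_regimen()))
    message("config: 'regimens' not given, using defaults")
  }
  for (arm in c("tdxd", "chemo")) {
    check_that(!is.null(x$regimens[[arm]]), "config field 'regimens$%s' is required", arm)
    for (cp in x$regimens[[arm]]$components) {
      check_that(is_number(cp$price_per_mg %||% NULL) && cp$price_per_mg >= 0,
                 "drug '%s' has no price_per_mg", cp$drug %||% "<unnamed>")
    }
    regimen_from_spec(x$regimens[[arm]])  # validates the rest
  }
  x$wtp <- unlist(x$wtp)
  check_that(is.numeric(x$wtp) && length(x$wtp) >= 1 && all(x$wtp > 0),
             "wtp thresholds must be positive")
  check_that(is_number(x$hr_pfs_tdxd) && x$hr_pfs_tdxd > 0, "hr_pfs_tdxd must be > 0")
  do.call(econ_inputs, x$econ)           # validate
  do.call(patient, x$patient)
  do.call(time_grid, x$grid)
  structure(x, class = "run_config")
}

#' Build a survival model from its serialized spec
#'
#' Passes through already-built model objects, so configs may carry
#' transformed curves (subgroup analysis) in memory.
#' @param spec List with `family` and named `params`, or a model object.
#' @return A model accepted by [survival_at()].
#' @export
model_from_spec <- function(spec) {
  if (inherits(spec, c("surv_model", "ph_model"))) return(spec)
  check_that(is.list(spec) && !is.null(spec$family) && !is.null(spec$params),
             "model spec needs 'family' and 'params'")
  surv_model(spec$family, unlist(spec$params))
}

#' Serialize a survival model to its config spec
#' @param model A `surv_model`.
#' @return List with `family` and `params`.
#' @export
model_to_spec <- function(model) {
  check_that(inherits(model, "surv_model"), "need a surv_model")
  list(family = model$family, params = as.list(model$params))
}

regimen_from_spec <- function(spec) {
  if (inherits(spec, "regimen")) return(spec)
  comps <- lapply(spec$components, function(cp) {
    do.call(regimen_component, cp[c("drug", "dose", "dose_rule", "n_admin_per_cycle",
                                    "cycle_length_days", "price_per_mg",
                                    "infusion_hours", "share")])
  })
  regimen(spec$name, comps,
          ae_cost_onetime = spec$ae_cost_onetime %||% 0,
          ae_disutility_onetime = spec$ae_disutility_onetime %||% 0)
}

unclass_regimen <- function(reg) {
  list(name = reg$name,
       components = lapply(reg$components, unclass),
       ae_cost_onetime = reg$ae_cost_onetime,
       ae_disutility_onetime = reg$ae_disutility_onetime)
}

#' Load a run configuration from YAML or JSON
#'
#' @param path File path; format chosen by extension (`.json` vs YAML
#'   otherwise).
#' @return A validated [as_run_config()] result.
#' @export
load_config <- function(path) {
  check_that(file.exists(path), "config file '%s' does not exist", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  as_run_config(raw)
}

#' Write a run configuration to YAML or JSON
#'
#' @param config A `run_config`.
#' @param path Output path (`.json` or `.yaml`/`.yml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

# Core deterministic pipeline shared by the base case, OWSA, PSA, threshold
# search and subgroup analysis.
run_pipeline <- function(config, traces = NULL) {
  config <- as_run_config(config)
  grid <- do.call(time_grid, config$grid)
  pt <- do.call(patient, config$patient)
  econ <- do.call(econ_inputs, config$econ)
  regs <- lapply(config$regimens, regimen_from_spec)
  if (is.null(traces)) traces <- pipeline_traces(config)
  res <- list(
    tdxd = accrue_strategy(traces$tdxd, regs$tdxd, econ, pt),
    chemo = accrue_strategy(traces$chemo, regs$chemo, econ, pt))
  comparisons <- lapply(config$wtp, function(l)
    compare_strategies(res$tdxd, res$chemo, wtp = l))
  list(strategies = res, comparisons = comparisons, traces = traces,
       grid = grid)
}

# State traces for both arms (survival side only; reusable across econ draws)
pipeline_traces <- function(config) {
  grid <- do.call(time_grid, config$grid)
  m <- lapply(config$survival, function(arm) lapply(arm, model_from_spec))
  pfs_t <- m$tdxd$pfs
  if (!is.null(config$hr_pfs_tdxd) && config$hr_pfs_tdxd != 1) {
    pfs_t <- apply_hazard_ratio(pfs_t, config$hr_pfs_tdxd)
  }
  list(tdxd = build_trace(m$tdxd$os, pfs_t, grid),
       chemo = build_trace(m$chemo$os, m$chemo$pfs, grid))
}

#' Run the deterministic base case
#'
#' Builds both arms' traces, accrues costs and QALYs, and compares the
#' strategies at every configured willingness-to-pay threshold. Deterministic:
#' two runs of the same config give identical output.
#'
#' @param config A `run_config` (see [scenario_config()], [load_config()]).
#' @param out_dir Optional directory; when given, writes
#'   `strategies.csv`, `comparisons.csv`, `report.json` and per-arm trace
#'   CSVs there.
#' @return List with `strategies` (data frame), `comparisons` (data frame),
#'   `meta` (package version, config hash, seed), and the underlying
#'   `result` objects.
#' @export
run_base_case <- function(config, out_dir = NULL) {
  config <- as_run_config(config)
  pipe <- run_pipeline(config)
  strat_df <- do.call(rbind, lapply(pipe$strategies, function(s)
    data.frame(unclass(s)[c("strategy", "ly_pf", "ly_total", "qaly",
                            "cost_drug", "cost_admin", "cost_monitoring",
                            "cost_bsc", "cost_ae", "cost_terminal",
                            "cost_total")])))
  rownames(strat_df) <- NULL
  comp_df <- do.call(rbind, lapply(pipe$comparisons, function(cc)
    data.frame(unclass(cc)[c("wtp_lambda", "delta_cost", "delta_effect",
                             "delta_ly", "icer_per_qaly", "icer_per_ly",
                             "inhb", "inmb", "dominance")])))
  rownames(comp_df) <- NULL
  meta <- list(package = "psmcea",
               version = as.character(utils::packageVersion("psmcea")),
               scenario = config$scenario,
               config_hash = content_hash(unclass(config)),
               seed = config$seed)
  out <- list(strategies = strat_df, comparisons = comp_df, meta = meta,
              result = pipe)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(strat_df, file.path(out_dir, "strategies.csv"), row.names = FALSE)
    utils::write.csv(comp_df, file.path(out_dir, "comparisons.csv"), row.names = FALSE)
    jsonlite::write_json(list(strategies = strat_df, comparisons = comp_df,
                              meta = meta),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write_trace(pipe$traces$tdxd, file.path(out_dir, "trace_tdxd.csv"))
    write_trace(pipe$traces$chemo, file.path(out_dir, "trace_chemo.csv"))
  }
  out
}
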