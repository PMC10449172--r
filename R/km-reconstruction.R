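# Pseudo individual-patient data from digitized Kaplan-Meier curves.
#
# Implements the iterative numbers-at-risk reconstruction of Guyot et al.:
# within each at-risk interval, event and censoring counts are solved so the
# Kaplan-Meier curve of the output matches the digitized survival drops and
# the published at-risk count at the start of the next interval. Censoring
# times are spread uniformly within an interval (the standard assumption when
# the censoring pattern is unknown); digitized survival probabilities are
# re-monotonized by cumulative minimum before solving to absorb digitizer
# jitter.

#' Pseudo individual-patient data container
#'
#' @param time_weeks Positive follow-up times (weeks).
#' @param event 1 = event, 0 = right-censored.
#' @return Data frame of class `pseudo_ipd` with columns `time_weeks`, `event`.
#' @export
pseudo_ipd <- function(time_weeks, event) {
  check_that(length(time_weeks) == length(event) && length(time_weeks) > 0,
             "time_weeks and event must be equal-length, non-empty")
  check_that(all(time_weeks > 0), "all times must be > 0")
  check_that(all(event %in% c(0, 1)), "event must be 0/1")
  structure(data.frame(time_weeks = as.numeric(time_weeks),
                       event = as.integer(event)),
            class = c("pseudo_ipd", "data.frame"))
}

#' Coerce to pseudo-IPD
#'
#' Accepts a `pseudo_ipd`, or any data frame with `time_weeks`/`event`
#' (or `time`/`event`) columns — e.g. one read from the CSV interchange format.
#' @param x Object to coerce.
#' @return A `pseudo_ipd`.
#' @export
as_pseudo_ipd <- function(x) {
  if (inherits(x, "pseudo_ipd")) return(x)
  check_that(is.data.frame(x), "expected a data frame of (time_weeks, event)")
  tcol <- intersect(c("time_weeks", "time"), names(x))[1]
  check_that(!is.na(tcol) && "event" %in% names(x),
             "need columns time_weeks (or time) and event")
  pseudo_ipd(x[[tcol]], x$event)
}

#' Digitized Kaplan-Meier curve with numbers at risk
#'
#' @param points Data frame `time_weeks`, `survival`: the digitized
#'   coordinates, starting at (0, 1), times strictly increasing.
#' @param at_risk Data frame `time_weeks`, `n_risk`: published numbers at
#'   risk, counts non-increasing, first row at the curve start.
#' @param total_events Optional total number of events (calibrates the final
#'   interval when given).
#' @return Object of class `digitized_curve`.
#' @export
digitized_curve <- function(points, at_risk, total_events = NULL) {
  check_that(is.data.frame(points) && all(c("time_weeks", "survival") %in% names(points)),
             "points needs columns time_weeks, survival")
  check_that(is.data.frame(at_risk) && all(c("time_weeks", "n_risk") %in% names(at_risk)),
             "at_risk needs columns time_weeks, n_risk")
  points <- points[order(points$time_weeks), , drop = FALSE]
  check_that(all(diff(points$time_weeks) > 0), "digitized times must be strictly increasing")
  check_that(nrow(at_risk) >= 1, "need at least one at-risk row")
  check_that(all(diff(at_risk$time_weeks) > 0), "at-risk times must be strictly increasing")
  check_that(all(diff(at_risk$n_risk) <= 0), "at-risk counts must be non-increasing")
  check_that(abs(points$time_weeks[1]) < 1e-9, "curve must start at time 0")
  check_that(abs(points$survival[1] - 1) <= 0.02, "curve must start at survival 1")
  check_that(all(points$survival >= -0.02 & points$survival <= 1.02),
             "survival outside [0, 1] beyond digitizer tolerance")
  # re-monotonize digitizer jitter
  s <- pmin(pmax(points$survival, 0), 1)
  s[1] <- 1
  points$survival <- cummin(s)
  structure(list(points = points,
                 at_risk = at_risk[order(at_risk$time_weeks), , drop = FALSE],
                 total_events = total_events),
            class = "digitized_curve")
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("<digitized_curve> %d points over [0, %.1f] weeks, %d at-risk rows (n0 = %d)\n",
              nrow(x$points), max(x$points$time_weeks), nrow(x$at_risk),
              x$at_risk$n_risk[1]))
  invisible(x)
}

# Run one interval of the reconstruction for a candidate censoring count.
# state: n (at risk entering click `from`), km (KM value at previous click).
# Returns events/censors per click and the exit state.
.guyot_interval <- function(tt, ss, from, to, n_in, km_in, n_cen, t_lo, t_hi) {
  k_idx <- from:to
  cen_k <- integer(length(tt))
  if (n_cen > 0) {
    cen_times <- t_lo + (seq_len(n_cen) - 0.5) / n_cen * (t_hi - t_lo)
    # censor after click k if cen time in [t_k, t_{k+1})
    bins <- findInterval(cen_times, tt[k_idx])
    bins[bins < 1L] <- 1L
    for (b in bins) cen_k[k_idx[b]] <- cen_k[k_idx[b]] + 1L
    cen_list <- split(cen_times, k_idx[bins])
  } else cen_list <- list()
  d_k <- integer(length(tt))
  n <- n_in; km <- km_in
  for (k in k_idx) {
    d <- if (km > 0 && n > 0) round(n * (1 - ss[k] / km)) else 0
    d <- max(0L, min(as.integer(d), n))
    if (d > 0) km <- km * (1 - d / n)
    d_k[k] <- d
    n <- n - d - cen_k[k]
    if (n < 0) n <- 0L
  }
  list(d_k = d_k, cen_k = cen_k, cen_list = cen_list, n_out = n, km_out = km)
}

#' Reconstruct pseudo-IPD from a digitized KM curve (Guyot algorithm)
#'
#' Deterministic (no RNG). The output has exactly the initial at-risk count
#' of records; subjects still at risk after the last digitized time are
#' censored there. When `total_events` is recorded on the curve, the final
#' interval's censoring is calibrated so the cumulative event count matches.
#'
#' @param curve A [digitized_curve()].
#' @return A [pseudo_ipd()] with attribute `intervals` (per-interval
#'   diagnostics: target and achieved at-risk counts, censor counts).
#' @export
reconstruct_ipd <- function(curve) {
  check_that(inherits(curve, "digitized_curve"), "curve must be a digitized_curve")
  tt <- curve$points$time_weeks
  ss <- curve$points$survival
  trisk <- curve$at_risk$time_weeks
  nrisk <- as.integer(curve$at_risk$n_risk)
  K <- length(tt); I <- length(trisk)
  check_that(tt[K] >= trisk[I], "digitized points must span the at-risk interval")

  lower <- vapply(trisk, function(a) which(tt >= a - 1e-9)[1], 0L)
  check_that(!anyNA(lower), "at-risk time outside digitized range")

  d_all <- integer(K)
  cen_records <- list()
  diag_rows <- list()
  n <- nrisk[1]; km <- 1
  for (i in seq_len(I)) {
    from <- lower[i]
    to <- if (i < I) lower[i + 1] - 1L else K
    if (to < from) next
    t_lo <- tt[from]; t_hi <- if (i < I) tt[lower[i + 1]] else tt[K]

    if (i < I) {
      target <- nrisk[i + 1]
      # initial censoring guess from the KM identity n_{i+1} ~ n_i S_{i+1}/S_i
      guess <- round(n * ss[lower[i + 1]] / max(ss[from], 1e-12)) - target
      n_cen <- max(0L, as.integer(guess))
      best <- NULL
      seen <- integer(0)
      for (iter in 1:60) {
        res <- .guyot_interval(tt, ss, from, to, n, km, n_cen, t_lo, t_hi)
        diff <- res$n_out - target
        if (is.null(best) || abs(diff) < abs(best$diff)) {
          best <- c(res, list(diff = diff, n_cen = n_cen))
        }
        if (diff == 0) break
        if (n_cen %in% seen && abs(diff) >= abs(best$diff)) break
        seen <- c(seen, n_cen)
        n_cen <- n_cen + diff
        if (n_cen < 0) { n_cen <- 0L; if (0L %in% seen) break }
      }
      res <- .guyot_interval(tt, ss, from, to, n, km, best$n_cen, t_lo, t_hi)
      if (res$n_out != target) {
        extra <- res$n_out - target
        if (extra > 0) {
          # surplus subjects: censor them at the interval end
          res$cen_list <- c(res$cen_list, list(rep(tt[to], extra)))
          res$cen_k[to] <- res$cen_k[to] + extra
        } else {
          # deficit (rounding under digitizer jitter): retract the latest
          # events, then the latest censorings; error only if the interval
          # admits no non-negative integer solution at all
          need <- -extra
          for (k in rev(from:to)) {
            take <- min(res$d_k[k], need)
            res$d_k[k] <- res$d_k[k] - take
            need <- need - take
            if (need == 0L) break
          }
          if (need > 0L) {
            for (j in rev(seq_along(res$cen_list))) {
              take <- min(length(res$cen_list[[j]]), need)
              if (take > 0) {
                res$cen_list[[j]] <- utils::head(res$cen_list[[j]],
                                                 length(res$cen_list[[j]]) - take)
                need <- need - take
              }
              if (need == 0L) break
            }
            res$cen_k <- integer(length(res$cen_k))
          }
          if (need > 0L) {
            stop(sprintf(paste0("inconsistent curve/at-risk input in interval %d ",
                                "[%.1f, %.1f): cannot reach the reported %d at risk"),
                         i, trisk[i], trisk[i + 1], target), call. = FALSE)
          }
          # replay the Kaplan-Meier product with the adjusted counts
          km2 <- km; n2 <- n
          cen_by_k <- integer(length(tt))
          cen_all <- unlist(res$cen_list, use.names = FALSE)
          if (length(cen_all)) {
            bins <- findInterval(cen_all, tt[from:to])
            bins[bins < 1L] <- 1L
            for (b in bins) cen_by_k[(from:to)[b]] <- cen_by_k[(from:to)[b]] + 1L
          }
          for (k in from:to) {
            if (res$d_k[k] > 0 && n2 > 0) km2 <- km2 * (1 - res$d_k[k] / n2)
            n2 <- n2 - res$d_k[k] - cen_by_k[k]
          }
          res$km_out <- km2
          res$cen_k <- cen_by_k
        }
        res$n_out <- target
      }
    } else {
      # final interval: calibrate to total events when known, else no
      # within-interval censoring
      n_cen <- 0L
      if (!is.null(curve$total_events)) {
        for (iter in 1:60) {
          res <- .guyot_interval(tt, ss, from, to, n, km, n_cen, t_lo, t_hi)
          ev_diff <- (sum(d_all) + sum(res$d_k)) - curve$total_events
          if (ev_diff == 0 || (ev_diff > 0 && n_cen >= n)) break
          if (ev_diff > 0) n_cen <- min(n, n_cen + ev_diff) else break
        }
      }
      res <- .guyot_interval(tt, ss, from, to, n, km, n_cen, t_lo, t_hi)
    }

    d_all <- d_all + res$d_k
    cen_records <- c(cen_records, res$cen_list)
    diag_rows[[i]] <- data.frame(interval = i, t_start = t_lo,
                                 n_in = n, n_out = res$n_out,
                                 events = sum(res$d_k), censored = sum(res$cen_k))
    n <- res$n_out; km <- res$km_out
  }

  ev_times <- rep(tt, d_all)
  cen_times <- unlist(cen_records, use.names = FALSE)
  if (is.null(cen_times)) cen_times <- numeric(0)
  # anyone still at risk leaves as censored at the last digitized time
  if (n > 0) cen_times <- c(cen_times, rep(tt[K], n))
  time <- c(ev_times, cen_times)
  event <- c(rep(1L, length(ev_times)), rep(0L, length(cen_times)))
  time <- pmax(time, 1e-6)  # events digitized exactly at 0 are not possible (S(0)=1)
  out <- pseudo_ipd(time, event)
  attr(out, "intervals") <- do.call(rbind, diag_rows)
  out
}

#' Kaplan-Meier (product-limit) estimate
#'
#' Thin wrapper around [survival::survfit()] returning the step function in a
#' plain tabular form plus an evaluator.
#'
#' @param ipd A [pseudo_ipd()] (or coercible data frame).
#' @return Object of class `km_curve`: data frame `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, with attribute `n0` (initial count).
#'   Evaluate with [km_survival_at()].
#' @export
km_estimate <- function(ipd) {
  ipd <- as_pseudo_ipd(ipd)
  fit <- survival::survfit(survival::Surv(time_weeks, event) ~ 1, data = ipd,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                    n_censor = fit$n.censor, survival = fit$surv)
  structure(out, class = c("km_curve", "data.frame"), n0 = nrow(ipd))
}

#' Evaluate a KM curve at arbitrary times
#'
#' Right-continuous step interpolation with `S(t) = 1` before the first
#' event/censoring time.
#'
#' @param km A `km_curve` from [km_estimate()].
#' @param t Times (weeks).
#' @return Survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  sf <- stats::stepfun(km$time, c(1, km$survival), right = FALSE)
  sf(t)
}
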