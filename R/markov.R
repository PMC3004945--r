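# Two-state Markov cohort engine on monthly cycles.
#
# The cohort model is deterministic: it tracks the expected event-free
# fraction, not individual patients. Death is not a separate state
# because both trial endpoints are composites that already fold death in.

#' Construct a survival trace
#'
#' @param label Scenario text label.
#' @param survival Event-free probabilities at cycles `0..N`;
#'   `survival[1]` (cycle 0) must be 1 and the sequence non-increasing.
#' @return An object of class `survival_trace` with fields `label`,
#'   `cycle_months` (0..N) and `survival`.
#' @export
survival_trace <- function(label, survival) {
  survival <- as.numeric(survival)
  stopifnot(length(survival) >= 1L, !anyNA(survival))
  if (abs(survival[1] - 1) > 1e-12) {
    stop("survival trace must start at 1 (cycle 0)")
  }
  if (any(diff(survival) > 1e-12)) stop("survival trace must be non-increasing")
  if (any(survival <= 0 | survival > 1)) {
    stop("survival values must lie in (0, 1]")
  }
  structure(list(label = as.character(label),
                 cycle_months = seq_along(survival) - 1L,
                 survival = survival),
            class = "survival_trace")
}

#' @export
print.survival_trace <- function(x, ...) {
  n <- length(x$survival) - 1L
  cat(sprintf("<survival_trace> %s: %d cycles, S(%d mo) = %.4f\n",
              x$label, n, n, x$survival[n + 1L]))
  invisible(x)
}

#' @export
as.data.frame.survival_trace <- function(x, ...) {
  data.frame(cycle = x$cycle_months,
             month = x$cycle_months,
             scenario = x$label,
             survival = x$survival)
}

#' Simulate event-free survival with the two-state Markov cohort model
#'
#' Runs the transition from the event-free state to the event state on
#' monthly cycles. Cycle m (1-based) belongs to year `ceiling(m / 12)`
#' and uses that year's monthly transition probability from
#' [annual_prob_to_monthly_prob()], so survival at cycle 12k equals the
#' product of the first k annual complements exactly.
#'
#' @param schedule A [hazard_schedule()].
#' @param cycles Number of monthly cycles to run; must not exceed
#'   `12 * horizon_years`. Defaults to the full horizon (60 cycles for a
#'   5-year schedule, 108 for a 9-year schedule).
#' @param label Trace label; defaults to `"trial/arm"`.
#' @return A [survival_trace()] of length `cycles + 1`.
#' @export
#' @examples
#' tr <- simulate_survival(trial_schedule("big198", "AI"))
#' survival_at(tr, 60)  # 5-year DFS on an AI
simulate_survival <- function(schedule, cycles = 12L * schedule$horizon_years,
                              label = paste0(schedule$trial_id, "/",
                                             schedule$arm)) {
  stopifnot(inherits(schedule, "hazard_schedule"))
  cycles <- as.integer(cycles)
  if (is.na(cycles) || cycles < 0L) stop("cycles must be a non-negative integer")
  if (cycles > 12L * schedule$horizon_years) {
    stop("cycles = ", cycles, " exceeds the schedule horizon of ",
         12L * schedule$horizon_years, " months; no extrapolation")
  }
  p_month <- annual_prob_to_monthly_prob(schedule$annual_rates)
  m <- seq_len(cycles)
  year_of_cycle <- ceiling(m / 12)
  surv <- c(1, cumprod(1 - p_month[year_of_cycle]))
  survival_trace(label, surv)
}

#' Look up a survival trace at a given month
#'
#' Exact lookup at a simulated cycle; no interpolation.
#'
#' @param trace A [survival_trace()].
#' @param months Integer month(s) in `0..N` where `N` is the last cycle.
#' @return Event-free probability at `months`.
#' @export
survival_at <- function(trace, months) {
  stopifnot(inherits(trace, "survival_trace"))
  months <- as.integer(months)
  N <- length(trace$survival) - 1L
  bad <- is.na(months) | months < 0L | months > N
  if (any(bad)) {
    stop("month out of trace range [0, ", N, "]: ",
         paste(months[bad], collapse = ", "))
  }
  trace$survival[months + 1L]
}

#' Write one or more survival traces to CSV
#'
#' Columns: `cycle`, `month`, `scenario`, `survival` (full precision) and
#' `percent` (1-decimal percentage, half-up rounding) for report parity.
#'
#' @param traces A [survival_trace()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  if (inherits(traces, "survival_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, as.data.frame))
  df$percent <- round_half_up(100 * df$survival, 1)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Round half away from zero
#'
#' Report percentages follow commercial (half-up) rounding, e.g. 83.25
#' becomes 83.3, rather than R's default round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  # the sqrt(eps) nudge keeps binary near-misses like 0.15 * 10 = 1.4999...
  # on the intended side of the half
  sign(x) * trunc(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}
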