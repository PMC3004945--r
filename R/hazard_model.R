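# Hazard schedules and probability/hazard conversions.
#
# An annual "hazard rate" here is the per-year probability of a first
# endpoint event among patients event-free at the start of that year.
# Within a year the instantaneous hazard is assumed constant, so the
# cumulative hazard is piecewise linear in time.

#' Construct a trial hazard schedule
#'
#' A hazard schedule holds one trial arm's sequence of annual event
#' probabilities, one entry per year starting at year 0--1, together with
#' the trial, arm and endpoint labels. The model horizon in years equals
#' the number of annual rates.
#'
#' @param trial_id Text label for the trial, e.g. `"BIG1-98"` or `"ATAC"`.
#' @param arm One of `"AI"`, `"TAM"`, or a subgroup tag such as
#'   `"TAM-EM"` / `"TAM-DM"` produced by [decompose_static()].
#' @param endpoint One of `"DFS"` or `"EFS"`.
#' @param annual_rates Numeric vector of per-year event probabilities,
#'   each in `[0, 1)`.
#'
#' @return An object of class `hazard_schedule` with fields `trial_id`,
#'   `arm`, `endpoint`, `annual_rates` and `horizon_years`.
#' @export
#' @examples
#' sched <- hazard_schedule("TOY", "TAM", "DFS", c(0.02, 0.03))
#' sched$horizon_years
hazard_schedule <- function(trial_id, arm, endpoint, annual_rates) {
  stopifnot(is.character(trial_id), length(trial_id) == 1L,
            is.character(arm), length(arm) == 1L,
            is.character(endpoint), length(endpoint) == 1L)
  if (!endpoint %in% c("DFS", "EFS")) {
    stop("endpoint must be 'DFS' or 'EFS', got '", endpoint, "'")
  }
  annual_rates <- as.numeric(annual_rates)
  if (length(annual_rates) < 1L || anyNA(annual_rates)) {
    stop("annual_rates must be a non-empty numeric vector without NA")
  }
  bad <- annual_rates < 0 | annual_rates >= 1
  if (any(bad)) {
    stop("annual rates must lie in [0, 1); offending value(s): ",
         paste(format(annual_rates[bad]), collapse = ", "))
  }
  structure(
    list(trial_id = trial_id, arm = arm, endpoint = endpoint,
         annual_rates = annual_rates,
         horizon_years = length(annual_rates)),
    class = "hazard_schedule"
  )
}

#' @export
print.hazard_schedule <- function(x, ...) {
  cat(sprintf("<hazard_schedule> %s / %s (%s), %d year(s)\n",
              x$trial_id, x$arm, x$endpoint, x$horizon_years))
  cat("  annual rates:", paste(format(x$annual_rates, digits = 4),
                               collapse = " "), "\n")
  invisible(x)
}

#' Read a hazard schedule from a YAML or JSON config file
#'
#' The file must contain keys `trial_id`, `arm`, `endpoint` and
#' `annual_rates` (a list of decimals). Format is chosen by extension
#' (`.yaml`/`.yml` vs `.json`); YAML is also a superset of JSON, so either
#' parser accepts either payload.
#'
#' @param path Path to the config file.
#' @return A [hazard_schedule()].
#' @export
read_hazard_schedule <- function(path) {
  if (!file.exists(path)) {
    stop("hazard-schedule file not found: ", path)
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("trial_id", "arm", "endpoint", "annual_rates")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("hazard-schedule file ", path, " lacks key(s): ",
         paste(missing, collapse = ", "))
  }
  hazard_schedule(cfg$trial_id, cfg$arm, cfg$endpoint,
                  unlist(cfg$annual_rates))
}

#' Write a hazard schedule to YAML or JSON
#'
#' @param schedule A [hazard_schedule()].
#' @param path Output path; format chosen by extension (`.json` writes
#'   JSON, anything else YAML).
#' @return `path`, invisibly.
#' @export
write_hazard_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "hazard_schedule"))
  payload <- list(trial_id = schedule$trial_id, arm = schedule$arm,
                  endpoint = schedule$endpoint,
                  annual_rates = schedule$annual_rates)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}

# Map user-facing trial names onto bundled fixture file stems.
.trial_fixture_stem <- c("big198" = "big198", "big1-98" = "big198",
                         "big 1-98" = "big198", "atac" = "atac")

#' List the trials with bundled hazard-rate fixtures
#'
#' @return Character vector of trial keys accepted by [trial_schedule()].
#' @export
available_trials <- function() c("big198", "atac")

#' Load a bundled trial hazard schedule
#'
#' The package ships the published annual hazard rates of the BIG 1-98
#' trial (5-year DFS, letrozole vs tamoxifen) and the ATAC trial (9-year
#' EFS, anastrozole vs tamoxifen) as YAML fixtures.
#'
#' @param trial_id `"big198"` or `"atac"` (case-insensitive; `"BIG1-98"`
#'   also accepted).
#' @param arm `"AI"` or `"TAM"`.
#' @return A [hazard_schedule()].
#' @export
#' @examples
#' trial_schedule("big198", "TAM")
trial_schedule <- function(trial_id, arm = c("AI", "TAM")) {
  arm <- match.arg(arm)
  key <- tolower(trial_id)
  stem <- .trial_fixture_stem[key]
  if (is.na(stem)) {
    stop("unknown trial '", trial_id, "'; available fixtures: ",
         paste(available_trials(), collapse = ", "))
  }
  fname <- sprintf("%s_%s.yaml", stem, tolower(arm))
  path <- system.file("extdata", fname, package = "tamsim")
  if (!nzchar(path)) stop("bundled fixture missing: ", fname)
  read_hazard_schedule(path)
}

#' Convert an annual event probability to a monthly cycle probability
#'
#' Uses the geometric (annually exact) conversion: the monthly
#' probability `p` satisfies `(1 - p)^12 = 1 - h`, so twelve equal
#' monthly cycles reproduce the annual probability exactly and the cycle
#' granularity does not perturb calibration.
#'
#' @param h Annual event probability (vectorized), each in `[0, 1)`.
#' @return Monthly event probability `p = 1 - (1 - h)^(1/12)`.
#' @export
#' @examples
#' annual_prob_to_monthly_prob(0.0264)
annual_prob_to_monthly_prob <- function(h) {
  h <- as.numeric(h)
  bad <- is.na(h) | h < 0 | h >= 1
  if (any(bad)) {
    stop("annual probability out of [0, 1): ",
         paste(format(h[bad]), collapse = ", "))
  }
  1 - (1 - h)^(1 / 12)
}

#' Convert an event probability to a cumulative hazard
#'
#' @param p Event probability (vectorized), each in `[0, 1)`.
#' @return Cumulative hazard in nats, `-log(1 - p)`.
#' @seealso [cumhaz_to_prob()] for the inverse.
#' @export
prob_to_cumhaz <- function(p) {
  p <- as.numeric(p)
  bad <- is.na(p) | p < 0 | p >= 1
  if (any(bad)) {
    stop("probability out of [0, 1): ",
         paste(format(p[bad]), collapse = ", "))
  }
  -log1p(-p)
}

#' Convert a cumulative hazard to an event probability
#'
#' @param lambda Cumulative hazard in nats (vectorized), non-negative.
#' @return Event probability `1 - exp(-lambda)`.
#' @export
cumhaz_to_prob <- function(lambda) {
  lambda <- as.numeric(lambda)
  bad <- is.na(lambda) | lambda < 0
  if (any(bad)) {
    stop("cumulative hazard must be non-negative: ",
         paste(format(lambda[bad]), collapse = ", "))
  }
  -expm1(-lambda)
}

#' Cumulative hazard of a schedule at a (possibly fractional) time
#'
#' Under the constant-within-year hazard assumption the cumulative hazard
#' is piecewise linear: at integer `t` it equals the partial sum of the
#' per-year hazards, and within a year it interpolates linearly. No
#' extrapolation beyond the schedule horizon is allowed.
#'
#' @param schedule A [hazard_schedule()].
#' @param t Time in years (vectorized), `0 <= t <= horizon_years`.
#' @return Cumulative hazard at `t`, in nats.
#' @export
#' @examples
#' schedule_cumhaz(trial_schedule("big198", "TAM"), 5)
schedule_cumhaz <- function(schedule, t) {
  stopifnot(inherits(schedule, "hazard_schedule"))
  t <- as.numeric(t)
  H <- schedule$horizon_years
  bad <- is.na(t) | t < 0 | t > H
  if (any(bad)) {
    stop("time out of schedule range [0, ", H, "]: ",
         paste(format(t[bad]), collapse = ", "))
  }
  lam <- prob_to_cumhaz(schedule$annual_rates)
  cum <- c(0, cumsum(lam))
  yr <- pmin(floor(t), H - 1)        # year index 0-based; t == H uses last year
  cum[yr + 1] + (t - yr) * lam[yr + 1]
}

#' Total cumulative hazard of a schedule at its horizon
#'
#' @param schedule A [hazard_schedule()].
#' @return Sum of per-year cumulative hazards, in nats.
#' @export
total_cumhaz <- function(schedule) {
  sum(prob_to_cumhaz(schedule$annual_rates))
}
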