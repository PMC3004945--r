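# Individual-level synthetic cohorts matching the cohort model's
# assumptions: two latent metabolizer classes with proportional hazards
# and piecewise-exponential event times (constant hazard within each
# year). Closes the parameter-recovery loop: generate -> product-limit
# estimate -> hazard-ratio recovery.

# Run code under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed)) {
    stop("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Invert a piecewise-linear cumulative hazard: given per-year hazard
# increments lam (years 1..H) and exponential deviates e, return the
# event time in years (Inf where e exceeds the total hazard).
invert_piecewise_cumhaz <- function(lam, e) {
  cum <- c(0, cumsum(lam))
  H <- length(lam)
  t <- rep(Inf, length(e))
  hit <- e < cum[H + 1]
  # year containing the crossing (1-based); lam can contain zero years,
  # which findInterval skips because e never lands strictly inside them
  yr <- findInterval(e[hit], cum, left.open = TRUE, rightmost.closed = TRUE)
  yr <- pmin(pmax(yr, 1L), H)
  t[hit] <- (yr - 1) + (e[hit] - cum[yr]) / lam[yr]
  t
}

#' Generate a synthetic patient-level cohort
#'
#' Draws each subject's metabolizer class (DM with probability `f_dm`),
#' then an event time from that class's piecewise-exponential
#' distribution by inverse transform on the cumulative hazard of the
#' decomposed subgroup schedule. Subjects whose exponential deviate
#' exceeds the subgroup's total cumulative hazard are administratively
#' censored at the horizon. Generation is fully determined by `seed`;
#' the caller's RNG state is left untouched.
#'
#' @param schedule The overall (tamoxifen-arm) [hazard_schedule()].
#' @param params A [metabolizer_params()].
#' @param n Cohort size (>= 1).
#' @param seed Integer seed; required.
#' @param method Decomposition method for the latent classes
#'   (`"static"` or `"dynamic"`).
#' @return An object of class `synthetic_cohort`: a list with `n`,
#'   `genotype` (factor EM/DM), `event_time_months` (in `(0, horizon]`),
#'   `event_indicator` (logical), `horizon_months`, `seed`, and
#'   `generating_params` (the params, schedule and method).
#' @export
#' @examples
#' coh <- generate_cohort(trial_schedule("big198", "TAM"),
#'                        metabolizer_params(1.29, 0.54),
#'                        n = 1000, seed = 7)
#' mean(coh$event_indicator)
generate_cohort <- function(schedule, params, n, seed,
                            method = c("static", "dynamic")) {
  stopifnot(inherits(schedule, "hazard_schedule"),
            inherits(params, "metabolizer_params"))
  method <- match.arg(method)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 ||
      n != trunc(n)) {
    stop("n must be a positive integer")
  }
  n <- as.integer(n)
  sub <- decompose(schedule, params, method)
  lam_em <- prob_to_cumhaz(sub$em$annual_rates)
  lam_dm <- prob_to_cumhaz(sub$dm$annual_rates)
  horizon <- 12 * schedule$horizon_years

  draws <- with_seed(seed, {
    genotype <- ifelse(stats::runif(n) < params$f_dm, "DM", "EM")
    e <- stats::rexp(n)
    list(genotype = genotype, e = e)
  })
  genotype <- factor(draws$genotype, levels = c("EM", "DM"))
  t_years <- rep(Inf, n)
  is_dm <- genotype == "DM"
  t_years[!is_dm] <- invert_piecewise_cumhaz(lam_em, draws$e[!is_dm])
  t_years[is_dm] <- invert_piecewise_cumhaz(lam_dm, draws$e[is_dm])

  event <- is.finite(t_years)
  time_months <- ifelse(event, 12 * t_years, horizon)
  # an exact-zero time has probability zero; clamp defensively
  time_months[event & time_months <= 0] <- .Machine$double.eps

  structure(list(n = n, genotype = genotype,
                 event_time_months = time_months,
                 event_indicator = event,
                 horizon_months = horizon, seed = seed,
                 generating_params = list(params = params,
                                          schedule = schedule,
                                          method = method)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> n = %d (DM %.1f%%), %d events by month %d, seed %d\n",
    x$n, 100 * mean(x$genotype == "DM"), sum(x$event_indicator),
    x$horizon_months, x$seed))
  invisible(x)
}

#' @export
as.data.frame.synthetic_cohort <- function(x, ...) {
  data.frame(subject_id = seq_len(x$n),
             genotype = as.character(x$genotype),
             time_months = x$event_time_months,
             event = as.integer(x$event_indicator))
}

#' Write a cohort to CSV with a JSON sidecar
#'
#' The CSV has columns `subject_id`, `genotype`, `time_months`, `event`
#' (1/0); the sidecar `<path>.json` records the generating parameters,
#' schedule and seed so a cohort file is self-describing.
#'
#' @param cohort A `synthetic_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  gp <- cohort$generating_params
  jsonlite::write_json(
    list(n = cohort$n, seed = cohort$seed,
         horizon_months = cohort$horizon_months,
         hr_dm = gp$params$hr_dm, f_dm = gp$params$f_dm,
         method = gp$method,
         schedule = list(trial_id = gp$schedule$trial_id,
                         arm = gp$schedule$arm,
                         endpoint = gp$schedule$endpoint,
                         annual_rates = gp$schedule$annual_rates)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Product-limit (Kaplan-Meier) survival estimate
#'
#' Computes the product-limit estimator from its definition: at each
#' distinct event time `t_i` with `d_i` events among `n_i` subjects
#' still at risk, survival multiplies by `(1 - d_i / n_i)`. Subjects
#' censored at a time are removed from the risk set after events at
#' that same time. With no censoring before the horizon the estimate
#' equals the empirical survival function.
#'
#' @param cohort A `synthetic_cohort`, or any list with numeric
#'   `event_time_months` and logical `event_indicator`.
#' @return An object of class `km_estimate`: `time` (distinct event
#'   times, ascending), `surv` (survival just after each time), `n`.
#'   Evaluate it with [km_at()].
#' @export
km_estimate <- function(cohort) {
  time <- cohort$event_time_months
  event <- cohort$event_indicator
  stopifnot(length(time) >= 1L, length(time) == length(event))
  ord <- order(time)
  time <- time[ord]; event <- as.logical(event)[ord]
  n <- length(time)
  # group tied times; the risk set at a distinct time is everyone whose
  # (event or censoring) time is >= it, so censoring at a time drops
  # subjects only after the events at that same time
  grp <- rle(time)
  ends <- cumsum(grp$lengths)
  starts <- ends - grp$lengths + 1L
  cum_ev <- cumsum(event)
  d <- cum_ev[ends] - c(0, cum_ev)[starts]
  at_risk <- n - starts + 1L
  keep <- d > 0L
  surv <- cumprod(1 - d[keep] / at_risk[keep])
  structure(list(time = grp$values[keep], surv = surv, n = n),
            class = "km_estimate")
}

#' Evaluate a product-limit estimate at given times
#'
#' Right-continuous step-function lookup: the survival just after the
#' last event time at or before `t` (1 before the first event).
#'
#' @param km A [km_estimate()].
#' @param t Time(s) in months.
#' @return Estimated survival at `t`.
#' @export
km_at <- function(km, t) {
  stopifnot(inherits(km, "km_estimate"))
  idx <- findInterval(t, km$time)
  c(1, km$surv)[idx + 1]
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("<km_estimate> n = %d, %d event time(s), final S = %.4f\n",
              x$n, length(x$time),
              if (length(x$surv)) x$surv[length(x$surv)] else 1))
  invisible(x)
}

#' Recover the DM-vs-EM hazard ratio from a synthetic cohort
#'
#' Estimates the hazard ratio as the ratio of genotype-specific
#' cumulative hazards at the horizon,
#' `HR = log(S_DM(horizon)) / log(S_EM(horizon))`, with each survival
#' from the genotype's product-limit estimate. Under proportional
#' hazards this ratio is the (time-constant) hazard ratio. A percentile
#' bootstrap over subjects supplies the interval.
#'
#' @param cohort A `synthetic_cohort`.
#' @param n_boot Number of bootstrap resamples (default 200).
#' @param seed Seed for the bootstrap (default: cohort seed + 1).
#' @param conf Interval coverage (default 0.95).
#' @return A list of class `hr_recovery`: `estimate`, `ci` (length-2),
#'   `n_boot`, per-genotype horizon survivals, and the generating
#'   `true_hr` when available.
#' @export
recover_hr <- function(cohort, n_boot = 200L, seed = cohort$seed + 1L,
                       conf = 0.95) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  horizon <- cohort$horizon_months
  for (g in c("EM", "DM")) {
    idx <- cohort$genotype == g
    if (!any(idx)) stop("genotype class ", g, " is empty")
    if (!any(cohort$event_indicator[idx])) {
      stop("genotype class ", g, " has zero events; ",
           "the cumulative-hazard ratio is not estimable")
    }
  }
  surv_g <- function(time, event) {
    km_at(km_estimate(list(event_time_months = time,
                           event_indicator = event)), horizon)
  }
  em <- cohort$genotype == "EM"
  s_em <- surv_g(cohort$event_time_months[em], cohort$event_indicator[em])
  s_dm <- surv_g(cohort$event_time_months[!em], cohort$event_indicator[!em])
  est <- log(s_dm) / log(s_em)

  # censoring is administrative at the horizon only, so the horizon
  # product-limit survival reduces to the event-free proportion; a
  # bootstrap over subjects is then a multinomial resample of the four
  # (genotype x event) cells
  cells <- c(em_event = sum(em & cohort$event_indicator),
             em_censor = sum(em & !cohort$event_indicator),
             dm_event = sum(!em & cohort$event_indicator),
             dm_censor = sum(!em & !cohort$event_indicator))
  boot <- with_seed(seed, {
    draws <- stats::rmultinom(n_boot, cohort$n, cells / cohort$n)
    n_em <- draws[1, ] + draws[2, ]
    n_dm <- draws[3, ] + draws[4, ]
    log1p(-draws[3, ] / pmax(n_dm, 1)) / log1p(-draws[1, ] / pmax(n_em, 1))
  })
  boot <- boot[is.finite(boot)]
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))
  structure(list(estimate = est, ci = ci, n_boot = n_boot,
                 s_em = s_em, s_dm = s_dm,
                 true_hr = cohort$generating_params$params$hr_dm),
            class = "hr_recovery")
}

#' @export
print.hr_recovery <- function(x, ...) {
  cat(sprintf(
    "<hr_recovery> HR = %.3f (%.0f%% CI %.3f-%.3f)%s\n",
    x$estimate, 100 * 0.95, x$ci[1], x$ci[2],
    if (!is.null(x$true_hr)) sprintf(", generating HR = %.2f", x$true_hr)
    else ""))
  invisible(x)
}
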