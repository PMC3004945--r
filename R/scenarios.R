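# Named treatment strategies and base-case assembly.
#
# Strategies:
#   AI_ALL          everyone on an aromatase inhibitor
#   TAM_ALL         everyone on tamoxifen (genotypically unselected)
#   TAM_EM          EM subgroup on tamoxifen
#   TAM_DM          DM subgroup on tamoxifen
#   GENOTYPE_GUIDED EM -> tamoxifen, DM -> AI (mixture by assignment)

.strategies <- c("AI_ALL", "TAM_ALL", "TAM_EM", "TAM_DM", "GENOTYPE_GUIDED")

new_scenario_result <- function(strategy, trial_id, trace, params) {
  structure(
    list(strategy = strategy, trial_id = trial_id,
         horizon_survival = trace$survival[length(trace$survival)],
         trace = trace, params = params),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  N <- length(x$trace$survival) - 1L
  cat(sprintf("<scenario_result> %s %s: %d-month survival %.4f (%.1f%%)\n",
              x$trial_id, x$strategy, N, x$horizon_survival,
              round_half_up(100 * x$horizon_survival, 1)))
  invisible(x)
}

# Pointwise mixture of two traces with weights (w, 1 - w).
mix_traces <- function(t1, t2, w, label) {
  stopifnot(length(t1$survival) == length(t2$survival))
  survival_trace(label, w * t1$survival + (1 - w) * t2$survival)
}

#' Run the base-case scenario set for a trial
#'
#' Simulates the five named strategies at the trial's horizon (60 monthly
#' cycles for BIG 1-98 DFS, 108 for ATAC EFS): both unselected arms, the
#' EM and DM tamoxifen subgroups from the mixture decomposition, and the
#' genotype-guided strategy that assigns EM patients to tamoxifen and DM
#' patients to an AI, whose survival is the frequency-weighted mixture
#' `(1 - f_dm) * S_TAM_EM + f_dm * S_AI`.
#'
#' @param trial_id Trial key accepted by [trial_schedule()].
#' @param params A [metabolizer_params()]; defaults to the endpoint's
#'   base case (1.29/0.54 for DFS, 1.33/0.54 for EFS).
#' @param method Decomposition method, `"static"` (default) or
#'   `"dynamic"`.
#' @return An object of class `base_case`: a named list of
#'   `scenario_result`s (one per strategy) with the trial id, horizon and
#'   parameters attached as attributes. `summary()` / `as.data.frame()`
#'   give a one-row-per-strategy table.
#' @export
#' @examples
#' bc <- run_base_case("big198")
#' as.data.frame(bc)
run_base_case <- function(trial_id, params = base_case_params(trial_id),
                          method = c("static", "dynamic")) {
  method <- match.arg(method)
  ai <- trial_schedule(trial_id, "AI")
  tam <- trial_schedule(trial_id, "TAM")
  cycles <- 12L * tam$horizon_years
  sub <- decompose(tam, params, method)

  tr_ai <- simulate_survival(ai, cycles, label = "AI_ALL")
  tr_tam <- simulate_survival(tam, cycles, label = "TAM_ALL")
  tr_em <- simulate_survival(sub$em, cycles, label = "TAM_EM")
  tr_dm <- simulate_survival(sub$dm, cycles, label = "TAM_DM")
  tr_gg <- mix_traces(tr_em, tr_ai, 1 - params$f_dm, "GENOTYPE_GUIDED")

  traces <- list(AI_ALL = tr_ai, TAM_ALL = tr_tam, TAM_EM = tr_em,
                 TAM_DM = tr_dm, GENOTYPE_GUIDED = tr_gg)
  res <- lapply(names(traces), function(s) {
    new_scenario_result(s, tam$trial_id, traces[[s]], params)
  })
  names(res) <- names(traces)
  structure(res, class = "base_case", trial_id = tam$trial_id,
            endpoint = tam$endpoint, horizon_months = cycles,
            params = params, method = method)
}

#' @export
as.data.frame.base_case <- function(x, ...) {
  data.frame(
    strategy = vapply(x, `[[`, "", "strategy"),
    trial = attr(x, "trial_id"),
    endpoint = attr(x, "endpoint"),
    horizon_months = attr(x, "horizon_months"),
    survival = vapply(x, `[[`, 0, "horizon_survival"),
    percent = round_half_up(
      100 * vapply(x, `[[`, 0, "horizon_survival"), 1),
    row.names = NULL)
}

#' @export
summary.base_case <- function(object, ...) as.data.frame(object)

#' @export
print.base_case <- function(x, ...) {
  cat(sprintf("<base_case> %s (%s, %d months), HR.DM = %g, f.DM = %g, %s\n",
              attr(x, "trial_id"), attr(x, "endpoint"),
              attr(x, "horizon_months"), attr(x, "params")$hr_dm,
              attr(x, "params")$f_dm, attr(x, "method")))
  print(as.data.frame(x))
  invisible(x)
}

#' Rank treatment strategies by horizon survival
#'
#' @param results A `base_case` object or list of `scenario_result`s
#'   sharing one trial and horizon.
#' @return A data frame ordered by decreasing horizon survival with the
#'   1-decimal percentage and the percentage-point difference from the
#'   best strategy; a full pairwise difference matrix (percentage points,
#'   1 decimal) is attached as attribute `"pairwise"`.
#' @export
#' @examples
#' compare_strategies(run_base_case("atac"))
compare_strategies <- function(results) {
  if (inherits(results, "base_case")) results <- unclass(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "scenario_result")))
  trials <- unique(vapply(results, `[[`, "", "trial_id"))
  horizons <- unique(vapply(results, function(r) {
    length(r$trace$survival)
  }, 0L))
  if (length(trials) != 1L || length(horizons) != 1L) {
    stop("all results must share one trial and one horizon; got trials ",
         paste(trials, collapse = ", "))
  }
  surv <- vapply(results, `[[`, 0, "horizon_survival")
  strat <- vapply(results, `[[`, "", "strategy")
  ord <- order(-surv, strat)   # survival desc, alphabetical tie-break
  # pairwise differences are taken between the 1-decimal report
  # percentages, so the summary agrees with what the table prints
  pct <- round_half_up(100 * surv, 1)
  pair <- round_half_up(outer(pct[ord], pct[ord], `-`), 1)
  dimnames(pair) <- list(strat[ord], strat[ord])
  out <- data.frame(rank = seq_along(ord),
                    strategy = strat[ord],
                    trial = trials,
                    survival = surv[ord],
                    percent = pct[ord],
                    diff_from_best = round_half_up(pct[ord][1] - pct[ord], 1),
                    row.names = NULL)
  attr(out, "pairwise") <- pair
  out
}

#' Write a base-case scenario summary to JSON and CSV
#'
#' @param base_case A `base_case` object from [run_base_case()].
#' @param stem Output path stem; writes `<stem>.json` and `<stem>.csv`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_scenario_summary <- function(base_case, stem) {
  df <- as.data.frame(base_case)
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, ".json")
  utils::write.csv(df, csv, row.names = FALSE)
  p <- attr(base_case, "params")
  jsonlite::write_json(
    list(trial = attr(base_case, "trial_id"),
         endpoint = attr(base_case, "endpoint"),
         horizon_months = attr(base_case, "horizon_months"),
         hr_dm = p$hr_dm, f_dm = p$f_dm,
         method = attr(base_case, "method"),
         strategies = df),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(json, csv))
}
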