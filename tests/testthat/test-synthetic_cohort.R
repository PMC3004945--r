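base_params <- function() metabolizer_params(1.29, 0.54)

test_that("cohort generation is deterministic in the seed and leaves the RNG alone", {
  tam <- trial_schedule("big198", "TAM")
  set.seed(99); before <- runif(1)
  a <- generate_cohort(tam, base_params(), 500, seed = 42)
  b <- generate_cohort(tam, base_params(), 500, seed = 42)
  expect_identical(a$event_time_months, b$event_time_months)
  expect_identical(a$genotype, b$genotype)
  c <- generate_cohort(tam, base_params(), 500, seed = 43)
  expect_false(identical(a$event_time_months, c$event_time_months))
  # caller's RNG stream is unaffected by the seeded generation
  set.seed(99)
  expect_identical(runif(1), before)
})

test_that("cohorts respect their structural invariants", {
  tam <- trial_schedule("big198", "TAM")
  coh <- generate_cohort(tam, base_params(), 20000, seed = 7)
  expect_true(all(coh$event_time_months > 0 &
                    coh$event_time_months <= coh$horizon_months))
  expect_true(all(coh$event_time_months[!coh$event_indicator] ==
                    coh$horizon_months))
  # empirical DM fraction within 4 binomial standard errors of f.DM
  f <- base_params()$f_dm
  se <- sqrt(f * (1 - f) / coh$n)
  expect_lt(abs(mean(coh$genotype == "DM") - f), 4 * se)
  # zero hazard: everyone administratively censored at the horizon
  zero <- hazard_schedule("TOY", "TAM", "DFS", c(0, 0))
  coh0 <- generate_cohort(zero, base_params(), 100, seed = 1)
  expect_true(all(!coh0$event_indicator))
  expect_true(all(coh0$event_time_months == 24))
  expect_error(generate_cohort(tam, base_params(), 0, seed = 1),
               "positive integer")
  expect_error(generate_cohort(tam, base_params(), 10, seed = "x"),
               "seed")
})

test_that("per-year event fractions match the generating annual probabilities", {
  tam <- trial_schedule("big198", "TAM")
  # dynamic decomposition makes the latent mixture reproduce the overall
  # schedule exactly at year boundaries, so among subjects at risk at a
  # year's start the event fraction estimates that year's annual rate
  coh <- generate_cohort(tam, base_params(), 100000, seed = 31,
                         method = "dynamic")
  t_years <- coh$event_time_months / 12
  for (y in seq_len(tam$horizon_years)) {
    at_risk <- sum(t_years > y - 1)
    events <- sum(coh$event_indicator & t_years > y - 1 & t_years <= y)
    h <- tam$annual_rates[y]
    se <- sqrt(h * (1 - h) / at_risk)
    expect_lt(abs(events / at_risk - h), 4 * se)
  }
})

test_that("the product-limit estimator matches its closed forms", {
  # three events, no censoring: steps 2/3, 1/3, 0
  km <- km_estimate(list(event_time_months = c(1, 2, 3),
                         event_indicator = c(TRUE, TRUE, TRUE)))
  expect_equal(km$surv, c(2, 1, 0) / 3)
  expect_equal(km_at(km, c(0, 1, 1.5, 3)), c(1, 2 / 3, 2 / 3, 0))
  # all censored: constant 1
  km0 <- km_estimate(list(event_time_months = c(5, 5, 5),
                          event_indicator = c(FALSE, FALSE, FALSE)))
  expect_equal(km_at(km0, c(0, 5)), c(1, 1))
  # ties and interleaved censoring: censored subjects leave the risk set
  # after same-time events
  km2 <- km_estimate(list(event_time_months = c(2, 2, 2, 4),
                          event_indicator = c(TRUE, TRUE, FALSE, TRUE)))
  expect_equal(km2$surv, c(1 - 2 / 4, (1 - 2 / 4) * (1 - 1 / 1)))
})

test_that("the product-limit estimator agrees with survival::survfit", {
  skip_if_not_installed("survival")
  coh <- generate_cohort(trial_schedule("big198", "TAM"), base_params(),
                         5000, seed = 3)
  fit <- survival::survfit(
    survival::Surv(coh$event_time_months, coh$event_indicator) ~ 1)
  km <- km_estimate(coh)
  expect_lt(max(abs(km_at(km, fit$time) - fit$surv)), 1e-12)
})

test_that("cohort KM converges to the cohort-model trace", {
  tam <- trial_schedule("big198", "TAM")
  coh <- generate_cohort(tam, base_params(), 50000, seed = 17)
  km60 <- km_at(km_estimate(coh), 60)
  sub <- decompose_static(tam, base_params())
  model60 <- 0.46 * survival_at(simulate_survival(sub$em), 60) +
    0.54 * survival_at(simulate_survival(sub$dm), 60)
  se <- sqrt(model60 * (1 - model60) / coh$n)
  expect_lt(abs(km60 - model60), 4 * se)
})

test_that("hazard-ratio recovery finds the generating value", {
  tam <- trial_schedule("big198", "TAM")
  coh <- generate_cohort(tam, base_params(), 50000, seed = 23)
  rec <- recover_hr(coh)
  expect_lt(abs(rec$estimate - 1.29), 0.1)
  expect_true(rec$ci[1] < rec$estimate & rec$estimate < rec$ci[2])
  # null effect: the interval straddles 1
  coh1 <- generate_cohort(tam, metabolizer_params(1, 0.54), 20000, seed = 5)
  rec1 <- recover_hr(coh1)
  expect_true(rec1$ci[1] <= 1 & 1 <= rec1$ci[2])
  # a class with no members or no events is an estimation error
  coh_em <- generate_cohort(tam, metabolizer_params(1.29, 0), 100, seed = 2)
  expect_error(recover_hr(coh_em), "DM")
  zero <- hazard_schedule("TOY", "TAM", "DFS", c(0, 0))
  coh0 <- generate_cohort(zero, base_params(), 100, seed = 1)
  expect_error(recover_hr(coh0), "zero events")
})

test_that("cohort CSV and sidecar round-trip the generating metadata", {
  tam <- trial_schedule("big198", "TAM")
  coh <- generate_cohort(tam, base_params(), 200, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  df <- read.csv(path)
  expect_named(df, c("subject_id", "genotype", "time_months", "event"))
  expect_equal(nrow(df), 200)
  expect_setequal(unique(df$genotype), c("EM", "DM"))
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(side$seed, 8)
  expect_equal(side$hr_dm, 1.29)
  expect_equal(side$schedule$annual_rates, tam$annual_rates)
})
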