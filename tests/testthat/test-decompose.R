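big_tam <- function() trial_schedule("big198", "TAM")

test_that("null and degenerate mixtures leave the schedule unchanged", {
  tam <- big_tam()
  for (method in c("static", "dynamic")) {
    sub <- decompose(tam, metabolizer_params(1, 0.54), method)
    expect_equal(sub$em$annual_rates, tam$annual_rates, tolerance = 1e-12)
    expect_equal(sub$dm$annual_rates, tam$annual_rates, tolerance = 1e-12)
  }
  # no DM patients: EM schedule is the overall schedule
  sub0 <- decompose_static(tam, metabolizer_params(1.8, 0))
  expect_equal(sub0$em$annual_rates, tam$annual_rates, tolerance = 1e-12)
  # subgroup schedules keep horizon/endpoint and gain arm tags
  expect_equal(sub0$em$horizon_years, tam$horizon_years)
  expect_equal(sub0$em$endpoint, tam$endpoint)
  expect_equal(sub0$em$arm, "TAM-EM")
  expect_equal(sub0$dm$arm, "TAM-DM")
})

test_that("static decomposition reproduces the base-case subgroup survivals", {
  sub <- decompose_static(big_tam(), metabolizer_params(1.29, 0.54))
  s_em <- annual_product_survival(sub$em$annual_rates)
  s_dm <- annual_product_survival(sub$dm$annual_rates)
  # closed form: exp(-Lambda / 1.1566) and exp(-1.29 Lambda / 1.1566)
  expect_equal(s_em, 0.83274740, tolerance = 1e-7)
  expect_equal(s_dm, 0.78970000, tolerance = 1e-7)
  # the EM value is the published 83.3%
  expect_equal(round_half_up(100 * s_em, 1), 83.3)
})

test_that("proportional hazards holds per year in both methods", {
  tam <- big_tam()
  for (method in c("static", "dynamic")) {
    for (hr in c(0.7, 1.29, 2.5)) {
      sub <- decompose(tam, metabolizer_params(hr, 0.54), method)
      expect_equal(prob_to_cumhaz(sub$dm$annual_rates),
                   hr * prob_to_cumhaz(sub$em$annual_rates),
                   tolerance = 1e-11)
    }
  }
})

test_that("dynamic decomposition reconstructs the overall survival exactly", {
  tam <- big_tam()
  p <- metabolizer_params(1.29, 0.54)
  dy <- decompose_dynamic(tam, p)
  mix <- 0.46 * cumprod(1 - dy$em$annual_rates) +
    0.54 * cumprod(1 - dy$dm$annual_rates)
  overall <- cumprod(1 - tam$annual_rates)
  expect_lt(max(abs(mix - overall)), 1e-10)
  expect_equal(mix[5], 0.80921824, tolerance = 1e-8)
  # agrees with an independent 200-step bisection
  oracle <- bisect_dynamic_em(tam$annual_rates, 1.29, 0.54)
  expect_equal(prob_to_cumhaz(dy$em$annual_rates), oracle$lam_em,
               tolerance = 1e-10)
  # depletion is second order at this horizon
  st <- decompose_static(tam, p)
  expect_lt(abs(annual_product_survival(st$em$annual_rates) -
                  annual_product_survival(dy$em$annual_rates)), 0.001)
})

test_that("subgroup survivals bracket the overall schedule", {
  tam <- big_tam()
  for (hr in c(1.29, 2.5)) {
    sub <- decompose_static(tam, metabolizer_params(hr, 0.54))
    s_em <- cumprod(1 - sub$em$annual_rates)
    s_dm <- cumprod(1 - sub$dm$annual_rates)
    s_all <- cumprod(1 - tam$annual_rates)
    expect_true(all(s_em >= s_all & s_all >= s_dm))
  }
  # ordering flips when DM fare better than EM
  sub <- decompose_static(tam, metabolizer_params(0.7, 0.54))
  s_em <- cumprod(1 - sub$em$annual_rates)
  s_dm <- cumprod(1 - sub$dm$annual_rates)
  expect_true(all(s_em <= cumprod(1 - tam$annual_rates)))
  expect_true(all(s_dm >= cumprod(1 - tam$annual_rates)))
})

test_that("EM survival increases in both hr and f over the sensitivity range", {
  tam <- trial_schedule("atac", "TAM")
  em_surv <- function(hr, f) {
    annual_product_survival(
      decompose_static(tam, metabolizer_params(hr, f))$em$annual_rates)
  }
  hr_axis <- seq(1.05, 3.05, by = 0.5)
  f_axis <- seq(0.2, 0.8, by = 0.1)
  m <- outer(f_axis, hr_axis, Vectorize(function(f, hr) em_surv(hr, f)))
  expect_true(all(apply(m, 1, diff) > 0))  # increasing in hr
  expect_true(all(apply(m, 2, diff) > 0))  # increasing in f (hr > 1)
})

test_that("mixture reconstruction error stays small over the full range", {
  for (trial in c("big198", "atac")) {
    tam <- trial_schedule(trial, "TAM")
    overall <- annual_product_survival(tam$annual_rates)
    for (hr in c(1, 1.5, 2.05, 3.05)) {
      for (f in c(0.2, 0.5, 0.8)) {
        p <- metabolizer_params(hr, f)
        st <- decompose_static(tam, p)
        err_st <- abs((1 - f) * annual_product_survival(st$em$annual_rates) +
                        f * annual_product_survival(st$dm$annual_rates) -
                        overall)
        expect_lt(err_st, 0.01)
        dy <- decompose_dynamic(tam, p)
        err_dy <- abs((1 - f) * annual_product_survival(dy$em$annual_rates) +
                        f * annual_product_survival(dy$dm$annual_rates) -
                        overall)
        expect_lt(err_dy, 1e-9)
      }
    }
  }
})

test_that("decomposing an AI arm warns that metabolizer status is ignored there", {
  expect_warning(decompose_static(trial_schedule("big198", "AI"),
                                  metabolizer_params(1.29, 0.54)),
                 "AI")
})
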