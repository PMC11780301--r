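test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- synth_config(n = 100, seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  # and the RNG state of the session is left untouched
  set.seed(99); before <- .Random.seed
  invisible(generate_cohort(cfg))
  expect_identical(.Random.seed, before)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(synth_config(n = 0), "`n`")
  expect_error(synth_config(missing_rate = 1.2), "`missing_rate`")
  expect_error(synth_config(confounding_strength = -1),
               "`confounding_strength`")
  expect_error(synth_config(wave = "2016"), "`wave`")
  expect_error(synth_config(tau_rural_only = NA), "`tau_rural_only`")
})

test_that("generated columns respect the codebook ranges", {
  coh <- generate_cohort(synth_config(n = 1500, seed = 3, missing_rate = 0.05,
                                      confounding_strength = 1.5))
  expect_equal(nrow(coh), 1500)
  expect_true(all(coh$age >= 50))
  expect_true(all(coh$sex %in% 0:1))
  expect_true(all(coh$education %in% 0:2))
  expect_true(all(coh$insurance %in% 1:3))
  expect_true(all(coh$region %in% 1:4))
  expect_true(all(coh$income >= 0))
  expect_true(all(coh$outpatient_visits >= 0 & coh$outpatient_visits <= 30))
  expect_true(all(coh$srh %in% 1:5 | is.na(coh$srh)))
  for (j in 1:6) {
    expect_true(all(coh[[paste0("adl", j)]] %in% 1:4 |
                      is.na(coh[[paste0("adl", j)]])))
    expect_true(all(coh[[paste0("iadl", j)]] %in% 1:4 |
                      is.na(coh[[paste0("iadl", j)]])))
  }
  expect_true(all(coh$mmse_total >= 0 & coh$mmse_total <= 30, na.rm = TRUE))
  # use items observed exactly for smart-device owners
  expect_true(all(is.na(coh$wechat) == (coh$n_smart_devices == 0)))
})

test_that("missing_rate = 0 leaves no missing cells in item columns", {
  coh <- generate_cohort(synth_config(n = 500, seed = 9, missing_rate = 0))
  items <- c("srh", paste0("adl", 1:6), paste0("iadl", 1:6), "mmse_total")
  expect_equal(sum(is.na(coh[items])), 0L)
  coh2 <- generate_cohort(synth_config(n = 500, seed = 9, missing_rate = 0.3))
  expect_gt(sum(is.na(coh2[items])), 0L)
})

test_that("wave prevalences are loosely calibrated to the survey margins", {
  c18 <- generate_cohort(synth_config(n = 1000, seed = 4, wave = "2018"))
  c20 <- generate_cohort(synth_config(n = 1000, seed = 4, wave = "2020"))
  expect_lt(abs(mean(c18$broadband) - 0.3922), 0.05)
  expect_lt(abs(mean(c20$broadband) - 0.5729), 0.05)
  expect_lt(abs(mean(c18$hukou) - 0.8437), 0.05)
  expect_lt(abs(mean(c18$n_smart_devices >= 1) - 0.105), 0.05)
  expect_lt(abs(mean(c20$n_smart_devices >= 1) - 0.355), 0.05)
})

test_that("with no confounding and no effect, health is balanced across arms", {
  coh <- derive_divide(score_health(generate_cohort(
    synth_config(n = 4000, seed = 5, treatment_effect_tau = 0,
                 confounding_strength = 0))))
  y <- coh$oriented_cognition
  d <- coh$access
  diff <- mean(y[d == 1]) - mean(y[d == 0])
  se <- sqrt(var(y[d == 1]) / sum(d == 1) + var(y[d == 0]) / sum(d == 0))
  expect_lt(abs(diff), 3 * se)
})

test_that("group-mean oriented health difference is monotone in tau", {
  diffs <- vapply(c(0.2, 0.6, 1.2), function(tau) {
    coh <- derive_divide(score_health(generate_cohort(
      synth_config(n = 4000, seed = 6, treatment_effect_tau = tau))))
    mean(coh$oriented_cognition[coh$access == 1]) -
      mean(coh$oriented_cognition[coh$access == 0])
  }, numeric(1))
  expect_true(all(diff(diffs) > 0))
})
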