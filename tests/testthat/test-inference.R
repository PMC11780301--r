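test_that("income is winsorized at 1/99 percentiles then log10(x+1) transformed", {
  expect_equal(trim_and_log_income(rep(9, 50)), rep(1, 50))   # no-op trim
  expect_equal(trim_and_log_income(c(0, rep(10, 200)))[1],
               log10(quantile(c(0, rep(10, 200)), 0.01, names = FALSE) + 1))
  x <- c(seq_len(200), 1e6)  # one extreme outlier at the max
  q99 <- quantile(x, 0.99, names = FALSE)
  expect_equal(trim_and_log_income(x)[201], log10(q99 + 1))
  expect_true(all(is.finite(trim_and_log_income(x))))
  expect_error(trim_and_log_income(c(NA, NA)), "entirely missing")
  expect_error(trim_and_log_income(c(-1, 2)), "nonnegative")
})

test_that("univariate screen picks the right test and handles degenerate inputs", {
  # independence: chi-square 0, p 1
  d <- data.frame(g = rep(0:1, each = 20), x = rep(rep(0:1, each = 10), 2))
  out <- univariate_screen(d, "g", "x")
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1)
  # perfect association: uncorrected chi-square = n = 40
  d2 <- data.frame(g = rep(0:1, each = 20), x = rep(0:1, each = 20))
  out2 <- univariate_screen(d2, "g", "x")
  expect_equal(out2$statistic, 40)
  expect_lt(out2$p, 0.001)
  # identical continuous samples: rank-sum p = 1
  z <- rexp(60)
  d3 <- data.frame(g = rep(0:1, each = 60), x = c(z, z))
  out3 <- univariate_screen(d3, "g", "x")
  expect_equal(out3$test, "Wilcoxon rank sum")
  expect_equal(out3$p, 1, tolerance = 1e-6)
  # normal samples get the t test
  set.seed(31)
  d4 <- data.frame(g = rep(0:1, each = 200), x = rnorm(400))
  expect_equal(univariate_screen(d4, "g", "x")$test, "t test")
  # degenerate margin skipped with warning
  d5 <- data.frame(g = rep(0:1, each = 10), x = rep(1, 20))
  expect_warning(out5 <- univariate_screen(d5, "g", "x"), "degenerate")
  expect_equal(nrow(out5), 0)
})

test_that("standardized OLS matches the normal-equations oracle", {
  set.seed(32)
  for (i in 1:10) {
    n <- 120
    X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4), c = rexp(n))
    y <- 1 + 0.5 * X[, 1] - X[, 2] + rnorm(n)
    d <- data.frame(y = y, X)
    fit <- rd_lm(y ~ a + b + c, d)
    expect_equal(unname(coef(fit)), unname(ols_oracle(y, X)),
                 tolerance = 1e-8)
  }
})

test_that("noise-free linear outcome gives standardized beta 1 and R2 1", {
  d <- data.frame(D = rep(0:1, 50))
  d$y <- 0.3 + 2 * d$D
  fit <- suppressWarnings(rd_lm(y ~ D, d, exposure = "D"))
  expect_equal(unname(coef(fit)["D"]), 1)
  expect_equal(fit$r.squared, 1)
})

test_that("permuted exposure is null: beta within 3 SE of zero", {
  set.seed(33)
  n <- 500
  d <- data.frame(y = rnorm(n), D = sample(rep(0:1, n / 2)), x = rnorm(n))
  fit <- rd_lm(y ~ D + x, d, exposure = "D")
  row <- fit$coefficients[fit$coefficients$term == "D", ]
  expect_lt(abs(row$beta), 3 * row$se)
})

test_that("standardized exposure beta is invariant to affine covariate rescaling", {
  set.seed(34)
  n <- 300
  d <- data.frame(y = rnorm(n), D = rbinom(n, 1, 0.5), age = runif(n, 50, 90))
  f1 <- rd_lm(y ~ D + age, d, exposure = "D")
  d2 <- d
  d2$age <- 12 * d2$age - 600   # months, shifted
  f2 <- rd_lm(y ~ D + age, d2, exposure = "D")
  expect_equal(coef(f1)["D"], coef(f2)["D"], tolerance = 1e-12)
  expect_equal(abs(coef(f1)["age"]), abs(coef(f2)["age"]), tolerance = 1e-12)
})

test_that("rank deficiency errors and names the collinear columns", {
  d <- data.frame(y = rnorm(50), a = rnorm(50), k = 1)
  expect_error(rd_lm(y ~ a + k, d), "k")
  d$b <- 2 * d$a
  expect_error(rd_lm(y ~ a + b, d), "b")
  # drop_constant instead recovers a reduced fit
  fit <- rd_lm(y ~ a + k, d, drop_constant = TRUE)
  expect_equal(fit$dropped, "k")
})

test_that("rd_lm methods are coherent on the original outcome scale", {
  set.seed(35)
  d <- data.frame(x = rnorm(80), z = rnorm(80))
  d$y <- 5 + 2 * d$x + rnorm(80)
  fit <- rd_lm(y ~ x + z, d)
  expect_equal(predict(fit), predict(fit, d), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unname(predict(fit) + residuals(fit)), d$y, tolerance = 1e-10)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(80, 2))
  expect_lt(abs(mean(sim[[1]]) - mean(d$y)), 1)
  expect_output(print(summary(fit)), "Standardized linear model")
})

test_that("moderation: null interaction is null, degenerate moderators error", {
  set.seed(36)
  n <- 600
  d <- data.frame(D = rbinom(n, 1, 0.5), m = rnorm(n))
  d$y <- 0.3 * d$D + 0.2 * d$m + rnorm(n)   # no interaction
  fit <- fit_moderation(y ~ D + m, d, exposure = "D", moderator = "m")
  row <- fit$coefficients[fit$coefficients$term == "D:m", ]
  expect_equal(nrow(row), 1)
  expect_lt(abs(row$beta), 3 * row$se)
  d$k <- 1
  expect_error(fit_moderation(y ~ D + m + k, d, "D", "k"), "constant")
  expect_error(fit_moderation(y ~ D + m, d, "D", "D"), "differ")
})

test_that("moderation recovers the sign of a sex-varying effect", {
  set.seed(37)
  hits <- 0
  for (i in 1:40) {
    n <- 1500
    d <- data.frame(D = rbinom(n, 1, 0.5), sex = rbinom(n, 1, 0.5))
    d$y <- 0.2 * d$D + 0.4 * d$D * d$sex + rnorm(n)  # positive Delta
    fit <- fit_moderation(y ~ D + sex, d, "D", "sex")
    b <- fit$coefficients$beta[fit$coefficients$term == "D:sex"]
    hits <- hits + (b > 0)
  }
  expect_gte(hits / 40, 0.95)
})

test_that("subgroup fits partition the sample and respect the size floor", {
  coh <- tiny_cohort(1200, seed = 44, confounding_strength = 0.5)
  dat <- prepare_analysis(coh, "cognition", "access")
  f <- reformulate(c("access", setdiff(control_terms(), "hukou")),
                   response = "rd")
  fits <- subgroup_fit(f, dat, dat$hukou, exposure = "access")
  expect_equal(sum(vapply(fits, `[[`, numeric(1), "n")), nrow(dat))
  # split on a constant column reduces to the full-sample fit
  one <- subgroup_fit(f, dat, rep(1, nrow(dat)), exposure = "access")
  full <- rd_lm(f, dat, exposure = "access")
  expect_equal(coef(one[["1"]]), coef(full))
  # tiny stratum skipped with warning
  s <- c(rep("big", nrow(dat) - 5), rep("small", 5))
  expect_warning(out <- subgroup_fit(f, dat, s), "below minimum size")
  expect_named(out, "big")
})

test_that("cohort-level fit wires deprivation outcome to the model", {
  coh <- tiny_cohort(800, seed = 45)
  fit <- fit_cohort(coh, "cognition", "access")
  expect_s3_class(fit, "rd_lm")
  expect_true("access" %in% fit$coefficients$term)
  expect_equal(fit$exposure, "access")
  # use-level analysis is restricted to the eligible subsample
  fit_use <- fit_cohort(coh, "srh", "use")
  d <- derive_divide(coh)
  expect_lte(fit_use$n, sum(d$eligibility_use == 1))
  expect_gt(fit$n, fit_use$n)
})
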