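test_that("propensity model degenerates gracefully and recovers known coefficients", {
  set.seed(51)
  n <- 800
  X <- cbind(x = rnorm(n))
  # null model limit: probabilities concentrate near mean(D)
  D0 <- rbinom(n, 1, 0.4)
  p0 <- estimate_propensity(D0, X)$propensity
  expect_lt(abs(mean(p0) - mean(D0)), 0.01)
  expect_lt(sd(p0), 0.1)
  # MLE recovery of a known logit within 3 SE
  b <- c(-0.3, 0.9)
  D <- rbinom(n, 1, plogis(b[1] + b[2] * X[, 1]))
  ps <- estimate_propensity(D, X)
  est <- coef(ps$fit)
  se <- sqrt(diag(vcov(ps$fit)))
  expect_true(all(abs(est - b) < 3 * se))
  # degenerate inputs
  expect_error(estimate_propensity(D, cbind(k = rep(1, n))), "constant")
  expect_error(estimate_propensity(rep(1, n), X), "nonempty")
  Xsep <- cbind(x = c(rnorm(100, -8), rnorm(100, 8)))
  Dsep <- rep(0:1, each = 100)
  expect_error(estimate_propensity(Dsep, Xsep), "separation")
})

test_that("nearest-neighbor matching follows the documented greedy rules", {
  # nearest control wins
  p <- c(0.8, 0.1, 0.79)
  D <- c(1, 0, 0)
  m <- match_nn(p, D)
  expect_equal(m$treated, 1)
  expect_equal(m$control, 3)
  # exact ties broken by lowest control index
  p2 <- c(0.5, 0.5, 0.5, 0.5)
  D2 <- c(1, 1, 0, 0)
  m2 <- match_nn(p2, D2)
  expect_equal(m2$control[m2$treated == 1], 3)
  expect_equal(m2$control[m2$treated == 2], 4)
  # caliper drops unmatched treated
  m3 <- match_nn(c(0.5, 0.45), c(1, 0), caliper = 0.01)
  expect_equal(nrow(m3), 0)
  expect_equal(attr(m3, "dropped_treated"), 1L)
  # surplus treated dropped with warning
  expect_warning(m4 <- match_nn(c(0.9, 0.8, 0.5), c(1, 1, 0)),
                 "fewer controls")
  expect_equal(nrow(m4), 1)
  expect_equal(attr(m4, "dropped_treated"), 1L)
  # every treated at most once; every partner an actual control
  set.seed(52)
  p5 <- runif(200)
  D5 <- rbinom(200, 1, 0.4)
  m5 <- match_nn(p5, D5)
  expect_false(any(duplicated(m5$treated)))
  expect_false(any(duplicated(m5$control)))
  expect_true(all(D5[m5$control] == 0))
  expect_true(all(D5[m5$treated] == 1))
  # determinism
  expect_identical(m5, match_nn(p5, D5))
})

test_that("ATT equals the matched mean difference with a paired test", {
  y <- c(2, 3, 5, 1, 0, 4)
  pairs <- data.frame(treated = c(1, 2, 3), control = c(4, 5, 6))
  a <- estimate_att(y, pairs)
  expect_equal(a$att, a$treated_mean - a$control_mean, tolerance = 1e-12)
  expect_equal(a$att, mean(c(2 - 1, 3 - 0, 5 - 4)))
  # constant differences: se 0, degenerate p, with warning
  y2 <- c(3, 4, 5, 1, 2, 3)
  expect_warning(a2 <- estimate_att(y2, pairs), "zero variance")
  expect_equal(a2$att, 2)
  expect_equal(a2$att_se, 0)
  expect_equal(a2$att_p, 0)
  expect_error(estimate_att(y, pairs[1, ]), "at least 2")
})

test_that("SMD balance table uses the pooled-variance formula", {
  # means 1 vs 0, both variances 1 -> SMD 1
  set.seed(53)
  x <- c(rnorm(4000, 1), rnorm(4000, 0))
  x <- (x - ave(x, rep(0:1, each = 4000))) +
    rep(c(1, 0), each = 4000)          # exact means
  g <- rep(c(1, 0), each = 4000)
  sd_pool <- sqrt((var(x[g == 1]) + var(x[g == 0])) / 2)
  X <- data.frame(x = x)
  pairs <- data.frame(treated = 1:100, control = 4001:4100)
  b <- balance_table(X, g, pairs)
  expect_equal(b$smd_before, 1 / sd_pool)
  # identical distributions -> SMD 0
  v <- rep(c(5, 7), 25)
  X2 <- data.frame(x = c(v, v))
  g2 <- rep(1:0, each = 50)
  b2 <- balance_table(X2, g2, data.frame(treated = which(g2 == 1)[1:10],
                                         control = which(g2 == 0)[1:10]))
  expect_equal(b2$smd_before, 0)
  # zero pooled variance: 0 when means equal, NA otherwise
  X3 <- data.frame(a = rep(1, 20), b = rep(c(0, 1), each = 10))
  g3 <- rep(c(1, 0), each = 10)
  pr <- data.frame(treated = 1:5, control = 11:15)
  b3 <- balance_table(X3, g3, pr)
  expect_equal(b3$smd_before[b3$covariate == "a"], 0)
  expect_true(is.na(b3$smd_before[b3$covariate == "b"]))
})

test_that("matching deconfounds a confounded synthetic cohort", {
  coh <- generate_cohort(synth_config(n = 2000, seed = 54,
                                      confounding_strength = 1.5))
  dat <- prepare_analysis(coh, "cognition", "access")
  D <- dat$access
  X <- dat[control_terms()]
  ps <- estimate_propensity(D, X)
  # arms are near-equal, so without-replacement matching needs a caliper
  # to be selective about controls
  pairs <- suppressWarnings(match_nn(ps$propensity, D, caliper = 0.02))
  bal <- balance_table(X, D, pairs, propensity = ps$propensity)
  conf <- c("edu_junior_plus", "age", "hukou", "log_income")
  rows <- bal[bal$covariate %in% conf, ]
  expect_true(all(rows$smd_after < rows$smd_before))
  expect_true(all(rows$smd_after < 0.20))
  expect_false(is.null(attr(bal, "support")))
})

test_that("randomized assignment: matched ATT agrees with the naive difference", {
  coh <- generate_cohort(synth_config(n = 3000, seed = 55,
                                      confounding_strength = 0,
                                      treatment_effect_tau = 0.5))
  dat <- prepare_analysis(coh, "cognition", "access")
  D <- dat$access
  naive <- mean(dat$rd[D == 1]) - mean(dat$rd[D == 0])
  ps <- estimate_propensity(D, dat[control_terms()])
  pairs <- suppressWarnings(match_nn(ps$propensity, D))
  a <- estimate_att(dat$rd, pairs)
  expect_lt(abs(a$att - naive), 3 * a$att_se)
})

test_that("rd_psm wraps the full matched analysis deterministically", {
  coh <- tiny_cohort(900, seed = 56, confounding_strength = 1)
  m1 <- suppressWarnings(rd_psm(coh, "cognition", "access"))
  m2 <- suppressWarnings(rd_psm(coh, "cognition", "access"))
  expect_identical(m1$pairs, m2$pairs)
  expect_identical(m1$att, m2$att)
  expect_equal(m1$att, m1$treated_mean - m1$control_mean, tolerance = 1e-12)
  expect_output(print(m1), "ATT")
  m3 <- suppressWarnings(rd_psm(coh, "srh", "use"))
  expect_true(m3$n <= sum(derive_divide(coh)$eligibility_use == 1))
})
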