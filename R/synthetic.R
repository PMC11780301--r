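# Wave-specific marginal prevalences the generator is calibrated to
# (loosely, +/- 5 points on each margin; joint structure is not targeted).
.wave_params <- list(
  "2018" = list(
    p_female = 0.5141, age_mean = 65.11, age_sd = 10.02,
    p_married = 0.7331,
    p_edu = c(0.2508, 0.4427, 0.3065),       # none / elementary / junior+
    p_rural = 0.8437,
    p_insurance = c(0.1025, 0.1147, 0.7828), # employee / resident / other
    p_chronic = 0.4643, p_disability = 0.1421, p_intergen = 0.6217,
    p_region = c(0.2733, 0.3168, 0.3456, 0.0643), # E / C / W / NE
    log_inc_mean = 0.71, log_inc_sd = 0.35, outpatient_mu = 0.39,
    p_broadband = 0.3922,
    p_smart1 = 0.1050, p_smart2_given = 0.1886,   # P(>=1), P(2 | >=1)
    p_digital1 = 0.08, p_digital2_given = 0.15,
    p_wechat_given = 0.933, p_moments_given = 0.734, p_pay_given = 0.518,
    srh_cum = c(0.105, 0.225, 0.694, 0.932),
    adl_a = c(-3.9, -3.7, -3.5, -3.4, -3.6, -3.8),
    iadl_a = c(-1.9, -1.7, -1.5, -1.6, -1.8, -1.6),
    mmse_center = 23.5
  ),
  "2020" = list(
    p_female = 0.5152, age_mean = 63.97, age_sd = 9.20,
    p_married = 0.8101,
    p_edu = c(0.2377, 0.4293, 0.3330),
    p_rural = 0.7768,
    p_insurance = c(0.1360, 0.8387, 0.0253),
    p_chronic = 0.4031, p_disability = 0.1469, p_intergen = 0.4346,
    p_region = c(0.3096, 0.3026, 0.3292, 0.0586),
    log_inc_mean = 0.72, log_inc_sd = 0.33, outpatient_mu = 0.49,
    p_broadband = 0.5729,
    p_smart1 = 0.3550, p_smart2_given = 0.0930,
    p_digital1 = 0.30, p_digital2_given = 0.12,
    p_wechat_given = 0.894, p_moments_given = 0.567, p_pay_given = 0.573,
    srh_cum = c(0.072, 0.272, 0.771, 0.891),
    adl_a = c(-3.4, -3.2, -3.0, -2.9, -3.1, -3.3),
    iadl_a = c(-2.7, -2.5, -2.3, -2.4, -2.6, -2.4),
    mmse_center = 20.0
  )
)

#' Configuration for the synthetic cohort generator
#'
#' Collects and validates the knobs of the generative model. The defaults,
#' together with the wave-specific prevalence tables, define the study
#' conditions every simulation in this package runs under.
#'
#' @param n number of respondents (>= 1).
#' @param seed integer RNG seed; identical `(config, seed)` reproduces the
#'   cohort byte-for-byte.
#' @param treatment_effect_tau additive shift of latent health (in latent
#'   SD units) for digitally connected persons; positive = health-raising.
#' @param confounding_strength nonnegative scalar scaling the effect of the
#'   education / age / hukou / income index on both the digital indicators
#'   (log-odds per index SD) and latent health.
#' @param missing_rate probability in \[0, 1\] of item-level missingness
#'   applied to self-rated health, the twelve ADL/iADL items and the
#'   cognitive total.
#' @param wave `"2018"` or `"2020"`, selecting the marginal prevalence
#'   table (e.g. broadband prevalence near 39% vs 57%).
#' @param tau_rural_only if `TRUE`, the treatment effect applies only to
#'   rural-hukou respondents (a known-heterogeneity benchmark).
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n = 1000, seed = 1, treatment_effect_tau = 0,
                         confounding_strength = 0, missing_rate = 0,
                         wave = "2018", tau_rural_only = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("invalid configuration field `n`: must be a single integer >= 1",
         call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed))
    stop("invalid configuration field `seed`: must be a single integer",
         call. = FALSE)
  if (!is.numeric(treatment_effect_tau) || length(treatment_effect_tau) != 1L ||
      !is.finite(treatment_effect_tau))
    stop("invalid configuration field `treatment_effect_tau`: must be a finite number",
         call. = FALSE)
  if (!is.numeric(confounding_strength) || length(confounding_strength) != 1L ||
      !is.finite(confounding_strength) || confounding_strength < 0)
    stop("invalid configuration field `confounding_strength`: must be a finite number >= 0",
         call. = FALSE)
  if (!is.numeric(missing_rate) || length(missing_rate) != 1L ||
      is.na(missing_rate) || missing_rate < 0 || missing_rate > 1)
    stop("invalid configuration field `missing_rate`: must be in [0, 1]",
         call. = FALSE)
  wave <- as.character(wave)
  if (length(wave) != 1L || !wave %in% names(.wave_params))
    stop("invalid configuration field `wave`: must be one of ",
         paste(names(.wave_params), collapse = ", "), call. = FALSE)
  if (!is.logical(tau_rural_only) || length(tau_rural_only) != 1L ||
      is.na(tau_rural_only))
    stop("invalid configuration field `tau_rural_only`: must be TRUE or FALSE",
         call. = FALSE)
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         treatment_effect_tau = treatment_effect_tau,
         confounding_strength = confounding_strength,
         missing_rate = missing_rate, wave = wave,
         tau_rural_only = tau_rural_only),
    class = "synth_config"
  )
}

with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic older-adult cohort
#'
#' Draws a person-level survey table mimicking a Chinese ageing cohort:
#' demographics, digital access/use indicators and four health instruments,
#' with known ground-truth structure. Digital indicators and latent health
#' both load (with weight `confounding_strength`) on a common standardized
#' index of education, age, hukou and log-income, so treatment assignment
#' is confounded by construction; `treatment_effect_tau` shifts latent
#' health additively for digitally connected persons (those with `access`
#' = 1). Latent health is mapped monotonically onto the self-rated health
#' level, the twelve ADL/iADL items, and the cognitive total. Use items
#' (WeChat, Moments, mobile payment) are observed only for smart-device
#' owners, mirroring the "Unknown" pattern of device non-owners in survey
#' tables. All ages are >= 50.
#'
#' @param config a [synth_config()] object.
#' @return A data.frame with one row per respondent and the documented
#'   column dictionary (see [cohort_dictionary()]); the config is attached
#'   as attribute `"config"`.
#' @examples
#' coh <- generate_cohort(synth_config(n = 200, seed = 7))
#' table(coh$broadband)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config"))
    config <- do.call(synth_config, as.list(config))
  wp <- .wave_params[[config$wave]]
  n <- config$n
  cs <- config$confounding_strength
  tau <- config$treatment_effect_tau

  with_local_seed(config$seed, {
    sex <- stats::rbinom(n, 1, 1 - wp$p_female)          # male = 1
    shape <- ((wp$age_mean - 50) / wp$age_sd)^2
    scale_ <- (wp$age_mean - 50) / shape
    age <- pmin(50 + stats::rgamma(n, shape = shape, scale = scale_), 105)
    marital <- stats::rbinom(n, 1, wp$p_married)
    education <- sample.int(3L, n, replace = TRUE, prob = wp$p_edu) - 1L
    hukou <- stats::rbinom(n, 1, wp$p_rural)             # 1 = rural
    insurance <- sample.int(3L, n, replace = TRUE, prob = wp$p_insurance)
    chronic <- stats::rbinom(n, 1, wp$p_chronic)
    disability <- stats::rbinom(n, 1, wp$p_disability)
    intergen <- stats::rbinom(n, 1, wp$p_intergen)
    region <- sample.int(4L, n, replace = TRUE, prob = wp$p_region)
    income <- pmax(10^stats::rnorm(n, wp$log_inc_mean, wp$log_inc_sd) - 1, 0)
    outpatient <- pmin(stats::rnbinom(n, mu = wp$outpatient_mu, size = 0.3),
                       30L)

    # shared confounding index: educated, younger, urban, richer persons are
    # both more connected and healthier; centered and scaled within sample
    # so marginal prevalence calibration survives confounding_strength > 0
    idx <- 0.6 * (education - 1) - 0.04 * (age - 64) - 0.5 * hukou +
      0.4 * log10(income + 1)
    if (n > 1L && stats::sd(idx) > 0) idx <- (idx - mean(idx)) / stats::sd(idx)
    else idx <- rep(0, n)

    broadband <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(wp$p_broadband) + cs * idx))
    smart_any <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(wp$p_smart1) + cs * idx))
    n_smart <- smart_any * (1L + stats::rbinom(n, 1, wp$p_smart2_given))
    dig_any <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(wp$p_digital1) + cs * idx))
    n_digital <- dig_any * (1L + stats::rbinom(n, 1, wp$p_digital2_given))

    wechat <- moments <- mobile_pay <- rep(NA_integer_, n)
    el <- which(n_smart >= 1L)
    if (length(el) > 0L) {
      wechat[el] <- stats::rbinom(length(el), 1,
        stats::plogis(stats::qlogis(wp$p_wechat_given) + 0.5 * cs * idx[el]))
      moments[el] <- stats::rbinom(length(el), 1,
        stats::plogis(stats::qlogis(wp$p_moments_given) + 0.5 * cs * idx[el]))
      mobile_pay[el] <- stats::rbinom(length(el), 1,
        stats::plogis(stats::qlogis(wp$p_pay_given) + 0.5 * cs * idx[el]))
    }

    access <- as.integer(broadband >= 1 | n_smart >= 1 | n_digital >= 1)
    treated <- if (config$tau_rural_only) access * hukou else access

    # latent health: confounded baseline + treatment shift + unit noise
    h <- 0.5 * cs * idx + tau * treated + stats::rnorm(n)

    srh_lat <- h + stats::rnorm(n, 0, 0.8)
    srh <- findInterval(srh_lat, stats::qnorm(wp$srh_cum) * sqrt(1.64)) + 1L

    adl <- matrix(0L, n, 6)
    iadl <- matrix(0L, n, 6)
    for (j in 1:6) {
      adl[, j] <- 1L + stats::rbinom(n, 3, stats::plogis(wp$adl_a[j] - 1.1 * h))
      iadl[, j] <- 1L + stats::rbinom(n, 3, stats::plogis(wp$iadl_a[j] - 1.1 * h))
    }
    mmse <- as.integer(round(pmin(30, pmax(0,
      wp$mmse_center + 3 * h + stats::rnorm(n, 0, 4.5)))))

    out <- data.frame(
      sex = sex, age = age, marital = marital, education = education,
      hukou = hukou, insurance = insurance, chronic = chronic,
      disability = disability, intergenerational_support = intergen,
      region = region, income = income, outpatient_visits = outpatient,
      broadband = broadband, n_smart_devices = n_smart,
      n_digital_devices = n_digital, wechat = wechat, moments = moments,
      mobile_pay = mobile_pay, srh = srh
    )
    colnames(adl) <- paste0("adl", 1:6)
    colnames(iadl) <- paste0("iadl", 1:6)
    out <- cbind(out, adl, iadl, mmse_total = mmse)

    if (config$missing_rate > 0) {
      for (col in c("srh", paste0("adl", 1:6), paste0("iadl", 1:6),
                    "mmse_total")) {
        hit <- stats::runif(n) < config$missing_rate
        out[[col]][hit] <- NA
      }
    }
    attr(out, "config") <- config
    out
  })
}

#' Column dictionary for the synthetic cohort table
#'
#' @return A data.frame describing every cohort column: name, type and
#'   codebook. Written as a JSON sidecar by [run_pipeline()].
#' @export
cohort_dictionary <- function() {
  data.frame(
    column = c("sex", "age", "marital", "education", "hukou", "insurance",
               "chronic", "disability", "intergenerational_support", "region",
               "income", "outpatient_visits", "broadband", "n_smart_devices",
               "n_digital_devices", "wechat", "moments", "mobile_pay", "srh",
               paste0("adl", 1:6), paste0("iadl", 1:6), "mmse_total"),
    type = c("binary", "continuous", "binary", "categorical", "binary",
             "categorical", "binary", "binary", "binary", "categorical",
             "continuous", "count", "binary", "count", "count",
             "binary", "binary", "binary", "ordinal",
             rep("ordinal", 12), "count"),
    codebook = c(
      "male=1, female=0", "years, >= 50", "married=1, unmarried=0",
      "0=no formal education, 1=elementary, 2=junior high and above",
      "0=urban, 1=rural",
      "1=urban employee, 2=urban and rural resident, 3=other",
      "chronic disease yes=1", "disability yes=1",
      "strong intergenerational support=1",
      "1=eastern, 2=central, 3=western, 4=northeast",
      "total family income, nonnegative", "per month, 0-30",
      "home broadband yes=1", "count >= 0", "count >= 0",
      "uses WeChat=1; NA if no smart device",
      "posts Moments=1; NA if no smart device",
      "uses mobile payment=1; NA if no smart device",
      "self-rated health 1=very unhealthy .. 5=very healthy",
      rep("1=no difficulty .. 4=unable", 12),
      "cognitive screen total 0-30, higher = better"),
    stringsAsFactors = FALSE
  )
}

#' Calibrate the latent treatment effect to a target standardized beta
#'
#' The generator's `treatment_effect_tau` acts on latent health, which maps
#' nonlinearly onto the deprivation-index outcome; this helper finds, by a
#' secant search on large pilot cohorts with common random numbers, the tau
#' whose fully standardized exposure coefficient in the covariate-adjusted
#' deprivation regression equals `target_beta`.
#'
#' @param target_beta desired standardized exposure coefficient (e.g.
#'   -0.05: access lowers deprivation by 0.05 outcome SD).
#' @param config base [synth_config()]; its `n`, `seed` and tau are
#'   overridden during calibration.
#' @param dimension health dimension whose deprivation index is the outcome.
#' @param n_pilot pilot cohort size per secant evaluation.
#' @param seed pilot seed (held fixed across evaluations so the beta(tau)
#'   curve is smooth).
#' @param tol convergence tolerance on the fitted beta.
#' @param max_iter maximum secant iterations.
#' @return The calibrated tau (numeric scalar), with the achieved pilot
#'   beta as attribute `"beta"`.
#' @export
calibrate_tau <- function(target_beta, config = synth_config(),
                          dimension = "cognition", n_pilot = 200000,
                          seed = 1, tol = 0.002, max_iter = 8) {
  eval_beta <- function(tau) {
    cfg <- config
    cfg$n <- as.integer(n_pilot)
    cfg$seed <- as.integer(seed)
    cfg$treatment_effect_tau <- tau
    fit <- fit_cohort(generate_cohort(cfg), dimension, exposure = "access")
    fit$coefficients$beta[fit$coefficients$term == "access"]
  }
  t0 <- 0; b0 <- eval_beta(t0)
  t1 <- if (target_beta < b0) 0.5 else -0.5
  b1 <- eval_beta(t1)
  for (i in seq_len(max_iter)) {
    if (abs(b1 - target_beta) < tol) break
    t2 <- t1 + (target_beta - b1) * (t1 - t0) / (b1 - b0)
    t0 <- t1; b0 <- b1
    t1 <- t2; b1 <- eval_beta(t1)
  }
  structure(t1, beta = b1)
}
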