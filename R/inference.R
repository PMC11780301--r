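#' Winsorize and log-transform income
#'
#' Total family income is bilaterally trimmed (winsorized) at the 1st and
#' 99th percentiles and then compressed with `log10(x + 1)`, so that a zero
#' income maps to 0 and the transformed scale matches the ~0.7 mean typical
#' of survey income in 10k-yuan units.
#'
#' @param income nonnegative numeric vector (`NA` allowed, preserved).
#' @param probs length-2 winsorization probabilities, default `c(.01, .99)`.
#' @return The transformed vector, finite wherever `income` is observed.
#' @export
trim_and_log_income <- function(income, probs = c(0.01, 0.99)) {
  if (all(is.na(income)))
    stop("income column is entirely missing", call. = FALSE)
  if (any(income < 0, na.rm = TRUE))
    stop("income must be nonnegative", call. = FALSE)
  q <- stats::quantile(income, probs, na.rm = TRUE, names = FALSE)
  log10(pmin(pmax(income, q[1]), q[2]) + 1)
}

#' Univariate screening of covariates against a binary exposure
#'
#' For each variable: categorical variables get an (uncorrected) chi-square
#' test of independence; continuous variables get a two-sample t test when
#' both groups pass a Shapiro-Wilk normality check (on a subsample of at
#' most 5000 per group), otherwise a Wilcoxon rank-sum test. All tests are
#' two-tailed; significance at alpha = .05.
#'
#' @param data a data.frame.
#' @param group name of the binary 0/1 grouping column.
#' @param vars character vector of columns to screen.
#' @param types optional named character vector (`"categorical"` /
#'   `"continuous"`) overriding automatic typing (numeric with > 10 unique
#'   values = continuous).
#' @param alpha significance level (two-tailed).
#' @return A data.frame with one row per screened variable: test name,
#'   statistic, p value and significance flag. Variables with a degenerate
#'   contingency margin are skipped with a warning.
#' @export
univariate_screen <- function(data, group, vars, types = NULL, alpha = 0.05) {
  g <- data[[group]]
  if (is.null(g) || length(unique(stats::na.omit(g))) != 2L)
    stop("`group` must name a binary column", call. = FALSE)
  rows <- list()
  for (v in vars) {
    x <- data[[v]]
    keep <- !is.na(x) & !is.na(g)
    xv <- x[keep]; gv <- g[keep]
    type <- if (!is.null(types) && v %in% names(types)) types[[v]]
            else if (is.numeric(xv) && length(unique(xv)) > 10L) "continuous"
            else "categorical"
    if (type == "categorical") {
      tab <- table(xv, gv)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
          nrow(tab) < 2L || ncol(tab) < 2L) {
        warning("skipping `", v, "`: degenerate contingency table",
                call. = FALSE)
        next
      }
      tt <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      rows[[v]] <- data.frame(variable = v, type = type, test = "chi-square",
                              statistic = unname(tt$statistic),
                              p = tt$p.value)
    } else {
      x0 <- xv[gv == sort(unique(gv))[1]]
      x1 <- xv[gv == sort(unique(gv))[2]]
      normal <- function(z) {
        if (length(unique(z)) < 3L) return(FALSE)
        z <- if (length(z) > 5000L) z[seq(1L, length(z), length.out = 5000L)]
             else z
        stats::shapiro.test(z)$p.value > 0.05
      }
      if (normal(x0) && normal(x1)) {
        tt <- stats::t.test(x0, x1)
        test <- "t test"
      } else {
        tt <- suppressWarnings(stats::wilcox.test(x0, x1, exact = FALSE))
        test <- "Wilcoxon rank sum"
      }
      rows[[v]] <- data.frame(variable = v, type = type, test = test,
                              statistic = unname(tt$statistic),
                              p = tt$p.value)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(variable = character(),
                                      type = character(), test = character(),
                                      statistic = numeric(), p = numeric(),
                                      significant = logical()))
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Fully standardized linear model for a deprivation outcome
#'
#' Ordinary least squares with classical (homoskedastic) standard errors,
#' reported on the fully standardized scale: the outcome and every
#' regressor -- continuous, binary and dummy alike -- are z-scored before
#' fitting, so coefficients are comparable across terms and invariant to
#' affine rescaling of any covariate. Cases with a missing value in any
#' model variable are dropped listwise.
#'
#' @param formula model formula, e.g. `rd ~ access + sex + age + ...`.
#' @param data a data.frame.
#' @param exposure optional name of the term of interest (stored for
#'   reporting; e.g. `"access"`).
#' @param drop_constant if `TRUE`, regressors constant in the analysis
#'   sample are silently dropped (recorded in `$dropped`) instead of
#'   raising a rank-deficiency error. Used for small subgroup fits.
#' @return An object of class `"rd_lm"`: coefficient table (`term`, `beta`,
#'   `se`, `statistic`, `p`), `n`, `r.squared`, the underlying `lm` fit on
#'   the standardized scale, and the standardization constants.
#' @examples
#' d <- data.frame(y = rnorm(100), x = rnorm(100))
#' fit <- rd_lm(y ~ x, d, exposure = "x")
#' coef(fit)
#' @export
rd_lm <- function(formula, data, exposure = NULL, drop_constant = FALSE) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  has_int <- "(Intercept)" %in% colnames(X)
  Xr <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  n <- nrow(Xr)
  if (n <= ncol(Xr) + has_int)
    stop("not enough cases (", n, ") for ", ncol(Xr), " terms", call. = FALSE)

  sds <- apply(Xr, 2, stats::sd)
  dropped <- character(0)
  if (any(sds == 0)) {
    if (!drop_constant)
      stop("constant or collinear columns in design: ",
           paste(colnames(Xr)[sds == 0], collapse = ", "), call. = FALSE)
    dropped <- colnames(Xr)[sds == 0]
    Xr <- Xr[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  mus <- colMeans(Xr)
  Z <- sweep(sweep(Xr, 2, mus), 2, sds, "/")

  qrz <- qr(cbind(1, Z))
  if (qrz$rank < ncol(Z) + 1L) {
    bad <- colnames(Z)[qrz$pivot[seq(qrz$rank + 1L, ncol(Z) + 1L)] - 1L]
    if (!drop_constant)
      stop("rank-deficient design; collinear columns: ",
           paste(bad, collapse = ", "), call. = FALSE)
    dropped <- c(dropped, bad)
    Z <- Z[, setdiff(colnames(Z), bad), drop = FALSE]
    mus <- mus[colnames(Z)]; sds <- sds[colnames(Z)]
  }

  y_mu <- mean(y); y_sd <- stats::sd(y)
  if (y_sd == 0) stop("outcome is constant", call. = FALSE)
  yz <- (y - y_mu) / y_sd

  dfit <- data.frame(.y = yz, Z, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = dfit)
  sm <- summary(fit)
  ct <- sm$coefficients[rownames(sm$coefficients) != "(Intercept)", ,
                        drop = FALSE]
  coefs <- data.frame(term = rownames(ct), beta = ct[, 1], se = ct[, 2],
                      statistic = ct[, 3], p = ct[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)

  structure(
    list(coefficients = coefs, n = n, r.squared = sm$r.squared,
         fit = fit, exposure = exposure, dropped = dropped,
         call = match.call(), formula = formula,
         scaling = list(y_mu = y_mu, y_sd = y_sd, x_mu = mus, x_sd = sds)),
    class = "rd_lm"
  )
}

#' @export
print.rd_lm <- function(x, digits = 4, ...) {
  cat("Standardized linear model")
  if (!is.null(x$exposure)) cat(" (exposure: ", x$exposure, ")", sep = "")
  cat("\n  n =", x$n, " R-squared =", signif(x$r.squared, digits), "\n\n")
  tab <- x$coefficients
  tab$beta <- signif(tab$beta, digits)
  tab$se <- signif(tab$se, digits)
  tab$p <- signif(tab$p, digits)
  print(tab[, c("term", "beta", "se", "p")], row.names = FALSE)
  if (length(x$dropped) > 0L)
    cat("  dropped constant/collinear terms:",
        paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.rd_lm <- function(object, ...) {
  object$sigma <- summary(object$fit)$sigma
  class(object) <- c("summary.rd_lm", "rd_lm")
  object
}

#' @export
print.summary.rd_lm <- function(x, ...) {
  NextMethod()
  cat("  residual SD (standardized scale):", signif(x$sigma, 4), "\n")
  invisible(x)
}

#' @export
coef.rd_lm <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$term)
}

#' @export
predict.rd_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(object$scaling$y_mu +
             object$scaling$y_sd * stats::fitted(object$fit))
  X <- stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                           newdata)
  Xr <- X[, names(object$scaling$x_mu), drop = FALSE]
  Z <- sweep(sweep(Xr, 2, object$scaling$x_mu), 2, object$scaling$x_sd, "/")
  pz <- as.vector(cbind(1, Z) %*% stats::coef(object$fit))
  object$scaling$y_mu + object$scaling$y_sd * pz
}

#' @export
residuals.rd_lm <- function(object, ...) {
  object$scaling$y_sd * stats::residuals(object$fit)
}

#' @export
plot.rd_lm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(stats::fitted(x$fit), stats::residuals(x$fit),
                 xlab = "fitted (std)", ylab = "residual (std)",
                 main = "Residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  stats::qqnorm(stats::residuals(x$fit), main = "Normal Q-Q")
  stats::qqline(stats::residuals(x$fit))
  invisible(x)
}

#' @export
simulate.rd_lm <- function(object, nsim = 1, seed = NULL, ...) {
  sims <- stats::simulate(object$fit, nsim = nsim, seed = seed, ...)
  as.data.frame(lapply(sims, function(s)
    object$scaling$y_mu + object$scaling$y_sd * s))
}

# canonical control-variable block for ageing-cohort analyses, with dummy
# coding: education ref = none, insurance ref = other, region ref = eastern
build_controls <- function(cohort) {
  data.frame(
    sex = cohort$sex, age = cohort$age, hukou = cohort$hukou,
    edu_elementary = as.integer(cohort$education == 1L),
    edu_junior_plus = as.integer(cohort$education == 2L),
    marital = cohort$marital,
    ins_employee = as.integer(cohort$insurance == 1L),
    ins_resident = as.integer(cohort$insurance == 2L),
    chronic = cohort$chronic, disability = cohort$disability,
    outpatient_visits = cohort$outpatient_visits,
    intergenerational_support = cohort$intergenerational_support,
    log_income = trim_and_log_income(cohort$income),
    region_central = as.integer(cohort$region == 2L),
    region_western = as.integer(cohort$region == 3L),
    region_northeast = as.integer(cohort$region == 4L)
  )
}

control_terms <- function() {
  c("sex", "age", "hukou", "edu_elementary", "edu_junior_plus", "marital",
    "ins_employee", "ins_resident", "chronic", "disability",
    "outpatient_visits", "intergenerational_support", "log_income",
    "region_central", "region_western", "region_northeast")
}

#' Assemble the analysis table for one health dimension
#'
#' Scores the cohort, derives the divide indicators, builds the control
#' block, computes the Kakwani deprivation index of the oriented dimension
#' on that dimension's listwise-complete analysis sample, and returns the
#' analysis data.frame with an `rd` outcome column.
#'
#' @param cohort a raw cohort data.frame.
#' @param dimension `"srh"`, `"adl"`, `"iadl"` or `"cognition"`.
#' @param exposure `"access"` (full sample) or `"use"` (restricted to
#'   records with all three use items observed; exposure column is the 0-3
#'   `use_score`).
#' @return A data.frame with columns `rd`, the exposure, and the controls;
#'   attribute `"kakwani"` holds the [kakwani_rd()] object.
#' @export
prepare_analysis <- function(cohort, dimension, exposure = c("access", "use")) {
  exposure <- match.arg(exposure)
  dimension <- match.arg(dimension, c("srh", "adl", "iadl", "cognition"))
  scored <- derive_divide(score_health(cohort))
  ycol <- paste0("oriented_", dimension)
  expo_col <- if (exposure == "access") "access" else "use_score"
  dat <- cbind(scored[c(ycol, expo_col)], build_controls(scored))
  names(dat)[1:2] <- c(".y", exposure)
  keep <- stats::complete.cases(dat)
  dat <- dat[keep, , drop = FALSE]
  if (nrow(dat) < 2L)
    stop("fewer than 2 complete cases for dimension ", dimension,
         call. = FALSE)
  k <- kakwani_rd(dat$.y, dimension = dimension)
  dat$rd <- k$rd
  dat$.y <- NULL
  attr(dat, "kakwani") <- k
  dat
}

#' Fit the deprivation regression for one dimension of a cohort
#'
#' Convenience wrapper: [prepare_analysis()] then [rd_lm()] of the
#' deprivation index on the exposure plus the full control block.
#'
#' @inheritParams prepare_analysis
#' @return An [rd_lm] fit; the exposure term carries the fully
#'   standardized association between the digital indicator and the
#'   deprivation index.
#' @export
fit_cohort <- function(cohort, dimension, exposure = c("access", "use")) {
  exposure <- match.arg(exposure)
  dat <- prepare_analysis(cohort, dimension, exposure)
  f <- stats::reformulate(c(exposure, control_terms()), response = "rd")
  rd_lm(f, dat, exposure = exposure)
}

#' Moderation (interaction) analysis
#'
#' Tests whether a covariate moderates the exposure-deprivation
#' association by adding the product of the centered exposure and centered
#' moderator to the model. The interaction term is reported alongside the
#' main effects.
#'
#' @param formula base model formula (exposure and moderator must appear
#'   among its terms).
#' @param data a data.frame.
#' @param exposure name of the exposure column.
#' @param moderator name of the moderating covariate (distinct from the
#'   exposure, non-constant).
#' @return An [rd_lm] fit whose table includes the
#'   `<exposure>:<moderator>` interaction term.
#' @export
fit_moderation <- function(formula, data, exposure, moderator) {
  if (identical(moderator, exposure))
    stop("moderator must differ from the exposure", call. = FALSE)
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  if (!moderator %in% names(mf) || !exposure %in% names(mf))
    stop("exposure and moderator must be terms of the model", call. = FALSE)
  if (stats::sd(mf[[moderator]]) == 0)
    stop("moderator `", moderator, "` is constant in the analysis sample",
         call. = FALSE)
  iname <- paste0(exposure, ":", moderator)
  mf[[".interaction"]] <- (mf[[exposure]] - mean(mf[[exposure]])) *
    (mf[[moderator]] - mean(mf[[moderator]]))
  resp <- as.character(formula[[2]])
  f2 <- stats::reformulate(setdiff(names(mf), resp), response = resp)
  fit <- rd_lm(f2, mf, exposure = iname)
  fit$coefficients$term[fit$coefficients$term == ".interaction"] <- iname
  names(fit$scaling$x_mu)[names(fit$scaling$x_mu) == ".interaction"] <- iname
  names(fit$scaling$x_sd)[names(fit$scaling$x_sd) == ".interaction"] <- iname
  fit
}

#' Subgroup (heterogeneity) fits
#'
#' Refits the deprivation regression within each level of a splitting
#' variable (sex, age bands, hukou, education, region, ...). Subgroups
#' smaller than `min_n` are skipped with a warning. Within-stratum constant
#' dummies are dropped rather than erroring (a region dummy is necessarily
#' constant inside its own region subgroup).
#'
#' @param formula model formula passed to [rd_lm()].
#' @param data a data.frame.
#' @param split name of the column to split on (each unique value is one
#'   subgroup), or a vector of the same length as `data`.
#' @param exposure exposure term name, for reporting.
#' @param min_n minimum subgroup size (default 50).
#' @return A named list of [rd_lm] fits, one per retained level.
#' @export
subgroup_fit <- function(formula, data, split, exposure = NULL, min_n = 50) {
  s <- if (length(split) == 1L && is.character(split)) data[[split]] else split
  if (is.null(s)) stop("unknown split column", call. = FALSE)
  out <- list()
  for (lev in sort(unique(stats::na.omit(s)))) {
    sub <- data[!is.na(s) & s == lev, , drop = FALSE]
    if (nrow(sub) < min_n) {
      warning("subgroup `", lev, "` below minimum size (", nrow(sub), " < ",
              min_n, "); skipped", call. = FALSE)
      next
    }
    out[[as.character(lev)]] <- rd_lm(formula, sub, exposure = exposure,
                                      drop_constant = TRUE)
  }
  out
}

#' Split age at 60
#'
#' @param age numeric vector of ages.
#' @return Character vector `"<60"` / `">=60"`.
#' @export
age_band <- function(age) ifelse(age < 60, "<60", ">=60")
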