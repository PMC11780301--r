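#' Estimate propensity scores by logistic regression
#'
#' Fits a maximum-likelihood logit of treatment on the covariates and
#' returns the fitted probabilities. Errors on degenerate designs (constant
#' columns, rank deficiency) and on (quasi-)perfect separation, which makes
#' the MLE diverge.
#'
#' @param D 0/1 treatment vector, both arms nonempty.
#' @param X covariate matrix or data.frame (numeric), full column rank.
#' @return A list with `propensity` (probabilities strictly inside (0, 1)),
#'   the underlying `glm` `fit`, and `converged`.
#' @export
estimate_propensity <- function(D, X) {
  if (!all(D %in% c(0, 1))) stop("`D` must be 0/1", call. = FALSE)
  if (sum(D == 1) == 0L || sum(D == 0) == 0L)
    stop("both treatment arms must be nonempty", call. = FALSE)
  X <- as.matrix(X)
  if (nrow(X) != length(D)) stop("X rows must match D", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s) in X: ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("X is rank deficient; remove collinear covariates", call. = FALSE)
  dat <- data.frame(.D = D, X, check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(.D ~ ., data = dat, family = stats::binomial())
  )
  p <- stats::fitted(fit)
  eps <- 1e-8
  if (!fit$converged || any(p < eps) || any(p > 1 - eps))
    stop("perfect (or quasi-perfect) separation detected; ",
         "reduce or coarsen the propensity covariates", call. = FALSE)
  list(propensity = unname(p), fit = fit, converged = fit$converged)
}

#' Greedy 1:1 nearest-neighbor matching on the propensity score
#'
#' Treated units are processed in descending propensity order (ties broken
#' by lowest index) and each is paired, without replacement, with the
#' not-yet-used control whose propensity score is nearest (ties broken by
#' lowest control index). With a caliper, treated units whose nearest
#' available control lies farther than the caliper are dropped. The
#' procedure is fully deterministic.
#'
#' @param propensity numeric vector of propensity scores.
#' @param D 0/1 treatment vector.
#' @param caliper optional maximum |propensity difference|; default none.
#' @return A data.frame of `pairs` (`treated`, `control`, `distance`) with
#'   attribute `"dropped_treated"` (count of unmatched treated units).
#' @export
match_nn <- function(propensity, D, caliper = NULL) {
  if (length(propensity) != length(D))
    stop("propensity and D must have equal length", call. = FALSE)
  ti <- which(D == 1)
  ci <- which(D == 0)
  if (length(ti) == 0L) stop("treated arm is empty", call. = FALSE)
  if (length(ti) > length(ci) && is.null(caliper))
    warning("fewer controls (", length(ci), ") than treated (", length(ti),
            "); surplus treated units are dropped", call. = FALSE)
  ord <- ti[order(-propensity[ti], ti)]
  avail <- rep(TRUE, length(ci))
  pc <- propensity[ci]
  treated <- control <- integer(0)
  dist <- numeric(0)
  dropped <- 0L
  for (t in ord) {
    if (!any(avail)) { dropped <- dropped + 1L; next }
    d <- abs(pc - propensity[t])
    d[!avail] <- Inf
    j <- which.min(d)                 # first minimum = lowest control index
    if (!is.null(caliper) && d[j] > caliper) { dropped <- dropped + 1L; next }
    treated <- c(treated, t)
    control <- c(control, ci[j])
    dist <- c(dist, d[j])
    avail[j] <- FALSE
  }
  out <- data.frame(treated = treated, control = control, distance = dist)
  attr(out, "dropped_treated") <- dropped
  out
}

#' ATT over matched pairs with a paired t test
#'
#' The average treatment effect on the treated is the mean within-pair
#' difference in the outcome (treated minus matched control), with SE and
#' two-tailed p value from the paired t test on the differences.
#'
#' @param outcome numeric outcome vector (indexed by the pair indices).
#' @param pairs a pairs data.frame from [match_nn()].
#' @return A list: `att`, `att_se`, `att_p`, `treated_mean`,
#'   `control_mean`, `n_pairs`, `conf_int` (95%), `dropped_treated`.
#' @export
estimate_att <- function(outcome, pairs) {
  if (nrow(pairs) < 2L) stop("need at least 2 matched pairs", call. = FALSE)
  yt <- outcome[pairs$treated]
  yc <- outcome[pairs$control]
  d <- yt - yc
  att <- mean(d)
  if (stats::var(d) == 0) {
    warning("zero variance of within-pair differences; ",
            "p value is the degenerate limit", call. = FALSE)
    se <- 0
    p <- if (att == 0) 1 else 0
    ci <- c(att, att)
  } else {
    tt <- stats::t.test(d)
    se <- unname(tt$stderr)
    p <- tt$p.value
    ci <- unname(tt$conf.int)
  }
  list(att = att, att_se = se, att_p = p,
       treated_mean = mean(yt), control_mean = mean(yc),
       n_pairs = nrow(pairs), conf_int = ci,
       dropped_treated = attr(pairs, "dropped_treated") %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

smd_one <- function(x, g) {
  mt <- mean(x[g == 1]); mc <- mean(x[g == 0])
  vt <- stats::var(x[g == 1]); vc <- stats::var(x[g == 0])
  pooled <- sqrt((vt + vc) / 2)
  if (pooled == 0) {
    if (mt == mc) 0 else NA_real_
  } else abs(mt - mc) / pooled
}

#' Covariate balance before and after matching
#'
#' Absolute standardized mean differences, `|mean_T - mean_C| /
#' sqrt((var_T + var_C)/2)`, computed on the full arms (before) and on the
#' matched sample (after). Covariates with post-match SMD >= 0.20 (the
#' conventional 20% criterion) are flagged. Propensity-support summaries
#' and Gaussian kernel density summaries (Silverman bandwidth) per arm,
#' before and after, are attached as attributes.
#'
#' @param X covariate matrix or data.frame.
#' @param D 0/1 treatment vector.
#' @param pairs matched pairs from [match_nn()].
#' @param propensity optional propensity vector for the support summary.
#' @return A data.frame of class `"balance_report"`: one row per covariate
#'   with `smd_before`, `smd_after`, percentage versions, and `flagged`.
#' @export
balance_table <- function(X, D, pairs, propensity = NULL) {
  X <- as.data.frame(X)
  matched <- c(pairs$treated, pairs$control)
  Dm <- D[matched]
  out <- data.frame(
    covariate = names(X),
    smd_before = vapply(X, smd_one, numeric(1), g = D),
    smd_after = vapply(X[matched, , drop = FALSE], smd_one, numeric(1),
                       g = Dm),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$smd_before_pct <- 100 * out$smd_before
  out$smd_after_pct <- 100 * out$smd_after
  out$flagged <- !is.na(out$smd_after) & out$smd_after >= 0.20
  if (!is.null(propensity)) {
    summ <- function(p) c(mean = mean(p), sd = stats::sd(p),
                          stats::quantile(p, c(.25, .5, .75)))
    kde <- function(p) {
      d <- stats::density(p, bw = "nrd0", n = 64, from = 0, to = 1)
      c(mode = d$x[which.max(d$y)], peak = max(d$y))
    }
    attr(out, "support") <- list(
      range_treated = range(propensity[D == 1]),
      range_control = range(propensity[D == 0]),
      before = list(treated = c(summ(propensity[D == 1]),
                                kde(propensity[D == 1])),
                    control = c(summ(propensity[D == 0]),
                                kde(propensity[D == 0]))),
      after = list(treated = c(summ(propensity[pairs$treated]),
                               kde(propensity[pairs$treated])),
                   control = c(summ(propensity[pairs$control]),
                               kde(propensity[pairs$control])))
    )
  }
  class(out) <- c("balance_report", "data.frame")
  out
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Covariate balance (absolute standardized mean differences)\n")
  df <- as.data.frame(x)
  df$smd_before <- round(df$smd_before, 3)
  df$smd_after <- round(df$smd_after, 3)
  print(df[, c("covariate", "smd_before", "smd_after", "flagged")],
        row.names = FALSE)
  if (any(x$flagged, na.rm = TRUE))
    cat("flagged: post-match SMD >= 0.20\n")
  else cat("all covariates balanced below the 20% criterion\n")
  invisible(x)
}

#' Propensity-score-matched sensitivity analysis of a cohort
#'
#' End-to-end matched analysis for one health dimension: builds the
#' analysis table ([prepare_analysis()]), forms the binary treatment
#' (access as-is; use median-binarized via [binarize_use()]), estimates
#' logit propensity scores on the full control-variable block, matches 1:1
#' nearest-neighbor without replacement, and reports the ATT on the
#' deprivation index with the paired test and the SMD balance table.
#'
#' @param cohort a raw cohort data.frame.
#' @param dimension `"srh"`, `"adl"`, `"iadl"` or `"cognition"`.
#' @param exposure `"access"` or `"use"` (median-binarized).
#' @param caliper optional propensity caliper passed to [match_nn()].
#' @return An object of class `"rd_psm"`: propensity scores, pairs, ATT
#'   fields, balance report, and sample sizes.
#' @export
rd_psm <- function(cohort, dimension, exposure = c("access", "use"),
                   caliper = NULL) {
  exposure <- match.arg(exposure)
  dat <- prepare_analysis(cohort, dimension, exposure)
  D <- if (exposure == "access") dat$access else binarize_use(dat$use)
  X <- dat[control_terms()]
  ps <- estimate_propensity(D, X)
  pairs <- match_nn(ps$propensity, D, caliper = caliper)
  att <- estimate_att(dat$rd, pairs)
  bal <- balance_table(X, D, pairs, propensity = ps$propensity)
  structure(
    c(list(dimension = dimension, exposure = exposure,
           propensity = ps$propensity, pairs = pairs, balance = bal,
           n = nrow(dat), n_treated = sum(D == 1), n_control = sum(D == 0)),
      att),
    class = "rd_psm"
  )
}

#' @export
print.rd_psm <- function(x, ...) {
  cat("Propensity-score-matched ATT on the deprivation index\n")
  cat(sprintf("  dimension: %s   exposure: %s\n", x$dimension, x$exposure))
  cat(sprintf("  n = %d (%d treated, %d control), %d pairs, %d treated dropped\n",
              x$n, x$n_treated, x$n_control, x$n_pairs, x$dropped_treated))
  cat(sprintf("  treated mean %.4f  control mean %.4f\n",
              x$treated_mean, x$control_mean))
  cat(sprintf("  ATT = %.4f (SE %.4f, p = %.4g)\n", x$att, x$att_se, x$att_p))
  invisible(x)
}

#' @export
summary.rd_psm <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$balance)
  invisible(object)
}
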