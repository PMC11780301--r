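#' Digital access indicator
#'
#' A person has internet access if any of three indicators is positive:
#' home broadband, owning at least one smart device, or owning at least one
#' digital device. The rule is monotone: increasing any input never removes
#' access.
#'
#' @param broadband 0/1 home broadband.
#' @param n_smart nonnegative count of smart devices owned.
#' @param n_digital nonnegative count of digital devices owned.
#' @return Integer 0/1 vector; `NA` where any input is missing.
#' @examples
#' derive_access(1, 0, 0)  # 1
#' derive_access(0, 2, 0)  # 1
#' derive_access(0, 0, 0)  # 0
#' @export
derive_access <- function(broadband, n_smart, n_digital) {
  for (nm in c("broadband", "n_smart", "n_digital")) {
    v <- get(nm)
    if (any(v < 0, na.rm = TRUE))
      stop("`", nm, "` must be nonnegative", call. = FALSE)
  }
  as.integer(broadband >= 1 | n_smart >= 1 | n_digital >= 1)
}

#' Digital use score
#'
#' Counts how many of three online activities a person performs: social
#' messaging (WeChat), social posting (Moments), and mobile payment. Score
#' ranges 0-3, higher = greater internet use capacity. The score is defined
#' only when all three items are observed; any missing item yields `NA`
#' (flagged, never silently treated as 0).
#'
#' @param wechat,moments,mobile_pay 0/1 indicators, `NA` if unobserved.
#' @return Integer score in \[0, 3\], `NA` where any item is missing.
#' @examples
#' derive_use(1, 0, 1)  # 2
#' derive_use(1, NA, 1) # NA: undefined, not 0
#' @export
derive_use <- function(wechat, moments, mobile_pay) {
  for (nm in c("wechat", "moments", "mobile_pay")) {
    v <- get(nm)
    if (any(!v %in% c(0, 1) & !is.na(v)))
      stop("`", nm, "` must be 0/1 or NA", call. = FALSE)
  }
  as.integer(wechat + moments + mobile_pay)
}

#' Median-binarize use scores for matching
#'
#' The matching analysis needs a binary treatment; use scores are split at
#' the sample median. Scores strictly greater than the median are coded 1;
#' ties at the median are coded 0 (a deterministic, conservative rule for
#' the treated group). Because the rule depends only on ranks, any strictly
#' monotone relabeling of the scores yields the same partition.
#'
#' @param use_scores nonempty numeric vector of defined (non-`NA`) use
#'   scores.
#' @return Integer 0/1 vector of the same length.
#' @examples
#' binarize_use(c(0, 1, 2, 3))  # 0 0 1 1 (median 1.5)
#' binarize_use(c(2, 2, 2, 2))  # all 0
#' @export
binarize_use <- function(use_scores) {
  if (length(use_scores) == 0L)
    stop("`use_scores` must be nonempty", call. = FALSE)
  if (any(is.na(use_scores)))
    stop("`use_scores` must not contain NA; restrict to defined scores first",
         call. = FALSE)
  med <- stats::median(use_scores)
  as.integer(use_scores > med)
}

#' Append digital-divide indicators to a cohort table
#'
#' Adds `access` (any of broadband / smart devices / digital devices),
#' `eligibility_use` (all three use items observed), `use_score` (0-3, `NA`
#' when ineligible) and `use_binary` (median split of the observed use
#' scores, `NA` when ineligible).
#'
#' @param cohort a cohort data.frame with columns `broadband`,
#'   `n_smart_devices`, `n_digital_devices`, `wechat`, `moments`,
#'   `mobile_pay`.
#' @return The cohort with indicator columns appended.
#' @export
derive_divide <- function(cohort) {
  need <- c("broadband", "n_smart_devices", "n_digital_devices",
            "wechat", "moments", "mobile_pay")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0L)
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cohort$access <- derive_access(cohort$broadband, cohort$n_smart_devices,
                                 cohort$n_digital_devices)
  cohort$use_score <- derive_use(cohort$wechat, cohort$moments,
                                 cohort$mobile_pay)
  cohort$eligibility_use <- as.integer(!is.na(cohort$use_score))
  cohort$use_binary <- NA_integer_
  obs <- which(cohort$eligibility_use == 1L)
  if (length(obs) > 0L)
    cohort$use_binary[obs] <- binarize_use(cohort$use_score[obs])
  cohort
}
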