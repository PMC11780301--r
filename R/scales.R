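#' Score the 6-item ADL scale
#'
#' Each of the six activities of daily living (dressing, bathing, feeding,
#' transferring, toileting, continence) is rated 1 (no difficulty) to 4
#' (unable to perform); the scale score is the item sum, ranging 6 (no
#' difficulty) to 24. Records with any missing item are flagged incomplete
#' (`NA` score) and are excluded from analyses of this dimension.
#'
#' @param items a numeric vector of 6 item responses, or a matrix /
#'   data.frame with 6 columns (one row per respondent). Values must be in
#'   1..4 or `NA`.
#' @return Integer score(s) in \[6, 24\]; `NA` where any item is missing.
#' @examples
#' score_adl(c(1, 1, 1, 1, 1, 1))  # 6
#' score_adl(c(1, 2, 3, 4, 1, 1))  # 12
#' @export
score_adl <- function(items) score_items(items, "adl")

#' Score the 6-item iADL scale
#'
#' Instrumental activities (cooking, housework, shopping, managing money,
#' phone use, medication), each rated 1-4; score is the item sum in
#' \[6, 24\], 6 indicating intact daily living skills.
#'
#' @inheritParams score_adl
#' @return Integer score(s) in \[6, 24\]; `NA` where any item is missing.
#' @examples
#' score_iadl(rep(2, 6))  # 12
#' @export
score_iadl <- function(items) score_items(items, "iadl")

score_items <- function(items, scale) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (is.matrix(items)) {
    if (ncol(items) != 6L)
      stop(sprintf("%s requires exactly 6 items, got %d columns",
                   scale, ncol(items)), call. = FALSE)
    m <- items
  } else {
    if (length(items) != 6L)
      stop(sprintf("%s requires exactly 6 items, got %d", scale,
                   length(items)), call. = FALSE)
    m <- matrix(items, nrow = 1L)
  }
  bad <- which(!is.na(m) & (m < 1 | m > 4 | m != round(m)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("%s item %d out of range {1,2,3,4} (value %s)",
                 scale, bad[1L, 2L], format(m[bad[1L, , drop = FALSE]])),
         call. = FALSE)
  s <- rowSums(m)            # NA if any item missing (incomplete record)
  if (!is.matrix(items)) s <- unname(s[1L])
  s
}

#' Orient a health score so that larger = healthier
#'
#' The deprivation index requires all dimensions on a common "higher is
#' healthier" orientation. ADL and iADL totals count difficulty (6 best, 24
#' worst) and are reflected by \eqn{x \mapsto 30 - x}, which maps 6..24 back
#' onto 6..24 reversing order. Self-rated health (5 = very healthy) and the
#' 0-30 cognitive screen already point the right way and pass through
#' unchanged. Each map is strictly monotone and self-inverse (ADL/iADL) or
#' the identity, so orientation is a bijection on each scale's range.
#'
#' @param score numeric score(s) on the named scale.
#' @param dimension one of `"srh"`, `"adl"`, `"iadl"`, `"cognition"`.
#' @return Oriented score(s), higher = healthier.
#' @examples
#' orient(6, "adl")        # 24
#' orient(30, "cognition") # 30
#' @export
orient <- function(score, dimension) {
  dimension <- match.arg(dimension, c("srh", "adl", "iadl", "cognition"))
  switch(dimension,
         adl = 30 - score,
         iadl = 30 - score,
         srh = score,
         cognition = score)
}

#' Append health scores to a cohort table
#'
#' Computes the ADL and iADL totals from the item columns (`adl1`..`adl6`,
#' `iadl1`..`iadl6`), carries the self-rated health level and the cognitive
#' total through, and appends oriented versions of all four dimensions
#' (`oriented_srh`, `oriented_adl`, `oriented_iadl`, `oriented_cognition`).
#' Records with a missing item are `NA` on that dimension (and only that
#' dimension): each dimension's analysis sample is formed listwise per
#' dimension downstream.
#'
#' @param cohort a cohort data.frame as produced by [generate_cohort()] or
#'   read from CSV with the same column dictionary.
#' @return The cohort with score columns appended.
#' @export
score_health <- function(cohort) {
  need <- c(paste0("adl", 1:6), paste0("iadl", 1:6), "srh", "mmse_total")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0L)
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cohort$adl <- score_adl(cohort[paste0("adl", 1:6)])
  cohort$iadl <- score_iadl(cohort[paste0("iadl", 1:6)])
  cohort$oriented_srh <- orient(cohort$srh, "srh")
  cohort$oriented_adl <- orient(cohort$adl, "adl")
  cohort$oriented_iadl <- orient(cohort$iadl, "iadl")
  cohort$oriented_cognition <- orient(cohort$mmse_total, "cognition")
  cohort
}
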