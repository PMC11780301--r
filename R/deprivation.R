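#' Kakwani relative deprivation index of health
#'
#' For a vector of health levels `y` (oriented so that larger = healthier),
#' the relative deprivation felt by person i is the mean shortfall of their
#' health relative to everyone strictly healthier, normalised by the sample
#' mean health level:
#'
#' \deqn{RD_i = \frac{1}{n\,\mu_Y}\sum_j \max(y_j - y_i,\; 0)
#'            = \gamma_i\,\frac{\mu_i^+ - y_i}{\mu_Y}}
#'
#' where \eqn{\gamma_i} is the share of the sample with health strictly
#' greater than \eqn{y_i} and \eqn{\mu_i^+} the mean health of that subset.
#' The index is dimensionless (invariant to rescaling \eqn{y \mapsto c y},
#' c > 0), zero for every person at the sample maximum, decreasing in own
#' health within a sample, and its sample mean equals the Gini coefficient
#' of `y`.
#'
#' Ties are handled by strict inequality: persons at the same health level
#' do not deprive each other.
#'
#' @param y numeric vector of oriented health levels; all finite, mean > 0.
#' @param dimension optional label naming the health dimension.
#' @return An object of class `"kakwani_rd"`: a list with components
#'   \item{rd}{per-person deprivation values, in input order;}
#'   \item{n}{sample size;}
#'   \item{mu}{sample mean health \eqn{\mu_Y};}
#'   \item{dimension}{the label, or `NULL`;}
#'   \item{frac_healthier}{\eqn{\gamma_i}, share strictly healthier;}
#'   \item{mean_healthier}{\eqn{\mu_i^+}, `NA` for sample maxima.}
#' @examples
#' k <- kakwani_rd(c(1, 2, 3))
#' k$rd                  # 0.5, 1/6, 0
#' mean(k$rd) == gini(c(1, 2, 3))
#' @seealso [gini()]
#' @export
kakwani_rd <- function(y, dimension = NULL) {
  if (length(y) == 0L)
    stop("`y` must be a nonempty numeric vector", call. = FALSE)
  if (!is.numeric(y))
    stop("`y` must be numeric", call. = FALSE)
  if (any(!is.finite(y)))
    stop("`y` must contain only finite values (remove missing cases first)",
         call. = FALSE)
  n <- length(y)
  mu <- mean(y)
  if (mu <= 0)
    stop("mean health level must be > 0; the deprivation index is undefined",
         call. = FALSE)

  o <- order(y)
  ys <- y[o]
  cs <- cumsum(ys)
  # index of the last element tied with ys[i] in the sorted vector
  last_eq <- findInterval(ys, ys)
  n_gt <- n - last_eq                 # count strictly healthier
  sum_gt <- cs[n] - cs[last_eq]       # their total health
  rd_s <- (sum_gt - n_gt * ys) / (n * mu)
  rd_s[n_gt == 0L] <- 0

  rd <- frac <- numeric(n)
  mu_plus <- rep(NA_real_, n)
  rd[o] <- rd_s
  frac[o] <- n_gt / n
  mu_plus[o] <- ifelse(n_gt > 0L, sum_gt / n_gt, NA_real_)

  structure(
    list(rd = rd, n = n, mu = mu, dimension = dimension,
         frac_healthier = frac, mean_healthier = mu_plus),
    class = "kakwani_rd"
  )
}

#' Gini coefficient
#'
#' Mean absolute difference between all pairs divided by twice the mean;
#' equals the sample mean of [kakwani_rd()] on the same vector. Used as the
#' internal consistency oracle for the deprivation index.
#'
#' @inheritParams kakwani_rd
#' @return The Gini coefficient, a scalar in \[0, 1).
#' @examples
#' gini(c(1, 2, 3))  # 2/9
#' @export
gini <- function(y) {
  if (length(y) == 0L)
    stop("`y` must be a nonempty numeric vector", call. = FALSE)
  if (!is.numeric(y) || any(!is.finite(y)))
    stop("`y` must be finite numeric", call. = FALSE)
  n <- length(y)
  mu <- mean(y)
  if (mu <= 0)
    stop("mean health level must be > 0; the Gini coefficient is undefined",
         call. = FALSE)
  ys <- sort(y)
  sum((2 * seq_len(n) - n - 1) * ys) / (n^2 * mu)
}

#' @export
print.kakwani_rd <- function(x, ...) {
  cat("Kakwani relative deprivation index",
      if (!is.null(x$dimension)) paste0("(", x$dimension, ")"), "\n")
  cat(sprintf("  n = %d, mean health = %.4f, mean RD (= Gini) = %.4f\n",
              x$n, x$mu, mean(x$rd)))
  invisible(x)
}

#' @export
summary.kakwani_rd <- function(object, ...) {
  out <- list(
    dimension = object$dimension,
    n = object$n,
    mu = object$mu,
    gini = mean(object$rd),
    quantiles = stats::quantile(object$rd, c(0, .25, .5, .75, 1))
  )
  class(out) <- "summary.kakwani_rd"
  out
}

#' @export
print.summary.kakwani_rd <- function(x, ...) {
  cat("Kakwani relative deprivation index",
      if (!is.null(x$dimension)) paste0("(", x$dimension, ")"), "\n")
  cat(sprintf("  n = %d\n  mean health (mu_Y) = %.4f\n  Gini = mean(RD) = %.4f\n",
              x$n, x$mu, x$gini))
  cat("  RD quantiles:\n")
  print(round(x$quantiles, 4))
  invisible(x)
}
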