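#' Jackknife standard error over replicates
#'
#' Leave-one-out resampling over replicates: the estimator is evaluated on
#' every (n-1)-replicate subset, and the standard error is
#' \deqn{SE = \sqrt{\frac{n-1}{n} \sum_i (\theta_i - \bar\theta_\cdot)^2}}
#' with \eqn{\theta_i} the estimate omitting replicate i and
#' \eqn{\bar\theta_\cdot} their mean.  Because each subset pools n-1
#' replicates, the estimator never runs on a single replicate, which
#' avoids error estimates from poorly converged single-replicate averages.
#' For a linear estimator (e.g. the mean) this reproduces the classical
#' standard error exactly.
#'
#' @param replicates number of replicates (>= 2), or a vector of replicate
#'   identifiers.
#' @param estimator function taking a vector of retained replicate
#'   identifiers and returning a numeric scalar or named vector.
#' @return a list with \code{estimate} (estimator on all replicates),
#'   \code{se} (per component) and \code{leave_one_out} (matrix, one row
#'   per omitted replicate).
#' @examples
#' v <- c(1, 2, 3)
#' jackknife_se(3, function(idx) mean(v[idx]))$se  # 1/sqrt(3)
#' @export
jackknife_se <- function(replicates, estimator) {
  ids <- if (length(replicates) == 1L && is.numeric(replicates))
    seq_len(replicates) else replicates
  n <- length(ids)
  if (n < 2L)
    stop("insufficient replicates: jackknife needs at least 2",
         call. = FALSE)
  est <- estimator(ids)
  loo <- vapply(seq_len(n), function(i) as.numeric(estimator(ids[-i])),
                numeric(length(est)))
  if (is.null(dim(loo))) loo <- matrix(loo, nrow = 1L)
  loo <- t(loo)  # one row per omitted replicate
  colnames(loo) <- names(est)
  bar <- colMeans(loo)
  se <- sqrt((n - 1) / n * colSums(sweep(loo, 2, bar)^2))
  names(se) <- names(est)
  list(estimate = est, se = se, leave_one_out = loo)
}

#' Pearson correlation coefficient
#'
#' Standard Pearson r with the preconditions made explicit: equal lengths
#' of at least 3 and non-degenerate variance in both inputs.
#'
#' @param x,y numeric vectors.
#' @return correlation coefficient in [-1, 1].
#' @examples
#' pearson(1:5, 2 * (1:5) + 1)  # 1
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values not allowed", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance input", call. = FALSE)
  cor(x, y)
}
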