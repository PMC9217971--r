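#' Goodness-of-fit statistics for a response-surface model
#'
#' Residual sum of squares, `rmse = sqrt(rss / n)`, adjusted r-squared with
#' the `(n-1)/(n-k-1)` correction, and the Akaike information criterion
#' `AIC = 2k - 2 ln L` under a Gaussian likelihood with the maximum-likelihood
#' variance `sigma^2 = rss / n` (the variance is not counted in `k`).
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param n_params Number of model parameters `k` (`n > k` required).
#' @return List with `rss`, `rmse`, `adjusted_r2`, `aic`, `loglik`, `n_obs`,
#'   `n_params`. A perfect fit (`rss = 0`) returns `aic = -Inf` with a
#'   warning.
#' @export
fit_statistics <- function(observed, predicted, n_params) {
  stopifnot(length(observed) == length(predicted),
            all(is.finite(observed)), all(is.finite(predicted)))
  n <- length(observed); k <- n_params
  if (n <= k) stop("need more observations than parameters", call. = FALSE)
  res <- observed - predicted
  rss <- sum(res^2)
  rmse <- sqrt(rss / n)
  tss <- sum((observed - mean(observed))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj <- if (is.na(r2) || n - k - 1 <= 0) NA_real_ else
    1 - (1 - r2) * (n - 1) / (n - k - 1)
  if (rss == 0) {
    warning("perfect fit: rss = 0, AIC is -Inf", call. = FALSE)
    ll <- Inf; aic <- -Inf
  } else {
    sigma2 <- rss / n
    ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
    aic <- 2 * k - 2 * ll
  }
  list(rss = rss, rmse = rmse, adjusted_r2 = adj, aic = aic, loglik = ll,
       n_obs = as.integer(n), n_params = as.integer(k))
}

#' Two-sample Wilcoxon-Mann-Whitney test
#'
#' Two-sided test that observed and modeled effects come from the same
#' distribution. For combined sample sizes up to 12 the exact permutation
#' distribution of the rank sum is enumerated (ties permitted); larger
#' samples use the tie-corrected normal approximation of
#' [stats::wilcox.test()].
#'
#' @param observed,predicted Numeric samples (at least 3 values each).
#' @return Two-sided p-value. All-tied samples give `p = 1` with a warning.
#' @export
mw_test <- function(observed, predicted) {
  x <- as.numeric(observed); y <- as.numeric(predicted)
  stopifnot(length(x) >= 3, length(y) >= 3)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all values tied; p = 1", call. = FALSE)
    return(1)
  }
  n1 <- length(x); N <- length(pooled)
  if (N <= 12) {
    r <- rank(pooled)
    w_obs <- sum(r[seq_len(n1)])
    combs <- utils::combn(N, n1)
    w_all <- apply(combs, 2, function(i) sum(r[i]))
    p_lo <- mean(w_all <= w_obs)
    p_hi <- mean(w_all >= w_obs)
    min(1, 2 * min(p_lo, p_hi))
  } else {
    stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                       correct = TRUE)$p.value
  }
}

#' Shapiro-Wilk normality test of fit residuals
#'
#' @param residuals Numeric vector (3 to 5000 values).
#' @return p-value; `p = 1` with a warning when all residuals are equal.
#' @export
shapiro_test <- function(residuals) {
  r <- as.numeric(residuals)
  stopifnot(length(r) >= 3)
  if (diff(range(r)) == 0) {
    warning("all residuals identical; p = 1", call. = FALSE)
    return(1)
  }
  stats::shapiro.test(r)$p.value
}
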