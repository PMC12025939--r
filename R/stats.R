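# Statistical layer: per-segment ordinary least squares on profile bins,
# Chow test for structural change between paired regressions, exact
# Wilcoxon signed-rank for paired segment means, paired t-test for clinical
# scores, Shapiro-Wilk normality check, and loess smoothing for plots.

#' Ordinary least-squares line fit
#'
#' Fits y = intercept + slope * x by unweighted least squares.  The x
#' coordinate is kept global (percent of tendon length, 0 at the footprint
#' for every segment), so a medial-segment intercept is the extrapolation
#' of that segment's line back to x = 0.
#'
#' @param x Numeric predictor (percent positions), not all equal, n >= 3.
#' @param y Numeric response (T2 in ms), same length.
#' @param weights Optional non-negative case weights (e.g. bin voxel
#'   counts) for a count-weighted fit.
#' @return An object of class \code{regression_fit}: \code{slope},
#'   \code{intercept}, \code{rss}, \code{n}, \code{x_range}.
#' @export
#' @examples
#' f <- ols_fit(1:10, 39.5 - 0.268 * (1:10))
#' f$slope
ols_fit <- function(x, y, weights = NULL) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 finite (x, y) points", call. = FALSE)
  if (max(x) - min(x) <= 0) stop("x values are all equal; slope undefined", call. = FALSE)
  if (is.null(weights)) {
    fit <- lm.fit(cbind(1, x), y)
  } else {
    w <- weights[keep]
    stopifnot(length(w) == length(x), all(w >= 0), sum(w > 0) >= 3L)
    fit <- stats::lm.wfit(cbind(1, x), y, w)
  }
  co <- fit$coefficients
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 rss = sum(if (is.null(weights)) fit$residuals^2
                           else weights[keep] * fit$residuals^2),
                 n = length(x), x_range = range(x)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> slope %.4g ms/%%, intercept %.4g ms, n = %d, RSS = %.4g\n",
              x$slope, x$intercept, x$n, x$rss))
  invisible(x)
}

#' Chow test for structural change between two regressions
#'
#' Tests whether two datasets share one regression line against the
#' alternative that slope and/or intercept differ:
#' F = [(RSS_p - RSS_a - RSS_b) / k] / [(RSS_a + RSS_b) / (n_a + n_b - 2k)]
#' with k = 2 parameters, where RSS_p comes from the pooled fit.  The
#' p-value is the upper tail of F(k, n_a + n_b - 2k).
#'
#' When both separate fits are perfect (RSS_a + RSS_b = 0) the statistic is
#' degenerate: p is reported as 0 when the pooled fit has residual error
#' (perfect but different lines) and 1 when it does not (identical lines),
#' with \code{degenerate = TRUE}.
#'
#' @param a,b Each a list or data frame with components \code{x}, \code{y}.
#' @return An object of class \code{chow_result}: \code{f_stat},
#'   \code{df1} (= 2), \code{df2} (= n_a + n_b - 4), \code{p_value},
#'   \code{degenerate}.
#' @export
chow_test <- function(a, b) {
  fa <- ols_fit(a$x, a$y)
  fb <- ols_fit(b$x, b$y)
  fp <- ols_fit(c(a$x, b$x), c(a$y, b$y))
  k <- 2L
  n <- fa$n + fb$n
  if (n < 2L * k + 3L) stop("combined sample too small for the Chow test", call. = FALSE)
  df2 <- n - 2L * k
  rss_sep <- fa$rss + fb$rss
  scale <- sum(c(a$y, b$y)^2) + 1
  tol <- 1e-12 * scale
  if (rss_sep <= tol) {
    gain <- fp$rss - rss_sep
    if (gain <= tol) {
      return(structure(list(f_stat = 0, df1 = k, df2 = df2, p_value = 1,
                            degenerate = TRUE), class = "chow_result"))
    }
    return(structure(list(f_stat = Inf, df1 = k, df2 = df2, p_value = 0,
                          degenerate = TRUE), class = "chow_result"))
  }
  f_stat <- max(0, (fp$rss - rss_sep) / k) / (rss_sep / df2)
  structure(list(f_stat = f_stat, df1 = k, df2 = df2,
                 p_value = pf(f_stat, k, df2, lower.tail = FALSE),
                 degenerate = FALSE),
            class = "chow_result")
}

#' @export
print.chow_result <- function(x, ...) {
  cat(sprintf("<chow_result> F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df1, x$df2, x$f_stat, x$p_value,
              if (x$degenerate) " (degenerate fit)" else ""))
  invisible(x)
}

# Exact distribution of W+ (sum of ranks of positive differences) over all
# 2^n equally likely sign patterns, by characteristic-polynomial
# convolution on doubled ranks (mid-ranks are multiples of 1/2, so doubling
# makes them integers).  Equivalent to full enumeration, at O(n * sum r).
signed_rank_cdf <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  probs <- numeric(total + 1L)  # index i -> P(2 W+ = i - 1)
  probs[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), probs[seq_len(total + 1L - r)])
    probs <- (probs + shifted) / 2
  }
  sum(probs[seq_len(min(total, floor(round(2 * w, 8))) + 1L)])
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences with classic zero handling: zero
#' differences are dropped, tied absolute differences receive mid-ranks,
#' and the statistic is W = min(W+, W-).  For n <= 25 retained pairs the
#' p-value is exact over all 2^n sign patterns (ties included); larger
#' samples use a normal approximation with the tie-exact variance
#' Var(W+) = sum(r_i^2) / 4 and a 0.5 continuity correction.
#'
#' @param before,after Paired numeric vectors in shared subject order;
#'   alternatively pass the differences as \code{before} and leave
#'   \code{after} NULL.
#' @param mode \code{"auto"} (exact for n <= 25), \code{"exact"},
#'   or \code{"normal"}.
#' @return List with \code{statistic} (W), \code{w_plus}, \code{n} (pairs
#'   retained after zero removal), \code{p_value}, \code{method},
#'   \code{all_zero} flag.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))$p_value
wilcoxon_signed_rank <- function(before, after = NULL,
                                 mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  d <- if (is.null(after)) before else {
    stopifnot(length(before) == length(after))
    before - after
  }
  if (anyNA(d)) stop("missing pairs are not allowed", call. = FALSE)
  if (length(d) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- d[d != 0]
  if (!length(d)) {
    return(list(statistic = 0, w_plus = 0, n = 0L, p_value = 1,
                method = "degenerate", all_zero = TRUE))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r) - w_plus
  w <- min(w_plus, w_minus)
  use_exact <- switch(mode, exact = TRUE, normal = FALSE,
                      auto = length(d) <= 25L)
  if (use_exact) {
    # symmetry of the sign-pattern distribution about sum(r)/2 makes
    # doubling the lower tail the two-sided p
    p <- min(1, 2 * signed_rank_cdf(r, w))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (abs(w_plus - mu) - 0.5) / sigma
    p <- min(1, 2 * pnorm(-max(z, 0)))
    method <- "normal-approximation"
  }
  list(statistic = w, w_plus = w_plus, n = length(d), p_value = p,
       method = method, all_zero = FALSE)
}

#' Paired t-test
#'
#' Two-sided paired Student t-test: t = mean(d) / (sd(d) / sqrt(n)) on the
#' differences d = before - after, df = n - 1.
#'
#' @param before,after Paired numeric vectors in shared subject order.
#' @return List with \code{t}, \code{df}, \code{p_value}, \code{mean_diff}.
#' @export
paired_t_test <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 2L)
  d <- before - after
  if (anyNA(d)) stop("missing pairs are not allowed", call. = FALSE)
  if (sd(d) == 0) {
    stop("differences have zero variance; the paired t statistic is undefined",
         call. = FALSE)
  }
  ht <- t.test(before, after, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_diff = unname(ht$estimate))
}

#' Shapiro-Wilk normality check
#'
#' @param values Numeric vector, 3 <= n <= 5000, not constant.
#' @param alpha Significance level for the normality flag (default 0.05).
#' @return List with \code{W}, \code{p_value}, \code{normal} (TRUE when
#'   p >= alpha).
#' @export
shapiro_wilk_check <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3L || length(values) > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (max(values) - min(values) == 0) {
    stop("constant input: normality test undefined", call. = FALSE)
  }
  ht <- shapiro.test(values)
  list(W = unname(ht$statistic), p_value = ht$p.value,
       normal = ht$p.value >= alpha)
}

#' Locally weighted smoothing of a T2 profile
#'
#' Local linear (degree-1, tricube-weighted) smoothing of the binned
#' profile, evaluated at the bin centers.  For display only: the regression
#' and Chow stages always consume the raw bin means.
#'
#' @param profile A \code{\link{bin_profile}} result.
#' @param span Fraction of points in each local window, 0 < span <= 1.
#' @return Data frame with \code{bin_center_pct} and \code{smoothed_t2_ms}
#'   for the nonempty bins.
#' @export
loess_smooth <- function(profile, span = 0.4) {
  stopifnot(inherits(profile, "t2_profile"), span > 0, span <= 1)
  keep <- profile$bin_counts > 0
  if (sum(keep) < 10L) stop("need at least 10 nonempty bins to smooth", call. = FALSE)
  if (span * sum(keep) < 3) {
    stop("span too small: each local window must cover at least 3 points",
         call. = FALSE)
  }
  df <- data.frame(x = profile$bin_centers[keep], y = profile$bin_means[keep])
  fit <- loess(y ~ x, data = df, span = span, degree = 1,
               family = "gaussian", surface = "direct")
  data.frame(bin_center_pct = df$x,
             smoothed_t2_ms = as.vector(predict(fit, newdata = df)))
}

#' Per-segment regression of a T2 profile
#'
#' Fits one line per tendon segment to the profile's nonempty bin means,
#' with x in global percent coordinates.
#'
#' @param profile A \code{\link{bin_profile}} result.
#' @param weight_by_count Weight bins by voxel count instead of equally.
#' @return Named list (lateral, middle, medial) of
#'   \code{\link{ols_fit}} results; segments with fewer than 3 nonempty
#'   bins are NULL.
#' @export
segment_regressions <- function(profile, weight_by_count = FALSE) {
  stopifnot(inherits(profile, "t2_profile"))
  seg <- segment_of(profile$bin_centers)
  out <- list()
  for (s in levels(seg)) {
    keep <- seg == s & profile$bin_counts > 0
    if (sum(keep) < 3L) {
      out[[s]] <- NULL
      next
    }
    out[[s]] <- ols_fit(profile$bin_centers[keep], profile$bin_means[keep],
                        weights = if (weight_by_count) profile$bin_counts[keep])
  }
  out
}
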