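# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: literal enumeration, brute-force grid search,
# and explicit normal-equation arithmetic.

# Exact signed-rank two-sided p by literal enumeration of all 2^n sign
# patterns (zeros dropped, mid-ranks for ties), p = min(1, 2 P(W+ <= W)).
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_plus_obs <- sum(r[d > 0])
  w_obs <- min(w_plus_obs, sum(r) - w_plus_obs)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_plus_all <- as.vector(signs %*% r)
  min(1, 2 * mean(w_plus_all <= w_obs + 1e-9))
}

# Brute-force mono-exponential T2 estimate: grid search over T2 with the
# amplitude profiled out analytically, minimizing signal-domain SSE.
grid_search_t2 <- function(signal, tes, t2_grid = seq(1, 300, by = 0.05)) {
  sse <- vapply(t2_grid, function(t2) {
    e <- exp(-tes / t2)
    s0 <- sum(signal * e) / sum(e^2)
    sum((signal - s0 * e)^2)
  }, numeric(1))
  t2_grid[which.min(sse)]
}

# OLS coefficients from the explicit normal equations.
normal_equations_fit <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2],
       rss = sum((y - X %*% beta)^2))
}

# Chow F statistic assembled from explicit residual sums of squares
# computed with lm().
explicit_chow_f <- function(xa, ya, xb, yb) {
  rss <- function(x, y) sum(resid(lm(y ~ x))^2)
  rss_a <- rss(xa, ya); rss_b <- rss(xb, yb)
  rss_p <- rss(c(xa, xb), c(ya, yb))
  n <- length(xa) + length(xb)
  f <- ((rss_p - rss_a - rss_b) / 2) / ((rss_a + rss_b) / (n - 4))
  list(f = f, p = pf(f, 2, n - 4, lower.tail = FALSE))
}

# Small phantom configurations used to keep the suite fast.
small_phantom <- function(...) {
  phantom_config(grid_shape = c(64L, 64L), ...)
}

# Straight horizontal band spanning the given columns; the analytic length
# coordinate is then a linear function of the column index.
straight_band <- function(col_from = 8, col_to = 56, row = 32,
                          grid = c(64L, 64L), ...) {
  phantom_config(grid_shape = grid, straight = TRUE,
                 control_points = rbind(c(row, col_from),
                                        c(row, (col_from + col_to) / 2),
                                        c(row, col_to)),
                 ...)
}
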