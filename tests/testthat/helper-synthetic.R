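# Shared fixtures and independent oracles, all built in code at test time.

tiny_grid <- function(n = 4, res = 0.5, lat0 = 30, lon0 = -10) {
  grid_spec(lat0, lat0 + n * res, lon0, lon0 + n * res, res)
}

# one-cell monthly precipitation tibble from a numeric vector
cell_precip <- function(values, start_year = 1981) {
  n <- length(values)
  stopifnot(n %% 12 == 0)
  tibble::tibble(
    lat = 0.25, lon = 0.25,
    year = rep(start_year:(start_year + n / 12 - 1), each = 12),
    month = rep(1:12, n / 12),
    precip = values
  )
}

# brute-force k-month rolling sum (naive loop oracle)
naive_rolling_sum <- function(x, k) {
  out <- rep(NA_real_, length(x))
  for (t in k:length(x)) out[t] <- sum(x[(t - k + 1):t])
  out
}

# closed-form OLS slope/intercept/p oracle (hand-coded formulas)
ols_oracle <- function(x, y) {
  n <- length(x)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - beta * mean(x)
  res <- y - a - beta * x
  se <- sqrt(sum(res^2) / (n - 2) / sum((x - mean(x))^2))
  tval <- beta / se
  list(a = a, beta = beta, se = se, p = 2 * stats::pt(-abs(tval), n - 2))
}

# simulate per-cell (anomaly, DI) pairs for regression property tests
sim_cell_pairs <- function(n, beta, a = 0, sigma = 3) {
  di <- stats::rexp(n, rate = 1)
  tibble::tibble(di = di, anomaly = a + beta * di + stats::rnorm(n, sd = sigma))
}
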