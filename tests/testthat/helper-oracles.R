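# Independent oracles and fixture builders shared across the suite.

make_tone <- function(freq, dur = 2, fs = 2000, amp = 1, phase = 0,
                      role = "CA3_LFP") {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  trace(amp * cos(2 * pi * freq * t + phase), fs, role)
}

# direct O(N^2) biased normalized autocorrelation (stats::acf convention)
acf_oracle <- function(x, max_lag_samples) {
  n <- length(x)
  x <- x - mean(x)
  v <- sum(x^2) / n
  vapply(0:max_lag_samples, function(k)
    sum(x[(1 + k):n] * x[1:(n - k)]) / n / v, numeric(1))
}

# direct O(N^2) cross-correlation, stats::ccf convention:
# r(k) = cov_k(y, x) / sqrt(var(x) var(y)), biased (1/n) covariances,
# positive k meaning y leads ... matched empirically to ccf(y, x)
ccf_oracle <- function(y, x, max_lag_samples) {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) / n * sum(yc^2) / n)
  ks <- -max_lag_samples:max_lag_samples
  vals <- vapply(ks, function(k) {
    if (k >= 0) sum(yc[(1 + k):n] * xc[1:(n - k)]) / n
    else sum(yc[1:(n + k)] * xc[(1 - k):n]) / n
  }, numeric(1))
  list(lags = ks, values = vals / denom)
}

# expected-counts chi-square (textbook sum formula), the independent route
chi2_expected_oracle <- function(m) {
  N <- sum(m)
  E <- outer(rowSums(m), colSums(m)) / N
  sum((m - E)^2 / E)
}

# brute-force extremum scan of an analytic ACF on a dense lag grid, applying
# the same trough-then-peak / (r+1)/2 definitions as the package, but without
# discretization or parabolic refinement
cr_dense_oracle <- function(rho, max_lag = 0.1, min_lag = 1e-3,
                            n_grid = 200000L) {
  tau <- seq(min_lag, max_lag, length.out = n_grid)
  v <- rho(tau)
  d <- diff(v)
  tr_i <- which(d[-length(d)] < 0 & d[-1] >= 0)[1] + 1L
  pk_i <- which(d[-length(d)] > 0 & d[-1] <= 0)
  pk_i <- pk_i[pk_i + 1L > tr_i][1] + 1L
  alpha <- (v[pk_i] + 1) / 2
  beta <- (v[tr_i] + 1) / 2
  (alpha - beta) / (alpha + beta)
}

# uniform-null Monte Carlo estimate of the Rayleigh p-value
rayleigh_mc_oracle <- function(phases, n_sim = 5000L) {
  n <- length(phases)
  r_obs <- sqrt(mean(cos(phases))^2 + mean(sin(phases))^2)
  hits <- replicate(n_sim, {
    u <- stats::runif(n, 0, 2 * pi)
    sqrt(mean(cos(u))^2 + mean(sin(u))^2) >= r_obs
  })
  mean(hits)
}

# cells with mean vectors drawn as bivariate normal points, packed as the
# gp_cell_phase fields the second-order tests consume
synthetic_cells <- function(n, mx = 0, my = 0, sd = 0.3) {
  X <- stats::rnorm(n, mx, sd); Y <- stats::rnorm(n, my, sd)
  lapply(seq_len(n), function(j) {
    r <- sqrt(X[j]^2 + Y[j]^2)
    structure(list(cell_id = j, spike_phases = numeric(0),
                   mean_angle = atan2(Y[j], X[j]) %% (2 * pi),
                   vector_length = min(r, 1), n_spikes = NA_integer_,
                   rayleigh_z = NA_real_, rayleigh_p = NA_real_,
                   locked = NA),
              class = "gp_cell_phase")
  })
}

# cell with a stated mean vector
cell_with_vector <- function(r, angle, id = "c") {
  structure(list(cell_id = id, spike_phases = numeric(0),
                 mean_angle = angle %% (2 * pi), vector_length = r,
                 n_spikes = NA_integer_, rayleigh_z = NA_real_,
                 rayleigh_p = NA_real_, locked = NA),
            class = "gp_cell_phase")
}

# analog-prototype Butterworth band-pass squared magnitude at frequency f
butter_bp_mag2 <- function(f, low, high, order = 3) {
  Q <- (f^2 - low * high) / (f * (high - low))
  1 / (1 + Q^(2 * order))
}
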