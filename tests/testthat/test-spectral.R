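test_that("band-pass filter passes the gamma band and rejects out-of-band", {
  fs <- 10000
  tone <- make_tone(40, dur = 10, fs = fs)
  y <- bandpass(tone, 5, 120)
  core <- y$samples[(2 * fs):(8 * fs)]   # away from filtfilt edge transients
  expect_lt(abs(max(abs(core)) - 1), 0.01)

  dc <- trace(rep(1, 10 * fs), fs, "CA3_LFP")
  ydc <- suppressWarnings(bandpass(dc, 5, 120))
  expect_lt(max(abs(ydc$samples[(2 * fs):(8 * fs)])), 0.01)

  hi <- make_tone(200, dur = 10, fs = fs)
  yhi <- bandpass(hi, 5, 120)
  gain <- max(abs(yhi$samples[(2 * fs):(8 * fs)]))
  expected <- butter_bp_mag2(200, 5, 120, order = 3)  # |H|^2: forward+backward
  expect_lt(abs(gain - expected) / expected, 0.05)

  expect_error(bandpass(tone, 100, 6000), "Nyquist|fs/2")
})

test_that("Welch spectrum satisfies Parseval and localizes a tone", {
  fs <- 2000
  amp <- 3
  windows <- split_windows(make_tone(40, dur = 40, fs = fs, amp = amp), 10)
  ps <- power_spectrum(windows, nperseg = 2^13)
  total <- band_power(ps, c(0, fs / 2))
  expect_lt(abs(total - amp^2 / 2) / (amp^2 / 2), 0.02)
  expect_lt(abs(ps$freqs[which.max(ps$psd)] - 40), ps$resolution + 1e-9)
})

test_that("white-noise spectrum is flat at sigma^2/(fs/2)", {
  set.seed(5)
  fs <- 2000; sigma <- 2
  windows <- lapply(1:20, function(i)
    trace(rnorm(10 * fs, sd = sigma), fs, "CA3_LFP"))
  ps <- power_spectrum(windows, nperseg = 2^11)
  level <- mean(ps$psd[ps$freqs > 50 & ps$freqs < 900])
  expect_lt(abs(level - sigma^2 / (fs / 2)) / (sigma^2 / (fs / 2)), 0.05)
})

test_that("spectrum averaging is idempotent and validates window shapes", {
  w <- make_tone(30, dur = 5, fs = 1000)
  one <- power_spectrum(list(w), nperseg = 2^10)
  two <- power_spectrum(list(w, w), nperseg = 2^10)
  expect_equal(one$psd, two$psd)
  expect_equal(two$epoch_count, 2)
  short <- make_tone(30, dur = 2, fs = 1000)
  expect_error(power_spectrum(list(w, short)), "length")
})

fake_spectrum <- function(freqs, psd) {
  structure(list(freqs = freqs, psd = psd,
                 resolution = freqs[2] - freqs[1], epoch_count = 1L),
            class = "gp_spectrum")
}

test_that("gamma metrics pick the argmax and integrate the fixed band", {
  f <- 0:120
  p1 <- rep(0, 121); p1[f == 40] <- 7
  m <- gamma_metrics(fake_spectrum(f, p1))
  expect_equal(m$peak_frequency, 40)
  expect_equal(m$peak_power, 7)

  p2 <- rep(0, 121); p2[f == 30] <- 1.0; p2[f == 65] <- 0.9
  expect_equal(gamma_metrics(fake_spectrum(f, p2))$peak_frequency, 30)

  c0 <- 0.37
  p3 <- ifelse(f >= 20 & f <= 80, c0, 0)
  expect_equal(gamma_metrics(fake_spectrum(f, p3))$bandwidth_power, 60 * c0)
})

test_that("mains exclusion applies to the peak search but not the integral", {
  f <- 0:120
  p <- rep(0.01, 121); p[f == 60] <- 50; p[f == 35] <- 5
  m_ex <- gamma_metrics(fake_spectrum(f, p), exclude_mains = TRUE)
  expect_equal(m_ex$peak_frequency, 35)
  m_in <- gamma_metrics(fake_spectrum(f, p), exclude_mains = FALSE)
  expect_equal(m_in$peak_frequency, 60)
  # integral identical either way: the band is fixed
  expect_equal(m_ex$bandwidth_power, m_in$bandwidth_power)
})

test_that("amplitude scaling moves powers quadratically, peak frequency not at all", {
  fs <- 2000
  set.seed(11)
  base <- rnorm(20 * fs, sd = 3) + 10 * cos(2 * pi * 43 * (0:(20 * fs - 1)) / fs)
  k <- 2.5
  ps1 <- power_spectrum(split_windows(trace(base, fs, "CA3_LFP"), 10),
                        nperseg = 2^12)
  ps2 <- power_spectrum(split_windows(trace(k * base, fs, "CA3_LFP"), 10),
                        nperseg = 2^12)
  m1 <- gamma_metrics(ps1); m2 <- gamma_metrics(ps2)
  expect_equal(m2$peak_frequency, m1$peak_frequency)
  expect_equal(m2$peak_power, k^2 * m1$peak_power, tolerance = 1e-10)
  expect_equal(m2$bandwidth_power, k^2 * m1$bandwidth_power, tolerance = 1e-10)
})

test_that("inclusion rules match the frequency/power/mains thresholds", {
  cfg <- analysis_config()
  fake_m <- function(freq, power, region) {
    structure(list(peak_frequency = freq, peak_power = power,
                   bandwidth_power = 1, region = region, qc_pass = NA,
                   qc_reasons = character()), class = "gp_gamma_metrics")
  }
  cases <- list(
    # freq, power, region, expect_pass, expected reasons
    list(15,   5,    "CA3", FALSE, "frequency"),
    list(85,   5,    "CA3", FALSE, "frequency"),
    list(19,   5,    "CA3", FALSE, "frequency"),   # bound is strict
    list(80,   5,    "CA3", FALSE, "frequency"),
    list(40,   0.5,  "CA3", FALSE, "power"),
    list(40,   1.0,  "CA3", FALSE, "power"),       # strictly greater than 1
    list(40,   1.01, "CA3", TRUE,  character()),
    list(40,   0.05, "CA1", FALSE, "power"),
    list(40,   0.1,  "CA1", FALSE, "power"),
    list(40,   0.5,  "CA1", TRUE,  character()),
    list(40,   5,    "CA3", TRUE,  character()),
    list(15,   0.5,  "CA3", FALSE, c("frequency", "power")))
  for (cs in cases) {
    out <- qc_slice(fake_m(cs[[1]], cs[[2]], cs[[3]]), ps = NULL, cfg = cfg)
    expect_equal(out$qc_pass, cs[[4]],
                 info = sprintf("freq=%g power=%g region=%s",
                                cs[[1]], cs[[2]], cs[[3]]))
    expect_equal(out$qc_reasons, cs[[5]])
  }
})

test_that("mains contamination flags a 60 Hz spike and QC reports it", {
  f <- seq(0, 120, by = 0.5)
  clean <- rep(1, length(f))
  dirty <- clean; dirty[f >= 58 & f <= 62] <- 20
  expect_lt(mains_contamination(fake_spectrum(f, clean)), 2)
  expect_gt(mains_contamination(fake_spectrum(f, dirty)), 5)
  m <- gamma_metrics(fake_spectrum(f, dirty))
  out <- qc_slice(m, fake_spectrum(f, dirty), analysis_config())
  expect_true("mains" %in% out$qc_reasons)
})

test_that("QC is monotone in peak power", {
  cfg <- analysis_config()
  set.seed(21)
  for (i in 1:50) {
    freq <- runif(1, 10, 100)
    p_lo <- runif(1, 0.01, 5)
    p_hi <- p_lo * runif(1, 1, 10)
    region <- sample(c("CA3", "CA1"), 1)
    mk <- function(p) qc_slice(structure(
      list(peak_frequency = freq, peak_power = p, bandwidth_power = 1,
           region = region, qc_pass = NA, qc_reasons = character()),
      class = "gp_gamma_metrics"), NULL, cfg)
    expect_false(mk(p_lo)$qc_pass && !mk(p_hi)$qc_pass)
  }
})

test_that("peak and integral agree with exhaustive oracles on small spectra", {
  set.seed(31)
  for (i in 1:25) {
    nb <- sample(16:64, 1)
    f <- seq(5, 120, length.out = nb)
    p <- runif(nb)
    ps <- fake_spectrum(f, p)
    m <- gamma_metrics(ps, band = c(20, 80), exclude_mains = FALSE)
    # exhaustive scan oracle
    expect_equal(m$peak_frequency, f[which.max(p)])
    expect_equal(m$peak_power, max(p))
    # Riemann/trapezoid oracle on the same grid, with interpolated edges
    fi <- c(20, f[f > 20 & f < 80], 80)
    pi_ <- approx(f, p, xout = fi)$y
    oracle <- sum(diff(fi) * (pi_[-1] + pi_[-length(pi_)]) / 2)
    expect_equal(m$bandwidth_power, oracle, tolerance = 1e-10)
  }
})
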