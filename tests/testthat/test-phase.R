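test_that("phase convention puts the cycle peak at 0 and trough at pi", {
  fs <- 4000   # 100 samples per 40 Hz cycle: quarter-period lands on the grid
  f0 <- 40
  tr <- make_tone(f0, dur = 10, fs = fs)
  ph <- instantaneous_phase(tr, band = c(20, 80))
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  core <- t > 1 & t < 9
  peaks <- which(core & abs((t * f0) %% 1) < 1e-9)         # cosine maxima
  troughs <- which(core & abs((t * f0) %% 1 - 0.5) < 1e-9) # cosine minima
  quarter <- which(core & abs((t * f0) %% 1 - 0.25) < 1e-9)
  wrapdist <- function(a, b) abs(atan2(sin(a - b), cos(a - b)))
  expect_lt(max(wrapdist(ph$phase[peaks], 0)), 0.05)
  expect_lt(max(wrapdist(ph$phase[troughs], pi)), 0.05)
  expect_lt(max(wrapdist(ph$phase[quarter], pi / 2)), 0.05)
  # polarity flip moves the peak to pi
  phi <- instantaneous_phase(tr, band = c(20, 80), invert = TRUE)
  expect_lt(max(wrapdist(phi$phase[peaks], pi)), 0.05)
  expect_error(instantaneous_phase(tr, band = c(80, 20)), "band")
})

test_that("spike phases are sampled at peaks/troughs and interpolated between", {
  fs <- 2000
  f0 <- 40
  tr <- make_tone(f0, dur = 10, fs = fs)
  ph <- instantaneous_phase(tr, band = c(20, 80))
  peak_times <- seq(1, 9, by = 1 / f0)
  trough_times <- peak_times + 1 / (2 * f0)
  pp <- spike_phases(peak_times, ph)
  pt <- spike_phases(trough_times, ph)
  wrapdist <- function(a, b) abs(atan2(sin(a - b), cos(a - b)))
  expect_lt(max(wrapdist(pp, 0)), 0.05)
  expect_lt(max(wrapdist(pt, pi)), 0.05)

  # midpoint interpolation on a linear phase ramp
  ramp <- structure(list(phase = c(0.2, 0.4) %% (2 * pi),
                         unwrapped = c(0.2, 0.4), fs = 1, t0 = 0),
                    class = "gp_phase")
  expect_equal(as.numeric(spike_phases(0.5, ramp)), 0.3)

  expect_warning(out <- spike_phases(c(5, 100), ph), "skipped")
  expect_equal(attr(out, "n_skipped"), 1)
  expect_length(out, 1)
})

test_that("circular mean vector handles concentration, antipodes and mixtures", {
  mv1 <- cell_mean_vector(rep(pi / 4, 8))
  expect_equal(mv1$mean_angle, pi / 4)
  expect_equal(mv1$vector_length, 1)
  mv2 <- cell_mean_vector(c(0, pi))
  expect_equal(mv2$vector_length, 0, tolerance = 1e-12)
  expect_true(is.nan(mv2$mean_angle))
  mv3 <- cell_mean_vector(c(0, pi / 2))
  expect_equal(mv3$mean_angle, pi / 4)
  expect_equal(mv3$vector_length, cos(pi / 4), tolerance = 1e-12)
  expect_error(cell_mean_vector(numeric(0)), "empty")
})

test_that("Rayleigh test is maximal for identical angles and calibrated under the null", {
  r1 <- rayleigh_test(rep(1.3, 100))
  expect_lt(r1$p, 1e-10)
  expect_equal(r1$z, 100, tolerance = 1e-9)

  set.seed(61)
  rej <- mean(replicate(1000, rayleigh_test(runif(30, 0, 2 * pi))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.02)
  expect_error(rayleigh_test(c(0, 1)), "at least 3")
})

test_that("Rayleigh series p agrees with a Monte-Carlo null oracle at small n", {
  set.seed(62)
  # a weakly concentrated sample of 10 angles (r around 0.2-0.4)
  phases <- c(0.1, 1.2, 2.5, 3.3, 4.0, 4.4, 5.0, 5.9, 0.7, 2.0)
  got <- rayleigh_test(phases)$p
  mc <- rayleigh_mc_oracle(phases, n_sim = 20000)
  expect_lt(abs(got - mc), 3 * sqrt(mc * (1 - mc) / 20000) + 0.01)
})

test_that("second-order grand mean is the average of the cell mean vectors", {
  cells <- list(cell_with_vector(1, 0), cell_with_vector(0.5, pi),
                cell_with_vector(0.8, 0), cell_with_vector(0.3, pi))
  # collinear mean vectors: the scatter is singular, which is warned about
  expect_warning(pop <- hotelling_one_sample(cells), "singular")
  # rectangular mean: ((1 - 0.5 + 0.8 - 0.3)/4, 0) = (0.25, 0)
  expect_equal(pop$grand_mean_length, 0.25, tolerance = 1e-12)
  expect_equal(pop$grand_mean_angle, 0)
  expect_equal(pop$n_cells, 4)
  # the two-cell case from vector arithmetic refuses the test
  expect_error(hotelling_one_sample(list(cell_with_vector(1, 0),
                                         cell_with_vector(0.5, pi))),
               "at least 3")
})

test_that("Hotelling one-sample test is calibrated and detects a shared direction", {
  set.seed(63)
  rej <- mean(replicate(2000, {
    hotelling_one_sample(synthetic_cells(20, 0, 0, sd = 0.3))$hotelling_p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.015)

  set.seed(64)
  target <- 5.0
  cells <- lapply(1:9, function(j)
    cell_with_vector(0.3 + rnorm(1, 0, 0.03),
                     target + rnorm(1, 0, 0.1), id = j))
  pop <- hotelling_one_sample(cells)
  expect_lt(pop$hotelling_p, 0.05)
  expect_lt(abs(pop$grand_mean_angle - target), 0.1)
})

test_that("Batschelet two-sample test is calibrated and separates opposed groups", {
  gA <- lapply(1:6, function(j) cell_with_vector(0.5 + 0.01 * j, 0.1 * j))
  same <- batschelet_two_sample(gA, gA)
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  set.seed(65)
  g0 <- lapply(1:10, function(j) cell_with_vector(0.8 + rnorm(1, 0, 0.05),
                                                  rnorm(1, 0, 0.15)))
  gpi <- lapply(1:10, function(j) cell_with_vector(0.8 + rnorm(1, 0, 0.05),
                                                   pi + rnorm(1, 0, 0.15)))
  expect_lt(batschelet_two_sample(g0, gpi)$p, 0.01)

  set.seed(66)
  rej <- mean(replicate(2000, {
    batschelet_two_sample(synthetic_cells(10, 0.2, 0.1, 0.25),
                          synthetic_cells(12, 0.2, 0.1, 0.25))$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.015)
  expect_error(batschelet_two_sample(gA, gA[1:2]), "at least 3")
})

test_that("modulation comparison reports variance-F and KS against formula oracles", {
  r <- c(0.2, 0.4, 0.5, 0.7)
  same <- modulation_comparison(r, r)
  expect_equal(same$var_F, 1)
  expect_equal(same$var_p, 1)
  expect_equal(same$ks_D, 0)
  expect_equal(same$ks_p, 1)

  rA <- rep(0.1, 4); rB <- c(0.0, 0.2, 0.4, 0.6)
  out <- modulation_comparison(rB, rA)  # rA has zero variance
  # formula oracle
  D_oracle <- suppressWarnings(unname(ks.test(rB, rA)$statistic))
  expect_equal(out$ks_D, D_oracle)
  expect_true(is.infinite(out$var_F))

  # cross-check the two-sided variance test against stats::var.test
  set.seed(67)
  a <- runif(11); b <- runif(8)
  out2 <- modulation_comparison(a, b)
  expect_equal(out2$var_p, var.test(a, b)$p.value, tolerance = 1e-12)

  # the published-scale case: F(10,7) = 6.19 gives p about 0.024
  expect_equal(2 * pf(6.19, 10, 7, lower.tail = FALSE), 0.0242,
               tolerance = 2e-3)
})

test_that("KS branch of the modulation comparison is calibrated under the null", {
  set.seed(68)
  rej <- mean(replicate(2000, {
    modulation_comparison(runif(10), runif(12))$ks_p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("all phase statistics are rotationally equivariant", {
  set.seed(69)
  delta <- 1.234
  groups <- lapply(1:2, function(g) {
    lapply(1:8, function(j) {
      ph <- (rnorm(40, mean = g, sd = 0.8)) %% (2 * pi)
      list(orig = cell_phase_stats(j, ph),
           rot = cell_phase_stats(j, (ph + delta) %% (2 * pi)))
    })
  })
  orig <- lapply(groups, function(g) lapply(g, `[[`, "orig"))
  rot <- lapply(groups, function(g) lapply(g, `[[`, "rot"))
  wrapdist <- function(a, b) abs(atan2(sin(a - b), cos(a - b)))
  for (j in 1:8) {
    expect_equal(rot[[1]][[j]]$vector_length, orig[[1]][[j]]$vector_length,
                 tolerance = 1e-12)
    expect_equal(rot[[1]][[j]]$rayleigh_p, orig[[1]][[j]]$rayleigh_p,
                 tolerance = 1e-12)
    expect_lt(wrapdist(rot[[1]][[j]]$mean_angle,
                       orig[[1]][[j]]$mean_angle + delta), 1e-9)
  }
  po <- hotelling_one_sample(orig[[1]]); pr <- hotelling_one_sample(rot[[1]])
  expect_equal(pr$hotelling_p, po$hotelling_p, tolerance = 1e-9)
  expect_lt(wrapdist(pr$grand_mean_angle, po$grand_mean_angle + delta), 1e-9)
  bo <- batschelet_two_sample(orig[[1]], orig[[2]])
  br <- batschelet_two_sample(rot[[1]], rot[[2]])
  expect_equal(br$p, bo$p, tolerance = 1e-9)
})

test_that("the grand mean length never exceeds the mean cell vector length", {
  set.seed(70)
  for (i in 1:20) {
    cells <- synthetic_cells(sample(3:15, 1), rnorm(1, 0, 0.3),
                             rnorm(1, 0, 0.3), sd = runif(1, 0.05, 0.4))
    pop <- hotelling_one_sample(cells)
    rj <- vapply(cells, `[[`, numeric(1), "vector_length")
    expect_lte(pop$grand_mean_length, mean(rj) + 1e-12)
    expect_lte(pop$grand_mean_length, max(rj) + 1e-12)
  }
})

test_that("degree reporting matches the paired radian/degree convention", {
  expect_equal(phase_degrees(5.070), 290L)
  expect_equal(phase_degrees(4.450), 255L)
  expect_equal(phase_degrees(4.958), 284L)
  expect_equal(phase_degrees(4.539), 260L)
  expect_equal(phase_degrees(0), 0L)
  expect_equal(phase_degrees(2 * pi - 1e-9), 0L)
  expect_equal(phase_degrees(-pi / 2), 270L)
})
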