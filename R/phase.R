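#' Instantaneous gamma phase of an LFP trace
#'
#' Band-passes the trace to the gamma band, forms the analytic signal
#' (FFT half-spectrum doubling), and returns its argument wrapped to
#' `[0, 2*pi)`. The convention places the positive peak of the oscillation
#' cycle at phase 0 and the trough at pi, with phase advancing through the
#' falling edge (0 -> pi) and the rising edge (pi -> 2*pi). `invert` flips the
#' signal first, for recordings whose field polarity is reversed.
#'
#' @param tr An LFP [trace()].
#' @param band Gamma band (Hz) for the pre-filter; `NULL` if `tr` is already
#'   filtered.
#' @param invert Flip signal polarity before phase extraction.
#' @return `gp_phase`: list with `phase` (rad, `[0, 2*pi)`), `unwrapped`
#'   (monotone-ish unwrapped phase used for interpolation), `fs`, `t0`.
#' @export
instantaneous_phase <- function(tr, band = c(20, 80), invert = FALSE) {
  stopifnot(inherits(tr, "gp_trace"))
  if (!is.null(band)) {
    if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2])
      stop("invalid phase-extraction band")
    tr <- bandpass(tr, band[1], band[2])
  }
  x <- tr$samples
  if (invert) x <- -x
  z <- analytic_signal(x)
  ph <- Arg(z)                      # cos-referenced: peak -> 0, trough -> +/-pi
  unw <- unwrap_phase(ph)
  structure(list(phase = ph %% (2 * pi), unwrapped = unw,
                 fs = tr$fs, t0 = tr$t0),
            class = "gp_phase")
}

analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1L], d))
}

#' Gamma phase at each spike time
#'
#' Samples the unwrapped instantaneous phase at each spike time by linear
#' interpolation and wraps back to `[0, 2*pi)`. Spikes outside the phase
#' trace's span are skipped; the number skipped is attached as an attribute.
#'
#' @param train A `gp_spiketrain` (or numeric vector of spike times, s).
#' @param ph A `gp_phase`.
#' @return Numeric vector of phases in radians with attribute `n_skipped`.
#' @export
spike_phases <- function(train, ph) {
  stopifnot(inherits(ph, "gp_phase"))
  times <- if (inherits(train, "gp_spiketrain")) train$times else as.numeric(train)
  tgrid_end <- ph$t0 + (length(ph$phase) - 1L) / ph$fs
  inside <- times >= ph$t0 & times <= tgrid_end
  n_skip <- sum(!inside)
  if (n_skip) warning(sprintf("%d spike(s) outside the phase-trace span skipped", n_skip))
  idx <- (times[inside] - ph$t0) * ph$fs + 1
  lo <- pmax(1L, pmin(floor(idx), length(ph$phase) - 1L))
  frac <- idx - lo
  val <- ph$unwrapped[lo] * (1 - frac) + ph$unwrapped[lo + 1L] * frac
  out <- val %% (2 * pi)
  attr(out, "n_skipped") <- n_skip
  out
}

#' Circular mean vector of a phase sample
#'
#' @param phases Radian angles (any range; wrapped internally).
#' @return List with `mean_angle` (rad in `[0, 2*pi)`, `NaN` when the
#'   resultant length is 0) and `vector_length` (r in `[0, 1]`).
#' @export
cell_mean_vector <- function(phases) {
  if (!length(phases)) stop("cannot compute a mean vector of an empty sample")
  C <- mean(cos(phases)); S <- mean(sin(phases))
  r <- sqrt(C^2 + S^2)
  ang <- if (r < .Machine$double.eps^0.5 * 10) NaN else atan2(S, C) %% (2 * pi)
  list(mean_angle = ang, vector_length = min(r, 1))
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that the spike phases are uniform on the circle.
#' `z = n * r^2`; the p-value uses the standard four-term series
#' approximation, clipped to `(0, 1]`.
#'
#' @param phases Radian angles, n >= 3.
#' @return List with `z`, `p`, `n`, `r`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n < 3L) stop("Rayleigh test needs at least 3 angles")
  r <- cell_mean_vector(phases)$vector_length
  z <- n * r^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, .Machine$double.xmin), 1)
  list(z = z, p = p, n = n, r = r)
}

#' First-order phase statistics for one cell
#'
#' Bundles the spike-phase sample of one cell with its circular mean vector
#' and Rayleigh test; `locked` flags p < alpha.
#'
#' @param cell_id Identifier.
#' @param phases Radian spike phases.
#' @param alpha Significance level for the `locked` flag.
#' @return `gp_cell_phase` with fields `cell_id`, `spike_phases`,
#'   `mean_angle`, `vector_length`, `n_spikes`, `rayleigh_z`, `rayleigh_p`,
#'   `locked`.
#' @export
cell_phase_stats <- function(cell_id, phases, alpha = 0.05) {
  phases <- as.numeric(phases) %% (2 * pi)
  mv <- cell_mean_vector(phases)
  ray <- if (length(phases) >= 3L) rayleigh_test(phases)
         else list(z = NA_real_, p = NA_real_)
  structure(list(cell_id = cell_id, spike_phases = phases,
                 mean_angle = mv$mean_angle,
                 vector_length = mv$vector_length,
                 n_spikes = length(phases),
                 rayleigh_z = ray$z, rayleigh_p = ray$p,
                 locked = is.finite(ray$p) && ray$p < alpha),
            class = "gp_cell_phase")
}

cells_xy <- function(cells) {
  r <- vapply(cells, `[[`, numeric(1), "vector_length")
  a <- vapply(cells, `[[`, numeric(1), "mean_angle")
  cbind(X = r * cos(a), Y = r * sin(a))
}

#' Hotelling's one-sample second-order test of a mean direction
#'
#' Each cell contributes its mean vector as a point `(X_j, Y_j) = (r_j cos
#' a_j, r_j sin a_j)`; cells are thereby implicitly weighted by their own
#' concentration r_j, never by spike count. The test asks whether the
#' population of these points is centred away from the origin, i.e. whether
#' the cell population as a whole has a mean phase preference:
#' `F = n(n-2)/2 * (Xbar^2 y - 2 Xbar Ybar xy + Ybar^2 x) / (xy_det)` with
#' `x, y, xy` the centred sums of squares/products and `F ~ F(2, n-2)` under
#' the null.
#'
#' @param cells List of `gp_cell_phase` (n >= 3).
#' @return `gp_population_phase` with `grand_mean_angle`, `grand_mean_length`,
#'   `n_cells`, `hotelling_F`, `hotelling_p`.
#' @export
hotelling_one_sample <- function(cells) {
  n <- length(cells)
  if (n < 3L) stop("second-order one-sample test needs at least 3 cells")
  P <- cells_xy(cells)
  Xb <- mean(P[, 1L]); Yb <- mean(P[, 2L])
  x <- sum((P[, 1L] - Xb)^2); y <- sum((P[, 2L] - Yb)^2)
  xy <- sum((P[, 1L] - Xb) * (P[, 2L] - Yb))
  det <- x * y - xy^2
  grand_r <- sqrt(Xb^2 + Yb^2)
  grand_a <- if (grand_r > 0) atan2(Yb, Xb) %% (2 * pi) else NaN
  if (det <= .Machine$double.eps) {
    warning("singular within-sample scatter; p reported as machine minimum")
    F <- Inf; p <- .Machine$double.xmin
  } else {
    F <- n * (n - 2) / 2 * (Xb^2 * y - 2 * Xb * Yb * xy + Yb^2 * x) / det
    p <- stats::pf(F, 2, n - 2, lower.tail = FALSE)
    p <- min(max(p, .Machine$double.xmin), 1)
  }
  structure(list(grand_mean_angle = grand_a, grand_mean_length = grand_r,
                 n_cells = n, hotelling_F = F, hotelling_p = p),
            class = "gp_population_phase")
}

#' @export
print.gp_population_phase <- function(x, ...) {
  cat(sprintf("<population phase> n=%d, grand mean %.3f rad/%d deg, length %.3f, Hotelling F=%.3f p=%.4g\n",
              x$n_cells, x$grand_mean_angle, phase_degrees(x$grand_mean_angle),
              x$grand_mean_length, x$hotelling_F, x$hotelling_p))
  invisible(x)
}

#' Batschelet's two-sample second-order test
#'
#' Compares the population mean vectors of two groups of cells via the
#' two-sample Hotelling statistic on the cells' mean-vector points, using the
#' pooled within-group scatter: `F ~ F(2, N-3)` under equality of the two
#' population centres.
#'
#' @param groupA,groupB Lists of `gp_cell_phase`, each with >= 3 cells.
#' @return List with `F`, `p`, `df` and the two group centres.
#' @export
batschelet_two_sample <- function(groupA, groupB) {
  n1 <- length(groupA); n2 <- length(groupB)
  if (n1 < 3L || n2 < 3L)
    stop("second-order two-sample test needs at least 3 cells per group")
  P1 <- cells_xy(groupA); P2 <- cells_xy(groupB)
  N <- n1 + n2
  cs <- function(v) sum((v - mean(v))^2)
  cp <- function(a, b) sum((a - mean(a)) * (b - mean(b)))
  x <- cs(P1[, 1L]) + cs(P2[, 1L])
  y <- cs(P1[, 2L]) + cs(P2[, 2L])
  xy <- cp(P1[, 1L], P1[, 2L]) + cp(P2[, 1L], P2[, 2L])
  det <- x * y - xy^2
  dX <- mean(P1[, 1L]) - mean(P2[, 1L])
  dY <- mean(P1[, 2L]) - mean(P2[, 2L])
  if (det <= .Machine$double.eps) {
    if (abs(dX) < 1e-12 && abs(dY) < 1e-12) return(
      list(F = 0, p = 1, df = c(2, N - 3),
           centreA = colMeans(P1), centreB = colMeans(P2)))
    warning("singular pooled scatter; degenerate p reported")
    return(list(F = Inf, p = .Machine$double.xmin, df = c(2, N - 3),
                centreA = colMeans(P1), centreB = colMeans(P2)))
  }
  F <- n1 * n2 * (N - 3) / (2 * N) *
    (dX^2 * y - 2 * dX * dY * xy + dY^2 * x) / det
  p <- min(max(stats::pf(F, 2, N - 3, lower.tail = FALSE),
               .Machine$double.xmin), 1)
  list(F = F, p = p, df = c(2, N - 3),
       centreA = colMeans(P1), centreB = colMeans(P2))
}

#' Compare modulation-strength distributions between two groups
#'
#' Two companion tests on the per-cell vector lengths: a two-sided
#' variance-ratio F test with the larger variance in the numerator, and a
#' two-sample Kolmogorov-Smirnov test (exact p at small samples) on the full
#' distributions.
#'
#' @param rA,rB Numeric vectors of vector lengths in `[0, 1]`, each n >= 2.
#' @return List with `var_F`, `var_df`, `var_p`, `ks_D`, `ks_p`.
#' @export
modulation_comparison <- function(rA, rB) {
  if (length(rA) < 2L || length(rB) < 2L)
    stop("each group needs at least 2 modulation values")
  vA <- stats::var(rA); vB <- stats::var(rB)
  if (vA == 0 && vB == 0) {
    F <- NA_real_; dfF <- c(NA, NA); pF <- NA_real_
    warning("zero variance in both groups; variance test degenerate")
  } else {
    if (vA >= vB) { F <- vA / vB; dfF <- c(length(rA) - 1L, length(rB) - 1L) }
    else { F <- vB / vA; dfF <- c(length(rB) - 1L, length(rA) - 1L) }
    pF <- min(1, 2 * stats::pf(F, dfF[1L], dfF[2L], lower.tail = FALSE))
  }
  ks <- suppressWarnings(stats::ks.test(rA, rB))
  list(var_F = F, var_df = dfF, var_p = pF,
       ks_D = unname(ks$statistic), ks_p = ks$p.value)
}

#' Report an angle in degrees as printed in figures
#'
#' Converts radians to degrees rounded to the nearest degree (e.g. 5.070 rad
#' -> 290 degrees; 4.450 rad -> 255 degrees).
#'
#' @param rad Angle(s) in radians.
#' @return Integer degrees in `[0, 360)`.
#' @export
phase_degrees <- function(rad) {
  as.integer(round((rad %% (2 * pi)) * 180 / pi)) %% 360L
}
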