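#' Normalized autocorrelogram of an LFP epoch
#'
#' Biased, normalized autocorrelation (value 1 at zero lag) of a
#' mean-subtracted epoch, mirrored over negative lags. This is the object from
#' which the coefficient of rhythmicity is read.
#'
#' @param epoch A [trace()].
#' @param max_lag Maximum lag in seconds (default 0.1 s, at least two gamma
#'   cycles at 20 Hz).
#' @return `gp_correlogram` with `lags` (s, symmetric about 0), `values`,
#'   `kind = "auto"`.
#' @export
autocorrelogram <- function(epoch, max_lag = 0.1) {
  stopifnot(inherits(epoch, "gp_trace"))
  if (max_lag <= 0) stop("'max_lag' must be positive")
  fs <- epoch$fs
  L <- round(max_lag * fs)
  n <- length(epoch$samples)
  if (n <= 2L * L)
    stop("epoch must be longer than twice the maximum lag")
  a <- stats::acf(epoch$samples, lag.max = L, type = "correlation",
                  demean = TRUE, plot = FALSE)
  v <- as.numeric(a$acf)
  lags <- c(rev(-(1:L)), 0:L) / fs
  vals <- c(rev(v[-1L]), v)
  structure(list(lags = lags, values = vals, kind = "auto",
                 peak_value = 1, peak_lag = 0, fs = fs),
            class = "gp_correlogram")
}

#' Normalized CA3-CA1 cross-correlogram
#'
#' Pearson-normalized (biased) cross-correlation between the two channels,
#' with the sign convention that a positive peak lag means the CA1 signal
#' follows (lags behind) the CA3 signal. Ties at the peak resolve to the
#' smallest absolute lag.
#'
#' @param ca3,ca1 [trace()] objects with equal sampling rate and length.
#' @param max_lag Maximum lag in seconds.
#' @return `gp_correlogram` with `kind = "cross"`, `peak_value`, `peak_lag`.
#' @export
cross_correlogram <- function(ca3, ca1, max_lag = 0.1) {
  stopifnot(inherits(ca3, "gp_trace"), inherits(ca1, "gp_trace"))
  if (max_lag <= 0) stop("'max_lag' must be positive")
  if (ca3$fs != ca1$fs || length(ca3$samples) != length(ca1$samples))
    stop("channels must share sampling rate and length")
  if (stats::sd(ca3$samples) == 0 || stats::sd(ca1$samples) == 0)
    stop("zero-variance input")
  fs <- ca3$fs
  L <- round(max_lag * fs)
  # ccf(ca1, ca3) at lag k estimates cor(ca1[t+k], ca3[t]); if CA1 is a
  # delayed copy of CA3 the peak sits at k = +delay, as required.
  cc <- stats::ccf(ca1$samples, ca3$samples, lag.max = L, plot = FALSE,
                   demean = TRUE)
  vals <- as.numeric(cc$acf)
  lags <- as.numeric(cc$lag) / fs
  best <- which(vals == max(vals))
  best <- best[which.min(abs(lags[best]))]
  structure(list(lags = lags, values = vals, kind = "cross",
                 peak_value = vals[best], peak_lag = lags[best], fs = fs),
            class = "gp_correlogram")
}

#' @export
print.gp_correlogram <- function(x, ...) {
  cat(sprintf("<gp_correlogram %s> lags +/-%.3g s (%d points), peak %.3f at %.4g ms\n",
              x$kind, max(x$lags), length(x$lags), x$peak_value,
              x$peak_lag * 1e3))
  invisible(x)
}

#' Coefficient of rhythmicity from an autocorrelogram
#'
#' Locates, on the positive-lag branch, the first trough (local minimum) and
#' the subsequent second peak (local maximum), refines both by three-point
#' parabolic interpolation, and computes `Cr = (alpha - beta)/(alpha + beta)`
#' where `alpha` and `beta` are the second-peak and first-trough heights after
#' the correlogram values (in `[-1, 1]`) are rescaled to `[0, 1]` via
#' `(r + 1)/2`. Under that convention a perfect oscillation gives Cr = 1
#' (alpha = 1, beta = 0) and white noise gives Cr near 0 (alpha and beta both
#' near 0.5); values of at least 0.01 are classed as rhythmic.
#'
#' @param acf_obj A `gp_correlogram` of kind `"auto"`.
#' @param min_lag Lags at or below this (s) are excluded from the extremum
#'   search, keeping the central peak out of consideration.
#' @param rhythmic_min Threshold on Cr for the `rhythmic` flag.
#' @return `gp_rhythmicity` with `cr`, `alpha`, `beta`, `second_peak_lag`,
#'   `rhythmic`, and `reason` when degenerate.
#' @export
coefficient_of_rhythmicity <- function(acf_obj, min_lag = 1e-3,
                                       rhythmic_min = 0.01) {
  stopifnot(inherits(acf_obj, "gp_correlogram"))
  if (acf_obj$kind != "auto")
    stop("coefficient of rhythmicity is defined on autocorrelograms")
  pos <- acf_obj$lags > 0
  lags <- acf_obj$lags[pos]
  vals <- acf_obj$values[pos]
  keep <- lags > min_lag
  lags <- lags[keep]; vals <- vals[keep]

  degenerate <- function(reason) {
    structure(list(cr = 0, alpha = NA_real_, beta = NA_real_,
                   second_peak_lag = NA_real_, rhythmic = FALSE,
                   reason = reason),
              class = "gp_rhythmicity")
  }
  n <- length(vals)
  if (n < 3L) return(degenerate("correlogram too short"))
  d <- diff(vals)
  # first interior local minimum
  tr_i <- which(d[-length(d)] < 0 & d[-1L] >= 0)
  if (!length(tr_i)) return(degenerate("no trough found (monotone correlogram)"))
  ti <- tr_i[1L] + 1L
  # first local maximum after the trough
  pk_i <- which(d[-length(d)] > 0 & d[-1L] <= 0)
  pk_i <- pk_i[pk_i + 1L > ti]
  if (!length(pk_i)) return(degenerate("no second peak after the trough"))
  pi_ <- pk_i[1L] + 1L

  ref <- function(i) {
    if (i <= 1L || i >= n) return(c(vals[i], lags[i]))
    y1 <- vals[i - 1L]; y2 <- vals[i]; y3 <- vals[i + 1L]
    den <- y1 - 2 * y2 + y3
    if (abs(den) < .Machine$double.eps) return(c(y2, lags[i]))
    dlt <- 0.5 * (y1 - y3) / den
    c(y2 - 0.25 * (y1 - y3) * dlt, lags[i] + dlt * (lags[2L] - lags[1L]))
  }
  trough <- ref(ti)
  peak <- ref(pi_)
  alpha <- (peak[1L] + 1) / 2
  beta <- (trough[1L] + 1) / 2
  cr <- (alpha - beta) / (alpha + beta)
  reason <- NULL
  if (!is.finite(cr)) return(degenerate("degenerate heights"))
  if (cr < 0 || cr > 1) {
    warning(sprintf("Cr = %.4g outside [0, 1]; clipping", cr))
    cr <- min(max(cr, 0), 1)
    reason <- "clipped"
  }
  structure(list(cr = cr, alpha = alpha, beta = beta,
                 second_peak_lag = peak[2L],
                 rhythmic = cr >= rhythmic_min, reason = reason),
            class = "gp_rhythmicity")
}

#' @export
print.gp_rhythmicity <- function(x, ...) {
  cat(sprintf("<rhythmicity> Cr = %.4f (alpha %.3f, beta %.3f), second peak at %.4g ms, %s\n",
              x$cr, x$alpha, x$beta, x$second_peak_lag * 1e3,
              if (x$rhythmic) "rhythmic" else "not rhythmic"))
  if (!is.null(x$reason)) cat("  note:", x$reason, "\n")
  invisible(x)
}
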