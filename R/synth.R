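#' Specification for a synthetic two-channel gamma LFP
#'
#' Parameters of the generator that emulates an interface-chamber slice
#' recording: a gamma-band carrier with a slowly waxing/waning envelope
#' (exponentiated Ornstein-Uhlenbeck modulation), 1/f^chi background noise,
#' an optional 60 Hz mains line, and a delayed, attenuated copy of the
#' oscillatory component in the CA1 channel. Defaults reflect the study
#' conditions: 10 kHz acquisition, ~40 Hz carbachol/kainate-style gamma of
#' ~50 uV amplitude analysed over a 5-minute washout-scale span, CA1 lagging
#' CA3 by a few milliseconds at roughly half the amplitude.
#'
#' @param duration Record length in seconds.
#' @param fs Sampling rate (Hz); must exceed twice the 120 Hz analysis band.
#' @param f0 Gamma carrier frequency (Hz).
#' @param gamma_amp Carrier amplitude (uV).
#' @param env_tau Envelope OU timescale (s).
#' @param env_depth Envelope modulation depth, 0 (constant) to ~1 (strongly
#'   waxing/waning).
#' @param phase_jitter Phase diffusion rate of the carrier (rad^2/s); 0 gives
#'   a perfectly rhythmic carrier, larger values degrade rhythmicity.
#' @param noise_chi Spectral exponent of the background noise (power ~
#'   1/f^chi).
#' @param noise_amp RMS amplitude of the background noise (uV).
#' @param mains_amp Amplitude of an added 60 Hz line component (uV).
#' @param ca1_delay CA3 -> CA1 propagation delay (s).
#' @param ca1_gain CA1 amplitude relative to CA3, in `[0, 1]`.
#' @param seed Integer seed; the generated recording is a pure function of
#'   the spec including this seed.
#' @return List of class `gp_lfp_spec`.
#' @export
lfp_spec <- function(duration = 300, fs = 10000, f0 = 40, gamma_amp = 50,
                     env_tau = 0.5, env_depth = 0.5, phase_jitter = 0,
                     noise_chi = 1, noise_amp = 20, mains_amp = 0,
                     ca1_delay = 0.005, ca1_gain = 0.5, seed = 1L) {
  if (fs <= 240) stop("sampling rate must exceed 240 Hz (2 x 120 Hz band)")
  if (duration <= 0) stop("duration must be positive")
  if (gamma_amp < 0 || noise_amp < 0 || mains_amp < 0)
    stop("amplitudes must be non-negative")
  if (ca1_gain < 0 || ca1_gain > 1) stop("ca1_gain must lie in [0, 1]")
  if (env_depth < 0 || phase_jitter < 0)
    stop("env_depth and phase_jitter must be non-negative")
  structure(list(duration = duration, fs = fs, f0 = f0,
                 gamma_amp = gamma_amp, env_tau = env_tau,
                 env_depth = env_depth, phase_jitter = phase_jitter,
                 noise_chi = noise_chi, noise_amp = noise_amp,
                 mains_amp = mains_amp, ca1_delay = ca1_delay,
                 ca1_gain = ca1_gain, seed = as.integer(seed)),
            class = "gp_lfp_spec")
}

# stationary unit-variance OU process sampled at dt, via its exact AR(1) form
ou_process <- function(n, dt, tau) {
  a <- exp(-dt / tau)
  innov <- stats::rnorm(n, sd = sqrt(1 - a^2))
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

# zero-mean noise with power spectral density ~ 1/f^chi, unit RMS,
# synthesized in the frequency domain and truncated below f_lo
colored_noise <- function(n, fs, chi, f_lo = 0.5) {
  freqs <- seq(0, fs / 2, by = fs / n)
  nf <- length(freqs)
  mag <- numeric(nf)
  ok <- freqs >= f_lo
  mag[ok] <- freqs[ok]^(-chi / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  half <- mag * exp(1i * ph)
  spec <- c(half, Conj(rev(half[2:(n - nf + 1L)])))
  x <- Re(stats::fft(spec[seq_len(n)], inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate a synthetic two-channel (CA3 + CA1) gamma recording
#'
#' CA3 is `gamma_amp * envelope * cos(2 pi f0 t + jitter)` plus coloured
#' noise and any mains line; CA1 is the same oscillatory component delayed by
#' `ca1_delay` and scaled by `ca1_gain`, plus independent noise. The whole
#' record is annotated as a single `drug` epoch. Output is fully determined
#' by the spec (same seed, bit-identical samples).
#'
#' @param spec An [lfp_spec()].
#' @param genotype,age_group,drug,subject_id Cohort labels for the recording.
#' @return A [recording()] with CA3_LFP and CA1_LFP channels.
#' @export
gen_lfp <- function(spec, genotype = "control", age_group = "young",
                    drug = "kainate", subject_id = "synthetic") {
  stopifnot(inherits(spec, "gp_lfp_spec"))
  set.seed(spec$seed)
  fs <- spec$fs
  n <- round(spec$duration * fs)
  nd <- round(spec$ca1_delay * fs)
  dt <- 1 / fs
  # oscillatory component over an extended span so CA1 can lag CA3 exactly
  next_ <- n + nd
  t_ext <- (seq_len(next_) - 1L) * dt
  env <- if (spec$env_depth > 0)
    exp(spec$env_depth * ou_process(next_, dt, spec$env_tau)) else rep(1, next_)
  jit <- if (spec$phase_jitter > 0)
    cumsum(stats::rnorm(next_, sd = sqrt(spec$phase_jitter * dt))) else 0
  osc <- spec$gamma_amp * env * cos(2 * pi * spec$f0 * t_ext + jit)
  t <- t_ext[seq_len(n)]
  noise3 <- if (spec$noise_amp > 0)
    spec$noise_amp * colored_noise(n, fs, spec$noise_chi) else 0
  noise1 <- if (spec$noise_amp > 0)
    spec$noise_amp * colored_noise(n, fs, spec$noise_chi) else 0
  mains <- if (spec$mains_amp > 0) spec$mains_amp * sin(2 * pi * 60 * t) else 0
  ca3 <- osc[(nd + 1L):(nd + n)] + noise3 + mains
  ca1 <- spec$ca1_gain * osc[seq_len(n)] + noise1 + mains
  recording(list(trace(ca3, fs, "CA3_LFP"), trace(ca1, fs, "CA1_LFP")),
            subject_id = subject_id, genotype = genotype,
            age_group = age_group, drug = drug,
            epochs = data.frame(label = "drug", start = 0,
                                end = spec$duration))
}

#' Specification for a phase-locked synthetic spike train
#'
#' @param rate Mean firing rate lambda0 (Hz). The phase modulation is
#'   normalized by the Bessel function I0(kappa) so the mean rate is
#'   independent of the concentration, letting rate and modulation vary
#'   orthogonally.
#' @param kappa von Mises concentration of the phase preference (0 = no
#'   locking).
#' @param mu Preferred phase in radians (peak = 0, trough = pi convention;
#'   the default sits on the rising phase of the cycle, where these
#'   interneurons preferentially fire).
#' @param refractory Absolute refractory period (s).
#' @param wf_amp Spike template amplitude (uV).
#' @param wf_halfwidth Template full width at half amplitude (ms); the
#'   template is Gaussian, so sigma = halfwidth / (2 sqrt(2 ln 2)).
#' @param noise_sd Cell-attached noise floor SD (uV).
#' @param seed Integer seed.
#' @return List of class `gp_spike_spec`.
#' @export
spike_spec <- function(rate = 25, kappa = 2, mu = 4.45, refractory = 2e-3,
                       wf_amp = 100, wf_halfwidth = 0.4, noise_sd = 5,
                       seed = 1L) {
  if (rate < 0 || kappa < 0 || refractory < 0)
    stop("rate, kappa and refractory must be non-negative")
  structure(list(rate = rate, kappa = kappa, mu = mu %% (2 * pi),
                 refractory = refractory, wf_amp = wf_amp,
                 wf_halfwidth = wf_halfwidth, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "gp_spike_spec")
}

#' Generate a von Mises phase-locked spike train and cell-attached trace
#'
#' Draws an inhomogeneous Poisson train with intensity
#' `lambda(t) = rate * exp(kappa * cos(phi(t) - mu)) / I0(kappa)` where
#' `phi(t)` is the instantaneous gamma phase of the supplied LFP, by thinning
#' a homogeneous train at the peak intensity; a refractory pass then removes
#' too-close spikes. A Gaussian waveform template of the requested half-width
#' is summed onto a Gaussian noise floor to build the cell-attached channel.
#'
#' @param lfp A gamma-carrying [trace()] (typically the CA3 channel).
#' @param spec A [spike_spec()].
#' @param band Gamma band used for phase extraction.
#' @return List with `train` (a `gp_spiketrain`), `trace` (cell-attached
#'   `gp_trace`), and `phase` (the `gp_phase` used, for reuse in analysis).
#' @export
gen_phase_locked_spikes <- function(lfp, spec, band = c(20, 80)) {
  stopifnot(inherits(lfp, "gp_trace"), inherits(spec, "gp_spike_spec"))
  set.seed(spec$seed)
  fs <- lfp$fs
  T <- trace_duration(lfp)
  ph <- instantaneous_phase(lfp, band = band)
  n_noise <- length(lfp$samples)
  cell <- stats::rnorm(n_noise, sd = spec$noise_sd)
  empty_train <- function() structure(
    list(times = numeric(0), waveforms = matrix(numeric(0), 0, 0),
         fs = fs, polarity = "positive"), class = "gp_spiketrain")
  if (spec$rate == 0) {
    return(list(train = empty_train(),
                trace = trace(cell, fs, "cell_attached", lfp$t0), phase = ph))
  }
  i0k <- besselI(spec$kappa, 0)
  lam_max <- spec$rate * exp(spec$kappa) / i0k
  n_cand <- stats::rpois(1L, lam_max * T)
  span_end <- lfp$t0 + (n_noise - 1L) / fs
  cand <- sort(stats::runif(n_cand, lfp$t0, span_end))
  phi <- spike_phases(cand, ph)
  accept <- stats::runif(length(cand)) <
    exp(spec$kappa * (cos(phi - spec$mu) - 1))
  times <- cand[accept]
  # refractory thinning
  if (length(times) > 1L && spec$refractory > 0) {
    keep <- logical(length(times)); last <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - last >= spec$refractory) { keep[i] <- TRUE; last <- times[i] }
    }
    times <- times[keep]
  }
  # build cell-attached trace: Gaussian template at each spike
  sig <- spec$wf_halfwidth * 1e-3 / (2 * sqrt(2 * log(2)))
  half_n <- max(1L, round(4 * sig * fs))
  tpl <- spec$wf_amp * exp(-((-half_n:half_n) / fs)^2 / (2 * sig^2))
  idx <- round((times - lfp$t0) * fs) + 1L
  for (i in idx) {
    a <- max(1L, i - half_n); b <- min(n_noise, i + half_n)
    cell[a:b] <- cell[a:b] + tpl[(a - i + half_n + 1L):(b - i + half_n + 1L)]
  }
  ctr <- trace(cell, fs, "cell_attached", lfp$t0)
  npre <- round(2e-3 * fs); npost <- round(3e-3 * fs)
  ok <- idx > npre & idx + npost <= n_noise
  wf <- if (any(ok))
    t(vapply(idx[ok], function(i) cell[(i - npre):(i + npost)],
             numeric(npre + npost + 1L)))
  else matrix(numeric(0), 0, 0)
  train <- structure(list(times = times[ok], waveforms = wf, fs = fs,
                          polarity = "positive"),
                     class = "gp_spiketrain")
  list(train = train, trace = ctr, phase = ph)
}

#' Inject ictal-like bursts into an LFP trace
#'
#' Adds `n_bursts` high-amplitude oscillatory bursts (flat-topped, with short
#' cosine onset/offset ramps to mimic the abrupt start of an epileptiform
#' discharge; default 10x the trace RMS, 100-500 ms long) at random
#' non-overlapping positions,
#' returning the modified trace together with the ground-truth event list.
#' With `n_bursts = 0` the trace is returned unchanged.
#'
#' @param tr Input [trace()].
#' @param n_bursts Number of bursts to inject.
#' @param amp_mult Burst amplitude as a multiple of the trace RMS.
#' @param dur_range Burst duration range (s).
#' @param burst_freq Intra-burst oscillation frequency (Hz).
#' @param seed Integer seed.
#' @return List with `trace` and `events` (data frame `start`, `end`,
#'   `amplitude`).
#' @export
gen_iie_trace <- function(tr, n_bursts, amp_mult = 10,
                          dur_range = c(0.1, 0.5), burst_freq = 25,
                          seed = 1L) {
  stopifnot(inherits(tr, "gp_trace"))
  set.seed(as.integer(seed))
  events <- data.frame(start = numeric(0), end = numeric(0),
                       amplitude = numeric(0))
  if (n_bursts == 0) return(list(trace = tr, events = events))
  fs <- tr$fs
  x <- tr$samples
  T <- trace_duration(tr)
  rms <- sqrt(mean((x - mean(x))^2))
  amp <- amp_mult * rms
  placed <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(placed) < n_bursts && tries < 1000L) {
    tries <- tries + 1L
    d <- stats::runif(1, dur_range[1], dur_range[2])
    s <- stats::runif(1, 0.5, T - d - 0.5)
    if (!nrow(placed) ||
        all(s > placed[, 2] + 0.2 | s + d < placed[, 1] - 0.2))
      placed <- rbind(placed, c(s, s + d))
  }
  if (nrow(placed) < n_bursts)
    stop("could not place the requested bursts without overlap")
  placed <- placed[order(placed[, 1]), , drop = FALSE]
  for (i in seq_len(nrow(placed))) {
    a <- round(placed[i, 1] * fs) + 1L
    b <- round(placed[i, 2] * fs)
    m <- b - a + 1L
    tt <- (0:(m - 1L)) / fs
    # fixed 10 ms onset/offset ramps, independent of burst duration
    burst <- amp * tukey_window(m, min(1, 2 * 0.01 * fs / m)) *
      sin(2 * pi * burst_freq * tt)
    x[a:b] <- x[a:b] + burst
  }
  events <- data.frame(start = tr$t0 + placed[, 1], end = tr$t0 + placed[, 2],
                       amplitude = amp)
  list(trace = trace(x, fs, tr$role, tr$t0), events = events)
}

# flat-topped cosine-tapered window; r = total taper fraction
tukey_window <- function(n, r = 0.1) {
  w <- rep(1, n)
  ramp <- max(1L, floor(r * n / 2))
  up <- 0.5 * (1 - cos(pi * (0:(ramp - 1L)) / ramp))
  w[seq_len(ramp)] <- up
  w[n + 1L - seq_len(ramp)] <- up
  w
}

#' Cohort specification for synthetic group data
#'
#' Describes a genotype x age cohort of slices. Each group carries the number
#' of slices, an amplitude scale on the gamma carrier (`gamma_scale`; peak
#' power scales as its square), the probability that the CA1 channel
#' participates in the oscillation, and the von Mises concentration of any
#' simulated interneuron phase locking. The default group table mirrors the
#' observed kainate-cohort structure: preserved CA3 gamma in young groups and
#' controls, halved power (amplitude x sqrt(0.5)) in old mutants, and CA1
#' participation of 0.88/0.68 (young control/mutant) and 0.91/0.45 (old
#' control/mutant).
#'
#' @param groups Data frame with columns `genotype`, `age_group`, `n_slices`,
#'   `gamma_scale`, `participation`, `cells_per_slice`, `kappa`.
#' @param seed Global integer seed; per-slice seeds derive from it.
#' @return List of class `gp_cohort_spec`.
#' @export
cohort_spec <- function(groups = NULL, seed = 1L) {
  if (is.null(groups)) {
    groups <- data.frame(
      genotype = c("control", "mutant", "control", "mutant"),
      age_group = c("young", "young", "old", "old"),
      n_slices = c(17L, 25L, 22L, 20L),
      gamma_scale = c(1, 1, 1, sqrt(0.5)),
      participation = c(0.88, 0.68, 0.91, 0.45),
      cells_per_slice = c(0L, 0L, 0L, 0L),
      kappa = c(2, 2, 2, 2),
      stringsAsFactors = FALSE)
  }
  need <- c("genotype", "age_group", "n_slices", "gamma_scale",
            "participation", "cells_per_slice", "kappa")
  stopifnot(all(need %in% names(groups)))
  if (any(groups$participation < 0 | groups$participation > 1))
    stop("participation probabilities must lie in [0, 1]")
  if (any(groups$n_slices < 1)) stop("each group needs at least one slice")
  structure(list(groups = groups, seed = as.integer(seed)),
            class = "gp_cohort_spec")
}

#' Generate a synthetic cohort of slice recordings
#'
#' Per group, draws `n_slices` recordings whose gamma amplitude is the base
#' amplitude times the group's `gamma_scale`, and whose CA1 channel is
#' suppressed (oscillatory gain ~ 0, so it fails CA1 QC) with probability
#' `1 - participation`. Returns the recordings with a ground-truth manifest;
#' optionally writes everything to a directory as CSV + JSON.
#'
#' @param spec A [cohort_spec()].
#' @param duration,fs Record length (s) and sampling rate (Hz) per slice.
#' @param base Template [lfp_spec()] supplying all non-varied parameters.
#' @param drug Drug label stamped on the recordings.
#' @param out_dir Optional directory; when given, recordings and
#'   `manifest.csv` are written there.
#' @return List with `recordings` (list of [recording()]) and `manifest`
#'   (data frame: `slice_id`, `genotype`, `age_group`, `gamma_scale`,
#'   `ca1_participates`, `seed`).
#' @export
gen_cohort <- function(spec, duration = 300, fs = 10000,
                       base = NULL, drug = "kainate", out_dir = NULL) {
  stopifnot(inherits(spec, "gp_cohort_spec"))
  if (is.null(base))
    base <- lfp_spec(duration = duration, fs = fs)
  set.seed(spec$seed)
  total <- sum(spec$groups$n_slices)
  slice_seeds <- sample.int(.Machine$integer.max - 1L, total)
  recs <- vector("list", total)
  man <- vector("list", total)
  k <- 0L
  for (g in seq_len(nrow(spec$groups))) {
    grp <- spec$groups[g, ]
    for (s in seq_len(grp$n_slices)) {
      k <- k + 1L
      participates <- stats::runif(1) < grp$participation
      sp <- base
      sp$duration <- duration; sp$fs <- fs
      sp$gamma_amp <- base$gamma_amp * grp$gamma_scale
      sp$ca1_gain <- if (participates) base$ca1_gain else 0
      sp$seed <- slice_seeds[k]
      id <- sprintf("%s_%s_s%02d", grp$genotype, grp$age_group, s)
      recs[[k]] <- gen_lfp(sp, genotype = grp$genotype,
                           age_group = grp$age_group, drug = drug,
                           subject_id = id)
      man[[k]] <- data.frame(slice_id = id, genotype = grp$genotype,
                             age_group = grp$age_group,
                             gamma_scale = grp$gamma_scale,
                             ca1_participates = participates,
                             seed = slice_seeds[k],
                             stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, man)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(total))
      save_recording(recs[[i]], file.path(out_dir,
                                          paste0(manifest$slice_id[i], ".csv")))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(recordings = recs, manifest = manifest)
}
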