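# Synthetic LFP-like signals: arch-shaped gamma waveforms with a controllable
# fundamental-harmonic phase relation, noise surrogates, and full trial sets
# emulating a visual-stimulation recording session.

#' Specification of a synthetic gamma-plus-harmonic waveform
#'
#' Defines the deterministic two-sinusoid construction
#' \deqn{x(t) = \cos(2\pi f t + \phi_G) + a \cos(2\pi \cdot 2f \cdot t)}
#' where \code{f} is the gamma fundamental (45 Hz default), the harmonic sits
#' at \code{2f}, \code{a} is the harmonic amplitude ratio (0.25 default) and
#' \code{phi_G} is the initial phase of the fundamental in degrees. With
#' \code{phi_G = 90} the troughs of the two components align, giving the
#' arch-shaped cycle whose measured gamma-harmonic phase difference is
#' 180 degrees.
#'
#' @param fundamental_freq gamma fundamental frequency in Hz.
#' @param harmonic_freq harmonic frequency in Hz; a true first harmonic has
#'   \code{harmonic_freq = 2 * fundamental_freq}.
#' @param harmonic_amp_ratio harmonic/fundamental amplitude ratio (>= 0).
#' @param phi_G initial phase of the fundamental in degrees.
#' @param noise_sd standard deviation of additive Gaussian noise in signal
#'   units (used by trial-set generation; the bare waveform is noiseless).
#' @param duration seconds.
#' @param sampling_rate Hz; must exceed twice the harmonic frequency.
#' @param seed integer seed for stochastic uses of the spec.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(fundamental_freq = 45,
                           harmonic_freq = 2 * fundamental_freq,
                           harmonic_amp_ratio = 0.25,
                           phi_G = 90,
                           noise_sd = 0,
                           duration = 1,
                           sampling_rate = 2000,
                           seed = 1L) {
  stopifnot(fundamental_freq > 0, harmonic_freq > 0,
            harmonic_amp_ratio >= 0, noise_sd >= 0, duration > 0)
  if (sampling_rate <= 2 * harmonic_freq) {
    stop("sampling_rate must exceed twice the harmonic frequency (Nyquist)")
  }
  structure(
    list(fundamental_freq = fundamental_freq,
         harmonic_freq = harmonic_freq,
         harmonic_amp_ratio = harmonic_amp_ratio,
         phi_G = phi_G,
         noise_sd = noise_sd,
         duration = duration,
         sampling_rate = sampling_rate,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Deterministic gamma-plus-harmonic waveform
#'
#' Samples \code{cos(2*pi*f*t + phi_G) + ratio * cos(2*pi*f_h*t)} on the
#' spec's time grid (0-based sample indices, \code{t = k / sampling_rate}).
#' No noise is added.
#'
#' @param spec a \code{synthetic_spec}.
#' @return numeric waveform of length \code{duration * sampling_rate}.
#' @export
make_arch_wave <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  t <- wave_time(spec)
  cos(2 * pi * spec$fundamental_freq * t + deg2rad(spec$phi_G)) +
    spec$harmonic_amp_ratio * cos(2 * pi * spec$harmonic_freq * t)
}

wave_time <- function(spec) {
  n <- round(spec$duration * spec$sampling_rate)
  (0:(n - 1)) / spec$sampling_rate
}

#' Add white Gaussian noise to a waveform
#'
#' @param wave numeric waveform.
#' @param noise_sd standard deviation of the i.i.d. zero-mean Gaussian noise.
#' @param seed optional integer; when given, the same seed always yields the
#'   same noise realization.
#' @return \code{wave} plus noise.
#' @export
add_gaussian_noise <- function(wave, noise_sd, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  wave + stats::rnorm(length(wave), sd = noise_sd)
}

#' Weighted stimulus/baseline mixture surrogate
#'
#' Emulates a graded reduction of gamma power by mixing a stimulus-period
#' segment with a baseline-period segment: \code{w * stim + (1 - w) * base}.
#'
#' @param stim_segment,base_segment equal-length numeric segments.
#' @param w mixing weight in \code{[0, 1]} (1 = pure stimulus).
#' @return mixed waveform.
#' @export
mix_baseline <- function(stim_segment, base_segment, w) {
  if (length(stim_segment) != length(base_segment)) {
    stop("stimulus and baseline segments must have equal length")
  }
  stopifnot(w >= 0, w <= 1)
  w * stim_segment + (1 - w) * base_segment
}

#' Synthetic multi-trial, multi-channel LFP trial set
#'
#' Builds trials that emulate the recording structure: broadband Gaussian
#' noise throughout the trial, with the gamma-plus-harmonic oscillation added
#' only after stimulus onset. Epoch markers follow the recording convention:
#' baseline window (-0.5, 0) s and stimulus window (0.25, 0.75) s relative to
#' onset (both half-open \code{[start, end)}), each 0.5 s long so their
#' spectral resolutions match. Optionally the per-trial fundamental phase is
#' jittered by a von Mises draw around \code{phi_G}.
#'
#' @param spec a \code{synthetic_spec}; \code{spec$noise_sd} sets the
#'   broadband noise level and \code{spec$phi_G} the (mean) initial phase.
#' @param n_trials number of trials (>= 1).
#' @param n_channels number of channels.
#' @param trial_phase_jitter circular SD of the per-trial phase jitter in
#'   degrees; 0 (default) disables jitter so worked examples are exact.
#' @param seed integer master seed.
#' @param pre_s seconds recorded before onset (>= 0.5).
#' @param post_s seconds recorded after onset (>= 0.75).
#' @return object of class \code{lfp_trialset}: list with \code{data}
#'   (trials x timepoints x channels array), \code{sampling_rate},
#'   \code{stimulus_onset_index} (1-based sample of onset),
#'   \code{baseline_window}, \code{stimulus_window} (s relative to onset),
#'   and the generating \code{spec}.
#' @export
make_trialset <- function(spec, n_trials, n_channels = 1,
                          trial_phase_jitter = 0, seed = spec$seed,
                          pre_s = 0.5, post_s = 1.0) {
  stopifnot(inherits(spec, "synthetic_spec"), n_trials >= 1, n_channels >= 1)
  fs <- spec$sampling_rate
  if (pre_s < 0.5 || post_s < 0.75) {
    stop("trial span must contain the baseline (-0.5, 0) and stimulus (0.25, 0.75) windows")
  }
  n_pre <- round(pre_s * fs)
  n_post <- round(post_s * fs)
  if (abs(n_pre - pre_s * fs) > 1e-9 || abs(n_post - post_s * fs) > 1e-9 ||
      round(0.25 * fs) != 0.25 * fs) {
    stop("epoch windows are not representable at this sampling rate")
  }
  n_time <- n_pre + n_post
  t_post <- (0:(n_post - 1)) / fs
  set.seed(seed)
  data <- array(0, dim = c(n_trials, n_time, n_channels))
  for (tr in seq_len(n_trials)) {
    phi <- spec$phi_G
    if (trial_phase_jitter > 0) {
      kappa <- 1 / deg2rad(trial_phase_jitter)^2
      phi <- phi + rad2deg(rvonmises(1, 0, kappa))
    }
    osc <- cos(2 * pi * spec$fundamental_freq * t_post + deg2rad(phi)) +
      spec$harmonic_amp_ratio * cos(2 * pi * spec$harmonic_freq * t_post)
    for (ch in seq_len(n_channels)) {
      x <- stats::rnorm(n_time, sd = spec$noise_sd)
      x[(n_pre + 1):n_time] <- x[(n_pre + 1):n_time] + osc
      data[tr, , ch] <- x
    }
  }
  structure(
    list(data = data,
         sampling_rate = fs,
         stimulus_onset_index = n_pre + 1L,
         baseline_window = c(-0.5, 0),
         stimulus_window = c(0.25, 0.75),
         spec = spec),
    class = "lfp_trialset"
  )
}

#' Sample indices of an epoch window
#'
#' Converts an epoch window given in seconds relative to stimulus onset into
#' 1-based sample indices, half-open \code{[start, end)}.
#'
#' @param trialset an \code{lfp_trialset}.
#' @param epoch \code{"baseline"}, \code{"stimulus"}, or a numeric length-2
#'   window in seconds relative to onset.
#' @return integer vector of sample indices.
#' @export
epoch_indices <- function(trialset, epoch = "stimulus") {
  stopifnot(inherits(trialset, "lfp_trialset"))
  win <- if (is.character(epoch)) {
    switch(match.arg(epoch, c("baseline", "stimulus")),
           baseline = trialset$baseline_window,
           stimulus = trialset$stimulus_window)
  } else epoch
  fs <- trialset$sampling_rate
  start <- trialset$stimulus_onset_index + round(win[1] * fs)
  n <- round((win[2] - win[1]) * fs)
  idx <- start:(start + n - 1)
  if (idx[1] < 1 || idx[length(idx)] > dim(trialset$data)[2]) {
    stop("epoch window lies outside the recorded span")
  }
  idx
}

#' @export
print.lfp_trialset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("LFP trial set: %d trials x %d samples x %d channels @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  cat(sprintf("  onset at sample %d; baseline (%g, %g) s; stimulus (%g, %g) s\n",
              x$stimulus_onset_index,
              x$baseline_window[1], x$baseline_window[2],
              x$stimulus_window[1], x$stimulus_window[2]))
  invisible(x)
}

#' Write / read a trial set as CSV + JSON sidecar
#'
#' The data go to a long-format CSV (columns trial, sample, channel, value);
#' sampling rate, epoch windows and the generating spec go to a JSON sidecar
#' at \code{paste0(path, ".json")}.
#'
#' @param trialset an \code{lfp_trialset}.
#' @param path CSV file path.
#' @return \code{write_trialset}: the path, invisibly. \code{read_trialset}:
#'   the reconstructed \code{lfp_trialset}.
#' @export
write_trialset <- function(trialset, path) {
  stopifnot(inherits(trialset, "lfp_trialset"))
  d <- dim(trialset$data)
  df <- data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    sample = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    channel = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(trialset$data)
  )
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(sampling_rate = trialset$sampling_rate,
               stimulus_onset_index = trialset$stimulus_onset_index,
               baseline_window = trialset$baseline_window,
               stimulus_window = trialset$stimulus_window,
               dim = d,
               spec = unclass(trialset$spec))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trialset
#' @export
read_trialset <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  d <- as.integer(meta$dim)
  data <- array(0, dim = d)
  data[cbind(df$trial, df$sample, df$channel)] <- df$value
  spec <- if (!is.null(meta$spec)) {
    structure(as.list(meta$spec), class = "synthetic_spec")
  }
  structure(
    list(data = data,
         sampling_rate = meta$sampling_rate,
         stimulus_onset_index = as.integer(meta$stimulus_onset_index),
         baseline_window = as.numeric(meta$baseline_window),
         stimulus_window = as.numeric(meta$stimulus_window),
         spec = spec),
    class = "lfp_trialset"
  )
}
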