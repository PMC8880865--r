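# Multitaper spectral estimation, change-in-power, and gamma/harmonic peak
# detection.

# taper cache, keyed by "n.k.nw"
.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first \code{k} DPSS sequences of length \code{n} with
#' time-bandwidth product \code{nw} by solving the classical symmetric
#' tridiagonal eigenproblem (Percival & Walden 1993, sec. 8.4), whose
#' eigenvectors are exactly the Slepian sequences. Tapers are normalized to
#' unit energy and cached per (n, k, nw).
#'
#' The default \code{k = 3}, \code{nw = 2} follows the usual taper-count
#' convention k = 2*nw - 1 for a three-taper estimate.
#'
#' @param n taper length in samples.
#' @param k number of tapers.
#' @param nw time-bandwidth product.
#' @return n x k matrix, one taper per column.
#' @export
dpss_tapers <- function(n, k = 3, nw = 2) {
  stopifnot(n >= 2, k >= 1, k < n, nw > 0)
  key <- paste(n, k, nw, sep = ".")
  hit <- .taper_cache[[key]]
  if (!is.null(hit)) return(hit)
  tt <- 0:(n - 1)
  dg <- ((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * nw / n)
  od <- tt[-1] * (n - tt[-1]) / 2
  M <- matrix(0, n, n)
  M[cbind(1:n, 1:n)] <- dg
  M[cbind(1:(n - 1), 2:n)] <- od
  M[cbind(2:n, 1:(n - 1))] <- od
  V <- eigen(M, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  # standard polarity: symmetric tapers have positive mean, antisymmetric
  # tapers a positive initial slope
  for (j in seq_len(k)) {
    if (j %% 2 == 1) {
      if (sum(V[, j]) < 0) V[, j] <- -V[, j]
    } else if (V[2, j] - V[1, j] < 0) {
      V[, j] <- -V[, j]
    }
  }
  .taper_cache[[key]] <- V
  V
}

#' Multitaper power spectral density
#'
#' One-sided PSD of a single segment, averaged across DPSS eigenspectra.
#' The frequency grid has resolution 1/T where T is the segment duration,
#' so the 0.5 s analysis windows used for LFP epochs give exactly 2 Hz bins.
#' The segment mean is removed before tapering; with unit-energy tapers the
#' one-sided spectrum then integrates to the sample variance (Parseval).
#'
#' @param segment numeric vector, one channel of one epoch.
#' @param sampling_rate sampling rate in Hz.
#' @param n_tapers number of DPSS tapers (default 3).
#' @param nw time-bandwidth product (default 2; k = 2*nw - 1 convention).
#' @param min_freq lowest frequency (Hz) the segment must resolve; a segment
#'   shorter than one cycle at this frequency is rejected.
#' @return object of class \code{psd_result}: list with \code{freqs} (Hz),
#'   \code{power} (density, units^2/Hz), \code{n_tapers},
#'   \code{window_length} (s).
#' @export
multitaper_psd <- function(segment, sampling_rate, n_tapers = 3, nw = 2,
                           min_freq = 30) {
  stopifnot(is.numeric(segment), sampling_rate > 0)
  n <- length(segment)
  if (n < sampling_rate / min_freq) {
    stop("segment shorter than one cycle of the lowest analyzed frequency (",
         min_freq, " Hz)")
  }
  x <- segment - mean(segment)
  V <- dpss_tapers(n, n_tapers, nw)
  nf <- n %/% 2 + 1
  P <- matrix(0, nf, n_tapers)
  for (j in seq_len(n_tapers)) {
    X <- stats::fft(x * V[, j])[seq_len(nf)]
    p <- Mod(X)^2 / sampling_rate
    # fold negative frequencies; DC (and Nyquist for even n) are not doubled
    last_double <- if (n %% 2 == 0) nf - 1 else nf
    if (last_double >= 2) p[2:last_double] <- 2 * p[2:last_double]
    P[, j] <- p
  }
  structure(
    list(freqs = (seq_len(nf) - 1) * sampling_rate / n,
         power = rowMeans(P),
         n_tapers = n_tapers,
         window_length = n / sampling_rate),
    class = "psd_result"
  )
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("multitaper PSD: %d bins, %.3g-%.5g Hz (resolution %.3g Hz), %d tapers\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              1 / x$window_length, x$n_tapers))
  invisible(x)
}

#' Change in power between stimulus and baseline spectra
#'
#' 10 * (log10 P_stim - log10 P_base) per frequency bin, in dB. Bins where the
#' baseline power is zero (dB undefined) are flagged rather than dropped.
#'
#' @param psd_stim,psd_base \code{psd_result} objects on identical grids.
#' @return object of class \code{db_spectrum}: list with \code{freqs},
#'   \code{db}, and logical \code{flagged}.
#' @export
change_in_power <- function(psd_stim, psd_base) {
  if (length(psd_stim$freqs) != length(psd_base$freqs) ||
      any(abs(psd_stim$freqs - psd_base$freqs) > 1e-9)) {
    stop("frequency grids of stimulus and baseline PSDs do not match")
  }
  flagged <- psd_base$power <= 0 | psd_stim$power <= 0
  db <- rep(NA_real_, length(psd_stim$freqs))
  ok <- !flagged
  db[ok] <- 10 * (log10(psd_stim$power[ok]) - log10(psd_base$power[ok]))
  structure(list(freqs = psd_stim$freqs, db = db, flagged = flagged),
            class = "db_spectrum")
}

# pull (freqs, values) out of either a psd_result or a db_spectrum
spectrum_values <- function(spec) {
  if (inherits(spec, "db_spectrum")) {
    list(freqs = spec$freqs, value = spec$db)
  } else if (inherits(spec, "psd_result")) {
    list(freqs = spec$freqs, value = spec$power)
  } else if (is.list(spec) && !is.null(spec$freqs)) {
    v <- if (!is.null(spec$db)) spec$db else spec$power
    list(freqs = spec$freqs, value = v)
  } else {
    stop("expected a psd_result or db_spectrum")
  }
}

#' Gamma peak frequency
#'
#' Frequency of the maximum spectral value within the gamma band (30-70 Hz by
#' default). Implemented as a band-restricted argmax of the supplied spectrum
#' (change-in-power for LFP epochs, raw PSD for model proxies); ties break to
#' the lower bin.
#'
#' @param spectrum a \code{db_spectrum} or \code{psd_result}.
#' @param band numeric length-2, inclusive band limits in Hz.
#' @return peak frequency in Hz.
#' @export
find_gamma_peak <- function(spectrum, band = c(30, 70)) {
  s <- spectrum_values(spectrum)
  sel <- s$freqs >= band[1] & s$freqs <= band[2] & !is.na(s$value)
  if (!any(sel)) stop("no usable bins in the gamma band")
  s$freqs[sel][which.max(s$value[sel])]
}

#' Harmonic peak frequency
#'
#' Frequency of the maximum spectral value in the band (gamma_peak + 12, 140]
#' Hz: the highest peak occurring beyond 12 Hz after the estimated gamma peak,
#' up to 140 Hz (to exclude higher-frequency bumps). Lower edge exclusive,
#' upper edge inclusive.
#'
#' @param spectrum a \code{db_spectrum} or \code{psd_result}.
#' @param gamma_peak previously detected gamma peak frequency in Hz.
#' @param gap minimum offset above the gamma peak (Hz, default 12).
#' @param fmax upper limit of the search band (Hz, default 140).
#' @return harmonic peak frequency in Hz.
#' @export
find_harmonic_peak <- function(spectrum, gamma_peak, gap = 12, fmax = 140) {
  s <- spectrum_values(spectrum)
  sel <- s$freqs > gamma_peak + gap & s$freqs <= fmax & !is.na(s$value)
  if (!any(sel)) stop("empty harmonic search band above ", gamma_peak + gap, " Hz")
  s$freqs[sel][which.max(s$value[sel])]
}

#' Detect gamma and harmonic peaks in one spectrum
#'
#' @param spectrum a \code{db_spectrum} or \code{psd_result}.
#' @param band gamma band in Hz.
#' @return object of class \code{peak_estimate}: gamma and harmonic peak
#'   frequencies, their ratio, and the spectral values at each peak.
#' @export
find_peaks <- function(spectrum, band = c(30, 70)) {
  s <- spectrum_values(spectrum)
  g <- find_gamma_peak(spectrum, band)
  h <- find_harmonic_peak(spectrum, g)
  structure(
    list(gamma_peak = g, harmonic_peak = h, ratio = h / g,
         gamma_amp_db = s$value[match(g, s$freqs)],
         harmonic_amp_db = s$value[match(h, s$freqs)]),
    class = "peak_estimate"
  )
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat(sprintf("gamma %.4g Hz, harmonic %.4g Hz, ratio %.4g\n",
              x$gamma_peak, x$harmonic_peak, x$ratio))
  invisible(x)
}

#' Artifact-rejection mask for a trial set
#'
#' A trial is kept iff no sample of its stimulus-period trace deflects from
#' the trace mean by more than \code{threshold} standard deviations (default
#' 6). With several channels a trial is rejected when any channel violates the
#' rule.
#'
#' @param trialset an \code{lfp_trialset}.
#' @param threshold deflection threshold in SD units.
#' @return logical keep-mask, one entry per trial.
#' @export
reject_artifact_trials <- function(trialset, threshold = 6) {
  stopifnot(inherits(trialset, "lfp_trialset"))
  idx <- epoch_indices(trialset, "stimulus")
  if (length(idx) == 0L) stop("empty stimulus window")
  nt <- dim(trialset$data)[1]
  nc <- dim(trialset$data)[3]
  keep <- rep(TRUE, nt)
  for (tr in seq_len(nt)) {
    for (ch in seq_len(nc)) {
      x <- trialset$data[tr, idx, ch]
      if (max(abs(x - mean(x))) > threshold * stats::sd(x)) {
        keep[tr] <- FALSE
        break
      }
    }
  }
  keep
}

#' Median peak-frequency ratio with bootstrap SE and Wilcoxon test
#'
#' Summarizes harmonic/gamma peak-frequency ratios across channels: the median
#' ratio, the bootstrap standard error of the median (N resamples with
#' replacement, each of size N, by default N = number of ratios), and a
#' two-sided Wilcoxon signed-rank p-value against the null median ratio of 2
#' (exact distribution for n <= 25 when there are no zeros or ties, normal
#' approximation otherwise).
#'
#' @param ratios numeric vector of per-channel harmonic/gamma frequency
#'   ratios, or a list of \code{peak_estimate} objects.
#' @param n_boot number of bootstrap resamples; defaults to
#'   \code{length(ratios)}.
#' @param null_ratio null-hypothesis median (default 2).
#' @param seed optional integer seeding the bootstrap's dedicated generator.
#' @return object of class \code{ratio_summary}: \code{median_ratio},
#'   \code{se_median} (\code{NA} and \code{se_defined = FALSE} when fewer than
#'   two ratios), \code{wilcoxon_p}, \code{n}.
#' @export
ratio_statistics <- function(ratios, n_boot = NULL, null_ratio = 2,
                             seed = NULL) {
  if (is.list(ratios)) ratios <- vapply(ratios, function(p) p$ratio, numeric(1))
  n <- length(ratios)
  if (n < 1L) stop("no ratio estimates supplied")
  med <- stats::median(ratios)
  se <- NA_real_
  se_defined <- n >= 2L
  if (se_defined) {
    if (is.null(n_boot)) n_boot <- n
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    meds <- vapply(seq_len(n_boot), function(i) {
      stats::median(sample(ratios, n, replace = TRUE))
    }, numeric(1))
    se <- stats::sd(meds)
  }
  d <- ratios - null_ratio
  p <- if (all(d == 0)) {
    1
  } else {
    use_exact <- n <= 25 && !any(d == 0) && !any(duplicated(abs(d)))
    suppressWarnings(stats::wilcox.test(ratios, mu = null_ratio,
                                        exact = use_exact)$p.value)
  }
  structure(list(median_ratio = med, se_median = se, se_defined = se_defined,
                 wilcoxon_p = p, n = n),
            class = "ratio_summary")
}

#' @export
print.ratio_summary <- function(x, ...) {
  se <- if (x$se_defined) sprintf("%.4g", x$se_median) else "undefined"
  cat(sprintf("median ratio %.4g +/- %s (bootstrap SE), Wilcoxon p = %.3g, n = %d\n",
              x$median_ratio, se, x$wilcoxon_p, x$n))
  invisible(x)
}
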