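# Input-drive grid scans: where in drive space does a model produce
# arch-shaped gamma (gamma-harmonic phase difference within 22.5 degrees of
# 180)?

# spectral + phase analysis of one proxy segment already decimated to fs
analyze_proxy_cell <- function(px, fs, amp_thresholds, tolerance, trim,
                               gamma_band = c(30, 70)) {
  out <- list(gamma_peak_hz = NA_real_, gamma_amp = NA_real_,
              harmonic_amp = NA_real_, phase_diff_deg = NA_real_,
              vector_strength = NA_real_, low_power_flag = TRUE)
  if (stats::sd(px) == 0) return(out)
  psd <- multitaper_psd(px, fs)
  sel <- psd$freqs >= gamma_band[1] & psd$freqs <= gamma_band[2]
  gi <- which.max(psd$power[sel])
  gf <- psd$freqs[sel][gi]
  out$gamma_peak_hz <- gf
  out$gamma_amp <- psd$power[sel][gi]
  hb <- which(abs(psd$freqs - 2 * gf) < 1e-9)
  out$harmonic_amp <- if (length(hb)) psd$power[hb] else NA_real_
  out$low_power_flag <- !(isTRUE(out$gamma_amp > amp_thresholds[1]) &&
                            isTRUE(out$harmonic_amp > amp_thresholds[2]))
  if (!out$low_power_flag) {
    gh <- gamma_harmonic_phase(px, fs, gf, trim = trim)
    out$phase_diff_deg <- gh$summary$circ_mean
    out$vector_strength <- gh$summary$vector_strength
  }
  out
}

#' In-regime mask from phase and amplitude maps
#'
#' A cell is in-regime when the circular distance of its gamma-harmonic phase
#' difference from 180 degrees is at most \code{tolerance} (inclusive
#' boundary, computed on the circle) and both amplitude gates pass
#' (gamma amplitude > \code{amp_thresholds[1]}, harmonic amplitude >
#' \code{amp_thresholds[2]}). The gates exclude near-zero-power cells whose
#' phase estimates are dominated by simulation noise.
#'
#' @param phase_deg phase-difference map in degrees (vector or matrix;
#'   \code{NA} means no estimate and yields \code{FALSE}).
#' @param gamma_amp,harmonic_amp amplitude maps, same shape as
#'   \code{phase_deg}.
#' @param tolerance degrees from 180 (default 22.5).
#' @param amp_thresholds length-2 gates on the linear PSD peak values, in
#'   model units (default \code{c(1e-3, 1e-6)}).
#' @return logical map of the same shape.
#' @export
in_regime_mask <- function(phase_deg, gamma_amp, harmonic_amp,
                           tolerance = 22.5, amp_thresholds = c(1e-3, 1e-6)) {
  if (length(phase_deg) != length(gamma_amp) ||
      length(phase_deg) != length(harmonic_amp)) {
    stop("phase and amplitude maps have different shapes")
  }
  m <- !is.na(phase_deg) &
    circ_dist_deg(phase_deg, 180) <= tolerance &
    !is.na(gamma_amp) & gamma_amp > amp_thresholds[1] &
    !is.na(harmonic_amp) & harmonic_amp > amp_thresholds[2]
  dim(m) <- dim(phase_deg)
  m
}

#' Scan the ISN model over an input-drive grid
#'
#' Simulates every (I_E, I_I) pair (vectorized forward Euler), forms the LFP
#' proxy over the analysis window (decimated to \code{fs_analysis}), detects
#' the gamma peak (argmax of the raw multitaper PSD in 30-70 Hz; harmonic
#' fixed at twice the gamma peak), computes the gamma-harmonic phase
#' difference and its vector strength, the excitatory-over-inhibitory phase
#' lead, and the superlinear classification at the equilibrium nearest the
#' trajectory mean. Deterministic: repeated scans are identical.
#'
#' @param params template \code{js_params}; its \code{I_E}/\code{I_I} are
#'   overridden by the grid.
#' @param I_E_grid,I_I_grid drive grids (defaults 0-20 in steps of 0.5,
#'   41 x 41 cells).
#' @param config a \code{sim_config}.
#' @param proxy_mode LFP proxy: \code{"EI"}, \code{"E"} or \code{"I"}.
#' @param fs_analysis analysis sampling rate (Hz) after decimation.
#' @param amp_thresholds gamma/harmonic linear-PSD gates (model units).
#' @param tolerance in-regime phase tolerance in degrees.
#' @param trim seconds trimmed from each window end before phase statistics.
#' @return a \code{regime_grid}: data frame with one row per cell (columns
#'   \code{I_E}, \code{I_I}, \code{gamma_peak_hz}, \code{gamma_amp},
#'   \code{harmonic_amp}, \code{phase_diff_deg}, \code{vector_strength},
#'   \code{e_lead_deg}, \code{superlinear}, \code{low_power_flag},
#'   \code{in_regime}) and scan provenance in attributes.
#' @export
scan_js <- function(params = js_params(),
                    I_E_grid = seq(0, 20, by = 0.5),
                    I_I_grid = seq(0, 20, by = 0.5),
                    config = sim_config(),
                    proxy_mode = c("EI", "E", "I"),
                    fs_analysis = 1000,
                    amp_thresholds = c(1e-3, 1e-6),
                    tolerance = 22.5,
                    trim = 0.1) {
  proxy_mode <- match.arg(proxy_mode)
  grid <- expand.grid(I_E = I_E_grid, I_I = I_I_grid,
                      KEEP.OUT.ATTRS = FALSE)
  dt_s <- config$dt / 1000
  n <- round(config$duration / dt_s)
  fs_in <- 1 / dt_s
  fac <- round(fs_in / fs_analysis)
  win <- config$analysis_window
  rec <- seq(round(win[1] * fs_in) + 1, round(win[2] * fs_in), by = fac)
  sim <- js_euler_core(grid$I_E, grid$I_I, params, dt_s, n, rec)
  nc <- nrow(grid)
  cols <- c("gamma_peak_hz", "gamma_amp", "harmonic_amp", "phase_diff_deg",
            "vector_strength", "e_lead_deg")
  for (cl in cols) grid[[cl]] <- NA_real_
  grid$superlinear <- NA
  grid$low_power_flag <- TRUE
  for (k in seq_len(nc)) {
    px <- switch(proxy_mode,
                 EI = -(sim$r_E[, k] + sim$r_I[, k]),
                 E = -sim$r_E[, k],
                 I = -sim$r_I[, k])
    a <- analyze_proxy_cell(px, fs_analysis, amp_thresholds, tolerance, trim)
    grid$gamma_peak_hz[k] <- a$gamma_peak_hz
    grid$gamma_amp[k] <- a$gamma_amp
    grid$harmonic_amp[k] <- a$harmonic_amp
    grid$phase_diff_deg[k] <- a$phase_diff_deg
    grid$vector_strength[k] <- a$vector_strength
    grid$low_power_flag[k] <- a$low_power_flag
    pk <- params
    pk$I_E <- grid$I_E[k]
    pk$I_I <- grid$I_I[k]
    fp <- js_fixed_point(pk, init = mean(sim$r_E[, k]))
    grid$superlinear[k] <- classify_superlinear(pk, fp)
    if (!a$low_power_flag) {
      xe <- sim$r_E[, k]
      xi <- sim$r_I[, k]
      pe <- hilbert_phase(bandpass(xe - mean(xe), fs_analysis,
                                   a$gamma_peak_hz))
      pi_ <- hilbert_phase(bandpass(xi - mean(xi), fs_analysis,
                                    a$gamma_peak_hz))
      keep <- trim_indices(length(xe), fs_analysis, trim)
      grid$e_lead_deg[k] <- rad2deg(Arg(mean(exp(1i * (pe - pi_))[keep])))
    }
  }
  grid$in_regime <- in_regime_mask(grid$phase_diff_deg, grid$gamma_amp,
                                   grid$harmonic_amp, tolerance,
                                   amp_thresholds)
  structure(grid,
            class = c("regime_grid", "data.frame"),
            model = "js", axes = c("I_E", "I_I"),
            proxy_mode = proxy_mode, params = params, config = config,
            tolerance = tolerance, amp_thresholds = amp_thresholds)
}

#' Scan the stochastic model over a stimulus grid
#'
#' For every (size r, contrast c) cell the model is run
#' \code{config$n_iterations} times (independent Poisson input draws;
#' analogous to repeated trials). The gamma peak and amplitudes come from the
#' PSD averaged across iterations; the gamma-harmonic phase difference is
#' summarized per iteration (time mean over the trimmed analysis window) and
#' the pool of per-iteration means is subjected to a Rayleigh test. A cell is
#' in-regime only when that pool is consistent (Rayleigh p <
#' \code{consistency_p}), its circular mean lies within \code{tolerance} of
#' 180 degrees, and the amplitude gates pass. Reproducible under
#' \code{config$seed}.
#'
#' @param params template \code{jxk_params}; \code{r}/\code{c} overridden by
#'   the grid.
#' @param r_grid stimulus sizes (default 1-5 in steps of 0.125).
#' @param c_grid contrasts (default log10 steps of 0.25 from 0.01 to 1).
#' @param config a \code{sim_config} (\code{n_iterations} defaults to 50).
#' @param proxy_mode,fs_analysis,amp_thresholds,tolerance,trim as in
#'   \code{\link{scan_js}}.
#' @param consistency_p Rayleigh p-value threshold (default 0.01).
#' @param activation,power_n,noise_scale forwarded to the simulator.
#' @param chunk_cells cells simulated per vectorized sweep (memory knob).
#' @return a \code{regime_grid} with one row per cell: \code{r}, \code{c},
#'   peak and amplitude fields as in \code{\link{scan_js}},
#'   \code{phase_diff_deg} (circular mean of per-iteration means),
#'   \code{vector_strength} (iteration-averaged time vector strength),
#'   \code{rayleigh_p}, \code{low_power_flag}, \code{in_regime}.
#' @export
scan_jxk <- function(params = jxk_params(),
                     r_grid = seq(1, 5, by = 0.125),
                     c_grid = 10^seq(-2, 0, by = 0.25),
                     config = sim_config(),
                     proxy_mode = c("EI", "E", "I"),
                     fs_analysis = 1000,
                     amp_thresholds = c(1e-3, 1e-6),
                     tolerance = 22.5,
                     trim = 0.1,
                     consistency_p = 0.01,
                     activation = "rectifier", power_n = 2.5,
                     noise_scale = 1,
                     chunk_cells = 40L) {
  proxy_mode <- match.arg(proxy_mode)
  grid <- expand.grid(r = r_grid, c = c_grid, KEEP.OUT.ATTRS = FALSE)
  dt_s <- config$dt / 1000
  n <- round(config$duration / dt_s)
  fs_in <- 1 / dt_s
  fac <- round(fs_in / fs_analysis)
  win <- config$analysis_window
  rec <- seq(round(win[1] * fs_in) + 1, round(win[2] * fs_in), by = fac)
  niter <- config$n_iterations
  nc <- nrow(grid)
  for (cl in c("gamma_peak_hz", "gamma_amp", "harmonic_amp", "phase_diff_deg",
               "vector_strength", "rayleigh_p")) grid[[cl]] <- NA_real_
  grid$low_power_flag <- TRUE
  set.seed(config$seed)
  nf <- length(rec) %/% 2 + 1
  keep <- trim_indices(length(rec), fs_analysis, trim)
  for (chunk in split(seq_len(nc), ceiling(seq_len(nc) / chunk_cells))) {
    cells <- rep(chunk, each = niter)
    drv <- contrast_drive(grid$c[cells], params$c50)
    sim <- jxk_euler_core(drv$I_E, drv$I_I, grid$r[cells], params, dt_s, n,
                          rec, noise_scale, activation, power_n)
    PX <- switch(proxy_mode,
                 EI = -(sim$r_E + sim$r_I),
                 E = -sim$r_E,
                 I = -sim$r_I)
    for (k in chunk) {
      jj <- which(cells == k)
      # average PSD across iterations, then peaks
      P <- rowMeans(vapply(jj, function(j) {
        multitaper_psd(PX[, j], fs_analysis)$power
      }, numeric(nf)))
      psd <- structure(list(freqs = (seq_len(nf) - 1) * fs_analysis / length(rec),
                            power = P, n_tapers = 3,
                            window_length = length(rec) / fs_analysis),
                       class = "psd_result")
      sel <- psd$freqs >= 30 & psd$freqs <= 70
      gi <- which.max(psd$power[sel])
      gf <- psd$freqs[sel][gi]
      grid$gamma_peak_hz[k] <- gf
      grid$gamma_amp[k] <- psd$power[sel][gi]
      grid$harmonic_amp[k] <- psd$power[which(abs(psd$freqs - 2 * gf) < 1e-9)]
      grid$low_power_flag[k] <- !(grid$gamma_amp[k] > amp_thresholds[1] &&
                                    grid$harmonic_amp[k] > amp_thresholds[2])
      # per-iteration time-mean phase difference and vector strength
      iter_mean <- numeric(length(jj))
      iter_vs <- numeric(length(jj))
      for (m in seq_along(jj)) {
        gh <- gamma_harmonic_phase(PX[, jj[m]], fs_analysis, gf, trim = trim)
        iter_mean[m] <- gh$summary$circ_mean
        iter_vs[m] <- gh$summary$vector_strength
      }
      grid$phase_diff_deg[k] <- wrap_deg(rad2deg(Arg(resultant(iter_mean))))
      grid$vector_strength[k] <- mean(iter_vs)
      grid$rayleigh_p[k] <- rayleigh_test(iter_mean)
    }
  }
  grid$in_regime <- grid$rayleigh_p < consistency_p &
    in_regime_mask(grid$phase_diff_deg, grid$gamma_amp, grid$harmonic_amp,
                   tolerance, amp_thresholds)
  structure(grid,
            class = c("regime_grid", "data.frame"),
            model = "jxk", axes = c("r", "c"),
            proxy_mode = proxy_mode, params = params, config = config,
            tolerance = tolerance, amp_thresholds = amp_thresholds)
}

#' Summarize a regime grid
#'
#' Counts of in-regime cells, their bounding box in input space, the fraction
#' of in-regime cells classified superlinear (ISN scans), the mean vector
#' strength, and the circular mean excitatory phase lead over in-regime
#' cells. Undefined means are returned as \code{NA} when the mask is empty.
#'
#' @param grid a \code{regime_grid}.
#' @return list of class \code{regime_summary}.
#' @export
summarize_regime <- function(grid) {
  stopifnot(inherits(grid, "regime_grid"))
  axes <- attr(grid, "axes")
  inr <- which(grid$in_regime)
  empty <- length(inr) == 0L
  bbox <- if (empty) NULL else {
    sapply(axes, function(a) range(grid[[a]][inr]))
  }
  sl_frac <- if (!is.null(grid$superlinear) && !empty) {
    mean(grid$superlinear[inr], na.rm = TRUE)
  } else NA_real_
  vs <- if (empty) NA_real_ else mean(grid$vector_strength[inr])
  lead <- if (!is.null(grid$e_lead_deg) && !empty) {
    rad2deg(Arg(resultant(grid$e_lead_deg[inr])))
  } else NA_real_
  structure(
    list(model = attr(grid, "model"),
         n_cells = nrow(grid),
         n_in_regime = length(inr),
         bounding_box = bbox,
         superlinear_fraction = sl_frac,
         mean_vector_strength = vs,
         mean_e_lead_deg = lead,
         empty = empty),
    class = "regime_summary"
  )
}

#' @export
print.regime_summary <- function(x, ...) {
  cat(sprintf("%s scan: %d / %d cells in-regime\n",
              toupper(x$model), x$n_in_regime, x$n_cells))
  if (!x$empty) {
    if (!is.na(x$superlinear_fraction)) {
      cat(sprintf("  superlinear fraction of in-regime cells: %.3f\n",
                  x$superlinear_fraction))
    }
    cat(sprintf("  mean vector strength: %.4f\n", x$mean_vector_strength))
    if (!is.na(x$mean_e_lead_deg)) {
      cat(sprintf("  mean E-over-I phase lead: %.1f deg\n", x$mean_e_lead_deg))
    }
  }
  invisible(x)
}

#' Persist a regime grid to CSV + JSON sidecar
#'
#' One row per grid cell; scan provenance (model, parameters, configuration,
#' seed, tolerance, gates) goes to \code{paste0(path, ".json")}.
#'
#' @param grid a \code{regime_grid}.
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
write_regime_grid <- function(grid, path) {
  stopifnot(inherits(grid, "regime_grid"))
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  meta <- list(model = attr(grid, "model"),
               axes = attr(grid, "axes"),
               proxy_mode = attr(grid, "proxy_mode"),
               params = unclass(attr(grid, "params")),
               config = unclass(attr(grid, "config")),
               tolerance = attr(grid, "tolerance"),
               amp_thresholds = attr(grid, "amp_thresholds"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
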