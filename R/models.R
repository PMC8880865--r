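# Wilson-Cowan-type rate models of visually induced gamma: the stochastically
# driven linear three-population model (E, I plus a global excitatory
# population; "JXK") and the two-population sigmoidal inhibition-stabilized
# model ("JS"). Both are integrated by forward Euler, as in the original
# formulations.

#' Parameters of the three-population stochastic rate model
#'
#' Recurrent weights, time constants, and stimulus parameters of the linear
#' rectified model with a global excitatory feedback population. Defaults are
#' the published table values. The stimulus is described by a size \code{r}
#' (scales the global feedback as \code{r^2 * W_GE}, exponent configurable)
#' and a contrast \code{c} that sets the mean input drives through
#' \code{\link{contrast_drive}}. The masked-noise pathway is fixed at 0.
#'
#' @param W_EE,W_EI,W_IE,W_II,W_EG,W_IG,W_GE dimensionless coupling weights.
#' @param tau_E,tau_I,tau_G time constants in ms.
#' @param r stimulus size (1-5).
#' @param c stimulus contrast (0.01-1).
#' @param size_exponent exponent of the size scaling of global feedback
#'   (default 2).
#' @param c50 semi-saturation contrast of the drive nonlinearity (default 0.3).
#' @param input_bin Poisson input bin width in ms (default 1).
#' @return object of class \code{jxk_params}.
#' @export
jxk_params <- function(W_EE = 1.5, W_EI = 3.25, W_IE = 3.5, W_II = 2.5,
                       W_EG = 0.25, W_IG = 0.5, W_GE = 0.6,
                       tau_E = 6, tau_I = 15, tau_G = 19,
                       r = 4.375, c = 10^-0.25,
                       size_exponent = 2, c50 = 0.3, input_bin = 1) {
  stopifnot(tau_E > 0, tau_I > 0, tau_G > 0, input_bin > 0, r > 0, c > 0)
  structure(as.list(environment()), class = "jxk_params")
}

#' Parameters of the two-population sigmoidal ISN model
#'
#' Weights, time constants, sigmoid slopes/thresholds and constant input
#' drives of the inhibition-stabilized model with activation
#' \code{\link{js_activation}}. Defaults are the published table values.
#'
#' @param W_EE,W_EI,W_IE,W_II dimensionless coupling weights.
#' @param tau_E,tau_I time constants in ms.
#' @param m_E,m_I sigmoid slopes.
#' @param theta_E,theta_I sigmoid thresholds.
#' @param I_E,I_I constant external drives (0-20 in the scanned grid).
#' @return object of class \code{js_params}.
#' @export
js_params <- function(W_EE = 16, W_EI = 26, W_IE = 20, W_II = 1,
                      tau_E = 20, tau_I = 10,
                      m_E = 1, m_I = 1, theta_E = 5, theta_I = 20,
                      I_E = 3, I_I = 7.5) {
  stopifnot(tau_E > 0, tau_I > 0, m_E > 0, m_I > 0)
  structure(as.list(environment()), class = "js_params")
}

#' Simulation configuration
#'
#' @param dt Euler step in ms (default 0.1).
#' @param duration total simulated time in s (default 2).
#' @param analysis_window length-2 window in s that excludes the initial
#'   transient (default: the second half of the simulation, \code{c(1, 2)} at
#'   the default duration).
#' @param seed integer seed for stochastic models.
#' @param n_iterations repeated stochastic runs per condition (default 50).
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(dt = 0.1, duration = 2,
                       analysis_window = c(duration / 2, duration),
                       seed = 1L, n_iterations = 50L) {
  n <- duration * 1000 / dt
  if (abs(n - round(n)) > 1e-9) stop("dt must divide duration")
  stopifnot(analysis_window[1] >= 0, analysis_window[2] <= duration,
            analysis_window[1] < analysis_window[2])
  structure(list(dt = dt, duration = duration,
                 analysis_window = analysis_window,
                 seed = as.integer(seed),
                 n_iterations = as.integer(n_iterations)),
            class = "sim_config")
}

#' Contrast-dependent input drives
#'
#' Naka-Rushton-type saturation of the mean drives with stimulus contrast:
#' \code{I_E = 40 c^2 / (c^2 + c50^2)}, \code{I_I = 32 c^2 / (c^2 + c50^2)},
#' with semi-saturation contrast \code{c50 = 0.3}, so \code{c = 0.3} yields
#' (20, 16) and large contrast saturates at (40, 32).
#'
#' @param c contrast (> 0; vectorized).
#' @param c50 semi-saturation contrast.
#' @return list with numeric \code{I_E} and \code{I_I}.
#' @export
contrast_drive <- function(c, c50 = 0.3) {
  stopifnot(all(c >= 0))
  g <- c^2 / (c^2 + c50^2)
  list(I_E = 40 * g, I_I = 32 * g)
}

#' Sigmoidal population activation
#'
#' \deqn{\sigma_P(x) = \frac{1}{1 + e^{m_P(\theta_P - x)}} -
#'   \frac{1}{1 + e^{m_P \theta_P}}}
#' The subtracted constant makes \eqn{\sigma_P(0) = 0}, so the origin is
#' always a fixed point at zero drive. Saturates below
#' \eqn{1 - 1/(1 + e^{m\theta})}.
#'
#' @param x summed input (vectorized).
#' @param m slope.
#' @param theta threshold (sigmoid midpoint).
#' @return activation value(s) in \code{[0, 1)}.
#' @export
js_activation <- function(x, m, theta) {
  1 / (1 + exp(m * (theta - x))) - 1 / (1 + exp(m * theta))
}

# derivative of js_activation wrt x
js_activation_deriv <- function(x, m, theta) {
  s <- 1 / (1 + exp(m * (theta - x)))
  m * s * (1 - s)
}

# --- vectorized Euler cores -------------------------------------------------
#
# Both cores integrate many independent parameter columns simultaneously so a
# full input-drive grid runs in a handful of vectorized sweeps. `record_steps`
# are the (1-based) Euler steps stored in the output matrices.

js_euler_core <- function(I_E, I_I, p, dt_s, n_steps, record_steps) {
  nc <- max(length(I_E), length(I_I))
  I_E <- rep_len(I_E, nc)
  I_I <- rep_len(I_I, nc)
  e <- numeric(nc)
  i <- numeric(nc)
  RE <- matrix(0, length(record_steps), nc)
  RI <- matrix(0, length(record_steps), nc)
  rec <- integer(n_steps)
  rec[record_steps] <- seq_along(record_steps)
  tE <- p$tau_E / 1000
  tI <- p$tau_I / 1000
  for (k in seq_len(n_steps)) {
    de <- (-e + js_activation(p$W_EE * e - p$W_EI * i + I_E, p$m_E, p$theta_E)) / tE
    di <- (-i + js_activation(p$W_IE * e - p$W_II * i + I_I, p$m_I, p$theta_I)) / tI
    e <- e + dt_s * de
    i <- i + dt_s * di
    if (!all(is.finite(e)) || !all(is.finite(i))) {
      stop("non-finite state at step ", k, " -- reduce dt or check parameters")
    }
    if (rec[k] > 0L) {
      RE[rec[k], ] <- e
      RI[rec[k], ] <- i
    }
  }
  list(r_E = RE, r_I = RI)
}

# activation applied to the inhibitory rate inside the coupling terms
jxk_inhibitory_coupling <- function(activation, power_n) {
  if (is.function(activation)) return(activation)
  switch(activation,
         rectifier = function(x) pmax(x, 0),
         power_law = function(x) pmax(x, 0)^power_n / power_n,
         stop("unknown activation variant: ", activation))
}

jxk_euler_core <- function(I_E, I_I, r, p, dt_s, n_steps, record_steps,
                           noise_scale = 1, activation = "rectifier",
                           power_n = 2.5) {
  nc <- max(length(I_E), length(I_I), length(r))
  I_E <- rep_len(I_E, nc)
  I_I <- rep_len(I_I, nc)
  r <- rep_len(r, nc)
  fI <- jxk_inhibitory_coupling(activation, power_n)
  pos <- function(x) pmax(x, 0)
  bin_steps <- max(1L, round(p$input_bin / 1000 / dt_s))
  n_bins <- ceiling(n_steps / bin_steps)
  # per-bin Poisson counts, held constant within the bin; time-average equals
  # the nominal drive, fluctuations scaled by noise_scale
  draw_inp <- function(I) {
    lam <- I * p$input_bin
    counts <- matrix(stats::rpois(n_bins * nc, rep(lam, each = n_bins)),
                     n_bins, nc)
    rate <- counts / p$input_bin
    sweep(rate, 2, I, "-") * noise_scale + rep(I, each = n_bins)
  }
  Einp <- draw_inp(I_E)
  Iinp <- draw_inp(I_I)
  gw <- r^p$size_exponent * p$W_GE
  e <- numeric(nc); i <- numeric(nc); g <- numeric(nc)
  RE <- matrix(0, length(record_steps), nc)
  RI <- matrix(0, length(record_steps), nc)
  RG <- matrix(0, length(record_steps), nc)
  rec <- integer(n_steps)
  rec[record_steps] <- seq_along(record_steps)
  tE <- p$tau_E / 1000; tI <- p$tau_I / 1000; tG <- p$tau_G / 1000
  for (k in seq_len(n_steps)) {
    b <- (k - 1L) %/% bin_steps + 1L
    ii <- fI(i)
    de <- (-e + p$W_EE * pos(e) - p$W_EI * ii + p$W_EG * pos(g) + Einp[b, ]) / tE
    di <- (-i + p$W_IE * pos(e) - p$W_II * ii + p$W_IG * pos(g) + Iinp[b, ]) / tI
    dg <- (-g + gw * pos(e)) / tG
    e <- e + dt_s * de
    i <- i + dt_s * di
    g <- g + dt_s * dg
    if (!all(is.finite(e)) || !all(is.finite(i)) || !all(is.finite(g))) {
      stop("non-finite state at step ", k, " -- reduce dt or check parameters")
    }
    if (rec[k] > 0L) {
      RE[rec[k], ] <- e
      RI[rec[k], ] <- i
      RG[rec[k], ] <- g
    }
  }
  list(r_E = RE, r_I = RI, r_G = RG, E_inp = Einp, I_inp = Iinp)
}

# ---------------------------------------------------------------------------

#' Simulate the two-population ISN model
#'
#' Forward-Euler integration from \code{r_E = r_I = 0}; fully deterministic.
#' Above the Hopf bifurcation the model settles on a gamma-band limit cycle
#' whose cycle shape repeats identically, below it the oscillation decays to
#' a stable fixed point.
#'
#' @param params a \code{js_params}.
#' @param config a \code{sim_config}.
#' @return object of class \code{sim_trace}: list with \code{time} (s),
#'   \code{r_E}, \code{r_I}, \code{sampling_rate} (Hz), \code{params},
#'   \code{config}.
#' @export
simulate_js <- function(params = js_params(), config = sim_config()) {
  stopifnot(inherits(params, "js_params"), inherits(config, "sim_config"))
  dt_s <- config$dt / 1000
  n <- round(config$duration / dt_s)
  out <- js_euler_core(params$I_E, params$I_I, params, dt_s, n, seq_len(n))
  structure(
    list(time = seq_len(n) * dt_s,
         r_E = out$r_E[, 1], r_I = out$r_I[, 1],
         sampling_rate = 1 / dt_s,
         model = "js", params = params, config = config),
    class = "sim_trace"
  )
}

#' Simulate the three-population stochastic model
#'
#' Forward-Euler integration with Poisson-derived input drives: counts are
#' drawn per \code{input_bin} (1 ms default) with means set by
#' \code{\link{contrast_drive}}, held constant within each bin, so the
#' time-averaged input equals the nominal drive. With inputs held exactly at
#' their means (\code{noise_scale = 0}) the model is a damped oscillator; the
#' stochastic drive is what sustains its gamma.
#'
#' @param params a \code{jxk_params}.
#' @param config a \code{sim_config}; \code{config$seed} seeds the input
#'   draws.
#' @param activation inhibitory coupling variant: \code{"rectifier"}
#'   (default), \code{"power_law"} (half-wave rectified rate raised to
#'   \code{power_n} and divided by it), or a user-supplied function of the
#'   inhibitory rate.
#' @param power_n exponent of the power-law variant (default 2.5).
#' @param noise_scale scale of input fluctuations around the mean drive
#'   (1 = Poisson, 0 = deterministic mean input).
#' @return object of class \code{sim_trace} with \code{r_E}, \code{r_I},
#'   \code{r_G} and the per-bin input realizations \code{E_inp},
#'   \code{I_inp}.
#' @export
simulate_jxk <- function(params = jxk_params(), config = sim_config(),
                         activation = "rectifier", power_n = 2.5,
                         noise_scale = 1) {
  stopifnot(inherits(params, "jxk_params"), inherits(config, "sim_config"))
  dt_s <- config$dt / 1000
  n <- round(config$duration / dt_s)
  drv <- contrast_drive(params$c, params$c50)
  set.seed(config$seed)
  out <- jxk_euler_core(drv$I_E, drv$I_I, params$r, params, dt_s, n,
                        seq_len(n), noise_scale, activation, power_n)
  structure(
    list(time = seq_len(n) * dt_s,
         r_E = out$r_E[, 1], r_I = out$r_I[, 1], r_G = out$r_G[, 1],
         E_inp = out$E_inp[, 1], I_inp = out$I_inp[, 1],
         sampling_rate = 1 / dt_s,
         model = "jxk", params = params, config = config),
    class = "sim_trace"
  )
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("%s model trace: %d steps @ %g kHz (%.3g s)\n",
              toupper(x$model), length(x$time), x$sampling_rate / 1000,
              max(x$time)))
  invisible(x)
}

#' LFP proxy of a simulated trace
#'
#' The model surrogate for the recorded LFP: the negated sum of the
#' excitatory and inhibitory population rates (\code{mode = "EI"}, default),
#' or the negation of a single population.
#'
#' @param trace a \code{sim_trace}.
#' @param mode \code{"EI"} (-(r_E + r_I)), \code{"E"} (-r_E), or \code{"I"}
#'   (-r_I).
#' @return numeric proxy series, one value per trace sample.
#' @export
lfp_proxy <- function(trace, mode = c("EI", "E", "I")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "sim_trace"))
  switch(mode,
         EI = -(trace$r_E + trace$r_I),
         E = -trace$r_E,
         I = -trace$r_I)
}

# decimate a trace vector from its native rate to fs_out by integer
# subsampling over the analysis window
analysis_segment <- function(x, fs_in, window, fs_out = 1000) {
  fac <- round(fs_in / fs_out)
  i0 <- round(window[1] * fs_in) + 1
  i1 <- round(window[2] * fs_in)
  x[seq(i0, i1, by = fac)]
}

#' Phase lead of the excitatory over the inhibitory population
#'
#' Band-passes both population rates around the gamma peak, Hilbert-phases
#' them, and reports the circular mean of \code{phi_rE - phi_rI} over the
#' trimmed analysis window, in degrees: positive values mean E peaks earlier
#' in the cycle than I. When the proxy oscillation amplitude over the window
#' is below \code{min_amplitude} the lead is flagged undefined.
#'
#' @param trace a \code{sim_trace}.
#' @param gamma_freq band center in Hz; \code{NULL} (default) detects the
#'   gamma peak from the proxy PSD.
#' @param width passband width in Hz.
#' @param fs_analysis analysis sampling rate after decimation (Hz).
#' @param trim seconds trimmed from each window end.
#' @param min_amplitude minimum SD of the windowed proxy for the lead to be
#'   considered defined.
#' @return list with \code{lead_deg} (degrees in (-180, 180]),
#'   \code{defined}, and \code{gamma_freq}.
#' @export
e_i_phase_lead <- function(trace, gamma_freq = NULL, width = 20,
                           fs_analysis = 1000, trim = 0.1,
                           min_amplitude = 1e-6) {
  stopifnot(inherits(trace, "sim_trace"))
  win <- trace$config$analysis_window
  px <- analysis_segment(lfp_proxy(trace), trace$sampling_rate, win, fs_analysis)
  if (stats::sd(px) < min_amplitude) {
    return(list(lead_deg = NA_real_, defined = FALSE, gamma_freq = NA_real_))
  }
  if (is.null(gamma_freq)) {
    gamma_freq <- find_gamma_peak(multitaper_psd(px, fs_analysis))
  }
  xe <- analysis_segment(trace$r_E, trace$sampling_rate, win, fs_analysis)
  xi <- analysis_segment(trace$r_I, trace$sampling_rate, win, fs_analysis)
  pe <- hilbert_phase(bandpass(xe - mean(xe), fs_analysis, gamma_freq, width))
  pi_ <- hilbert_phase(bandpass(xi - mean(xi), fs_analysis, gamma_freq, width))
  keep <- trim_indices(length(xe), fs_analysis, trim)
  z <- mean(exp(1i * (pe - pi_))[keep])
  list(lead_deg = rad2deg(Arg(z)), defined = TRUE, gamma_freq = gamma_freq)
}

#' Equilibrium of the ISN model
#'
#' Finds an equilibrium of the sigmoidal model by a one-dimensional
#' reduction: for each candidate excitatory rate the inhibitory equation
#' \code{r_I = sigma_I(W_IE r_E - W_II r_I + I_I)} has a unique solution
#' (monotone in \code{r_I}), solved by bracketing; the excitatory consistency
#' residual is then rooted over a fine bracket scan of \code{[0, 1]}. When
#' several equilibria exist the one closest to \code{init} is returned.
#' Also reports the inhibitory operating point
#' \code{W_IE r_E* - W_II r_I* + I_I} -- the summed input at which the
#' inhibitory sigmoid operates.
#'
#' @param params a \code{js_params}.
#' @param init excitatory rate the returned root should be nearest to
#'   (default 0).
#' @param tol root tolerance.
#' @return list with \code{r_E}, \code{r_I}, \code{operating_point},
#'   \code{residual}, \code{converged}, \code{n_roots}.
#' @export
js_fixed_point <- function(params, init = 0, tol = 1e-12) {
  stopifnot(inherits(params, "js_params"))
  i_of_e <- function(e) {
    stats::uniroot(function(i) {
      js_activation(params$W_IE * e - params$W_II * i + params$I_I,
                    params$m_I, params$theta_I) - i
    }, c(0, 1), tol = tol)$root
  }
  fe <- function(e) {
    js_activation(params$W_EE * e - params$W_EI * i_of_e(e) + params$I_E,
                  params$m_E, params$theta_E) - e
  }
  grid <- seq(0, 1, length.out = 201)
  fv <- vapply(grid, fe, numeric(1))
  roots <- c()
  for (k in seq_len(length(grid) - 1)) {
    if (fv[k] == 0) {
      roots <- c(roots, grid[k])
    } else if (sign(fv[k]) != sign(fv[k + 1])) {
      roots <- c(roots, stats::uniroot(fe, grid[k:(k + 1)], tol = tol)$root)
    }
  }
  if (length(roots) == 0) {
    return(list(r_E = NA_real_, r_I = NA_real_, operating_point = NA_real_,
                residual = NA_real_, converged = FALSE, n_roots = 0L))
  }
  e <- roots[which.min(abs(roots - init))]
  i <- i_of_e(e)
  res <- max(abs(fe(e)),
             abs(js_activation(params$W_IE * e - params$W_II * i + params$I_I,
                               params$m_I, params$theta_I) - i))
  list(r_E = e, r_I = i,
       operating_point = params$W_IE * e - params$W_II * i + params$I_I,
       residual = res, converged = res < 1e-9, n_roots = length(roots))
}

#' Is the inhibitory population superlinear at its operating point?
#'
#' TRUE iff the inhibitory summed input at equilibrium lies strictly below
#' the sigmoid threshold \code{theta_I}, i.e. in the lower half of the
#' sigmoid where the activation curves upward (slope increasing with input).
#'
#' @param params a \code{js_params}.
#' @param fixed_point optional precomputed result of
#'   \code{\link{js_fixed_point}}.
#' @return logical; \code{NA} if no equilibrium was found.
#' @export
classify_superlinear <- function(params, fixed_point = NULL) {
  if (is.null(fixed_point)) fixed_point <- js_fixed_point(params)
  if (!isTRUE(fixed_point$converged)) return(NA)
  fixed_point$operating_point < params$theta_I
}

#' Export a simulated trace to CSV
#'
#' One row per timepoint: time, rates, and the EI proxy. Parameters and the
#' seed go to a JSON sidecar.
#'
#' @param trace a \code{sim_trace}.
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
write_sim_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sim_trace"))
  df <- data.frame(time = trace$time, r_E = trace$r_E, r_I = trace$r_I)
  if (!is.null(trace$r_G)) df$r_G <- trace$r_G
  df$proxy <- lfp_proxy(trace)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(model = trace$model, params = unclass(trace$params),
               config = unclass(trace$config))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
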