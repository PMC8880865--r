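# Expensive scans are computed once per test session and shared across
# test files.
.scan_cache <- new.env(parent = emptyenv())

cached_js_scan <- function() {
  if (is.null(.scan_cache$js)) .scan_cache$js <- scan_js()
  .scan_cache$js
}

cached_jxk_reduced_scan <- function() {
  if (is.null(.scan_cache$jxk)) {
    .scan_cache$jxk <- scan_jxk(
      r_grid = c(1, 2.5, 4.375),
      c_grid = 10^c(-1, -0.5, -0.25, 0),
      config = sim_config(seed = 3, n_iterations = 50))
  }
  .scan_cache$jxk
}

# small sine-based trial set builder used by several files
clean_trialset <- function(n_trials = 5, n_channels = 2, noise_sd = 0,
                           phi_G = 90, seed = 11) {
  make_trialset(synthetic_spec(phi_G = phi_G, noise_sd = noise_sd,
                               seed = seed),
                n_trials = n_trials, n_channels = n_channels)
}
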