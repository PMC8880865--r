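test_that("in-regime mask applies circular distance and amplitude gates", {
  amp_ok <- rep(1, 5)
  h_ok <- rep(1, 5)
  phases <- c(180, 150, 157.5, 202.5, NA)
  m <- in_regime_mask(phases, amp_ok, h_ok)
  expect_equal(m, c(TRUE, FALSE, TRUE, TRUE, FALSE))  # 157.5: inclusive edge

  # amplitude gates veto regardless of phase
  expect_false(any(in_regime_mask(rep(180, 3), rep(1e-4, 3), rep(1, 3))))
  expect_false(any(in_regime_mask(rep(180, 3), rep(1, 3), rep(1e-7, 3))))

  # circular, not linear, distance: 350 deg is 170 deg away from 180
  expect_false(in_regime_mask(350, 1, 1))
  expect_error(in_regime_mask(1:3, 1:2, 1:3), "shapes")
})

test_that("mask is monotone in tolerance", {
  set.seed(8)
  ph <- runif(300, 0, 360)
  ga <- runif(300, 0, 2e-3)
  ha <- runif(300, 0, 2e-6)
  prev <- in_regime_mask(ph, ga, ha, tolerance = 5)
  for (tol in c(10, 22.5, 45, 90, 180)) {
    cur <- in_regime_mask(ph, ga, ha, tolerance = tol)
    expect_true(all(cur[prev]))  # enlarging tolerance never removes a cell
    prev <- cur
  }
})

test_that("a focused ISN scan finds arch-shaped cells inside the superlinear set", {
  g <- scan_js(I_E_grid = seq(1.5, 5.5, by = 1),
               I_I_grid = seq(6.5, 9.5, by = 1))
  expect_s3_class(g, "regime_grid")
  expect_true(all(c("gamma_peak_hz", "gamma_amp", "harmonic_amp",
                    "phase_diff_deg", "vector_strength", "e_lead_deg",
                    "superlinear", "low_power_flag", "in_regime") %in%
                    names(g)))
  expect_gt(sum(g$in_regime), 0)
  expect_true(all(g$superlinear[g$in_regime]))
  expect_true(all(g$vector_strength[g$in_regime] > 0.99))
  expect_true(all(!g$low_power_flag[g$in_regime]))

  # deterministic: repeated scans are identical
  g2 <- scan_js(I_E_grid = seq(1.5, 5.5, by = 1),
                I_I_grid = seq(6.5, 9.5, by = 1))
  expect_identical(as.data.frame(g), as.data.frame(g2))
})

test_that("drive trends match the size and contrast effects on gamma", {
  g <- cached_js_scan()
  # increasing I_I at fixed in-regime I_E: frequency falls, amplitude rises
  sub <- g[g$I_E == 3 & g$I_I >= 6.5 & g$I_I <= 9 & !g$low_power_flag, ]
  expect_gte(nrow(sub), 4)
  ord <- order(sub$I_I)
  expect_true(all(diff(sub$gamma_peak_hz[ord]) <= 0))
  expect_true(all(diff(sub$gamma_amp[ord]) > 0))
})

test_that("stochastic-model size trends and consistency gating behave as expected", {
  gj <- cached_jxk_reduced_scan()
  expect_true(all(is.finite(gj$rayleigh_p)))
  # gamma frequency decreases with stimulus size at every contrast
  for (cc in unique(gj$c)) {
    sub <- gj[gj$c == cc, ]
    ord <- order(sub$r)
    expect_true(all(diff(sub$gamma_peak_hz[ord]) <= 0))
  }
  # gamma power increases with size at the fixed demonstration contrast
  sub <- gj[abs(gj$c - 10^-0.25) < 1e-9, ]
  expect_true(all(diff(sub$gamma_amp[order(sub$r)]) > 0))
  # same master seed reproduces the grid exactly
  g1 <- scan_jxk(r_grid = c(2, 4), c_grid = 10^-0.25,
                 config = sim_config(seed = 5, n_iterations = 4))
  g2 <- scan_jxk(r_grid = c(2, 4), c_grid = 10^-0.25,
                 config = sim_config(seed = 5, n_iterations = 4))
  expect_identical(as.data.frame(g1), as.data.frame(g2))
})

test_that("an iteration-inconsistent cell cannot be in-regime", {
  # synthetic grid row: uniform per-iteration phases fail the Rayleigh gate
  g <- scan_jxk(r_grid = 2, c_grid = 0.02,
                config = sim_config(seed = 2, n_iterations = 6))
  # this near-zero-drive cell has negligible oscillation; gates must hold
  expect_true(all(!g$in_regime | g$rayleigh_p < 0.01))
})

test_that("regime summary flags empty masks and reports set-level statistics", {
  g <- cached_js_scan()
  s <- summarize_regime(g)
  expect_equal(s$n_cells, 41 * 41)
  expect_gt(s$n_in_regime, 0)
  expect_equal(s$superlinear_fraction, 1)
  expect_gt(s$mean_vector_strength, 0.99)
  expect_false(s$empty)
  expect_equal(dim(s$bounding_box), c(2, 2))

  empty <- g[g$I_E < -1, , drop = FALSE]  # no rows
  attr(empty, "model") <- "js"
  attr(empty, "axes") <- c("I_E", "I_I")
  class(empty) <- c("regime_grid", "data.frame")
  se <- summarize_regime(empty)
  expect_true(se$empty)
  expect_equal(se$n_in_regime, 0)
  expect_true(is.na(se$mean_vector_strength))
})

test_that("regime grids round-trip through CSV with provenance sidecar", {
  g <- scan_js(I_E_grid = c(2, 3), I_I_grid = c(7, 8))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))))
  write_regime_grid(g, path)
  s <- cmd_summarize(path)
  expect_equal(s$n_cells, 4)
  expect_equal(s$n_in_regime, sum(g$in_regime))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$model, "js")
  expect_equal(meta$tolerance, 22.5)
})
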