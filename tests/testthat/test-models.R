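test_that("contrast drives saturate and half-saturate at c50", {
  expect_equal(unlist(contrast_drive(1e6)), c(I_E = 40, I_I = 32),
               tolerance = 1e-10)
  expect_equal(unlist(contrast_drive(0)), c(I_E = 0, I_I = 0))
  expect_equal(unlist(contrast_drive(0.3)), c(I_E = 20, I_I = 16))
})

test_that("sigmoidal activation is zero at rest and saturates correctly", {
  for (m in c(0.5, 1, 2)) for (th in c(5, 20)) {
    expect_equal(js_activation(0, m, th), 0)
    expect_equal(js_activation(1e4, m, th), 1 - 1 / (1 + exp(m * th)),
                 tolerance = 1e-12)
  }
  expect_equal(js_activation(20, 1, 20), 0.5 - 1 / (1 + exp(20)),
               tolerance = 1e-12)
})

test_that("ISN model sits at the origin without drive and oscillates in-regime", {
  z <- simulate_js(js_params(I_E = 0, I_I = 0),
                   sim_config(duration = 0.2))
  expect_true(all(z$r_E == 0))
  expect_true(all(z$r_I == 0))

  tr <- simulate_js(js_params(I_E = 3, I_I = 7.5))
  px <- lfp_proxy(tr)
  seg <- px[seq(10001, 20000, by = 10)]
  pk <- find_gamma_peak(multitaper_psd(seg, 1000))
  expect_gte(pk, 30)
  expect_lte(pk, 70)
  # deterministic: bit-identical repeat
  tr2 <- simulate_js(js_params(I_E = 3, I_I = 7.5))
  expect_identical(tr$r_E, tr2$r_E)
})

test_that("Euler refinement leaves the gamma peak stable within 1 Hz", {
  peak_at <- function(dt) {
    tr <- simulate_js(js_params(I_E = 3, I_I = 7.5), sim_config(dt = dt))
    px <- lfp_proxy(tr)
    fs_in <- round(1000 / dt)
    seg <- px[seq(fs_in + 1, 2 * fs_in, by = fs_in / 1000)]
    find_gamma_peak(multitaper_psd(seg, 1000))
  }
  p1 <- peak_at(0.1)
  p2 <- peak_at(0.05)
  p3 <- peak_at(0.025)
  expect_lt(abs(p1 - p2), 1 + 1e-9)
  expect_lt(abs(p2 - p3), 1 + 1e-9)
})

test_that("oscillation envelope decays below the bifurcation and persists above", {
  below <- simulate_js(js_params(I_E = 2, I_I = 4))
  tail_sd <- sd(below$r_E[(length(below$r_E) - 999):length(below$r_E)])
  expect_lt(tail_sd, 1e-6)

  above <- simulate_js(js_params(I_E = 3, I_I = 7.5))
  w <- above$r_E[10001:20000]
  sd1 <- sd(w[1:5000])
  sd2 <- sd(w[5001:10000])
  expect_lt(abs(sd1 - sd2) / sd1, 0.1)
})

test_that("equilibrium matches long-time integration below the bifurcation", {
  p <- js_params(I_E = 2, I_I = 4)
  fp <- js_fixed_point(p)
  expect_true(fp$converged)
  expect_lt(fp$residual, 1e-9)
  tr <- simulate_js(p)
  expect_equal(mean(tail(tr$r_E, 1000)), fp$r_E, tolerance = 1e-6)
  expect_equal(mean(tail(tr$r_I, 1000)), fp$r_I, tolerance = 1e-6)

  z <- js_fixed_point(js_params(I_E = 0, I_I = 0))
  expect_equal(z$r_E, 0, tolerance = 1e-9)
  expect_equal(z$operating_point, 0, tolerance = 1e-8)
})

test_that("superlinear classification uses a strict threshold inequality", {
  expect_true(classify_superlinear(js_params(I_E = 0, I_I = 0)))
  p <- js_params()
  expect_false(classify_superlinear(
    p, fixed_point = list(converged = TRUE, operating_point = p$theta_I)))
  expect_true(classify_superlinear(
    p, fixed_point = list(converged = TRUE, operating_point = p$theta_I - 0.01)))
})

test_that("stochastic model is a damped oscillator whose noise sustains gamma", {
  quiet <- simulate_jxk(noise_scale = 0)
  px <- lfp_proxy(quiet)
  sds <- vapply(split(px[2001:20000], rep(1:9, each = 2000)), sd, numeric(1))
  expect_true(all(diff(sds[1:5]) < 0))   # envelope strictly decaying
  expect_lt(sds[5] / sds[1], 1e-3)

  # near-zero contrast: all rates decay to zero
  lowc <- simulate_jxk(jxk_params(c = 1e-4), sim_config(duration = 0.5),
                       noise_scale = 0)
  expect_lt(max(abs(tail(lowc$r_E, 100))), 1e-3)

  # seeded reproducibility
  a <- simulate_jxk(config = sim_config(seed = 12))
  b <- simulate_jxk(config = sim_config(seed = 12))
  expect_identical(a$r_E, b$r_E)
  expect_identical(a$E_inp, b$E_inp)
  # Poisson inputs time-average to the nominal drive
  drv <- contrast_drive(a$params$c)
  expect_equal(mean(a$E_inp), drv$I_E, tolerance = 0.02)
})

test_that("LFP proxy modes are linear combinations of the population rates", {
  tr <- simulate_js(js_params(I_E = 3, I_I = 7.5), sim_config(duration = 0.5))
  expect_equal(lfp_proxy(tr, "EI"), lfp_proxy(tr, "E") + lfp_proxy(tr, "I"))
  expect_equal(lfp_proxy(tr, "E"), -tr$r_E)
})

test_that("E-over-I phase lead recovers a constructed delay and flags flat traces", {
  fs <- 10000
  t <- seq(0.0001, 2, by = 1e-4)
  base <- 0.1 + 0.05 * cos(2 * pi * 40 * t)
  fake <- structure(
    list(time = t, r_E = base,
         r_I = 0.1 + 0.05 * cos(2 * pi * 40 * t - pi / 2),  # quarter cycle later
         sampling_rate = fs, model = "js",
         config = sim_config()),
    class = "sim_trace")
  lead <- e_i_phase_lead(fake, gamma_freq = 40)
  expect_true(lead$defined)
  expect_equal(lead$lead_deg, 90, tolerance = 0.5)

  fake$r_I <- fake$r_E  # identical copy: zero lead
  expect_equal(e_i_phase_lead(fake, gamma_freq = 40)$lead_deg, 0,
               tolerance = 0.5)

  flat <- fake
  flat$r_E <- rep(0.1, length(t))
  flat$r_I <- rep(0.2, length(t))
  expect_false(e_i_phase_lead(flat)$defined)
})

test_that("model phase analysis finds the harmonic at twice gamma for any proxy", {
  tr <- simulate_js(js_params(I_E = 3, I_I = 7.5))
  for (mode in c("EI", "E", "I")) {
    px <- lfp_proxy(tr, mode)
    seg <- px[seq(10001, 20000, by = 10)]
    gf <- find_gamma_peak(multitaper_psd(seg, 1000))
    gh <- gamma_harmonic_phase(seg, 1000, gf)
    expect_gt(gh$summary$vector_strength, 0.95)
  }
})
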