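test_that("peak_iv recovers the analytic extremum of a constructed family", {
  # build a fake two-sweep step family with known waveforms
  mk <- function(sweep, v, f) {
    t_h <- seq(0, 200, by = 1)
    t_s <- seq(0, 100, by = 1)
    rbind(
      data.frame(time_ms = t_h, seg_time_ms = t_h, sweep = sweep,
                 label = "hold", step_mv = v, i_clamp = 2),
      data.frame(time_ms = 200 + t_s, seg_time_ms = t_s, sweep = sweep,
                 label = "step", step_mv = v, i_clamp = 2 + f(t_s))
    )
  }
  tr <- rbind(mk(1, -10, function(t) -50 * exp(-t / 30)),
              mk(2, 0, function(t) 20 * t / 100))
  iv <- peak_iv(tr, mode = "peak", cm = 20)
  expect_equal(iv$current_pa[iv$step_mv == -10], -50)
  expect_equal(iv$current_pa[iv$step_mv == 0], 20)
  expect_equal(iv$density_pa_pf, iv$current_pa / 20)
  # all-zero trace maps to a zero curve
  tr0 <- tr; tr0$i_clamp <- 0
  expect_true(all(peak_iv(tr0, cm = 20)$current_pa == 0))
})

test_that("steady mode averages the final 5% of the step", {
  t_s <- seq(0, 100, by = 0.5)
  tr <- rbind(
    data.frame(time_ms = seq(0, 100, 0.5), seg_time_ms = seq(0, 100, 0.5),
               sweep = 1, label = "hold", step_mv = 10, i_clamp = 0),
    data.frame(time_ms = 100 + t_s, seg_time_ms = t_s, sweep = 1,
               label = "step", step_mv = 10, i_clamp = t_s)
  )
  iv <- peak_iv(tr, mode = "steady", cm = 20)
  expect_equal(iv$current_pa, mean(t_s[t_s >= 95]))
})

test_that("Boltzmann fit recovers noiseless parameters to machine precision", {
  v <- seq(-80, 10, by = 5)
  y <- 1 / (1 + exp((-40 - v) / 6))
  f <- fit_boltzmann(data.frame(v = v, y = y), "activation")
  expect_equal(f$v_half, -40, tolerance = 1e-8)
  expect_equal(f$k, 6, tolerance = 1e-8)
  expect_equal(f$ymax, 1, tolerance = 1e-8)
  yi <- 1 / (1 + exp((v + 48.9) / 6.3))
  fi <- fit_boltzmann(data.frame(v = v, y = yi), "inactivation")
  expect_equal(fi$v_half, -48.9, tolerance = 1e-6)
  expect_equal(fi$k, 6.3, tolerance = 1e-6)
})

test_that("the complementary inactivation convention fits the same data", {
  v <- seq(-90, 0, by = 5)
  y <- 1 / (1 + exp((v + 48.9) / 6.3))
  f <- fit_boltzmann(data.frame(v = v, y = y), "inactivation",
                     convention = "one_minus")
  expect_equal(f$v_half, -48.9, tolerance = 1e-6)
  expect_equal(abs(f$k), 6.3, tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)
})

test_that("fit is scale invariant apart from the amplitude", {
  v <- seq(-80, 10, by = 5)
  y <- 0.9 / (1 + exp((-35 - v) / 5))
  f1 <- fit_boltzmann(data.frame(v = v, y = y), "activation")
  f2 <- fit_boltzmann(data.frame(v = v, y = 3.7 * y), "activation")
  expect_equal(f2$v_half, f1$v_half, tolerance = 1e-8)
  expect_equal(f2$k, f1$k, tolerance = 1e-8)
  expect_equal(f2$ymax / f1$ymax, 3.7, tolerance = 1e-8)
})

test_that("noisy Boltzmann recovery is unbiased within 1 mV", {
  withr::local_seed(42)
  v <- seq(-70, 0, by = 5)
  truth <- 1 / (1 + exp((-32.3 - v) / 6))
  est <- replicate(100, {
    y <- truth + rnorm(length(v), 0, 0.03)
    fit_boltzmann(data.frame(v = v, y = y), "activation")$v_half
  })
  expect_lt(abs(mean(est) + 32.3), 1)
})

test_that("a trend opposite to the requested kind produces a warning", {
  v <- seq(-80, 0, by = 5)
  y <- 1 / (1 + exp((v + 40) / 6))   # decreasing, i.e. inactivation-shaped
  expect_warning(fit_boltzmann(data.frame(v = v, y = y), "activation"),
                 "opposite")
})

test_that("fit demands enough points around the midpoint", {
  expect_error(fit_boltzmann(data.frame(v = c(-40, -30), y = c(0.4, 0.6))),
               "at least 4")
})

test_that("subtracting a trace from itself is zero; mismatches error", {
  p <- leak_only_params()
  tr <- simulate_neuron(p, one_step_protocol(0, step_ms = 50,
                                             settle_ms = 100),
                        settle_ms = 0)
  d <- drug_subtraction(tr, tr)
  expect_true(all(abs(d$i_clamp) < 1e-12, na.rm = TRUE))
  tr2 <- simulate_neuron(p, one_step_protocol(10, step_ms = 50,
                                              settle_ms = 100),
                         settle_ms = 0)
  expect_error(drug_subtraction(tr, tr2), "different protocols")
})

test_that("drug subtraction equals the stored SK decomposition", {
  p <- kndy_params("ovx_e2")
  proto <- one_step_protocol(40)
  init <- kndy_initial_state(p, -70)
  ctl <- simulate_neuron(p, proto, init = init)
  trt <- simulate_neuron(apply_drug(p, "apamin"), proto, init = init)
  d <- drug_subtraction(ctl, trt)
  on_step <- d$label == "step"
  expect_lt(max(abs(d$i_clamp[on_step] - ctl$i_sk[on_step])), 1e-4)
})

test_that("M-current amplitude: constant trace gives 0, exponential matches closed form", {
  t_s <- seq(0, 500, by = 0.1)
  mk <- function(i) rbind(
    data.frame(time_ms = t_s, seg_time_ms = t_s, sweep = 1, label = "step",
               step_mv = -40, i_clamp = i))
  expect_equal(m_current_amplitude(mk(rep(7, length(t_s))))$amplitude_pa, 0)
  A <- 80; tau <- 100
  amp <- m_current_amplitude(mk(A * exp(-t_s / tau)))$amplitude_pa
  # analytic window means of the exponential
  early <- A * tau / 10 * (1 - exp(-10 / tau))
  late <- A * tau / 25 * (exp(-475 / tau) - exp(-500 / tau))
  expect_equal(amp, early - late, tolerance = 1e-3)
})

test_that("slow EPSP metrics: flat trace undetectable, symmetric epochs ratio 1", {
  t <- seq(0, 120000, by = 5)
  base <- data.frame(time_ms = t, vm = -65,
                     label = "baseline", sweep = 1)
  epoch <- function(t0, sweep) {
    lab <- ifelse(t >= t0 & t < t0 + 10000, "train",
                  ifelse(t >= t0 + 10000 & t < t0 + 50000, "post",
                         "baseline"))
    lab
  }
  lab <- epoch(5000, 1)
  lab[t >= 60000] <- epoch(65000, 2)[t >= 60000]
  sweep <- ifelse(t < 60000, 1, 2)
  flat <- data.frame(time_ms = t, vm = -65, label = lab, sweep = sweep)
  m0 <- slow_epsp_metrics(flat)
  expect_equal(m0$r1_mv, 0, tolerance = 1e-6)
  expect_true(is.na(m0$ratio))
  bump <- function(t0) 12 * exp(-(t - (t0 + 10000))^2 / (2 * 4000^2)) *
    (t > t0)
  vm <- -65 + bump(5000) + bump(65000)
  sym <- data.frame(time_ms = t, vm = vm, label = lab, sweep = sweep)
  m1 <- slow_epsp_metrics(sym)
  expect_equal(m1$ratio, 1, tolerance = 0.02)
  expect_equal(m1$r1_mv, 12, tolerance = 0.05 * 12)
})

test_that("rheobase: subthreshold ramp is not-reached, spikes give the ramp current", {
  t <- seq(0, 2000, by = 0.5)
  flat <- data.frame(time_ms = t, vm = -70, label = "ramp",
                     i_inj = 0.05 * t)
  expect_true(is.na(rheobase(flat)$rheobase_pa))
  vm <- rep(-70, length(t)); vm[t >= 1000 & t < 1002] <- 10
  tr <- data.frame(time_ms = t, vm = vm, label = "ramp", i_inj = 0.05 * t)
  expect_equal(rheobase(tr)$rheobase_pa, 50, tolerance = 0.001)
})

test_that("firing classification matches constructed ground truth", {
  expect_equal(classify_firing(generate_spike_train("silent", 20, 1))$label,
               "silent")
  expect_equal(classify_firing(
    generate_spike_train("tonic", 20, 2, rate_hz = 5, isi_cv = 0.1))$label,
    "tonic")
  expect_equal(classify_firing(
    generate_spike_train("irregular", 30, 3, rate_hz = 4, isi_cv = 1.2))$label,
    "irregular")
  expect_equal(classify_firing(
    generate_spike_train("burst", 20, 4))$label, "phasic_burst")
  expect_equal(classify_firing(
    generate_spike_train("burst", 20, 5, updown = FALSE))$label,
    "irregular_burst")
})

test_that("classification is invariant to time origin and to resampling", {
  tr <- generate_spike_train("burst", 20, 7)
  a <- classify_firing(tr)
  shifted <- tr; shifted$time_ms <- shifted$time_ms + 12345
  expect_equal(classify_firing(shifted)$label, a$label)
  up <- generate_spike_train("burst", 20, 7, dt_ms = 0.25)
  expect_equal(classify_firing(up)$label, a$label)
})

test_that("classification refuses traces shorter than 10 s", {
  expect_error(classify_firing(generate_spike_train("tonic", 5, 1)),
               "10 s")
})

test_that("a 1x1 regime map equals direct classification", {
  p <- kndy_params("ovx")
  proto <- constant_drive_protocol(12)
  m <- regime_map(p, list(channel = "TRPC5", values = 2),
                  list(channel = "GIRK", values = 1.2), proto)
  expect_equal(nrow(m), 1)
  direct <- classify_firing(simulate_neuron(p, proto))
  expect_equal(m$label, direct$label)
})
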