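test_that("a leak-only cell at its reversal potential is at equilibrium", {
  p <- leak_only_params()
  st <- kndy_initial_state(p, -70)
  r <- membrane_rhs(st, p, i_inj = 0)
  expect_equal(max(abs(r$derivatives)), 0, tolerance = 1e-12)
})

test_that("leak-only membrane equation gives dVm/dt in mV/ms (pA/pF)", {
  # 1 nS x 10 mV = 10 pA; 10 pA / 10 pF = 1 mV/ms
  p <- leak_only_params(g_leak = 1, e_leak = -70, cm = 10)
  st <- kndy_initial_state(p, -60)
  r <- membrane_rhs(st, p, i_inj = 0)
  expect_equal(unname(r$derivatives[["v"]]), -1)
  expect_equal(unname(r$currents[["i_leak"]]), 10)
})

test_that("gating variables at steady state have zero derivatives", {
  p <- kndy_params("ovx")
  st <- kndy_initial_state(p, -55)
  r <- membrane_rhs(st, p, i_inj = 0)
  gate_names <- c("h_na", "b_a", "m_ca", "h_ca", "m_t", "h_t", "m_m", "r")
  expect_equal(max(abs(r$derivatives[gate_names])), 0, tolerance = 1e-12)
})

test_that("current/voltage clamp modes are mutually exclusive", {
  p <- kndy_params("ovx")
  st <- kndy_initial_state(p, -70)
  expect_error(membrane_rhs(st, p), "exactly one")
  expect_error(membrane_rhs(st, p, i_inj = 0, v_cmd = -70), "exactly one")
})

test_that("compiled and reference right-hand sides integrate identically", {
  p <- kndy_params("ovx_e2")
  st <- kndy_initial_state(p, -65)
  r_fun <- function(t, y, parms) {
    names(y) <- names(st)
    list(unname(membrane_rhs(y, parms, i_inj = 20)$derivatives))
  }
  t_out <- seq(0, 50, by = 1)
  ref <- deSolve::ode(unname(st), t_out, r_fun, p,
                      rtol = 1e-9, atol = 1e-11)
  proto <- kndysim:::new_protocol(
    kndysim:::new_segment(50, "cc", "step", value = 20, dt = 1), "pulse")
  cc <- simulate_neuron(p, proto, init = st, rtol = 1e-9, atol = 1e-11)
  expect_lt(max(abs(ref[, 2] - cc$vm)), 1e-3)
})

test_that("leak-only relaxation matches the closed form", {
  p <- leak_only_params(g_leak = 1, e_leak = -70, cm = 10)  # tau = 10 ms
  st <- kndy_initial_state(p, -50)
  proto <- kndysim:::new_protocol(
    kndysim:::new_segment(60, "cc", "relax", value = 0, dt = 0.1), "relax")
  tr <- simulate_neuron(p, proto, init = st)
  expected <- -70 + 20 * exp(-tr$time_ms / 10)
  expect_lt(max(abs(tr$vm - expected) / pmax(abs(expected), 1)), 1e-3)
})

test_that("gating stays in [0,1] and calcium non-negative on trajectories", {
  for (state in c("ovx", "ovx_e2")) {
    tr <- simulate_neuron(kndy_params(state), spontaneous_protocol(12))
    expect_true(all(tr$ca_d >= 0))
    expect_true(all(tr$ca_b >= 0))
    expect_true(all(tr$a_n >= 0 & tr$a_n <= 1))
    expect_true(all(tr$a_d >= 0 & tr$a_d <= 1))
    expect_true(all(is.finite(tr$vm)))
  }
})

test_that("stored per-current decomposition sums to the net current", {
  tr <- simulate_neuron(kndy_params("ovx_e2"), spontaneous_protocol(3))
  err <- abs(rowSums(as.matrix(tr[, current_cols])) - tr$i_net)
  expect_lt(max(err), 1e-8)
})

test_that("voltage clamp converges to the analytic steady-state current", {
  p <- kndy_params("ovx")
  v <- -30
  tr <- simulate_neuron(p, one_step_protocol(v, step_ms = 20000))
  i_end <- utils::tail(tr$i_clamp[tr$label == "step"], 1)

  # analytic fixed point: every gate at its v-steady value, the submembrane
  # pool at the self-consistent CDI root, the bulk pool at its own root
  ca <- p$calcium
  kC <- p$channels$Ca$kin
  g_ca <- p$channels$Ca$gbar
  m_inf <- gating_steady_state(v, kC$vh_m, kC$k_m)
  h_inf <- kC$h_floor + (1 - kC$h_floor) *
    gating_steady_state(v, kC$vh_h, kC$k_h, "inactivation")
  ica_of <- function(cad) {
    g_ca * m_inf * h_inf * (ca$k_cdi / (ca$k_cdi + cad)) * (v - 100)
  }
  cad_star <- stats::uniroot(function(x) {
    ca$ca0_d - ca$kd * ca$tau_d * ica_of(x) - x
  }, c(0, 10))$root
  k5 <- p$channels$TRPC5$kin
  gt5 <- p$channels$TRPC5$gbar
  kT <- p$channels$T$kin
  it <- p$channels$T$gbar *
    gating_steady_state(v, kT$vh_m, kT$k_m)^2 *
    gating_steady_state(v, kT$vh_h, kT$k_h, "inactivation") * (v - 100)
  cab_star <- stats::uniroot(function(x) {
    cinf <- x^2 / (x^2 + k5$k_ca^2)
    flux <- ica_of(cad_star) + it +
      k5$ca_flux_frac * gt5 * cinf * (1 - k5$des_max * cinf) * (v - 100)
    ca$ca0 - ca$kb * ca$tau_b * flux - x
  }, c(0, 10))$root

  st <- kndy_initial_state(p, v)
  st[["ca_d"]] <- cad_star
  st[["ca_b"]] <- cab_star
  ksk <- p$channels$SK$kin$k_ca
  st[["s"]] <- cad_star^4 / (cad_star^4 + ksk^4)
  st[["c"]] <- cab_star^2 / (cab_star^2 + k5$k_ca^2)
  st[["dtr"]] <- k5$des_max * st[["c"]]
  r <- membrane_rhs(st, p, v_cmd = v)
  expect_equal(i_end, r$i_clamp, tolerance = 0.01)
})

test_that("adaptive solution matches a fixed-step RK4 reference", {
  p <- kndy_params("ovx")
  proto <- spontaneous_protocol(1)
  a <- simulate_neuron(p, proto, settle_ms = 1000)
  b <- simulate_neuron(p, proto, settle_ms = 1000, method = "rk4",
                       rk4_dt = 0.01)
  expect_lt(max(abs(a$vm - b$vm)), 0.5)
})

test_that("tighter solver tolerances do not change the solution", {
  p <- kndy_params("ovx")
  proto <- spontaneous_protocol(1)
  a <- simulate_neuron(p, proto, settle_ms = 1000)
  b <- simulate_neuron(p, proto, settle_ms = 1000,
                       rtol = 1e-7, atol = 1e-10)
  expect_lt(max(abs(a$vm - b$vm)), 0.1)
})

test_that("trace round-trips through its tabular file format", {
  tr <- simulate_neuron(leak_only_params(), spontaneous_protocol(1),
                        settle_ms = 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sim_trace(tr, path)
  back <- read_sim_trace(path)
  expect_equal(back$vm, tr$vm, tolerance = 1e-6)
  expect_true(any(grepl("protocol_hash", readLines(path, n = 5))))
})
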