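# a cell with every conductance removed except leak
leak_only_params <- function(g_leak = 1, e_leak = -70, cm = 10) {
  kndy_params("custom",
              gbar = c(NaT = 0, NaP = 0, A = 0, BK = 0, h = 0, SK = 0,
                       M = 0, T = 0, Ca = 0, TRPC5 = 0, GIRK = 0,
                       leak = g_leak),
              cm = cm) |>
    (\(p) {
      p$channels$leak$erev <- e_leak
      p
    })()
}

# single-sweep voltage-clamp step protocol with a short settle
one_step_protocol <- function(v_step, hold = -70, step_ms = 500,
                              settle_ms = 5000) {
  kndysim:::new_protocol(
    kndysim:::step_family(hold, v_step, step_ms, settle_ms = settle_ms),
    "one_step")
}

current_cols <- c("i_nat", "i_nap", "i_a", "i_bk", "i_h", "i_sk",
                  "i_m", "i_t", "i_ca", "i_trpc5", "i_girk", "i_leak")

# steady drug-sensitive density at one voltage (pA/pF)
drug_sensitive_density <- function(params, drug, v = 40) {
  proto <- k_iv_protocol(steps_mv = v)
  ctl <- peak_iv(simulate_neuron(params, proto), mode = "steady")
  trt <- peak_iv(simulate_neuron(apply_drug(params, drug), proto),
                 mode = "steady")
  drug_subtraction(ctl, trt)$density_pa_pf
}
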