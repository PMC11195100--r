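.kndy_current_names <- c("i_nat", "i_nap", "i_a", "i_bk", "i_h", "i_sk",
                         "i_m", "i_t", "i_ca", "i_trpc5", "i_girk", "i_leak")
.kndy_out_names <- c(.kndy_current_names, "i_net", "i_inj", "v_used")

#' Membrane and gating right-hand side (reference implementation)
#'
#' Evaluates the time-derivatives of the full neuron state at one instant, in
#' plain R. The compiled solver core computes the same quantities; this
#' function is the readable reference, used for single evaluations and for
#' cross-checking the compiled code.
#'
#' In current clamp (`i_inj` given) the membrane equation is
#' `dVm/dt = (I_inj - sum(I_ionic)) / Cm`, with currents in pA, Cm in pF and
#' the result in mV/ms. In voltage clamp (`v_cmd` given) the clamp is ideal:
#' `dVm/dt` is zero, the gating and calcium dynamics see `v_cmd`, and the
#' clamp current equals the net ionic current.
#'
#' @param state Named state vector as produced by [kndy_initial_state()].
#' @param params A `neuron_params` object.
#' @param i_inj Injected current (pA); exactly one of `i_inj`/`v_cmd`.
#' @param v_cmd Command potential (mV).
#' @param nkb,dyn Receptor drive inputs in `[0, 1]`.
#' @return List with `derivatives` (named vector), `currents` (named vector of
#'   the 12 ionic currents, pA, outward positive) and `i_clamp` (voltage clamp
#'   only).
#' @export
membrane_rhs <- function(state, params, i_inj = NULL, v_cmd = NULL,
                         nkb = 0, dyn = 0) {
  validate_neuron_params(params)
  if (is.null(i_inj) == is.null(v_cmd)) {
    abort("exactly one of `i_inj` (current clamp) or `v_cmd` (voltage clamp) must be given")
  }
  if (any(state[2:13] < -1e-9) || any(state[2:13] > 1 + 1e-9)) {
    abort("gating/drive state variables must lie in [0, 1]")
  }
  if (any(state[c("ca_d", "ca_b")] < 0)) abort("calcium must be >= 0")

  vclamp <- !is.null(v_cmd)
  v <- if (vclamp) v_cmd else unname(state[["v"]])
  ch <- params$channels
  g <- function(nm) max(0, ch[[nm]]$gbar * (1 - ch[[nm]]$block))
  kin <- function(nm) ch[[nm]]$kin
  act <- function(nm, vh, k) gating_steady_state(v, vh, k, "activation")
  inact <- function(nm, vh, k) gating_steady_state(v, vh, k, "inactivation")

  cad <- unname(state[["ca_d"]]); cab <- unname(state[["ca_b"]])
  kN <- kin("NaT"); kA <- kin("A"); kB <- kin("BK"); kH <- kin("h")
  kS <- kin("SK"); kM <- kin("M"); kT <- kin("T"); kC <- kin("Ca")
  k5 <- kin("TRPC5"); kG <- kin("GIRK")
  eca <- ch$Ca$erev

  mna <- act("NaT", kN$vh_m, kN$k_m)
  cur <- c(
    i_nat = g("NaT") * mna^3 * state[["h_na"]] * (v - ch$NaT$erev),
    i_nap = g("NaP") * act("NaP", kin("NaP")$vh, kin("NaP")$k) *
      (v - ch$NaP$erev),
    i_a = g("A") * act("A", kA$vh_a, kA$k_a) * state[["b_a"]] *
      (v - ch$A$erev),
    i_bk = g("BK") * act("BK", kB$vh, kB$k) *
      (cad^4 / (cad^4 + kB$k_ca^4)) * (v - ch$BK$erev),
    i_h = g("h") * state[["r"]] * (v - ch$h$erev),
    i_sk = g("SK") * state[["s"]] * (v - ch$SK$erev),
    i_m = g("M") * state[["m_m"]] *
      (1 - kG$pip2_frac * state[["a_n"]]) * (v - ch$M$erev),
    i_t = g("T") * state[["m_t"]]^2 * state[["h_t"]] * (v - ch$T$erev),
    i_ca = g("Ca") * state[["m_ca"]] * state[["h_ca"]] *
      (params$calcium$k_cdi / (params$calcium$k_cdi + cad)) * (v - eca),
    i_trpc5 = g("TRPC5") * state[["c"]] * (1 - state[["dtr"]]) *
      (v - ch$TRPC5$erev),
    i_girk = g("GIRK") * (kG$a0 + (1 - kG$a0) * state[["a_d"]]) *
      gating_steady_state(v, kG$vh_rect, kG$k_rect, "inactivation") *
      (1 - kG$pip2_frac * state[["a_n"]]) * (v - ch$GIRK$erev),
    i_leak = g("leak") * (v - ch$leak$erev)
  )
  i_net <- sum(cur)

  tau_hna <- kN$tau_h_base + kN$tau_h_amp * exp(-((v + 60) / 25)^2)
  hfl <- kC$h_floor
  s_inf <- cad^4 / (cad^4 + kS$k_ca^4)
  cca <- cab^2 / (cab^2 + k5$k_ca^2)
  g_t5 <- g("TRPC5") * state[["c"]] * (1 - state[["dtr"]])
  i_t5_ca <- k5$ca_flux_frac * g_t5 * (v - eca)
  ca <- params$calcium; dr <- params$drive

  d <- c(
    v = if (vclamp) 0 else (i_inj - i_net) / params$cm,
    h_na = (inact("NaT", kN$vh_h, kN$k_h) - state[["h_na"]]) / tau_hna,
    b_a = (inact("A", kA$vh_b, kA$k_b) - state[["b_a"]]) / kA$tau_b,
    m_ca = (act("Ca", kC$vh_m, kC$k_m) - state[["m_ca"]]) / kC$tau_m,
    h_ca = (hfl + (1 - hfl) * inact("Ca", kC$vh_h, kC$k_h) -
              state[["h_ca"]]) / kC$tau_h,
    m_t = (act("T", kT$vh_m, kT$k_m) - state[["m_t"]]) / kT$tau_m,
    h_t = (inact("T", kT$vh_h, kT$k_h) - state[["h_t"]]) /
      (kT$tau_h * (kT$tau_h_floor + (1 - kT$tau_h_floor) *
                     gating_steady_state(v, -60, 6, "inactivation"))),
    s = (s_inf - state[["s"]]) / kS$tau,
    m_m = (act("M", kM$vh, kM$k) - state[["m_m"]]) / kM$tau,
    r = (inact("h", kH$vh, kH$k) - state[["r"]]) / kH$tau,
    c = (1 - (1 - state[["a_n"]]) * (1 - cca) - state[["c"]]) / k5$tau,
    a_n = nkb * (1 - state[["a_n"]]) / dr$tau_nkb_on -
      state[["a_n"]] / dr$tau_nkb_off,
    a_d = dyn * (1 - state[["a_d"]]) / dr$tau_dyn_on -
      state[["a_d"]] / dr$tau_dyn_off,
    ca_d = -ca$kd * cur[["i_ca"]] - (cad - ca$ca0_d) / ca$tau_d,
    ca_b = -ca$kb * (cur[["i_ca"]] + cur[["i_t"]] + i_t5_ca) -
      (cab - ca$ca0) / ca$tau_b,
    dtr = (k5$des_max * state[["c"]] - state[["dtr"]]) / k5$tau_des
  )
  list(derivatives = d, currents = cur, i_net = i_net,
       i_clamp = if (vclamp) i_net else NA_real_)
}

#' Simulate a neuron under a stimulus protocol
#'
#' Integrates the 12-current model over the protocol's segments with an
#' adaptive solver (compiled right-hand side). Unless an initial state is
#' supplied, the membrane is first settled for `settle_ms` at zero injected
#' current from -70 mV so that the protocol starts from the model's resting
#' state.
#'
#' @param params A `neuron_params` object.
#' @param protocol A `stimulus_protocol`.
#' @param init Optional named initial state vector.
#' @param settle_ms Settling time before the protocol (ms); 5 s by default.
#' @param rtol,atol Solver relative/absolute tolerances.
#' @param max_step Maximum solver step (ms).
#' @param method deSolve method: `"lsoda"` (default) or a fixed-step
#'   `"rk4"` reference (`rk4_dt` then sets the step).
#' @param rk4_dt Fixed step for `method = "rk4"` (ms).
#' @return A `sim_trace` tibble: `time_ms`, `vm`, `i_clamp` (voltage-clamp
#'   segments), `i_inj`, the 12 per-channel currents, `i_net`, both calcium
#'   pools, receptor drives, and the segment bookkeeping columns
#'   (`sweep`, `label`, `mode`, `step_mv`). Parameters, protocol and solver
#'   options are attached as attributes.
#' @export
simulate_neuron <- function(params, protocol, init = NULL, settle_ms = 5000,
                            rtol = 1e-6, atol = 1e-9, max_step = 1,
                            method = c("lsoda", "rk4"), rk4_dt = 0.01) {
  validate_neuron_params(params)
  stopifnot(inherits(protocol, "stimulus_protocol"), nrow(protocol) > 0)
  method <- match.arg(method)

  y <- init %||% kndy_initial_state(params, -70)
  if (is.null(init) && settle_ms > 0) {
    pv <- params_vector(params)
    y <- run_segment(y, pv, 0, settle_ms, dt = min(settle_ms, 5),
                     rtol = rtol, atol = atol, max_step = max_step,
                     method = method, rk4_dt = rk4_dt, final_only = TRUE)
  }

  t0 <- 0
  pieces <- vector("list", nrow(protocol))
  for (i in seq_len(nrow(protocol))) {
    sg <- protocol[i, ]
    pv <- params_vector(
      params,
      mode = if (sg$mode == "vc") 1 else 0,
      cmd_kind = if (sg$cmd == "ramp") 1 else 0,
      cmd_value = sg$value, cmd_rate = sg$rate, t0 = t0,
      nkb_mode = if (sg$nkb_mode == "train") 1 else 0,
      nkb_level = sg$nkb_level, nkb_period = sg$nkb_period,
      nkb_width = sg$nkb_width,
      dyn_mode = if (sg$dyn_mode == "train") 1 else 0,
      dyn_level = sg$dyn_level, dyn_period = sg$dyn_period,
      dyn_width = sg$dyn_width
    )
    if (sg$mode == "vc") y[["v"]] <- sg$value
    out <- run_segment(y, pv, t0, sg$duration, dt = sg$dt,
                       rtol = rtol, atol = atol, max_step = max_step,
                       method = method, rk4_dt = rk4_dt)
    y <- out$final
    df <- out$table
    df$sweep <- sg$sweep
    df$label <- sg$label
    df$mode <- sg$mode
    df$step_mv <- sg$step_mv
    df$seg_time_ms <- df$time_ms - t0
    pieces[[i]] <- df
    t0 <- t0 + sg$duration
  }
  tr <- bind_rows(pieces)
  tr$vm <- tr$v_used
  tr$i_clamp <- ifelse(tr$mode == "vc", tr$i_net, NA_real_)
  tr <- tr[, c("time_ms", "seg_time_ms", "sweep", "label", "mode", "step_mv",
               "vm", "i_clamp", "i_inj", .kndy_current_names, "i_net",
               "ca_d", "ca_b", "a_n", "a_d")]
  structure(as_tibble(tr),
            class = c("sim_trace", class(as_tibble(tr))),
            params = params, protocol = protocol,
            protocol_hash = protocol_hash(protocol),
            solver = list(method = method, rtol = rtol, atol = atol,
                          max_step = max_step),
            class_keep = TRUE)
}

run_segment <- function(y, pv, t0, duration, dt, rtol, atol, max_step,
                        method, rk4_dt, final_only = FALSE) {
  times <- seq(t0, t0 + duration, by = dt)
  if (times[length(times)] < t0 + duration) {
    times <- c(times, t0 + duration)
  }
  if (method == "rk4") {
    out <- deSolve::rk4(y, seq(t0, t0 + duration, by = rk4_dt),
                        func = "derivs_kndysim", parms = pv,
                        dllname = "kndysim", initfunc = "initmod_kndysim",
                        nout = 15, outnames = .kndy_out_names)
    keep <- findInterval(times, out[, 1])
    out <- out[keep, , drop = FALSE]
  } else {
    out <- deSolve::ode(y, times, func = "derivs_kndysim", parms = pv,
                        dllname = "kndysim", initfunc = "initmod_kndysim",
                        nout = 15, outnames = .kndy_out_names,
                        method = "lsoda", rtol = rtol, atol = atol,
                        hmax = max_step, maxsteps = 50000)
  }
  m <- unclass(out)
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "integration failure: non-finite value of '%s' at t = %.3f ms",
      colnames(m)[bad[["col"]]], m[bad[["row"]], 1]))
  }
  final <- m[nrow(m), 1 + seq_along(y)]
  names(final) <- names(y)
  if (final_only) return(final)
  df <- as.data.frame(m)
  names(df)[1] <- "time_ms"
  list(final = final, table = df)
}

#' @export
print.sim_trace <- function(x, ...) {
  cat("<sim_trace>", nrow(x), "samples,",
      round(max(x$time_ms) / 1000, 2), "s;",
      "protocol:", attr(attr(x, "protocol"), "protocol_name"), "\n")
  NextMethod()
}

#' Write / read a simulated trace
#'
#' Traces are persisted as plain tab-separated tables with a `#`-prefixed
#' header block recording the originating state label, protocol name and
#' hash, and solver options.
#'
#' @param trace A `sim_trace`.
#' @param path File path.
#' @export
write_sim_trace <- function(trace, path) {
  solver <- attr(trace, "solver")
  hdr <- c(
    paste0("# kndysim sim_trace"),
    paste0("# state: ", attr(trace, "params")$state_label),
    paste0("# protocol: ",
           attr(attr(trace, "protocol"), "protocol_name")),
    paste0("# protocol_hash: ", attr(trace, "protocol_hash")),
    paste0("# solver: ", solver$method, " rtol=", solver$rtol,
           " atol=", solver$atol, " max_step=", solver$max_step)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(trace), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sim_trace
#' @export
read_sim_trace <- function(path) {
  lines <- readLines(path, n = 20)
  skip <- sum(startsWith(lines, "#"))
  df <- utils::read.table(path, skip = skip, header = TRUE, sep = "\t")
  structure(as_tibble(df), class = c("sim_trace", class(as_tibble(df))))
}
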