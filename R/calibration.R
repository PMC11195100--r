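#' Calibrate a channel conductance against current-density targets
#'
#' Finds the maximal conductance for which the simulated drug-sensitive
#' steady-state current density matches target densities at given step
#' potentials. The drug-sensitive density is obtained exactly as in the
#' experiments: the step-family protocol is simulated with and without the
#' channel's blocker and the steady-state densities are subtracted.
#'
#' For channels whose current does not feed back on its own gating (SK, BK,
#' M, GIRK, A, leak under voltage clamp) the drug-sensitive density is
#' exactly linear in `gbar`, so the unweighted least-squares solution is
#' closed-form from a single reference simulation. Channels that alter the
#' calcium pools (Ca, T, TRPC5) are fitted by bounded scalar minimization.
#' Negative solutions are clamped to zero with a warning; a flat
#' (all-zero-sensitivity) objective is an error.
#'
#' @param channel Channel name (e.g. `"SK"`, `"BK"`).
#' @param targets Data frame with columns `v` (mV) and `density` (pA/pF).
#' @param params Base parameter set (preset) to calibrate within.
#' @param protocol Step-family protocol; defaults to [k_iv_protocol()]
#'   restricted to the target voltages.
#' @param mode Measurement mode passed to [peak_iv()] (`"steady"` for the
#'   K+-current calibrations).
#' @param gmax Upper bound for the nonlinear search (nS).
#' @return A `conductance_fit` tibble: `channel`, `gbar_ns`, `rss`, `method`,
#'   plus the per-voltage fit table as attribute `"detail"`.
#' @export
calibrate_conductance <- function(channel, targets, params,
                                  protocol = NULL,
                                  mode = "steady", gmax = 100) {
  stopifnot(all(c("v", "density") %in% names(targets)), nrow(targets) >= 1)
  drug <- names(Filter(function(chs) channel %in% chs, .kndy_full_blocks))[1]
  if (is.na(drug) || !length(drug)) {
    abort(paste0("no full blocker is defined for channel ", channel))
  }
  protocol <- protocol %||% k_iv_protocol(steps_mv = sort(unique(targets$v)))

  sens_density <- function(p) {
    ctl <- peak_iv(simulate_neuron(p, protocol), mode = mode)
    trt <- peak_iv(simulate_neuron(apply_drug(p, drug), protocol),
                   mode = mode)
    d <- drug_subtraction(ctl, trt)
    d$density_pa_pf[match(targets$v, d$step_mv)]
  }

  if (all(targets$density == 0)) {
    out <- tibble(channel = channel, gbar_ns = 0, rss = 0,
                  method = "trivial")
    return(structure(out, class = c("conductance_fit", class(out))))
  }

  linear <- channel %in% c("SK", "BK", "M", "GIRK", "A", "NaP", "leak")
  if (linear) {
    g0 <- params$channels[[channel]]$gbar
    if (g0 <= 0) g0 <- 1
    p0 <- params
    p0$channels[[channel]]$gbar <- g0
    s <- sens_density(p0) / g0        # density per nS at each target voltage
    if (all(abs(s) < 1e-3)) {
      abort(paste0("calibration objective is flat: channel ", channel,
                   " contributes no drug-sensitive current at the target",
                   " voltages"))
    }
    ghat <- sum(s * targets$density) / sum(s^2)
    method <- "closed_form"
  } else {
    obj <- function(g) {
      p <- params
      p$channels[[channel]]$gbar <- g
      sum((sens_density(p) - targets$density)^2)
    }
    opt <- stats::optimize(obj, c(0, gmax))
    ghat <- opt$minimum
    method <- "bounded_search"
    s <- NULL
  }
  if (ghat < 0) {
    warning("calibrated conductance was negative; clamped to 0",
            call. = FALSE)
    ghat <- 0
  }
  pfit <- params
  pfit$channels[[channel]]$gbar <- ghat
  fitted <- sens_density(pfit)
  out <- tibble(channel = channel, gbar_ns = ghat,
                rss = sum((fitted - targets$density)^2), method = method)
  attr(out, "detail") <- tibble(v = targets$v, target = targets$density,
                                fitted = fitted)
  structure(out, class = c("conductance_fit", class(out)))
}

#' Per-channel steady-state density contributions of a preset
#'
#' Verifies a parameter set's calibration the way the recordings do: each
#' Ca2+-activated / voltage-gated K+ channel's contribution is the
#' drug-sensitive steady-state density at +40 mV under the K+ step protocol,
#' and the calcium-channel contribution is the Cd-sensitive peak density at
#' -10 mV under the Ca2+ step protocol (with the cesium-internal condition).
#'
#' @param params A `neuron_params` object.
#' @param k_channels K+ channels to probe.
#' @return Tibble with `channel`, `probe`, `v_mv`, `density_pa_pf`.
#' @export
verify_state_contributions <- function(params,
                                       k_channels = c("SK", "BK", "M")) {
  kproto <- k_iv_protocol(steps_mv = 40)
  kv <- purrr::map_dfr(k_channels, function(ch) {
    drug <- names(Filter(function(chs) ch %in% chs, .kndy_full_blocks))[1]
    ctl <- peak_iv(simulate_neuron(params, kproto), mode = "steady")
    trt <- peak_iv(simulate_neuron(apply_drug(params, drug), kproto),
                   mode = "steady")
    tibble(channel = ch, probe = drug, v_mv = 40,
           density_pa_pf = drug_subtraction(ctl, trt)$density_pa_pf)
  })
  csp <- apply_drug(apply_drug(params, "cs_internal"), "ttx")
  cproto <- ca_iv_protocol()
  init <- kndy_initial_state(csp, -80)
  ctl <- simulate_neuron(csp, cproto, init = init)
  trt <- simulate_neuron(apply_drug(csp, "cd"), cproto, init = init)
  d <- peak_iv(drug_subtraction(ctl, trt), mode = "peak")
  ca <- tibble(channel = "Ca_total", probe = "cd", v_mv = -10,
               density_pa_pf = d$density_pa_pf[d$step_mv == -10])
  bind_rows(kv, ca)
}

#' Decompose the repolarizing K+ current during burst firing
#'
#' Simulates spontaneous activity and, at each sample where the net K+
#' current is outward, expresses each K+ channel's current as a percentage of
#' the total outward K+ current. The percentages sum to 100 at every sample.
#'
#' @param params A `neuron_params` object (the estradiol-treated preset
#'   reproduces the burst-repolarization decomposition).
#' @param duration_s Simulated length (s).
#' @return Long tibble: `time_ms`, `channel`, `percent`.
#' @export
repolarization_contributions <- function(params, duration_s = 10) {
  tr <- simulate_neuron(params, spontaneous_protocol(duration_s))
  kcur <- c("i_a", "i_bk", "i_sk", "i_m", "i_girk")
  m <- as.matrix(tr[, kcur])
  m[m < 0] <- 0
  tot <- rowSums(m)
  keep <- tot > 1  # pA; repolarization phases only
  pct <- sweep(m[keep, , drop = FALSE], 1, tot[keep], "/") * 100
  tibble(time_ms = rep(tr$time_ms[keep], times = length(kcur)),
         channel = rep(sub("^i_", "", kcur), each = sum(keep)),
         percent = as.numeric(pct))
}
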