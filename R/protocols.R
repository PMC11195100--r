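#' @importFrom dplyr %>% mutate filter group_by summarise ungroup arrange
#'   bind_rows left_join select slice pull across
NULL

new_segment <- function(duration, mode, label, sweep = 1L, step_mv = NA_real_,
                        cmd = "const", value = 0, rate = 0,
                        nkb_mode = "const", nkb_level = 0,
                        nkb_period = 0, nkb_width = 0,
                        dyn_mode = "const", dyn_level = 0,
                        dyn_period = 0, dyn_width = 0,
                        dt = if (mode == "vc") 1 else 0.5) {
  stopifnot(duration > 0)
  tibble(sweep = as.integer(sweep), label = label, duration = duration,
         mode = mode, cmd = cmd, value = value, rate = rate,
         nkb_mode = nkb_mode, nkb_level = nkb_level,
         nkb_period = nkb_period, nkb_width = nkb_width,
         dyn_mode = dyn_mode, dyn_level = dyn_level,
         dyn_period = dyn_period, dyn_width = dyn_width,
         dt = dt, step_mv = step_mv)
}

new_protocol <- function(segments, name) {
  structure(segments, class = c("stimulus_protocol", class(segments)),
            protocol_name = name)
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("<stimulus_protocol>", attr(x, "protocol_name"),
      "-", nrow(x), "segments,", max(x$sweep), "sweep(s),",
      sum(x$duration) / 1000, "s total\n")
  NextMethod()
}

#' Protocol hash
#'
#' Stable hash of a protocol's segment table, used to assert that two traces
#' were recorded under identical stimulation before they are subtracted.
#'
#' @param protocol A `stimulus_protocol`.
#' @export
protocol_hash <- function(protocol) {
  rlang::hash(as.data.frame(protocol))
}

step_family <- function(hold_mv, steps_mv, step_ms, settle_ms = 5000,
                        prepulse_mv = NULL, prepulse_ms = 0, dt_step = 1) {
  segs <- lapply(seq_along(steps_mv), function(i) {
    v <- steps_mv[[i]]
    out <- list(new_segment(settle_ms, "vc", "hold", sweep = i, step_mv = v,
                            value = hold_mv, dt = 5))
    if (!is.null(prepulse_mv)) {
      out <- c(out, list(new_segment(prepulse_ms, "vc", "prepulse", sweep = i,
                                     step_mv = v, value = prepulse_mv,
                                     dt = dt_step)))
    }
    c(out, list(new_segment(step_ms, "vc", "step", sweep = i, step_mv = v,
                            value = v, dt = dt_step)))
  })
  bind_rows(unlist(segs, recursive = FALSE))
}

#' Calcium-current I-V protocol
#'
#' Voltage-clamp step family for the whole-cell calcium current: 150-ms pulses
#' from a holding potential of -80 mV in 10-mV increments. The upper bound of
#' the step family is configurable; +30 mV by default.
#'
#' @param v_max Most depolarized step (mV).
#' @param settle_ms Inter-sweep settling time at the holding potential (ms);
#'   the default matches the 0.2-Hz pacing used for the K+ protocols.
#' @export
ca_iv_protocol <- function(v_max = 30, settle_ms = 5000) {
  new_protocol(step_family(-80, seq(-80, v_max, by = 10), 150,
                           settle_ms = settle_ms, dt_step = 0.5),
               "ca_iv")
}

#' Potassium-current I-V protocol
#'
#' 500-ms voltage pulses from -60 to +40 mV in 10-mV steps from a holding
#' potential of -70 mV, paced at 0.2 Hz (5-s inter-sweep interval).
#' @param steps_mv Step potentials (mV).
#' @export
k_iv_protocol <- function(steps_mv = seq(-60, 40, by = 10)) {
  new_protocol(step_family(-70, steps_mv, 500, settle_ms = 5000),
               "k_iv")
}

#' M-current deactivation protocol
#'
#' 500-ms voltage steps from -30 down to -75 mV in 5-mV increments, each
#' preceded by a 300-ms prepulse to -20 mV; steps are presented in descending
#' order, as in the standard deactivation protocol.
#' @export
m_current_protocol <- function() {
  new_protocol(step_family(-70, seq(-30, -75, by = -5), 500,
                           settle_ms = 5000,
                           prepulse_mv = -20, prepulse_ms = 300,
                           dt_step = 0.5),
               "m_current")
}

#' Current-ramp protocol
#'
#' Current-clamp ramp from 0 pA at a given rate, used to measure rheobase.
#' A zero rate degenerates to a constant zero-current segment.
#'
#' @param rate_pa_per_s Ramp rate (pA/s).
#' @param max_current_pa Current at which the ramp ends (pA).
#' @param pre_ms Pre-ramp baseline at 0 pA (ms).
#' @export
ramp_protocol <- function(rate_pa_per_s = 50, max_current_pa = 100,
                          pre_ms = 2000) {
  segs <- new_segment(pre_ms, "cc", "baseline")
  if (rate_pa_per_s == 0) {
    segs <- bind_rows(segs, new_segment(2000, "cc", "ramp", value = 0))
  } else {
    dur <- max_current_pa / rate_pa_per_s * 1000
    segs <- bind_rows(segs,
                      new_segment(dur, "cc", "ramp", cmd = "ramp",
                                  value = 0, rate = rate_pa_per_s / 1000))
  }
  new_protocol(segs, "ramp")
}

#' Current-step (F-I) protocol
#'
#' Family of 1-s depolarizing current steps used to build the firing
#' frequency versus injected current curve.
#'
#' @param currents_pa Injected currents (pA), one sweep each.
#' @param duration_ms Step duration (ms).
#' @param pre_ms Baseline before each step (ms).
#' @export
fi_protocol <- function(currents_pa = seq(10, 90, by = 10),
                        duration_ms = 1000, pre_ms = 1000) {
  segs <- lapply(seq_along(currents_pa), function(i) {
    bind_rows(new_segment(pre_ms, "cc", "baseline", sweep = i,
                          step_mv = currents_pa[[i]]),
              new_segment(duration_ms, "cc", "step", sweep = i,
                          value = currents_pa[[i]],
                          step_mv = currents_pa[[i]]))
  })
  new_protocol(bind_rows(segs), "fi_steps")
}

#' Spontaneous-activity protocol
#'
#' Current clamp at zero injected current.
#' @param duration_s Recording length (s).
#' @export
spontaneous_protocol <- function(duration_s = 20) {
  new_protocol(new_segment(duration_s * 1000, "cc", "spontaneous"),
               "spontaneous")
}

#' High-frequency NKB stimulation protocol
#'
#' Current clamp at zero injected current with the NKB receptor drive pulsed
#' at 20 Hz for 10 s (200 pulses), emulating high-frequency stimulation of
#' the KNDy network, followed by a post-train observation window. Dynorphin
#' is co-released with NKB by default and drives GIRK; set `dyn = FALSE` to
#' stimulate the NKB/TRPC5 arm alone.
#'
#' @param n_epochs Number of stimulation epochs (2 for R2/R1 measurements).
#' @param pre_ms Pre-train baseline (ms).
#' @param train_s Train duration (s).
#' @param freq_hz Pulse frequency (Hz).
#' @param pulse_ms Single pulse width (ms).
#' @param post_ms Post-train observation (ms); at least 60 s by default.
#' @param nkb_level,dyn_level Drive amplitudes in `[0, 1]`.
#' @param dyn Logical; co-release dynorphin during the train.
#' @export
nkb_synchronization_protocol <- function(n_epochs = 1, pre_ms = 5000,
                                         train_s = 10, freq_hz = 20,
                                         pulse_ms = 5, post_ms = 60000,
                                         nkb_level = 1, dyn = TRUE,
                                         dyn_level = 1) {
  period <- 1000 / freq_hz
  epoch <- function(i) {
    bind_rows(
      new_segment(pre_ms, "cc", "baseline", sweep = i),
      new_segment(train_s * 1000, "cc", "train", sweep = i,
                  nkb_mode = "train", nkb_level = nkb_level,
                  nkb_period = period, nkb_width = pulse_ms,
                  dyn_mode = if (dyn) "train" else "const",
                  dyn_level = if (dyn) dyn_level else 0,
                  dyn_period = period, dyn_width = pulse_ms),
      new_segment(post_ms, "cc", "post", sweep = i)
    )
  }
  new_protocol(bind_rows(lapply(seq_len(n_epochs), epoch)),
               "nkb_synchronization")
}

#' Constant-drive protocol
#'
#' Current clamp under constant (saturating by default) NKB and Dyn receptor
#' drives, used for the TRPC5/GIRK conductance regime maps.
#'
#' @param duration_s Length (s).
#' @param nkb,dyn Constant drive levels in `[0, 1]`.
#' @export
constant_drive_protocol <- function(duration_s = 20, nkb = 1, dyn = 1) {
  new_protocol(new_segment(duration_s * 1000, "cc", "drive",
                           nkb_mode = "const", nkb_level = nkb,
                           dyn_mode = "const", dyn_level = dyn),
               "constant_drive")
}

# drug -> (channels, fraction); fractions of 1 mean complete block
.kndy_full_blocks <- list(
  apamin      = "SK",
  iberiotoxin = "BK",
  xe991       = "M",
  ttap2       = "T",
  cd          = c("T", "Ca"),
  ttx         = c("NaT", "NaP"),
  cs_internal = c("SK", "BK", "M", "A", "GIRK")
)

# subtype-selective HVA blockers: the model lumps L/N/P/Q/R into one Ca
# conductance, so these block the printed percentage of it, per state
.kndy_hva_fractions <- list(
  ovx    = c(nifedipine = 0.261, conogvia = 0.251, agaiva = 0.039,
             snx = 0.311),
  ovx_e2 = c(nifedipine = 0.249, conogvia = 0.246, agaiva = 0.110,
             snx = 0.270)
)

#' Apply in-silico pharmacology
#'
#' Returns a copy of the parameter set with the block fraction of the drug's
#' target channel(s) set. Apamin (SK), iberiotoxin (BK), XE-991 (M), TTA-P2
#' (T), Cd2+ (T and HVA Ca) and TTX (NaT and NaP) are complete blocks. The
#' HVA-subtype blockers nifedipine (L), omega-conotoxin GVIA (N),
#' omega-agatoxin IVA (P/Q) and SNX-482 (R) remove the fraction of the lumped
#' HVA Ca conductance that the corresponding subtype carries in the preset's
#' state (`custom` parameter sets use the ovx fractions).
#'
#' @param params A `neuron_params` object (not modified).
#' @param drug One of `"none"`, `"apamin"`, `"iberiotoxin"`, `"xe991"`,
#'   `"ttap2"`, `"cd"`, `"ttx"`, `"nifedipine"`, `"conogvia"`, `"agaiva"`,
#'   `"snx"`, or `"cs_internal"` (the cesium/TEA pipette solution used for
#'   calcium-current isolation: blocks all K+ channels).
#' @return A new `neuron_params` object with block fractions set.
#' @examples
#' apply_drug(kndy_params("ovx"), "apamin")$channels$SK$block
#' @export
apply_drug <- function(params, drug) {
  validate_neuron_params(params)
  drug <- tolower(drug)
  if (drug == "none") return(params)
  if (drug %in% names(.kndy_full_blocks)) {
    for (nm in .kndy_full_blocks[[drug]]) params$channels[[nm]]$block <- 1
    return(params)
  }
  state <- if (params$state_label %in% names(.kndy_hva_fractions)) {
    params$state_label
  } else {
    "ovx"
  }
  fr <- .kndy_hva_fractions[[state]]
  if (drug %in% names(fr)) {
    params$channels$Ca$block <-
      min(1, params$channels$Ca$block + unname(fr[[drug]]))
    return(params)
  }
  abort(paste0("unknown drug: '", drug, "'; known drugs: none, ",
               paste(c(names(.kndy_full_blocks), names(fr)),
                     collapse = ", ")))
}
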