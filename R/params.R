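#' @importFrom tibble tibble as_tibble
#' @importFrom rlang %||% abort
NULL

# channel order; must match the compiled right-hand side
.kndy_channels <- c("NaT", "NaP", "A", "BK", "h", "SK", "M", "T", "Ca",
                    "TRPC5", "GIRK", "leak")

# kinetic constants per channel, in compiled-slot order (k1..k7)
.kndy_kin_slots <- list(
  NaT   = c("vh_m", "k_m", "vh_h", "k_h", "tau_h_base", "tau_h_amp"),
  NaP   = c("vh", "k"),
  A     = c("vh_a", "k_a", "vh_b", "k_b", "tau_b"),
  BK    = c("vh", "k", "k_ca"),
  h     = c("vh", "k", "tau"),
  SK    = c("k_ca", "hill", "tau"),
  M     = c("vh", "k", "tau"),
  T     = c("vh_m", "k_m", "vh_h", "k_h", "tau_m", "tau_h", "tau_h_floor"),
  Ca    = c("vh_m", "k_m", "vh_h", "k_h", "tau_m", "tau_h", "h_floor"),
  TRPC5 = c("k_ca", "tau", "ca_flux_frac", "des_max", "tau_des"),
  GIRK  = c("a0", "vh_rect", "k_rect", "pip2_frac"),
  leak  = character(0)
)

# shared (state-independent) channel definitions
.kndy_base_channels <- function() {
  list(
    NaT = list(gbar = 550, erev = 50, block = 0,
               kin = list(vh_m = -34, k_m = 5, vh_h = -48, k_h = 7,
                          tau_h_base = 0.6, tau_h_amp = 8)),
    NaP = list(gbar = 0.3, erev = 50, block = 0,
               kin = list(vh = -52, k = 5)),
    A = list(gbar = 25, erev = -90, block = 0,
             kin = list(vh_a = -35, k_a = 9, vh_b = -68, k_b = 6,
                        tau_b = 80)),
    BK = list(gbar = 7.64, erev = -90, block = 0,
              kin = list(vh = -5, k = 11, k_ca = 0.2185)),
    h = list(gbar = 0.35, erev = -30, block = 0,
             kin = list(vh = -78, k = 6, tau = 800)),
    SK = list(gbar = 28.1, erev = -90, block = 0,
              kin = list(k_ca = 0.3, hill = 4, tau = 25)),
    M = list(gbar = 0.5, erev = -90, block = 0,
             kin = list(vh = -35, k = 10, tau = 120)),
    T = list(gbar = 0.66, erev = 100, block = 0,
             kin = list(vh_m = -56, k_m = 6.2, vh_h = -70, k_h = 5.5,
                        tau_m = 8, tau_h = 400, tau_h_floor = 0.03)),
    Ca = list(gbar = 2.1, erev = 100, block = 0,
              kin = list(vh_m = -32.3, k_m = 8.5, vh_h = -48.9, k_h = 6.3,
                         tau_m = 5.5, tau_h = 25, h_floor = 0.8)),
    TRPC5 = list(gbar = 2.0, erev = -7, block = 0,
                 kin = list(k_ca = 0.5, tau = 150, ca_flux_frac = 0.15,
                            des_max = 0.55, tau_des = 12000)),
    GIRK = list(gbar = 1.2, erev = -90, block = 0,
                kin = list(a0 = 0.05, vh_rect = -30, k_rect = 20, pip2_frac = 0.85)),
    leak = list(gbar = 1.3, erev = -70, block = 0, kin = list())
  )
}

# conductances that differ between the two physiological states (nS)
.kndy_state_gbar <- list(
  ovx    = c(Ca = 2.1, T = 0.66, h = 0.35, TRPC5 = 2.0, GIRK = 1.2,
             BK = 7.64, M = 0.5),
  ovx_e2 = c(Ca = 2.8, T = 5.0, h = 2.0, TRPC5 = 0.68, GIRK = 0.4,
             BK = 20.0, M = 2.0)
)

#' Neuron parameter set
#'
#' Builds the full parameter set of the 12-current KNDy neuron model:
#' membrane capacitance, the per-channel conductances, reversal potentials and
#' gating constants, the two-pool calcium handling, and the NKB/Dyn receptor
#' kinetics. Two presets are available: `"ovx"` (ovariectomized, low-estradiol
#' state) and `"ovx_e2"` (ovariectomized with a positive-feedback estradiol
#' regimen). The presets share all gating kinetics and differ only in the
#' conductances the physiology documents as estradiol-sensitive (HVA Ca,
#' T-type, h, TRPC5, GIRK, BK, M).
#'
#' @param state `"ovx"`, `"ovx_e2"`, or `"custom"`.
#' @param gbar Named numeric vector of conductance overrides (nS), e.g.
#'   `c(TRPC5 = 1.0)`.
#' @param cm Membrane capacitance (pF).
#' @param block Named numeric vector of pharmacological block fractions in
#'   `[0, 1]` per channel (normally set via [apply_drug()]).
#' @return An object of class `neuron_params`.
#' @examples
#' p <- kndy_params("ovx_e2")
#' p$channels$Ca$gbar
#' @export
kndy_params <- function(state = c("ovx", "ovx_e2", "custom"),
                        gbar = NULL, cm = 20, block = NULL) {
  state <- match.arg(state)
  ch <- .kndy_base_channels()
  if (state %in% names(.kndy_state_gbar)) {
    sg <- .kndy_state_gbar[[state]]
    for (nm in names(sg)) ch[[nm]]$gbar <- unname(sg[[nm]])
  }
  if (!is.null(gbar)) {
    bad <- setdiff(names(gbar), names(ch))
    if (length(bad)) abort(paste0("unknown channel(s): ",
                                  paste(bad, collapse = ", ")))
    for (nm in names(gbar)) ch[[nm]]$gbar <- unname(gbar[[nm]])
  }
  if (!is.null(block)) {
    bad <- setdiff(names(block), names(ch))
    if (length(bad)) abort(paste0("unknown channel(s): ",
                                  paste(bad, collapse = ", ")))
    for (nm in names(block)) ch[[nm]]$block <- unname(block[[nm]])
  }
  out <- structure(list(
    cm = cm,
    state_label = state,
    channels = ch,
    calcium = list(kd = 4.33e-5, tau_d = 120, kb = 2.2e-6, tau_b = 2000,
                   ca0 = 0.1, ca0_d = 0.02, k_cdi = 0.2),
    drive = list(tau_nkb_on = 100, tau_nkb_off = 8000,
                 tau_dyn_on = 500, tau_dyn_off = 8000)
  ), class = "neuron_params")
  validate_neuron_params(out)
  out
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params> state:", x$state_label, " Cm:", x$cm, "pF\n")
  g <- vapply(x$channels, function(ch) ch$gbar, numeric(1))
  b <- vapply(x$channels, function(ch) ch$block, numeric(1))
  df <- data.frame(channel = names(g), gbar_nS = unname(g),
                   block = unname(b))
  print(df, row.names = FALSE)
  invisible(x)
}

validate_neuron_params <- function(p) {
  stopifnot(inherits(p, "neuron_params"))
  if (!is.numeric(p$cm) || p$cm <= 0) abort("Cm must be positive")
  if (!identical(sort(names(p$channels)), sort(.kndy_channels)) ||
      length(p$channels) != 12L) {
    abort("parameter set must contain exactly the 12 named channel blocks")
  }
  for (nm in names(p$channels)) {
    ch <- p$channels[[nm]]
    if (ch$gbar < 0) abort(paste0(nm, ": gbar must be >= 0"))
    if (ch$block < 0 || ch$block > 1) {
      abort(paste0(nm, ": block fraction must lie in [0, 1]"))
    }
  }
  invisible(p)
}

# flatten a neuron_params object into the compiled parameter vector,
# with the segment descriptor in the global slots
params_vector <- function(p, mode = 0, cmd_kind = 0, cmd_value = 0,
                          cmd_rate = 0, t0 = 0,
                          nkb_mode = 0, nkb_level = 0, nkb_period = 0,
                          nkb_width = 0,
                          dyn_mode = 0, dyn_level = 0, dyn_period = 0,
                          dyn_width = 0) {
  vec <- numeric(145)
  vec[1:14] <- c(p$cm, mode, cmd_kind, cmd_value, cmd_rate, t0,
                 nkb_mode, nkb_level, nkb_period, nkb_width,
                 dyn_mode, dyn_level, dyn_period, dyn_width)
  for (i in seq_along(.kndy_channels)) {
    nm <- .kndy_channels[[i]]
    ch <- p$channels[[nm]]
    base <- 14 + 10 * (i - 1)
    vec[base + 1] <- ch$gbar
    vec[base + 2] <- ch$block
    vec[base + 3] <- ch$erev
    slots <- .kndy_kin_slots[[nm]]
    if (length(slots)) {
      vec[base + 3 + seq_along(slots)] <-
        vapply(slots, function(s) ch$kin[[s]], numeric(1))
    }
  }
  ca <- p$calcium
  dr <- p$drive
  vec[135:144] <- c(ca$kd, ca$tau_d, ca$kb, ca$tau_b, ca$ca0, ca$k_cdi,
                    dr$tau_nkb_on, dr$tau_nkb_off,
                    dr$tau_dyn_on, dr$tau_dyn_off)
  vec[145] <- ca$ca0_d
  vec
}

#' Write a neuron parameter set to a YAML config file
#'
#' The file is a human-editable key/value hierarchy mirroring the parameter
#' object; [read_neuron_params()] restores it. The installed package ships
#' `ovx.yaml` and `ovx_e2.yaml` under `presets/` (see
#' `system.file("presets", package = "kndysim")`).
#'
#' @param params A `neuron_params` object.
#' @param path Output file path.
#' @export
write_neuron_params <- function(params, path) {
  validate_neuron_params(params)
  x <- unclass(params)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_neuron_params
#' @export
read_neuron_params <- function(path) {
  x <- yaml::read_yaml(path)
  out <- structure(x, class = "neuron_params")
  # yaml drops empty lists; restore leak's empty kinetics block
  for (nm in names(out$channels)) {
    out$channels[[nm]]$kin <- out$channels[[nm]]$kin %||% list()
  }
  validate_neuron_params(out)
  out
}

#' Initial neuron state
#'
#' State-variable vector at a given membrane potential with every gating
#' variable at its voltage steady state and both calcium pools at rest.
#'
#' @param params A `neuron_params` object.
#' @param vm Membrane potential (mV).
#' @return Named numeric vector of the 16 state variables.
#' @export
kndy_initial_state <- function(params, vm = -70) {
  k <- function(nm) params$channels[[nm]]$kin
  ca0 <- params$calcium$ca0
  ca0d <- params$calcium$ca0_d
  ksk <- k("SK")$k_ca
  s0 <- ca0d^4 / (ca0d^4 + ksk^4)
  kt5 <- k("TRPC5")$k_ca
  cca <- ca0^2 / (ca0^2 + kt5^2)
  hfl <- k("Ca")$h_floor
  dmax <- k("TRPC5")$des_max
  c(v    = vm,
    h_na = gating_steady_state(vm, k("NaT")$vh_h, k("NaT")$k_h, "inactivation"),
    b_a  = gating_steady_state(vm, k("A")$vh_b, k("A")$k_b, "inactivation"),
    m_ca = gating_steady_state(vm, k("Ca")$vh_m, k("Ca")$k_m),
    h_ca = hfl + (1 - hfl) *
           gating_steady_state(vm, k("Ca")$vh_h, k("Ca")$k_h, "inactivation"),
    m_t  = gating_steady_state(vm, k("T")$vh_m, k("T")$k_m),
    h_t  = gating_steady_state(vm, k("T")$vh_h, k("T")$k_h, "inactivation"),
    s    = s0,
    m_m  = gating_steady_state(vm, k("M")$vh, k("M")$k),
    r    = gating_steady_state(vm, k("h")$vh, k("h")$k, "inactivation"),
    c    = cca,
    a_n  = 0,
    a_d  = 0,
    ca_d = ca0d,
    ca_b = ca0,
    dtr  = dmax * cca)
}
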