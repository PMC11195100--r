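#' Current-voltage relationship from a voltage-clamp step family
#'
#' Reduces a step-family trace to one current per step potential. The holding
#' (baseline) current, measured over the final 50 ms before each step, is
#' subtracted. In `"peak"` mode the extremum by absolute value of the
#' baseline-subtracted current within the step is taken (inward currents are
#' negative); in `"steady"` mode the mean over the final 5% of the step.
#'
#' @param trace A `sim_trace` from a voltage-clamp step protocol.
#' @param mode `"peak"` or `"steady"`.
#' @param cm Capacitance used for the density column (pF); defaults to the
#'   simulated cell's.
#' @return An `iv_curve` tibble: `step_mv`, `current_pa`, `density_pa_pf`,
#'   `cm_used`, `mode`.
#' @export
peak_iv <- function(trace, mode = c("peak", "steady"), cm = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(trace))
  if (!all(c("hold", "step") %in% trace$label)) {
    abort("trace does not contain hold/step segments of a step family")
  }
  cm <- cm %||% attr(trace, "params")$cm
  if (is.null(cm)) abort("no capacitance available; pass `cm`")
  base <- trace %>%
    filter(.data$label == "hold") %>%
    group_by(.data$sweep) %>%
    summarise(baseline = mean(
      .data$i_clamp[.data$seg_time_ms >= max(.data$seg_time_ms) - 50]),
      .groups = "drop")
  steps <- trace %>%
    filter(.data$label == "step") %>%
    left_join(base, by = "sweep") %>%
    group_by(.data$sweep, .data$step_mv)
  out <- if (mode == "peak") {
    steps %>% summarise(current_pa = {
      d <- .data$i_clamp - .data$baseline
      d[which.max(abs(d))]
    }, .groups = "drop")
  } else {
    steps %>% summarise(current_pa = {
      keep <- .data$seg_time_ms >= 0.95 * max(.data$seg_time_ms)
      mean(.data$i_clamp[keep] - .data$baseline[keep])
    }, .groups = "drop")
  }
  out <- out %>%
    arrange(.data$step_mv) %>%
    mutate(density_pa_pf = .data$current_pa / cm, cm_used = cm, mode = mode) %>%
    select(-"sweep")
  structure(out, class = c("iv_curve", class(out)))
}

#' Normalized activation curve from an I-V relationship
#'
#' Converts currents to chord conductances `G = I / (V - E_rev)` and
#' normalizes by the maximum, the standard transformation before an
#' activation Boltzmann fit.
#'
#' @param iv An `iv_curve` (or tibble with `step_mv` and `current_pa`).
#' @param erev Reversal potential of the underlying current (mV).
#' @param v_range Optional voltage window to keep (e.g. up to the I-V peak).
#' @return Tibble with `v` and normalized `y`.
#' @export
activation_curve <- function(iv, erev, v_range = NULL) {
  df <- tibble(v = iv$step_mv,
               g = iv$current_pa / (iv$step_mv - erev))
  if (!is.null(v_range)) df <- filter(df, .data$v >= v_range[1],
                                      .data$v <= v_range[2])
  tibble(v = df$v, y = df$g / max(df$g))
}

#' Fit a Boltzmann activation or inactivation curve
#'
#' Least-squares fit of the two-parameter Boltzmann sigmoid to normalized
#' current (or conductance) data. For activation,
#' `y = ymax / (1 + exp((v_half - v) / k))`; for inactivation the argument
#' sign flips so that `y` decreases with `v`. Under
#' `convention = "one_minus"` the inactivation branch is fitted as
#' `y = ymax * (1 - 1 / (1 + exp((v - v_half) / k)))`, the complementary
#' parameterization some papers print; both conventions describe the same
#' family and return `k > 0`.
#'
#' @param data Data frame with columns `v` (mV) and `y` (normalized, I/Imax).
#' @param kind `"activation"` or `"inactivation"`.
#' @param convention `"standard"` or `"one_minus"` (inactivation only).
#' @param start Optional named list of start values (`v_half`, `k`, `ymax`).
#' @param fix_ymax Fit with `ymax` fixed at 1 instead of free.
#' @return A `boltzmann_fit` object with elements `v_half`, `k`, `ymax`,
#'   `kind`, `rss`, `fitted`, `data`; see [tidy.boltzmann_fit()].
#' @export
fit_boltzmann <- function(data, kind = c("activation", "inactivation"),
                          convention = c("standard", "one_minus"),
                          start = NULL, fix_ymax = FALSE) {
  kind <- match.arg(kind)
  convention <- match.arg(convention)
  stopifnot(all(c("v", "y") %in% names(data)))
  data <- as.data.frame(data)[stats::complete.cases(data[, c("v", "y")]), ]
  if (nrow(data) < 4) abort("need at least 4 points to fit a Boltzmann")
  mid <- data$v[which.min(abs(data$y - max(data$y) / 2))]
  if (mid <= min(data$v) || mid >= max(data$v)) {
    abort("data must span both sides of the midpoint")
  }
  rho <- suppressWarnings(
    stats::cor(data$v, data$y, method = "spearman"))
  expected <- if (kind == "activation") 1 else -1
  if (is.finite(rho) && sign(rho) != expected) {
    warning("data trend is opposite to the requested kind; check `kind`",
            call. = FALSE)
  } else if (is.finite(rho) && abs(rho) < 0.8) {
    warning("data are strongly non-monotone; fit quality is suspect",
            call. = FALSE)
  }

  one_minus <- kind == "inactivation" && convention == "one_minus"
  sgn <- if (kind == "activation") 1 else -1
  form <- if (one_minus) {
    # the complementary printed form, 1 - 1/(1 + exp((v - v_half)/k));
    # it matches decreasing data with a negative slope factor
    if (fix_ymax) y ~ 1 - 1 / (1 + exp((v - v_half) / k))
    else          y ~ ymax * (1 - 1 / (1 + exp((v - v_half) / k)))
  } else if (fix_ymax) {
    y ~ 1 / (1 + exp(sgn * (v_half - v) / k))
  } else {
    y ~ ymax / (1 + exp(sgn * (v_half - v) / k))
  }
  st <- list(v_half = start$v_half %||% mid,
             k = start$k %||% (if (one_minus) -6 else 6))
  if (!fix_ymax) st$ymax <- start$ymax %||% max(data$y)
  do_fit <- function(start) {
    minpack.lm::nlsLM(form, data = data, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fit <- tryCatch(do_fit(st), error = function(e) {
    st$k <- -st$k   # retry with the opposite slope sign
    do_fit(st)
  })
  cf <- stats::coef(fit)
  k_hat <- if (one_minus) unname(cf[["k"]]) else abs(unname(cf[["k"]]))
  structure(list(
    v_half = unname(cf[["v_half"]]),
    k = k_hat,
    ymax = if (fix_ymax) 1 else unname(cf[["ymax"]]),
    kind = kind,
    convention = convention,
    rss = sum(stats::residuals(fit)^2),
    n = nrow(data),
    fitted = stats::fitted(fit),
    data = tibble(v = data$v, y = data$y)
  ), class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> %s: V1/2 = %.2f mV, k = %.2f mV, ymax = %.3f (rss %.2e, n %d)\n",
              x$kind, x$v_half, x$k, x$ymax, x$rss, x$n))
  invisible(x)
}

#' Drug-subtraction current isolation
#'
#' Pointwise difference `control - treated` of two traces (or I-V curves)
#' recorded under identical protocols, the standard way a drug-sensitive
#' current is isolated. For model traces with a full block of one channel the
#' result equals the model's own stored per-current decomposition of that
#' channel, which the tests use as an oracle.
#'
#' @param control,treated Two `sim_trace`s (same protocol) or two
#'   `iv_curve`s (same steps).
#' @return Object of the same type containing the difference.
#' @export
drug_subtraction <- function(control, treated) {
  if (inherits(control, "iv_curve") || !("time_ms" %in% names(control))) {
    stopifnot(identical(control$step_mv, treated$step_mv))
    out <- control
    out$current_pa <- control$current_pa - treated$current_pa
    out$density_pa_pf <- control$density_pa_pf - treated$density_pa_pf
    return(out)
  }
  h1 <- attr(control, "protocol_hash")
  h2 <- attr(treated, "protocol_hash")
  if (!is.null(h1) && !is.null(h2) && !identical(h1, h2)) {
    abort("traces were recorded under different protocols")
  }
  if (nrow(control) != nrow(treated) ||
      max(abs(control$time_ms - treated$time_ms)) > 1e-9) {
    abort("traces are not sampled on the same time grid")
  }
  out <- control
  num <- intersect(c("vm", "i_clamp", "i_inj", .kndy_current_names, "i_net",
                     "ca_d", "ca_b"), names(control))
  for (cn in num) out[[cn]] <- control[[cn]] - treated[[cn]]
  out
}

#' M-current deactivation amplitude
#'
#' Per deactivation step, the difference between the initial current (mean
#' over the first 10 ms of the step) and the sustained current (mean over
#' 475-500 ms), the standard quantification of the slowly deactivating
#' KCNQ-mediated relaxation.
#'
#' @param trace A `sim_trace` from [m_current_protocol()] (or any step family
#'   with steps of at least 500 ms).
#' @return Tibble with `step_mv` and `amplitude_pa`.
#' @export
m_current_amplitude <- function(trace) {
  steps <- trace %>% filter(.data$label == "step")
  if (!nrow(steps)) abort("trace contains no step segments")
  if (max(steps$seg_time_ms) < 500) {
    abort("steps are shorter than the 500 ms the measurement requires")
  }
  steps %>%
    group_by(.data$sweep, .data$step_mv) %>%
    summarise(amplitude_pa =
                mean(.data$i_clamp[.data$seg_time_ms > 0 &
                                     .data$seg_time_ms <= 10]) -
                mean(.data$i_clamp[.data$seg_time_ms >= 475 &
                                     .data$seg_time_ms <= 500]),
              .groups = "drop") %>%
    arrange(.data$step_mv) %>%
    select("step_mv", "amplitude_pa")
}

lowpass_vm <- function(vm, dt_ms, cutoff_hz, order = 4) {
  fs <- 1000 / dt_ms
  wn <- cutoff_hz / (fs / 2)
  if (wn >= 1) return(vm)
  bf <- signal::butter(order / 2, wn)  # filtfilt doubles the order
  # mean-center and reflect-pad so the zero-phase filter has no edge
  # transient on finite traces
  mu <- mean(vm)
  npad <- min(length(vm) - 1, ceiling(2 * fs / cutoff_hz))
  x <- c(rev(vm[seq_len(npad)]), vm, rev(vm[length(vm) - seq_len(npad) + 1]))
  f <- as.numeric(signal::filtfilt(bf, x - mu)) + mu
  f[npad + seq_along(vm)]
}

#' Slow-EPSP amplitude metrics
#'
#' Low-pass filters the membrane potential (zero-phase Butterworth, 2 Hz by
#' default), then measures the post-train depolarization for each stimulation
#' epoch as the peak of the filtered trace within the 30 s after train onset
#' minus the mean over the 5 s before it. With two epochs the ratio
#' `R2 / R1` is reported; an undetectable `R1` makes the ratio `NA`.
#'
#' @param trace A `sim_trace` containing `train`-labelled epochs (see
#'   [nkb_synchronization_protocol()]).
#' @param cutoff_hz Low-pass cutoff (Hz).
#' @param min_r1 Detectability floor for `R1` (mV).
#' @return Tibble with one row: `r1_mv`, `r2_mv` (NA if single epoch),
#'   `ratio`, `cutoff_hz`.
#' @export
slow_epsp_metrics <- function(trace, cutoff_hz = 2, min_r1 = 0.5) {
  if (!"train" %in% trace$label) abort("trace contains no stimulation epoch")
  dt <- stats::median(diff(trace$time_ms))
  f <- lowpass_vm(trace$vm, dt, cutoff_hz)
  epochs <- trace %>%
    mutate(.f = f) %>%
    filter(.data$label == "train") %>%
    group_by(.data$sweep) %>%
    summarise(t_on = min(.data$time_ms), t_off = max(.data$time_ms),
              .groups = "drop")
  amp <- vapply(seq_len(nrow(epochs)), function(i) {
    t_on <- epochs$t_on[i]; t_off <- epochs$t_off[i]
    pre <- f[trace$time_ms >= t_on - 5000 & trace$time_ms < t_on]
    post <- f[trace$time_ms > t_off &
                trace$time_ms <= t_off + 30000]
    if (!length(pre) || !length(post)) return(NA_real_)
    max(post) - mean(pre)
  }, numeric(1))
  r1 <- amp[1]
  r2 <- if (length(amp) >= 2) amp[2] else NA_real_
  ratio <- if (!is.na(r1) && r1 >= min_r1 && !is.na(r2)) r2 / r1 else NA_real_
  tibble(r1_mv = r1, r2_mv = r2, ratio = ratio, cutoff_hz = cutoff_hz)
}

#' Spike detection
#'
#' Upward threshold crossings of the membrane potential with a refractory
#' period.
#'
#' @param trace A `sim_trace` (current-clamp), or any tibble with `time_ms`
#'   and `vm`.
#' @param threshold_mv Crossing threshold (mV).
#' @param refractory_ms Minimum separation between detected spikes (ms).
#' @return Numeric vector of spike times (ms).
#' @export
detect_spikes <- function(trace, threshold_mv = -20, refractory_ms = 2) {
  v <- trace$vm
  t <- trace$time_ms
  idx <- which(v[-1] >= threshold_mv & v[-length(v)] < threshold_mv) + 1L
  if (!length(idx)) return(numeric(0))
  st <- t[idx]
  keep <- c(TRUE, diff(st) > refractory_ms)
  while (!all(keep)) {
    st <- st[keep]
    keep <- c(TRUE, diff(st) > refractory_ms)
  }
  st
}

#' Rheobase from a current-ramp trace
#'
#' The injected current at the moment of the first spike on the ramp; a trace
#' with no spike returns `NA` (not reached).
#'
#' @param trace A `sim_trace` from [ramp_protocol()].
#' @param ... Passed to [detect_spikes()].
#' @return Tibble with `rheobase_pa` and `t_first_spike_ms`.
#' @export
rheobase <- function(trace, ...) {
  ramp <- trace %>% filter(.data$label == "ramp")
  if (!nrow(ramp)) abort("trace contains no ramp segment")
  sp <- detect_spikes(ramp, ...)
  if (!length(sp)) {
    return(tibble(rheobase_pa = NA_real_, t_first_spike_ms = NA_real_))
  }
  i_at <- stats::approx(ramp$time_ms, ramp$i_inj, xout = sp[1])$y
  tibble(rheobase_pa = i_at, t_first_spike_ms = sp[1])
}

#' Firing frequency versus injected current (F-I) curve
#'
#' Spike rate during each current step of a step-family trace.
#'
#' @param trace A `sim_trace` from [fi_protocol()].
#' @param ... Passed to [detect_spikes()].
#' @return Tibble with `current_pa` and `rate_hz`.
#' @export
fi_curve <- function(trace, ...) {
  steps <- trace %>% filter(.data$label == "step")
  if (!nrow(steps)) abort("trace contains no current steps")
  out <- lapply(split(steps, steps$sweep), function(s) {
    dur_s <- (max(s$seg_time_ms) - min(s$seg_time_ms)) / 1000
    tibble(current_pa = s$step_mv[1],
           rate_hz = length(detect_spikes(s, ...)) / dur_s)
  })
  arrange(bind_rows(out), .data$current_pa)
}

#' Default firing-classification constants
#'
#' The taxonomy thresholds: spike threshold and refractory period, the
#' burst grouping rules (intra-burst inter-spike interval, minimum quiescence
#' between bursts), the minimum rate below which a cell is silent, the
#' ISI coefficient-of-variation split between tonic and irregular, and the
#' up/down-state bimodality criterion (two-mode separation of the low-pass
#' filtered membrane potential).
#'
#' @return Named list of constants.
#' @export
classify_config <- function() {
  list(spike_threshold_mv = -20,
       refractory_ms = 2,
       silent_rate_hz = 0.1,
       intra_burst_isi_ms = 80,
       inter_burst_gap_ms = 300,
       min_spikes_per_burst = 2,
       burst_fraction = 0.5,
       cv_split = 0.5,
       bimodal_sep_mv = 10,
       bimodal_min_weight = 0.05,
       bimodal_cutoff_hz = 10)
}

#' Classify the firing pattern of a trace
#'
#' Deterministic rule cascade over spike and membrane-potential features,
#' yielding exactly one of five labels: `silent` (rate below the silent
#' threshold), `phasic_burst` (bursting with clear up/down membrane states),
#' `irregular_burst` (bursting without bimodality), `tonic` (regular firing,
#' ISI CV below the split) or `irregular`. Bursts are runs of at least two
#' spikes with intra-burst ISIs up to 80 ms, separated by at least 300 ms of
#' quiescence; a cell is bursting when at least half its spikes fall in
#' bursts. Up/down bimodality is detected on the low-pass filtered potential
#' as two occupancy modes separated by at least 10 mV.
#'
#' @param trace A current-clamp `sim_trace`, at least 10 s long.
#' @param config Constants from [classify_config()].
#' @return A `firing_class` tibble (one row): `label` plus the features it
#'   was derived from.
#' @export
classify_firing <- function(trace, config = classify_config()) {
  dur_s <- (max(trace$time_ms) - min(trace$time_ms)) / 1000
  if (dur_s < 10) abort("need at least 10 s of activity to classify")
  sp <- detect_spikes(trace, config$spike_threshold_mv, config$refractory_ms)
  n <- length(sp)
  rate <- n / dur_s
  isi <- diff(sp)
  cv <- if (length(isi) >= 2) stats::sd(isi) / mean(isi) else NA_real_

  # burst grouping
  burst_count <- 0L
  frac_in_burst <- 0
  intra_rate <- NA_real_
  if (n >= 2) {
    grp <- cumsum(c(1, diff(sp) > config$intra_burst_isi_ms))
    sizes <- tabulate(grp)
    starts <- sp[!duplicated(grp)]
    ends <- sp[rev(!duplicated(rev(grp)))]
    ok_gap <- c(TRUE, starts[-1] - ends[-length(ends)] >=
                  config$inter_burst_gap_ms)
    is_burst <- sizes >= config$min_spikes_per_burst & ok_gap
    burst_count <- sum(is_burst)
    frac_in_burst <- sum(sizes[is_burst]) / n
    if (burst_count > 0) {
      bi <- which(is_burst & sizes >= 2)
      if (length(bi)) {
        intra <- unlist(lapply(bi, function(g) diff(sp[grp == g])))
        intra_rate <- 1000 / mean(intra)
      }
    }
  }

  # up/down-state bimodality on the low-pass filtered potential
  dt <- stats::median(diff(trace$time_ms))
  f <- lowpass_vm(trace$vm, dt, config$bimodal_cutoff_hz)
  if (diff(range(f)) < 1e-6) {
    sep <- 0
    wmin <- 0
  } else {
    km <- stats::kmeans(f, centers = matrix(range(f)), iter.max = 50)
    sep <- abs(diff(km$centers[, 1]))
    wmin <- min(km$size) / length(f)
  }
  bimodal <- sep >= config$bimodal_sep_mv &&
    wmin >= config$bimodal_min_weight

  label <- if (rate < config$silent_rate_hz) {
    "silent"
  } else if (burst_count >= 2 && frac_in_burst >= config$burst_fraction) {
    if (bimodal) "phasic_burst" else "irregular_burst"
  } else if (!is.na(cv) && cv < config$cv_split) {
    "tonic"
  } else {
    "irregular"
  }
  out <- tibble(label = label, n_spikes = n, rate_hz = rate, isi_cv = cv,
                burst_count = burst_count, frac_in_burst = frac_in_burst,
                intra_burst_rate_hz = intra_rate,
                updown_separation_mv = as.numeric(sep), bimodal = bimodal)
  structure(out, class = c("firing_class", class(out)))
}

#' Two-parameter conductance regime map
#'
#' Simulates and classifies the model over a rectangular grid of two
#' conductances (e.g. TRPC5 against GIRK under saturating NKB/Dyn drive) and
#' labels every grid point with its firing class. Integration failures at a
#' grid point are recorded as label `"failed"` rather than aborting the map.
#'
#' @param base A `neuron_params` object providing every other parameter.
#' @param axis1,axis2 Named lists `list(channel =, values =)` giving the grid.
#' @param protocol Stimulus applied at every grid point (fixed across the
#'   map); [constant_drive_protocol()] reproduces the saturating-signal maps.
#' @param summarise_burst Collapse `phasic_burst`/`irregular_burst` to
#'   `"burst"` and everything above the silent threshold to `"firing"` in the
#'   extra `activity` column.
#' @param ... Passed to [simulate_neuron()].
#' @return A `regime_map` tibble: `g1`, `g2`, `label`, `activity`, `rate_hz`.
#' @export
regime_map <- function(base, axis1, axis2,
                       protocol = constant_drive_protocol(15),
                       summarise_burst = TRUE, ...) {
  stopifnot(length(axis1$values) >= 1, length(axis2$values) >= 1)
  grid <- tidyr::expand_grid(g1 = axis1$values, g2 = axis2$values)
  res <- purrr::pmap_dfr(grid, function(g1, g2) {
    p <- base
    p$channels[[axis1$channel]]$gbar <- g1
    p$channels[[axis2$channel]]$gbar <- g2
    out <- tryCatch({
      tr <- simulate_neuron(p, protocol, ...)
      cl <- classify_firing(tr)
      tibble(g1 = g1, g2 = g2, label = cl$label, rate_hz = cl$rate_hz)
    }, error = function(e) {
      tibble(g1 = g1, g2 = g2, label = "failed", rate_hz = NA_real_)
    })
    out
  })
  res$activity <- dplyr::case_when(
    res$label %in% c("phasic_burst", "irregular_burst") ~ "burst",
    res$label == "silent" ~ "silent",
    res$label == "failed" ~ "failed",
    TRUE ~ "firing"
  )
  attr(res, "axes") <- list(axis1 = axis1, axis2 = axis2)
  structure(res, class = c("regime_map", class(res)))
}

#' @importFrom rlang .data
NULL
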