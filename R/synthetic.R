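#' Synthetic multi-cell voltage-clamp dataset
#'
#' Generates per-cell current-density curves with the statistical structure
#' of a patch-clamp cohort: a group mean density curve, a Gaussian
#' between-cell offset, and Gaussian within-curve noise. Group summaries
#' (mean +/- SEM over cells) converge to the specification as the number of
#' cells grows. All randomness is controlled by `seed`.
#'
#' @param group_spec Data frame with columns `group`, `v`, `mean_density`
#'   (pA/pF); one row per group x voltage.
#' @param n_cells Named vector (or single number) of cells per group.
#' @param between_sd Between-cell SD of the per-cell offset (pA/pF); a
#'   cohort printed as mean +/- SEM over n cells has `between_sd =
#'   sem * sqrt(n)`.
#' @param within_sd Within-curve measurement noise SD (pA/pF).
#' @param seed Integer seed (required: datasets are reproducible by
#'   construction).
#' @return Tibble: `group`, `cell`, `v`, `density`.
#' @export
generate_vclamp_cells <- function(group_spec, n_cells, between_sd,
                                  within_sd = 0.5, seed) {
  stopifnot(all(c("group", "v", "mean_density") %in% names(group_spec)),
            between_sd > 0, within_sd >= 0)
  groups <- unique(group_spec$group)
  if (length(n_cells) == 1 && is.null(names(n_cells))) {
    n_cells <- stats::setNames(rep(n_cells, length(groups)), groups)
  }
  if (any(n_cells < 2)) abort("need at least 2 cells per group")
  withr::local_seed(seed)
  purrr::map_dfr(groups, function(gr) {
    spec <- group_spec[group_spec$group == gr, ]
    n <- n_cells[[gr]]
    offs <- stats::rnorm(n, 0, between_sd)
    purrr::map_dfr(seq_len(n), function(i) {
      tibble(group = gr, cell = paste0(gr, "_", i), v = spec$v,
             density = spec$mean_density + offs[i] +
               stats::rnorm(nrow(spec), 0, within_sd))
    })
  })
}

#' Synthetic spike-train membrane-potential trace
#'
#' Builds a membrane-potential trace whose firing pattern is known by
#' construction, for validating the firing classifier: `tonic` (gamma ISIs at
#' a given rate and CV), `irregular` (high-CV ISIs), `burst` (bursts of
#' spikes riding on depolarized up-states separated by quiescent down-states)
#' or `silent`. Spikes are stereotyped 2-ms triangular waveforms.
#'
#' @param pattern `"tonic"`, `"irregular"`, `"burst"`, or `"silent"`.
#' @param duration_s Trace length (s).
#' @param seed Integer seed.
#' @param rate_hz Mean firing rate for tonic/irregular.
#' @param isi_cv ISI coefficient of variation for tonic/irregular.
#' @param burst_n Spikes per burst.
#' @param intra_isi_ms Intra-burst inter-spike interval (ms).
#' @param inter_burst_ms Gap between bursts (ms).
#' @param updown Depolarize to an up-state during bursts (gives the
#'   two-mode membrane histogram of phasic bursting).
#' @param baseline_mv,up_mv Down- and up-state potentials (mV).
#' @param dt_ms Sample interval (ms).
#' @param noise_sd Additive Gaussian noise on the potential (mV).
#' @return Tibble with `time_ms`, `vm`, plus attribute `"true_label"`.
#' @export
generate_spike_train <- function(pattern = c("tonic", "irregular", "burst",
                                             "silent"),
                                 duration_s = 20, seed = 1,
                                 rate_hz = 5, isi_cv = 0.1,
                                 burst_n = 4, intra_isi_ms = 30,
                                 inter_burst_ms = 2000, updown = TRUE,
                                 baseline_mv = -70, up_mv = -45,
                                 dt_ms = 0.5, noise_sd = 0.3) {
  pattern <- match.arg(pattern)
  withr::local_seed(seed)
  t_end <- duration_s * 1000
  tms <- seq(0, t_end, by = dt_ms)
  vm <- rep(baseline_mv, length(tms))

  spike_times <- switch(pattern,
    silent = numeric(0),
    tonic = ,
    irregular = {
      if (pattern == "irregular" && missing(isi_cv)) isi_cv <- 1
      shape <- 1 / isi_cv^2
      mean_isi <- 1000 / rate_hz
      isis <- stats::rgamma(ceiling(2 * rate_hz * duration_s) + 10,
                            shape = shape, rate = shape / mean_isi)
      st <- cumsum(isis) + 200
      st[st < t_end - 50]
    },
    burst = {
      starts <- seq(500, t_end - 500,
                    by = inter_burst_ms + burst_n * intra_isi_ms)
      as.numeric(vapply(starts, function(s) {
        s + (0:(burst_n - 1)) * intra_isi_ms
      }, numeric(burst_n)))
    })

  if (pattern == "burst" && updown) {
    starts <- spike_times[seq(1, length(spike_times), by = burst_n)]
    for (s in starts) {
      up <- tms >= s - 20 & tms <= s + burst_n * intra_isi_ms + 60
      vm[up] <- up_mv
    }
  }
  for (s in spike_times) {
    seg <- tms >= s & tms < s + 2
    if (any(seg)) {
      ph <- (tms[seg] - s) / 2
      vm[seg] <- pmax(vm[seg], baseline_mv) +
        (20 - baseline_mv) * (1 - abs(2 * ph - 1))
    }
  }
  vm <- vm + stats::rnorm(length(vm), 0, noise_sd)
  out <- tibble(time_ms = tms, vm = vm)
  attr(out, "true_label") <- switch(pattern,
    silent = "silent",
    tonic = "tonic",
    irregular = "irregular",
    burst = if (updown) "phasic_burst" else "irregular_burst")
  out
}

#' Synthetic qPCR CT pools
#'
#' Generates tidy CT tables for two treatment groups with prescribed true
#' fold changes per gene, Gaussian cycle-scale noise, per-animal random
#' effects, and a shared reference gene, emulating multi-cell-pool qPCR
#' designs (several pools per animal, a handful of animals per group).
#'
#' @param fold_changes Named numeric vector: true treated/control expression
#'   ratio per target gene (e.g. `c(Tac2 = 0.5)`).
#' @param ct_sd Cycle-scale noise SD per pool.
#' @param n_animals Animals per group.
#' @param pools_per_animal Pools per animal.
#' @param seed Integer seed.
#' @param groups Group labels, calibrator first.
#' @param ref_gene Reference gene name.
#' @param base_ref_ct Mean reference-gene CT.
#' @param base_dct Control-group mean dCT per target gene (recycled).
#' @param animal_sd SD of the per-animal random CT offset.
#' @return Tidy tibble with `animal`, `group`, `gene`, `pool`, `ct`.
#' @export
generate_qpcr_pools <- function(fold_changes, ct_sd = 0.2, n_animals = 5,
                                pools_per_animal = 3, seed = 1,
                                groups = c("oil", "e2"), ref_gene = "Gapdh",
                                base_ref_ct = 20, base_dct = 6,
                                animal_sd = 0.3) {
  stopifnot(length(groups) == 2, !is.null(names(fold_changes)))
  withr::local_seed(seed)
  base_dct <- rep_len(base_dct, length(fold_changes))
  rows <- list()
  for (gi in seq_along(groups)) {
    gr <- groups[gi]
    for (a in seq_len(n_animals)) {
      an <- paste0(gr, "_a", a)
      a_off <- stats::rnorm(1, 0, animal_sd)
      for (p in seq_len(pools_per_animal)) {
        ref_ct <- base_ref_ct + a_off + stats::rnorm(1, 0, ct_sd)
        rows[[length(rows) + 1]] <- tibble(
          animal = an, group = gr, gene = ref_gene, pool = p, ct = ref_ct)
        for (g in seq_along(fold_changes)) {
          dct <- base_dct[g] -
            (if (gi == 2) log2(fold_changes[[g]]) else 0)
          rows[[length(rows) + 1]] <- tibble(
            animal = an, group = gr, gene = names(fold_changes)[g],
            pool = p, ct = ref_ct + dct + stats::rnorm(1, 0, ct_sd))
        }
      }
    }
  }
  bind_rows(rows)
}
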