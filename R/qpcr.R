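#' qPCR primer efficiency from a standard-curve slope
#'
#' Computes the real-time PCR amplification efficiency from the slope of a
#' standard (dilution) curve, `E = 10^(-1/m) - 1`, and reports it the way
#' primer tables print it: as a percentage rounded to the nearest integer and
#' capped at 100. A slope of -3.3219 (perfect doubling per cycle) gives
#' exactly 100%; shallower-than-perfect slopes, which the raw formula pushes
#' above 100%, report the cap.
#'
#' @param m Standard-curve slope (cycles per log10 dilution); must be
#'   negative. Vectorized.
#' @param cap Cap applied after rounding (percent).
#' @return Integer percentage(s). The uncapped, unrounded efficiency is
#'   available via `attr(, "raw")`.
#' @examples
#' primer_efficiency(-3.352)  # 99
#' primer_efficiency(-3.478)  # 94
#' @export
primer_efficiency <- function(m, cap = 100) {
  if (!is.numeric(m) || any(!is.finite(m)) || any(m >= 0)) {
    abort("standard-curve slope `m` must be negative and finite")
  }
  e <- 10^(-1 / m) - 1
  pct <- pmin(cap, round(100 * e))
  structure(as.integer(pct), raw = 100 * e)
}

#' Comparative delta-delta-CT quantification
#'
#' Implements the comparative CT method on a tidy table of cycle-threshold
#' values from multi-cell pools. Per pool, `dCT = CT_target - CT_reference`;
#' `ddCT` subtracts the mean `dCT` of the calibrator group (per gene); the
#' relative quantity is `2^-ddCT`. Pools are averaged within animal, making
#' the animal the unit of analysis; the calibrator group's mean fold change
#' is 1 by construction.
#'
#' @param pools Tidy data frame with columns `animal`, `group`, `gene`,
#'   `pool`, `ct`. The reference gene's rows carry `gene == ref_gene`.
#' @param calibrator_group Group whose mean dCT is the calibrator.
#' @param ref_gene Reference (housekeeping) gene name.
#' @return Tibble with per-animal relative quantities: `gene`, `animal`,
#'   `group`, `n_pools`, `dct`, `ddct`, `fold_change`.
#' @export
ddct_fold_change <- function(pools, calibrator_group, ref_gene = "Gapdh") {
  need <- c("animal", "group", "gene", "pool", "ct")
  if (!all(need %in% names(pools))) {
    abort(paste0("pools must have columns: ", paste(need, collapse = ", ")))
  }
  if (!calibrator_group %in% pools$group) {
    abort(paste0("calibrator group '", calibrator_group, "' not present"))
  }
  if (length(unique(pools$group)) < 2) {
    abort("need at least two groups (calibrator and comparison)")
  }
  refs <- pools %>%
    filter(.data$gene == ref_gene) %>%
    select("animal", "group", "pool", ref_ct = "ct")
  if (!nrow(refs)) abort(paste0("reference gene '", ref_gene, "' missing"))
  dct <- pools %>%
    filter(.data$gene != ref_gene) %>%
    left_join(refs, by = c("animal", "group", "pool"))
  if (any(is.na(dct$ref_ct))) {
    abort("some pools are missing a reference-gene CT")
  }
  dct <- dct %>% mutate(dct = .data$ct - .data$ref_ct)
  calib <- dct %>%
    filter(.data$group == calibrator_group) %>%
    group_by(.data$gene) %>%
    summarise(calib_dct = mean(.data$dct), .groups = "drop")
  dct %>%
    left_join(calib, by = "gene") %>%
    mutate(ddct = .data$dct - .data$calib_dct,
           fold = 2^(-.data$ddct)) %>%
    group_by(.data$gene, .data$animal, .data$group) %>%
    summarise(n_pools = dplyr::n(), dct = mean(.data$dct),
              ddct = mean(.data$ddct), fold_change = mean(.data$fold),
              .groups = "drop")
}

#' Student's t from summary statistics
#'
#' Unpaired two-tailed t-test computed from group means, SEMs and sizes, as
#' used to compare printed group summaries. The default is the
#' pooled-variance Student form (`SD_i = SEM_i * sqrt(n_i)`,
#' `df = n1 + n2 - 2`); `welch = TRUE` gives the unequal-variance variant.
#'
#' @param mean1,sem1,n1 First group's mean, SEM and size.
#' @param mean2,sem2,n2 Second group's.
#' @param welch Use the Welch (unequal-variance) form.
#' @return Tibble with `t`, `df`, `p_value`.
#' @examples
#' t_from_summary(7.2, 0.5, 40, 13.4, 0.9, 11)  # |t| near 5.8, df 49
#' @export
t_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2, welch = FALSE) {
  if (n1 < 2 || n2 < 2) abort("both groups need n >= 2")
  if (sem1 <= 0 || sem2 <= 0) abort("SEMs must be positive")
  v1 <- (sem1 * sqrt(n1))^2
  v2 <- (sem2 * sqrt(n2))^2
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
    tt <- (mean1 - mean2) / se
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tibble(t = tt, df = df,
         p_value = 2 * stats::pt(-abs(tt), df))
}

#' Chi-square test on firing-pattern counts
#'
#' Plain Pearson chi-square on a contingency table of firing-pattern counts
#' per group (no continuity correction).
#'
#' @param counts Matrix or table of counts (groups x patterns).
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
firing_distribution_test <- function(counts) {
  ct <- suppressWarnings(stats::chisq.test(as.matrix(counts), correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}

#' Read / write CT tables
#'
#' CT tables are plain delimited text with columns
#' `animal, group, gene, pool, ct`.
#'
#' @param path File path.
#' @param pools Tidy CT table.
#' @export
read_ct_table <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_ct_table
#' @export
write_ct_table <- function(pools, path) {
  utils::write.csv(as.data.frame(pools), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
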