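#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Boltzmann fit
#'
#' @param x A `boltzmann_fit`.
#' @param ... Unused.
#' @return One row per parameter (`v_half`, `k`, `ymax`) with estimates.
#' @exportS3Method generics::tidy
tidy.boltzmann_fit <- function(x, ...) {
  tibble(term = c("v_half", "k", "ymax"),
         estimate = c(x$v_half, x$k, x$ymax))
}

#' @rdname tidy.boltzmann_fit
#' @exportS3Method generics::glance
glance.boltzmann_fit <- function(x, ...) {
  tibble(kind = x$kind, convention = x$convention, rss = x$rss, n = x$n)
}

#' Tidy a conductance calibration
#'
#' @param x A `conductance_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.conductance_fit <- function(x, ...) {
  tibble(term = paste0("gbar_", x$channel), estimate = x$gbar_ns)
}

#' @rdname tidy.conductance_fit
#' @exportS3Method generics::glance
glance.conductance_fit <- function(x, ...) {
  tibble(channel = x$channel, rss = x$rss, method = x$method)
}

#' Tidy a neuron parameter set
#'
#' One row per channel with conductance, block and reversal potential.
#'
#' @param x A `neuron_params`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.neuron_params <- function(x, ...) {
  purrr::map_dfr(names(x$channels), function(nm) {
    ch <- x$channels[[nm]]
    tibble(channel = nm, gbar_ns = ch$gbar, block = ch$block,
           erev_mv = ch$erev)
  })
}
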