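#' Boltzmann steady-state gating value
#'
#' Voltage dependence of channel gating in the usual two-parameter Boltzmann
#' form. For `kind = "activation"` the value increases with depolarization,
#' `1 / (1 + exp((v_half - vm) / k))`; for `kind = "inactivation"` it
#' decreases, `1 / (1 + exp((vm - v_half) / k))`. The slope factor `k` is
#' positive in both parameterizations.
#'
#' @param vm Membrane potential (mV). Vectorized.
#' @param v_half Half-activation (or half-inactivation) potential (mV).
#' @param k Slope factor (mV), must be non-zero.
#' @param kind `"activation"` or `"inactivation"`.
#' @return Steady-state open (or available) fraction in `[0, 1]`.
#' @examples
#' gating_steady_state(-32.3, -32.3, 6)          # midpoint: 0.5
#' gating_steady_state(-32.3 + 6 * log(3), -32.3, 6)  # 0.75
#' @export
gating_steady_state <- function(vm, v_half, k,
                                kind = c("activation", "inactivation")) {
  kind <- match.arg(kind)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k == 0) {
    stop("slope factor `k` must be a single non-zero finite number",
         call. = FALSE)
  }
  k <- abs(k)
  if (kind == "activation") {
    1 / (1 + exp((v_half - vm) / k))
  } else {
    1 / (1 + exp((vm - v_half) / k))
  }
}
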