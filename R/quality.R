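#' Entropy-based signal quality index (ESQI)
#'
#' Quantifies the uncertainty of a raw PPG window as
#' `E = -sum(x^2 * ln(x^2))`. When any sample is (numerically) zero the
#' term `0 * ln(0)` is undefined, and the whole index is reported as
#' undefined: such windows are skipped by the pipeline when quality
#' gating is enabled. The index is evaluated on the raw-scale signal
#' (after missing-value interpolation, before enhancement) and is
#' deliberately scale-sensitive: no normalisation is applied.
#'
#' @param samples Nonempty numeric window without missing values.
#' @param zero_tol Samples with `|x| <= zero_tol` are treated as exact
#'   zeros (default 1e-12, guarding against floating-point underflow in
#'   `x^2 * log(x^2)`).
#' @return A list with `esqi` (the value, or `NA` when undefined) and
#'   `defined` (logical).
#' @examples
#' esqi(exp(-1 / 2))$esqi # exp(-1)
#' esqi(c(1, 0, 1))$defined # FALSE
#' @export
esqi <- function(samples, zero_tol = 1e-12) {
  if (length(samples) == 0) stop("empty window", call. = FALSE)
  if (anyNA(samples)) stop("`samples` must not contain missing values",
                           call. = FALSE)
  if (any(abs(samples) <= zero_tol)) {
    return(list(esqi = NA_real_, defined = FALSE))
  }
  x2 <- samples^2
  list(esqi = -sum(x2 * log(x2)), defined = TRUE)
}

#' Quality gate for an analysis window
#'
#' Decides whether a window proceeds to respiratory-rate estimation.
#' With gating disabled every window proceeds; with gating enabled a
#' window proceeds only when its ESQI is defined.
#'
#' @param quality Result of [esqi()].
#' @param use_esqi Logical; is quality gating enabled?
#' @return `TRUE` when the window should be processed.
#' @export
gate_window <- function(quality, use_esqi = TRUE) {
  if (!use_esqi) return(TRUE)
  isTRUE(quality$defined)
}
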