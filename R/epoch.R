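#' EEG epoch container
#'
#' An `eeg_epoch` is the atomic unit of the coupling analysis: one
#' fixed-length, single-channel segment of EEG together with its sampling
#' rate and bookkeeping labels.
#'
#' @param samples Numeric vector of voltage samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel Channel name (e.g. `"Fz"`).
#' @param condition Condition label (e.g. `"resting"`).
#' @param index Ordinal position of the epoch within its recording.
#'
#' @return An object of class `eeg_epoch`: a list with elements `samples`,
#'   `sampling_rate`, `channel`, `condition`, `index`.
#' @export
epoch <- function(samples, sampling_rate, channel = NA_character_,
                  condition = NA_character_, index = NA_integer_) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = sampling_rate,
         channel = channel, condition = condition, index = index),
    class = "eeg_epoch"
  )
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d samples @ %g Hz (%.3g s)",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  if (!is.na(x$channel)) cat(sprintf(" channel=%s", x$channel))
  if (!is.na(x$condition)) cat(sprintf(" condition=%s", x$condition))
  cat("\n")
  invisible(x)
}

#' @export
length.eeg_epoch <- function(x) length(x$samples)

#' Analytic (phase/amplitude) series of a band-filtered epoch
#'
#' Holds the per-sample instantaneous phase and amplitude of one
#' band-limited epoch, as returned by [hilbert_decompose()].
#'
#' @param phase Numeric vector of phases in radians, in (-pi, pi].
#' @param amplitude Numeric vector of non-negative instantaneous amplitudes.
#' @param band Band label, `"delta"` or `"beta"` (free-form allowed).
#' @param sampling_rate Sampling rate in Hz.
#'
#' @return An object of class `analytic_series` with elements `phase`,
#'   `amplitude`, `band`, `sampling_rate`, `n`.
#' @export
analytic_series <- function(phase, amplitude, band = NA_character_,
                            sampling_rate = NA_real_) {
  if (length(phase) != length(amplitude)) {
    stop("`phase` and `amplitude` must have equal length", call. = FALSE)
  }
  if (length(phase) == 0L) stop("empty analytic series", call. = FALSE)
  if (any(amplitude < 0)) {
    stop("`amplitude` must be non-negative", call. = FALSE)
  }
  structure(
    list(phase = as.numeric(phase), amplitude = as.numeric(amplitude),
         band = band, sampling_rate = sampling_rate, n = length(phase)),
    class = "analytic_series"
  )
}

#' @export
print.analytic_series <- function(x, ...) {
  cat(sprintf("<analytic_series> band=%s n=%d @ %g Hz\n",
              x$band, x$n, x$sampling_rate))
  invisible(x)
}
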