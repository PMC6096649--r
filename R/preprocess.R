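#' Segment a continuous signal into non-overlapping epochs
#'
#' Cuts a continuous single-channel series into consecutive fixed-length
#' epochs; any trailing remainder shorter than one epoch is discarded.
#'
#' @param signal Numeric vector, the continuous recording.
#' @param sampling_rate Sampling rate in Hz.
#' @param epoch_duration Epoch length in seconds (default 8, giving 4,096
#'   samples at 512 Hz).
#' @param channel,condition Labels propagated to each [epoch()].
#'
#' @return List of [epoch()] objects in temporal order.
#' @export
segment_epochs <- function(signal, sampling_rate, epoch_duration = 8,
                           channel = NA_character_,
                           condition = NA_character_) {
  len <- round(sampling_rate * epoch_duration)
  if (abs(len - sampling_rate * epoch_duration) > 1e-9) {
    stop("epoch_duration x sampling_rate must be an integer number of samples",
         call. = FALSE)
  }
  if (length(signal) < len) {
    stop(sprintf("signal (%d samples) is shorter than one epoch (%d samples)",
                 length(signal), len), call. = FALSE)
  }
  n_ep <- length(signal) %/% len
  lapply(seq_len(n_ep), function(i) {
    epoch(signal[((i - 1L) * len + 1L):(i * len)], sampling_rate,
          channel = channel, condition = condition, index = i)
  })
}

#' Randomly select clean early and late epochs
#'
#' Mirrors the selection used for task data: from the first ten epochs of a
#' recording, `n_early` artifact-free epochs are drawn uniformly at random,
#' and likewise `n_late` from the last ten. Selected epochs keep their
#' original temporal order. For the resting state the convention is
#' `n_early = 3, n_late = 3`, combined into one six-epoch set.
#'
#' @param epochs List of [epoch()] objects in temporal order.
#' @param clean_mask Logical vector, `TRUE` for epochs free of artifacts.
#' @param n_early,n_late Number of epochs to draw from the first/last ten.
#' @param seed Integer seed making the draw reproducible.
#' @param window Number of epochs at each end eligible for selection
#'   (default 10).
#'
#' @return List with elements `early` and `late`, each a list of epochs.
#' @export
select_clean_epochs <- function(epochs, clean_mask, n_early, n_late,
                                seed = NULL, window = 10L) {
  n <- length(epochs)
  if (length(clean_mask) != n) {
    stop("`clean_mask` must have one entry per epoch", call. = FALSE)
  }
  head_idx <- seq_len(min(window, n))
  tail_idx <- seq.int(max(1L, n - window + 1L), n)
  early_pool <- head_idx[clean_mask[head_idx]]
  late_pool <- tail_idx[clean_mask[tail_idx]]
  if (length(early_pool) < n_early) {
    stop(sprintf(
      "insufficient clean early epochs: need %d, only %d clean among the first %d",
      n_early, length(early_pool), length(head_idx)), call. = FALSE)
  }
  if (length(late_pool) < n_late) {
    stop(sprintf(
      "insufficient clean late epochs: need %d, only %d clean among the last %d",
      n_late, length(late_pool), length(tail_idx)), call. = FALSE)
  }
  pick <- with_seed(seed, {
    e <- sort(early_pool[sample.int(length(early_pool), n_early)])
    l <- sort(late_pool[sample.int(length(late_pool), n_late)])
    list(e = e, l = l)
  })
  list(early = epochs[pick$e], late = epochs[pick$l])
}

#' Downsample an epoch by an integer factor
#'
#' Anti-alias-filtered decimation: a zero-phase low-pass Butterworth
#' (order 8, cutoff 0.8 x target Nyquist) is applied before keeping every
#' k-th sample. 4,096 samples at 512 Hz become 1,024 samples at 128 Hz.
#'
#' @param x An [epoch()].
#' @param target_rate Target sampling rate in Hz; must divide the epoch's
#'   rate, and the target Nyquist must clear the highest analysis band.
#' @param min_nyquist Lowest acceptable target Nyquist in Hz (default 30,
#'   the beta upper edge).
#'
#' @return The decimated [epoch()].
#' @export
downsample <- function(x, target_rate, min_nyquist = 30) {
  stopifnot(inherits(x, "eeg_epoch"))
  factor <- x$sampling_rate / target_rate
  if (abs(factor - round(factor)) > 1e-9) {
    stop(sprintf("target rate %g Hz is not an integer divisor of %g Hz",
                 target_rate, x$sampling_rate), call. = FALSE)
  }
  factor <- as.integer(round(factor))
  if (target_rate / 2 <= min_nyquist) {
    stop(sprintf("target Nyquist (%g Hz) must exceed %g Hz",
                 target_rate / 2, min_nyquist), call. = FALSE)
  }
  if (factor == 1L) return(x)
  sos <- butter_lowpass_sos(8, 0.8 * target_rate / 2, x$sampling_rate)
  y <- sos_filtfilt(x$samples, sos)
  epoch(y[seq.int(1L, length(y), by = factor)], target_rate,
        channel = x$channel, condition = x$condition, index = x$index)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth IIR band-pass of the given one-pass order forward
#' and backward (zero net phase shift; effective order doubled). The filter
#' is realized as cascaded second-order sections, which keeps high orders
#' (beta uses 34) numerically stable. Standard orders: 8 for delta (1-4 Hz),
#' 34 for beta (14-30 Hz).
#'
#' @param x An [epoch()].
#' @param band Numeric pair `(low, high)` in Hz, inside (0, Nyquist).
#' @param order One-pass band-pass order (even).
#' @param demean Subtract the epoch mean before filtering (default TRUE).
#'
#' @return The filtered [epoch()], same length as the input.
#' @export
bandpass_zero_phase <- function(x, band, order, demean = TRUE) {
  stopifnot(inherits(x, "eeg_epoch"))
  sos <- butter_bandpass_sos(order, band, x$sampling_rate)
  s <- x$samples
  if (demean) s <- s - mean(s)
  epoch(sos_filtfilt(s, sos), x$sampling_rate,
        channel = x$channel, condition = x$condition, index = x$index)
}

#' Hilbert decomposition into instantaneous phase and amplitude
#'
#' Computes the analytic signal of a band-limited epoch; the modulus gives
#' the instantaneous amplitude envelope and the argument the instantaneous
#' phase. Phase follows the cosine convention: 0 radians at the positive
#' peak of the oscillation.
#'
#' @param x A band-filtered [epoch()] (output of [bandpass_zero_phase()]).
#' @param band Band label stored on the result.
#'
#' @return An [analytic_series()].
#' @export
hilbert_decompose <- function(x, band = NA_character_) {
  stopifnot(inherits(x, "eeg_epoch"))
  z <- analytic_signal(x$samples)
  analytic_series(phase = Arg(z), amplitude = Mod(z),
                  band = band, sampling_rate = x$sampling_rate)
}

#' Trim filter edge artifacts from an analytic series
#'
#' Removes the first and last `n_trim` samples (default 16, matching the
#' doubled delta filter order) from both the phase and amplitude series.
#'
#' @param series An [analytic_series()].
#' @param n_trim Samples to cut from each edge.
#'
#' @return The trimmed [analytic_series()].
#' @export
trim_edges <- function(series, n_trim = 16L) {
  stopifnot(inherits(series, "analytic_series"))
  if (n_trim < 0) stop("`n_trim` must be >= 0", call. = FALSE)
  if (n_trim == 0L) return(series)
  if (series$n <= 2L * n_trim) {
    stop(sprintf("series of length %d too short to trim %d samples per edge",
                 series$n, n_trim), call. = FALSE)
  }
  keep <- (n_trim + 1L):(series$n - n_trim)
  analytic_series(series$phase[keep], series$amplitude[keep],
                  band = series$band, sampling_rate = series$sampling_rate)
}

#' Full preprocessing chain for a set of epochs
#'
#' Convenience wrapper running, per epoch: decimation to `target_rate`,
#' zero-phase band-pass in the delta and beta bands independently (both
#' applied to the same decimated epoch, never in cascade), Hilbert
#' decomposition, and edge trimming.
#'
#' @param epochs List of [epoch()] objects for one electrode.
#' @param target_rate Analysis sampling rate in Hz (default 128).
#' @param delta_band,beta_band Band edges in Hz.
#' @param delta_order,beta_order One-pass filter orders.
#' @param n_trim Edge samples trimmed from each analytic series.
#' @param demean Subtract each epoch's mean before filtering.
#'
#' @return List with elements `delta` and `beta`, each a list of trimmed
#'   [analytic_series()], one per input epoch.
#' @export
preprocess_epochs <- function(epochs, target_rate = 128,
                              delta_band = c(1, 4), beta_band = c(14, 30),
                              delta_order = 8L, beta_order = 34L,
                              n_trim = 16L, demean = TRUE) {
  stopifnot(length(epochs) >= 1L)
  fs <- epochs[[1L]]$sampling_rate
  sos_aa <- if (fs != target_rate) {
    butter_lowpass_sos(8, 0.8 * target_rate / 2, fs)
  } else NULL
  sos_d <- butter_bandpass_sos(delta_order, delta_band, target_rate)
  sos_b <- butter_bandpass_sos(beta_order, beta_band, target_rate)
  factor <- as.integer(round(fs / target_rate))
  out_d <- vector("list", length(epochs))
  out_b <- vector("list", length(epochs))
  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    if (ep$sampling_rate != fs) {
      stop("all epochs must share one sampling rate", call. = FALSE)
    }
    s <- ep$samples
    if (!is.null(sos_aa)) {
      s <- sos_filtfilt(s, sos_aa)[seq.int(1L, length(s), by = factor)]
    }
    if (demean) s <- s - mean(s)
    zd <- analytic_signal(sos_filtfilt(s, sos_d))
    zb <- analytic_signal(sos_filtfilt(s, sos_b))
    keep <- (n_trim + 1L):(length(s) - n_trim)
    out_d[[i]] <- analytic_series(Arg(zd)[keep], Mod(zd)[keep],
                                  band = "delta", sampling_rate = target_rate)
    out_b[[i]] <- analytic_series(Arg(zb)[keep], Mod(zb)[keep],
                                  band = "beta", sampling_rate = target_rate)
  }
  list(delta = out_d, beta = out_b)
}
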