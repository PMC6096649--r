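# Butterworth filters realized as cascaded second-order sections (biquads).
#
# High-order IIR band-pass filters (the beta band uses total order 34) are
# numerically fragile in direct transfer-function form: expanding the
# polynomial coefficients loses the pole positions to rounding. The designs
# here therefore stay in pole form throughout and are applied biquad by
# biquad, which keeps every section stable. The digital magnitude response
# equals the bilinear-transformed analog Butterworth response to machine
# precision (checked in the test-suite against the closed form).

butter_proto_poles <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# Band-pass Butterworth as an SOS matrix (rows = sections, cols = b0 b1 b2
# a0 a1 a2). `order` is the total band-pass order (even); the underlying
# low-pass prototype has order/2 poles, so a forward-backward pass doubles
# the effective order exactly as quoted for zero-phase filtering.
butter_bandpass_sos <- function(order, band, sampling_rate) {
  if (order %% 2 != 0 || order < 2) {
    stop("band-pass `order` must be a positive even integer", call. = FALSE)
  }
  validate_band(band, sampling_rate)
  n <- order / 2L
  fs2 <- 2 * sampling_rate
  # prewarp band edges so the digital -3 dB points land on `band`
  w1 <- fs2 * tan(pi * band[1] / sampling_rate)
  w2 <- fs2 * tan(pi * band[2] / sampling_rate)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  p <- butter_proto_poles(n)
  # low-pass -> band-pass: each prototype pole maps to a conjugate-quad pair
  ph <- p * bw / 2
  rt <- sqrt(ph^2 - w0^2)
  poles_s <- c(ph + rt, ph - rt)
  poles_z <- (fs2 + poles_s) / (fs2 - poles_s)
  # n zeros at z = 1 and n at z = -1; one (1,-1) pair per section
  pos <- poles_z[Im(poles_z) > 0]
  if (length(pos) != n) {   # degenerate: real poles (never for Butterworth bp)
    stop("unexpected real poles in band-pass design", call. = FALSE)
  }
  sos <- matrix(0, n, 6)
  for (i in seq_len(n)) {
    pk <- pos[i]
    sos[i, ] <- c(1, 0, -1, 1, -2 * Re(pk), Mod(pk)^2)
  }
  # unit gain at the (geometric) band centre
  wc <- 2 * pi * sqrt(band[1] * band[2]) / sampling_rate
  sos[1, 1:3] <- sos[1, 1:3] / Mod(sos_response(sos, wc))
  check_sos_stable(sos)
  sos
}

# Low-pass Butterworth SOS (order may be odd; odd order yields one
# first-order section). Used as the anti-alias filter for decimation.
butter_lowpass_sos <- function(order, cutoff, sampling_rate) {
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  if (cutoff <= 0 || cutoff >= sampling_rate / 2) {
    stop("`cutoff` must lie in (0, Nyquist)", call. = FALSE)
  }
  fs2 <- 2 * sampling_rate
  wc <- fs2 * tan(pi * cutoff / sampling_rate)
  p <- butter_proto_poles(order) * wc
  pz <- (fs2 + p) / (fs2 - p)
  pos <- pz[Im(pz) > 1e-12]
  real_p <- Re(pz[abs(Im(pz)) <= 1e-12])
  nsec <- length(pos) + length(real_p)
  sos <- matrix(0, nsec, 6)
  i <- 0L
  for (pk in pos) {
    i <- i + 1L
    sos[i, ] <- c(1, 2, 1, 1, -2 * Re(pk), Mod(pk)^2)
  }
  for (pk in real_p) {
    i <- i + 1L
    sos[i, ] <- c(1, 1, 0, 1, -pk, 0)
  }
  sos[1, 1:3] <- sos[1, 1:3] / Mod(sos_response(sos, 0))
  check_sos_stable(sos)
  sos
}

# Frequency response of an SOS cascade at digital radian frequency w.
sos_response <- function(sos, w) {
  zi <- exp(-1i * w)
  H <- rep(1 + 0i, length(w))
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]; a <- sos[i, 4:6]
    H <- H * (b[1] + b[2] * zi + b[3] * zi^2) /
      (a[1] + a[2] * zi + a[3] * zi^2)
  }
  H
}

check_sos_stable <- function(sos) {
  for (i in seq_len(nrow(sos))) {
    r <- Mod(polyroot(rev(sos[i, 4:6])))
    if (any(r >= 1)) {
      stop("unstable filter realization detected; use a cascaded ",
           "second-order-sections design", call. = FALSE)
    }
  }
  invisible(TRUE)
}

validate_band <- function(band, sampling_rate) {
  if (length(band) != 2L || !is.numeric(band)) {
    stop("`band` must be a numeric pair (low, high) in Hz", call. = FALSE)
  }
  if (band[1] <= 0 || band[1] >= band[2]) {
    stop(sprintf("invalid band edges: low (%g) must be in (0, high = %g)",
                 band[1], band[2]), call. = FALSE)
  }
  if (band[2] >= sampling_rate / 2) {
    stop(sprintf(
      "invalid band edges: high (%g Hz) must be below Nyquist (%g Hz)",
      band[2], sampling_rate / 2), call. = FALSE)
  }
  invisible(TRUE)
}

# One biquad over a vector, vectorized through stats::filter. Initial
# conditions assume the signal was at steady state x[1] before the first
# sample (the standard zero-phase-filtering initialization), which together
# with edge padding suppresses start-up transients.
biquad_filter <- function(x, b, a) {
  n <- length(x)
  u <- b[1] * x +
    b[2] * c(x[1], x[-n]) +
    b[3] * c(x[1], x[1], x[-c(n - 1L, n)])
  asum <- 1 + a[2] + a[3]
  y0 <- if (abs(asum) > 1e-300) x[1] * sum(b) / asum else 0
  as.numeric(stats::filter(u, c(-a[2], -a[3]), method = "recursive",
                           init = c(y0, y0)))
}

sos_filter <- function(x, sos) {
  for (i in seq_len(nrow(sos))) x <- biquad_filter(x, sos[i, 1:3], sos[i, 4:6])
  x
}

# Zero-phase filtering: odd-reflection padding, forward pass through the
# cascade, time reversal, second pass, reversal, unpad. Forward + backward
# application squares the magnitude response and cancels the phase.
sos_filtfilt <- function(x, sos) {
  n <- length(x)
  padlen <- min(n - 1L, max(3L * (2L * nrow(sos) + 1L), 64L))
  if (padlen < 1L) stop("signal too short to filter", call. = FALSE)
  pre <- 2 * x[1] - x[(padlen + 1L):2]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  y <- sos_filter(c(pre, x, post), sos)
  y <- rev(sos_filter(rev(y), sos))
  y[(padlen + 1L):(padlen + n)]
}

# Analytic signal via the frequency-domain Hilbert transform: negative
# frequencies zeroed, positive doubled, DC (and Nyquist for even n) kept.
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty input", call. = FALSE)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
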