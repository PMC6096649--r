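# Core coupling estimators.
#
# With beta amplitude a_t and delta phase phi_t over n samples:
#   PAC  = (1/n) sum_t a_t exp(i phi_t)            (mean-normalized)
#   PC   = (1/n) sum_t exp(i phi_t)                (phase clustering)
#   dPAC = | (1/n) sum_t a_t (exp(i phi_t) - PC) | (debiased PAC)
#   dPACz = (dPAC - mean(dPAC_null)) / sd(dPAC_null)
# where dPAC_null comes from re-pairing phase epochs with amplitude epochs
# under random epoch permutations.

#' Phase clustering (complex mean of unit phase vectors)
#'
#' The modulus measures how non-uniform the phase-angle distribution is
#' (0 = uniform, 1 = total clustering); the argument is the mean direction.
#'
#' @param phases Numeric vector of phases in radians.
#' @return A single complex number.
#' @export
phase_clustering <- function(phases) {
  if (length(phases) == 0L) stop("empty phase vector", call. = FALSE)
  mean(exp(1i * phases))
}

#' Debiased phase-amplitude coupling over one phase/amplitude pairing
#'
#' Computes mean-normalized PAC, phase clustering (PC), and debiased PAC
#' (dPAC), where the PC vector is subtracted from each unit phase vector
#' before amplitude weighting. Under a uniform phase distribution PC = 0
#' and dPAC coincides with |PAC|; under phase clustering the subtraction
#' removes the bias that inflates raw PAC.
#'
#' @param delta Either an [analytic_series()] supplying the phases, a list
#'   of them (concatenated), or a numeric phase vector.
#' @param beta Either an [analytic_series()] supplying the amplitudes, a
#'   list of them, or a numeric amplitude vector.
#'
#' @return An object of class `coupling_estimate`: list with `pac_complex`,
#'   `pc` (complex), `dpac_complex`, `dpac_magnitude`, `preferred_phase`
#'   (argument of the debiased mean vector), `n_samples`, and
#'   `degenerate` (TRUE when the amplitude series is identically zero).
#' @export
debiased_pac <- function(delta, beta) {
  phi <- extract_field(delta, "phase")
  amp <- extract_field(beta, "amplitude")
  if (length(phi) != length(amp)) {
    stop(sprintf("phase (%d) and amplitude (%d) series differ in length",
                 length(phi), length(amp)), call. = FALSE)
  }
  n <- length(phi)
  u <- exp(1i * phi)
  pc <- mean(u)
  pac <- mean(amp * u)
  dp <- pac - pc * mean(amp)
  degenerate <- all(amp == 0)
  structure(
    list(pac_complex = pac, pc = pc, dpac_complex = dp,
         dpac_magnitude = Mod(dp), preferred_phase = Arg(dp),
         n_samples = n, degenerate = degenerate),
    class = "coupling_estimate"
  )
}

#' @export
print.coupling_estimate <- function(x, ...) {
  cat(sprintf(
    "<coupling_estimate> dPAC=%.4g |PAC|=%.4g |PC|=%.4g pref.phase=%.3f rad (n=%d)%s\n",
    x$dpac_magnitude, Mod(x$pac_complex), Mod(x$pc), x$preferred_phase,
    x$n_samples, if (x$degenerate) " [degenerate: zero amplitude]" else ""))
  invisible(x)
}

extract_field <- function(x, field) {
  if (is.numeric(x)) return(as.numeric(x))
  if (inherits(x, "analytic_series")) return(x[[field]])
  if (is.list(x)) {
    return(unlist(lapply(x, extract_field, field = field), use.names = FALSE))
  }
  stop(sprintf("cannot extract %s from object of class %s",
               field, class(x)[1]), call. = FALSE)
}

# Pairing matrix M[e, f] = mean_t( amp[e, t] * exp(i phase[f, t]) ).
# dPAC under any epoch permutation `perm` of the phase epochs equals
# | mean_e M[e, perm[e]] - PC * mean(amp) |, because PC and mean(amp) are
# permutation-invariant over the concatenation. This makes 1,000 surrogates
# essentially free after E^2 vector operations.
pairing_matrix <- function(delta_epochs, beta_epochs) {
  E <- length(delta_epochs)
  lens <- vapply(delta_epochs, function(s) s$n, integer(1))
  lens_b <- vapply(beta_epochs, function(s) s$n, integer(1))
  if (length(unique(c(lens, lens_b))) != 1L) {
    stop("all epochs must have equal length for epoch shuffling",
         call. = FALSE)
  }
  U <- lapply(delta_epochs, function(s) exp(1i * s$phase))
  A <- lapply(beta_epochs, function(s) s$amplitude)
  M <- matrix(0i, E, E)
  for (e in seq_len(E)) for (f in seq_len(E)) {
    M[e, f] <- mean(A[[e]] * U[[f]])
  }
  M
}

#' Epoch-shuffled surrogate null distribution for dPAC
#'
#' Destroys the within-epoch pairing of phase and amplitude by randomly
#' permuting the epoch order of the phase series while the amplitude series
#' stays intact, recomputing dPAC over the re-paired concatenation for each
#' of `n_perm` draws. Permutations are drawn uniformly and independently
#' (the identity is permitted). The resulting distribution is the null
#' expected in the absence of coupling.
#'
#' @param delta_epochs,beta_epochs Lists (length >= 2) of equal-length
#'   [analytic_series()]; delta supplies phase, beta amplitude.
#' @param n_perm Number of surrogate draws (default 1000).
#' @param seed Integer seed for reproducible permutations.
#' @param scheme `"permute"` for uniform random epoch permutations, or
#'   `"shift"` for random circular shifts of the epoch order.
#'
#' @return An object of class `surrogate_null`: list with `values`
#'   (surrogate dPAC magnitudes), `n_perm`, `mean`, `sd` (sample SD, n-1),
#'   `seed`, `scheme`.
#' @export
surrogate_null <- function(delta_epochs, beta_epochs, n_perm = 1000L,
                           seed = NULL, scheme = c("permute", "shift")) {
  scheme <- match.arg(scheme)
  E <- length(delta_epochs)
  if (E < 2L) {
    stop("epoch shuffling undefined for a single epoch (need >= 2)",
         call. = FALSE)
  }
  if (length(beta_epochs) != E) {
    stop("delta and beta epoch lists must have equal length", call. = FALSE)
  }
  M <- pairing_matrix(delta_epochs, beta_epochs)
  pc <- phase_clustering(extract_field(delta_epochs, "phase"))
  abar <- mean(extract_field(beta_epochs, "amplitude"))
  base <- pc * abar
  vals <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      perm <- if (scheme == "permute") sample.int(E) else {
        k <- sample.int(E - 1L, 1L)
        ((seq_len(E) - 1L + k) %% E) + 1L
      }
      Mod(mean(M[cbind(seq_len(E), perm)]) - base)
    }, numeric(1))
  })
  structure(
    list(values = vals, n_perm = as.integer(n_perm),
         mean = mean(vals), sd = stats::sd(vals),
         seed = seed, scheme = scheme),
    class = "surrogate_null"
  )
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat(sprintf("<surrogate_null> %d %s surrogates: mean=%.4g sd=%.4g\n",
              x$n_perm, x$scheme, x$mean, x$sd))
  invisible(x)
}

#' Standardize dPAC against its surrogate null
#'
#' `z = (dPAC - mean(dPAC_null)) / sd(dPAC_null)`, in standard-deviation
#' units of the epoch-shuffled null.
#'
#' @param estimate A `coupling_estimate` from [debiased_pac()] (or a single
#'   dPAC magnitude).
#' @param null A `surrogate_null`.
#' @return Numeric z-value.
#' @export
dpac_z <- function(estimate, null) {
  stopifnot(inherits(null, "surrogate_null"))
  dpac <- if (inherits(estimate, "coupling_estimate")) {
    estimate$dpac_magnitude
  } else as.numeric(estimate)
  if (!is.finite(null$sd) || null$sd <= 0) {
    stop("degenerate surrogate set: null standard deviation is zero",
         call. = FALSE)
  }
  (dpac - null$mean) / null$sd
}

#' Within-subject amplitude-amplitude correlation (AAC)
#'
#' Product-moment correlation of the delta and beta amplitude envelopes
#' treated as two time series over all timepoints of the (concatenated,
#' trimmed) epochs. A Spearman variant is available for sensitivity checks.
#'
#' @param delta_amp,beta_amp Amplitude series: numeric vectors,
#'   [analytic_series()], or lists of them (concatenated).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `aac_estimate`: list with `r`, `n_samples`,
#'   `method`.
#' @export
amplitude_correlation <- function(delta_amp, beta_amp,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- extract_field(delta_amp, "amplitude")
  b <- extract_field(beta_amp, "amplitude")
  if (length(a) != length(b)) {
    stop("amplitude series differ in length", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in an amplitude series; correlation undefined",
         call. = FALSE)
  }
  structure(
    list(r = stats::cor(a, b, method = method), n_samples = length(a),
         method = method),
    class = "aac_estimate"
  )
}

#' @export
print.aac_estimate <- function(x, ...) {
  cat(sprintf("<aac_estimate> r=%.4f (%s, n=%d)\n", x$r, x$method,
              x$n_samples))
  invisible(x)
}

#' Average a per-electrode metric into a frontal composite
#'
#' Arithmetic mean of one metric across the configured electrode set
#' (default the frontal composite F3, Fz, F4); applied identically to dPAC,
#' dPACz and AAC r.
#'
#' @param values Named numeric vector, one finite value per electrode.
#' @param electrodes Required electrode names.
#' @return The composite (mean) value.
#' @export
electrode_composite <- function(values, electrodes = c("F3", "Fz", "F4")) {
  if (is.null(names(values))) {
    if (length(values) != length(electrodes)) {
      stop("unnamed `values` must match the electrode set in length",
           call. = FALSE)
    }
    names(values) <- electrodes
  }
  missing <- setdiff(electrodes, names(values))
  if (length(missing) > 0L) {
    stop(sprintf("missing electrode value(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  v <- values[electrodes]
  if (any(!is.finite(v))) stop("non-finite electrode value", call. = FALSE)
  mean(v)
}

#' Fit the delta-beta coupling model to one electrode's epochs
#'
#' The central fitting function: takes one electrode's epochs (raw, or
#' already preprocessed analytic series), runs the preprocessing chain if
#' needed, and estimates debiased phase-amplitude coupling with its
#' epoch-shuffled surrogate null and Z-score, plus the within-subject
#' amplitude-envelope correlation, over the concatenation of the trimmed
#' epochs.
#'
#' @param epochs List of raw [epoch()] objects for one electrode, or
#'   `NULL` when `delta`/`beta` are supplied directly.
#' @param delta,beta Optional lists of trimmed [analytic_series()] epochs
#'   (bypassing preprocessing).
#' @param n_perm Number of surrogate permutations (default 1000).
#' @param seed Integer seed for the surrogate permutations.
#' @param surrogate `"permute"` or `"shift"` (see [surrogate_null()]).
#' @param aac_method `"pearson"` or `"spearman"`.
#' @param ... Preprocessing options passed to [preprocess_epochs()].
#'
#' @return An object of class `cfc`: list with `estimate`
#'   (`coupling_estimate`), `null` (`surrogate_null`), `z` (dPACz), `aac`
#'   (`aac_estimate`), `n_epochs`, `n_samples`, `call`.
#' @export
cfc_fit <- function(epochs = NULL, delta = NULL, beta = NULL,
                    n_perm = 1000L, seed = NULL,
                    surrogate = c("permute", "shift"),
                    aac_method = c("pearson", "spearman"), ...) {
  surrogate <- match.arg(surrogate)
  aac_method <- match.arg(aac_method)
  if (is.null(delta) || is.null(beta)) {
    if (is.null(epochs)) {
      stop("supply either `epochs` or both `delta` and `beta`",
           call. = FALSE)
    }
    pre <- preprocess_epochs(epochs, ...)
    delta <- pre$delta
    beta <- pre$beta
  }
  est <- debiased_pac(delta, beta)
  null <- surrogate_null(delta, beta, n_perm = n_perm, seed = seed,
                         scheme = surrogate)
  aac <- amplitude_correlation(delta, beta, method = aac_method)
  structure(
    list(estimate = est, null = null, z = dpac_z(est, null), aac = aac,
         n_epochs = length(delta), n_samples = est$n_samples,
         call = match.call()),
    class = "cfc"
  )
}

#' @export
print.cfc <- function(x, ...) {
  cat("Delta-beta cross-frequency coupling fit\n")
  cat(sprintf("  epochs: %d (concatenated n = %d samples)\n",
              x$n_epochs, x$n_samples))
  cat(sprintf("  dPAC  = %.4f   (|PC| = %.3f, preferred phase = %.2f rad)\n",
              x$estimate$dpac_magnitude, Mod(x$estimate$pc),
              x$estimate$preferred_phase))
  cat(sprintf("  dPACz = %.3f   (%d %s surrogates)\n",
              x$z, x$null$n_perm, x$null$scheme))
  cat(sprintf("  AAC r = %.4f  (%s)\n", x$aac$r, x$aac$method))
  invisible(x)
}

#' @export
summary.cfc <- function(object, ...) {
  p_emp <- (1 + sum(object$null$values >= object$estimate$dpac_magnitude)) /
    (1 + object$null$n_perm)
  out <- list(
    dpac = object$estimate$dpac_magnitude,
    pac = Mod(object$estimate$pac_complex),
    pc = Mod(object$estimate$pc),
    preferred_phase = object$estimate$preferred_phase,
    dpac_z = object$z,
    p_surrogate = p_emp,
    aac_r = object$aac$r,
    n_epochs = object$n_epochs,
    n_samples = object$n_samples,
    null_mean = object$null$mean,
    null_sd = object$null$sd
  )
  class(out) <- "summary.cfc"
  out
}

#' @export
print.summary.cfc <- function(x, ...) {
  cat("Delta-beta cross-frequency coupling\n")
  cat(sprintf("  n_epochs = %d, n_samples = %d\n", x$n_epochs, x$n_samples))
  cat(sprintf("  raw |PAC|      = %.4f\n", x$pac))
  cat(sprintf("  |PC|           = %.4f\n", x$pc))
  cat(sprintf("  dPAC           = %.4f (preferred phase %.2f rad)\n",
              x$dpac, x$preferred_phase))
  cat(sprintf("  surrogate null = %.4f (sd %.4f)\n", x$null_mean, x$null_sd))
  cat(sprintf("  dPACz          = %.3f (empirical p = %.4f)\n",
              x$dpac_z, x$p_surrogate))
  cat(sprintf("  AAC r          = %.4f\n", x$aac_r))
  invisible(x)
}

#' @export
coef.cfc <- function(object, ...) {
  c(dpac = object$estimate$dpac_magnitude, dpac_z = object$z,
    aac_r = object$aac$r)
}

#' Plot a coupling fit: surrogate null and observed dPAC
#'
#' Histogram of the epoch-shuffled surrogate dPAC magnitudes with the
#' observed dPAC marked; the distance in null SDs is the reported dPACz.
#'
#' @param x A `cfc` fit.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.cfc <- function(x, ...) {
  obs <- x$estimate$dpac_magnitude
  h <- graphics::hist(x$null$values,
                      xlim = range(c(x$null$values, obs)),
                      main = "Epoch-shuffled surrogate null",
                      xlab = "surrogate dPAC magnitude", ...)
  graphics::abline(v = obs, col = "firebrick", lwd = 2)
  graphics::mtext(sprintf("observed dPAC = %.4f (z = %.2f)", obs, x$z),
                  side = 3, line = 0, col = "firebrick")
  invisible(h)
}
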