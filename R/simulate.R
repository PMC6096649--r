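#' Configuration for the synthetic nested-oscillation EEG generator
#'
#' Parameterizes epochs containing a delta oscillation and a beta
#' oscillation embedded in 1/f background noise, with controllable
#' delta-phase -> beta-amplitude coupling (`pac_depth`), delta-beta
#' envelope correlation (`aac_rho`), and a non-uniform delta phase
#' distribution (`phase_bias`) for exercising the phase-clustering
#' correction.
#'
#' @param sampling_rate Native sampling rate in Hz (default 512).
#' @param epoch_duration Epoch length in seconds (default 8).
#' @param n_epochs Epochs per condition (default 6).
#' @param delta_band,beta_band Band edges in Hz; carriers sit at the band
#'   centres (2.5 Hz and 22 Hz).
#' @param pac_depth Fractional modulation of beta amplitude by delta phase,
#'   in \[0, 1\]. 0 injects no coupling.
#' @param aac_rho Target correlation of the slow delta and beta amplitude
#'   envelopes, in \[-1, 1\].
#' @param noise_sd SD of the 1/f background noise as a ratio of the delta
#'   oscillation amplitude.
#' @param phase_bias Strength of the non-uniform delta phase distribution,
#'   in \[0, 1\); 0 keeps phases uniform over full cycles.
#' @param preferred_phase Delta phase (radians) at which beta amplitude is
#'   maximal; also the clustering angle when `phase_bias > 0`.
#' @param delta_amp,beta_amp Oscillation amplitudes (defaults 1 and 0.5;
#'   beta is the weaker rhythm, as in scalp EEG).
#' @param env_depth Fractional SD of the slow multiplicative amplitude
#'   envelopes used by [generate_aac_epochs()] (default 0.3).
#' @param env_cutoff Upper frequency (Hz) of the slow envelopes (default
#'   0.5, i.e. envelopes vary over seconds).
#' @param noise_type `"pink"` (1/f spectral shaping, exponent 1) or
#'   `"white"`.
#' @param seed Integer seed; every generator is a pure function of its
#'   configuration including the seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(sampling_rate = 512, epoch_duration = 8,
                       n_epochs = 6L, delta_band = c(1, 4),
                       beta_band = c(14, 30), pac_depth = 0,
                       aac_rho = 0, noise_sd = 0.5, phase_bias = 0,
                       preferred_phase = 0, delta_amp = 1, beta_amp = 0.5,
                       env_depth = 0.3, env_cutoff = 0.5,
                       noise_type = c("pink", "white"), seed = NULL) {
  noise_type <- match.arg(noise_type)
  n_samples <- sampling_rate * epoch_duration
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("epoch_duration x sampling_rate must be an integer", call. = FALSE)
  }
  validate_band(delta_band, sampling_rate)
  validate_band(beta_band, sampling_rate)
  if (pac_depth < 0 || pac_depth > 1) {
    stop("`pac_depth` must lie in [0, 1]", call. = FALSE)
  }
  if (abs(aac_rho) > 1) stop("`aac_rho` must lie in [-1, 1]", call. = FALSE)
  if (phase_bias < 0 || phase_bias >= 1) {
    stop("`phase_bias` must lie in [0, 1)", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(sampling_rate = sampling_rate, epoch_duration = epoch_duration,
         n_epochs = as.integer(n_epochs), n_samples = as.integer(n_samples),
         delta_band = delta_band, beta_band = beta_band,
         delta_freq = mean(delta_band), beta_freq = mean(beta_band),
         pac_depth = pac_depth, aac_rho = aac_rho, noise_sd = noise_sd,
         phase_bias = phase_bias, preferred_phase = preferred_phase,
         delta_amp = delta_amp, beta_amp = beta_amp,
         env_depth = env_depth, env_cutoff = env_cutoff,
         noise_type = noise_type, seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %g Hz x %g s, %d epochs | pac_depth=%g aac_rho=%g noise_sd=%g phase_bias=%g\n",
    x$sampling_rate, x$epoch_duration, x$n_epochs, x$pac_depth,
    x$aac_rho, x$noise_sd, x$phase_bias))
  invisible(x)
}

# 1/f-shaped (or white) Gaussian noise, standardized to unit SD.
noise_series <- function(n, sampling_rate, type = "pink") {
  w <- stats::rnorm(n)
  if (type == "white") return(w)
  W <- stats::fft(w)
  k <- seq_len(n) - 1L
  kf <- pmin(k, n - k)                  # symmetric bin index
  f <- kf * sampling_rate / n
  s <- ifelse(f > 0, 1 / sqrt(f), 0)    # amplitude ~ f^(-1/2): power ~ 1/f
  x <- Re(stats::fft(W * s, inverse = TRUE) / n)
  x / stats::sd(x)
}

# Slowly varying standardized series: white noise restricted to |f| below
# `cutoff` in the frequency domain.
smooth_noise <- function(n, sampling_rate, cutoff) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * sampling_rate / n
  W[f > cutoff] <- 0
  x <- Re(stats::fft(W, inverse = TRUE) / n)
  s <- stats::sd(x)
  if (s < 1e-12) return(numeric(n))
  (x - mean(x)) / s
}

# Closed-form solution of the dwell-time oscillator: given a uniformly
# advancing phase `psi` (radians) and bias b in [0, 1), returns the warped
# phase u with density proportional to 1 / (1 - b cos(u)), i.e. clustered
# around 0. Solves dphi/dt = w (1 - b cos(phi)) via the half-angle
# substitution tan(u/2) = k tan(psi'/2), k = sqrt((1-b)/(1+b)), where
# psi' = psi * sqrt(1-b^2) is the rescaled uniform phase. The map is
# monotone and 2*pi-periodic, so it operates on wrapped phases.
warp_phase <- function(psi, b, rescale = TRUE) {
  if (b <= 0) return(psi)
  k <- sqrt((1 - b) / (1 + b))
  if (rescale) psi <- psi * sqrt(1 - b^2)
  base <- 2 * pi * round(psi / (2 * pi))       # keep the cycle count
  w <- psi - base
  base + 2 * atan2(k * sin(w / 2), cos(w / 2))
}

# Unwrap a wrapped phase sequence into a continuous one.
unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  phi[1] + c(0, cumsum(d))
}

# Core single-epoch synthesizer. `env_d` / `env_b` are multiplicative slow
# envelopes (1 = constant). Draws from the current RNG stream.
synth_epoch <- function(cfg, env_d = 1, env_b = 1, index = NA_integer_,
                        channel = NA_character_, condition = NA_character_) {
  n <- cfg$n_samples
  t <- (seq_len(n) - 1L) / cfg$sampling_rate
  phi <- if (cfg$phase_bias > 0) {
    # dwell-time oscillator dphi/dt = w0 (1 - b cos(phi - theta)): the
    # phase lingers near the preferred angle, giving a non-uniform phase
    # distribution whose harmonics stay inside the delta band (fundamental
    # w0 sqrt(1 - b^2)), so the bias survives band-pass filtering
    warp_phase(2 * pi * cfg$delta_freq * t, cfg$phase_bias) +
      cfg$preferred_phase
  } else {
    2 * pi * cfg$delta_freq * t + stats::runif(1, -pi, pi)
  }
  psi0 <- stats::runif(1, -pi, pi)
  delta <- cfg$delta_amp * env_d * cos(phi)
  beta_env <- cfg$beta_amp * env_b *
    (1 + cfg$pac_depth * cos(phi - cfg$preferred_phase))
  beta <- beta_env * cos(2 * pi * cfg$beta_freq * t + psi0)
  s <- delta + beta
  if (cfg$noise_sd > 0) {
    s <- s + cfg$noise_sd * cfg$delta_amp *
      noise_series(n, cfg$sampling_rate, cfg$noise_type)
  }
  ep <- epoch(s, cfg$sampling_rate, channel = channel,
              condition = condition, index = index)
  attr(ep, "env_delta") <- if (length(env_d) == 1L) rep(env_d, n) else env_d
  attr(ep, "env_beta") <- if (length(env_b) == 1L) rep(env_b, n) else env_b
  ep
}

#' Generate one epoch with delta-phase -> beta-amplitude coupling
#'
#' The epoch is a delta oscillation (random initial phase unless
#' `phase_bias > 0`) plus a beta carrier whose instantaneous amplitude is
#' `beta_amp * (1 + pac_depth * cos(phi_delta - preferred_phase))`, plus
#' 1/f background noise scaled by `noise_sd`. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param index,channel,condition Optional labels stored on the epoch.
#' @return An [epoch()].
#' @export
generate_pac_epoch <- function(cfg, index = NA_integer_,
                               channel = NA_character_,
                               condition = NA_character_) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed,
            synth_epoch(cfg, index = index, channel = channel,
                        condition = condition))
}

#' Generate epochs with correlated delta and beta amplitude envelopes
#'
#' Each epoch receives slowly varying multiplicative envelopes on the delta
#' and beta components, built from a shared latent envelope and independent
#' envelopes mixed so that the population correlation of the two equals
#' `cfg$aac_rho` (`aac_rho = 0` gives independent envelopes; `aac_rho = 1`
#' identical ones). Phase-amplitude coupling is injected on top when
#' `cfg$pac_depth > 0`, making this the general-purpose generator.
#'
#' @param cfg A [sim_config()].
#' @param n Number of epochs (default `cfg$n_epochs`).
#' @param channel,condition Optional labels.
#' @return List of [epoch()] objects; each carries its injected envelopes
#'   as attributes `env_delta` and `env_beta`.
#' @export
generate_aac_epochs <- function(cfg, n = cfg$n_epochs,
                                channel = NA_character_,
                                condition = NA_character_) {
  stopifnot(inherits(cfg, "sim_config"))
  rho <- cfg$aac_rho
  with_seed(cfg$seed, {
    lapply(seq_len(n), function(i) {
      zs <- smooth_noise(cfg$n_samples, cfg$sampling_rate, cfg$env_cutoff)
      z1 <- smooth_noise(cfg$n_samples, cfg$sampling_rate, cfg$env_cutoff)
      z2 <- smooth_noise(cfg$n_samples, cfg$sampling_rate, cfg$env_cutoff)
      a <- sqrt(abs(rho))
      b <- sqrt(1 - abs(rho))
      zd <- a * zs + b * z1
      zb <- sign(rho + (rho == 0)) * a * zs + b * z2
      env_d <- pmax(1 + cfg$env_depth * zd, 0.05)
      env_b <- pmax(1 + cfg$env_depth * zb, 0.05)
      synth_epoch(cfg, env_d = env_d, env_b = env_b, index = i,
                  channel = channel, condition = condition)
    })
  })
}

#' Inject a phase-clustering bias into an existing epoch
#'
#' Makes the delta waveform non-sinusoidal by a monotone warp of its phase
#' timeline (the dwell-time map of `warp_phase`), so that the extracted
#' delta phase-angle distribution becomes non-uniform -- clustered around
#' `cfg$preferred_phase` -- with clustering strength increasing in
#' `cfg$phase_bias`. The epoch's duration, sampling rate and first/last
#' sample times are unchanged, as is everything outside the delta band: the
#' delta component is isolated by zero-phase filtering, its analytic phase
#' is warped while its analytic amplitude is kept, and the result is added
#' back to the residual.
#'
#' @param ep An [epoch()].
#' @param cfg A [sim_config()] with `phase_bias > 0` supplying the delta
#'   band, warp strength and clustering angle.
#' @param delta_order Band-pass order used to isolate the delta component.
#' @return The biased [epoch()].
#' @export
apply_phase_clustering_bias <- function(ep, cfg, delta_order = 8L) {
  stopifnot(inherits(ep, "eeg_epoch"), inherits(cfg, "sim_config"))
  b <- cfg$phase_bias
  if (b <= 0) stop("`cfg$phase_bias` must be > 0", call. = FALSE)
  delta <- bandpass_zero_phase(ep, cfg$delta_band, delta_order,
                               demean = FALSE)
  residual <- ep$samples - delta$samples
  z <- analytic_signal(delta$samples)
  psi <- unwrap_phase(Arg(z)) - cfg$preferred_phase
  warped <- Mod(z) * cos(warp_phase(psi, b) + cfg$preferred_phase)
  epoch(residual + warped, ep$sampling_rate, channel = ep$channel,
        condition = ep$condition, index = ep$index)
}

#' Generate a synthetic cohort
#'
#' Builds a full study cohort: two groups of subjects (defaults 32 LSA and
#' 20 HSA), each with every condition, each condition holding
#' `n_epochs` epochs per channel. Per-subject seeds are derived
#' reproducibly from `master_seed`. Optionally attaches a synthetic
#' self-report covariate ("nervousness") rank-correlated with the
#' subject's injected coupling depth, to exercise the correlation layer.
#'
#' @param configs Either a single [sim_config()] used for every group x
#'   condition cell, or a named list `list(LSA = ., HSA = .)` whose
#'   elements are a single config or a named list of configs per condition.
#' @param n_subjects Named integer vector of group sizes (each >= 2).
#' @param conditions Character vector of condition labels.
#' @param channels Character vector of channel names.
#' @param master_seed Integer master seed.
#' @param covariate_rho If non-`NULL`, target correlation between the
#'   synthetic nervousness score and the subject's injected `pac_depth`.
#' @param pac_depth_sd Between-subject SD of the injected coupling depth
#'   (enables covariate correlation; default 0 = homogeneous).
#'
#' @return An object of class `cfc_cohort`: list with `subjects` (each a
#'   list `id`, `group`, `pac_depth`, `data[[condition]][[channel]]` =
#'   list of epochs), `conditions`, `channels`, `covariates` (data frame or
#'   `NULL`), and `provenance` (the configs and seeds).
#' @export
generate_cohort <- function(configs,
                            n_subjects = c(LSA = 32L, HSA = 20L),
                            conditions = c("resting",
                                           "early_anticipation",
                                           "late_anticipation",
                                           "early_recovery",
                                           "late_recovery"),
                            channels = c("F3", "Fz", "F4"),
                            master_seed = 1L,
                            covariate_rho = NULL,
                            pac_depth_sd = 0) {
  groups <- names(n_subjects)
  if (is.null(groups) || any(n_subjects < 2L)) {
    stop("`n_subjects` must be a named vector with every group size >= 2",
         call. = FALSE)
  }
  cfg_for <- function(group, condition) {
    if (inherits(configs, "sim_config")) return(configs)
    gc <- configs[[group]]
    if (is.null(gc)) stop(sprintf("missing config for group '%s'", group),
                          call. = FALSE)
    if (inherits(gc, "sim_config")) return(gc)
    cc <- gc[[condition]]
    if (is.null(cc)) {
      stop(sprintf("missing config for group '%s', condition '%s'",
                   group, condition), call. = FALSE)
    }
    cc
  }
  for (g in groups) for (cond in conditions) {
    stopifnot(inherits(cfg_for(g, cond), "sim_config"))
  }
  n_total <- sum(n_subjects)
  seeds <- derive_seeds(master_seed, n_total + 2L)
  cov_seed <- seeds[n_total + 1L]
  jitter_seed <- seeds[n_total + 2L]

  subj_group <- rep(groups, times = n_subjects)
  ids <- sprintf("S%03d", seq_len(n_total))
  jitter <- if (pac_depth_sd > 0) {
    with_seed(jitter_seed, stats::rnorm(n_total, 0, pac_depth_sd))
  } else numeric(n_total)

  subjects <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    g <- subj_group[i]
    ep_seeds <- derive_seeds(seeds[i], length(conditions) * length(channels))
    k <- 0L
    data <- list()
    depth_i <- NA_real_
    for (cond in conditions) {
      data[[cond]] <- list()
      for (ch in channels) {
        k <- k + 1L
        cfg <- cfg_for(g, cond)
        depth_i <- max(0, min(1, cfg$pac_depth + jitter[i]))
        cfg_i <- cfg
        cfg_i$pac_depth <- depth_i
        cfg_i$seed <- ep_seeds[k]
        data[[cond]][[ch]] <- generate_aac_epochs(cfg_i, channel = ch,
                                                  condition = cond)
      }
    }
    subjects[[i]] <- list(id = ids[i], group = g, pac_depth = depth_i,
                          data = data)
  }

  covariates <- NULL
  if (!is.null(covariate_rho)) {
    depths <- vapply(subjects, `[[`, numeric(1), "pac_depth")
    zs <- if (stats::sd(depths) > 0) scale(depths)[, 1] else
      stats::rnorm(n_total)
    covariates <- with_seed(cov_seed, data.frame(
      subject = ids, group = subj_group,
      nervousness = covariate_rho * zs +
        sqrt(max(0, 1 - covariate_rho^2)) * stats::rnorm(n_total)
    ))
  }

  structure(
    list(subjects = subjects, conditions = conditions, channels = channels,
         groups = groups, covariates = covariates,
         provenance = list(configs = configs, master_seed = master_seed,
                           subject_seeds = seeds[seq_len(n_total)],
                           n_subjects = n_subjects,
                           covariate_rho = covariate_rho,
                           pac_depth_sd = pac_depth_sd)),
    class = "cfc_cohort"
  )
}

#' @export
print.cfc_cohort <- function(x, ...) {
  sizes <- table(vapply(x$subjects, `[[`, character(1), "group"))
  cat(sprintf("<cfc_cohort> %d subjects (%s) x %d conditions x %d channels\n",
              length(x$subjects),
              paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "),
              length(x$conditions), length(x$channels)))
  invisible(x)
}
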