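test_that("config validation rejects out-of-range coupling parameters", {
  expect_error(sim_config(pac_depth = 1.2), "pac_depth")
  expect_error(sim_config(aac_rho = -1.5), "aac_rho")
  expect_error(sim_config(phase_bias = 1), "phase_bias")
  expect_error(sim_config(delta_band = c(4, 1)), "invalid band")
  expect_error(sim_config(beta_band = c(14, 300)), "Nyquist")
  expect_error(sim_config(sampling_rate = 100, epoch_duration = 0.305),
               "integer")
})

test_that("generators are pure functions of config and seed", {
  cfg <- sim_config(pac_depth = 0.4, aac_rho = 0.3, seed = 123)
  e1 <- generate_pac_epoch(cfg)
  e2 <- generate_pac_epoch(cfg)
  expect_identical(e1$samples, e2$samples)
  l1 <- generate_aac_epochs(cfg)
  l2 <- generate_aac_epochs(cfg)
  expect_identical(lapply(l1, `[[`, "samples"), lapply(l2, `[[`, "samples"))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_pac_epoch(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("without modulation or noise the beta envelope is constant", {
  # isolate the beta component (delta_amp = 0) so its Hilbert envelope is
  # exact: no modulation injected means a flat envelope
  cfg <- sim_config(pac_depth = 0, noise_sd = 0, delta_amp = 0, seed = 8)
  ep <- generate_pac_epoch(cfg)
  env <- Mod(crossfreq:::analytic_signal(ep$samples))
  expect_lt(sd(env) / mean(env), 1e-6)
  # with modulation the same construction has a strongly varying envelope
  cfg8 <- sim_config(pac_depth = 0.8, noise_sd = 0, delta_amp = 0, seed = 8)
  env8 <- Mod(crossfreq:::analytic_signal(generate_pac_epoch(cfg8)$samples))
  expect_gt(sd(env8) / mean(env8), 0.1)
})

test_that("injected coupling raises downstream dPAC above matched null epochs", {
  res <- vapply(1:100, function(s) {
    d8 <- sim_config(sampling_rate = 128, pac_depth = 0.8, seed = s)
    d0 <- sim_config(sampling_rate = 128, pac_depth = 0, seed = s)
    p8 <- preprocess_epochs(generate_aac_epochs(d8))
    p0 <- preprocess_epochs(generate_aac_epochs(d0))
    debiased_pac(p8$delta, p8$beta)$dpac_magnitude >
      debiased_pac(p0$delta, p0$beta)$dpac_magnitude
  }, logical(1))
  expect_gte(mean(res), 0.95)
})

test_that("downstream dPAC is monotone in the injected coupling depth", {
  depths <- c(0, 0.2, 0.5, 0.8)
  med <- vapply(depths, function(d) {
    median(vapply(1:50, function(s) {
      cfg <- sim_config(sampling_rate = 128, pac_depth = d, seed = 1000 + s)
      pre <- preprocess_epochs(generate_aac_epochs(cfg))
      debiased_pac(pre$delta, pre$beta)$dpac_magnitude
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("envelope mixing hits the target correlation", {
  # injected envelopes at rho = 0.9: sample r in [0.8, 0.97] nearly always
  rs9 <- vapply(1:100, function(s) {
    cfg <- sim_config(aac_rho = 0.9, noise_sd = 0, seed = 2000 + s)
    eps <- generate_aac_epochs(cfg)
    cor(unlist(lapply(eps, attr, "env_delta")),
        unlist(lapply(eps, attr, "env_beta")))
  }, numeric(1))
  expect_gte(mean(rs9 >= 0.8 & rs9 <= 0.97), 0.9)
  # rho = 1 with no noise: identical envelopes
  cfg1 <- sim_config(aac_rho = 1, noise_sd = 0, seed = 4)
  eps1 <- generate_aac_epochs(cfg1)
  expect_equal(cor(unlist(lapply(eps1, attr, "env_delta")),
                   unlist(lapply(eps1, attr, "env_beta"))), 1,
               tolerance = 1e-9)
  # rho = 0: recovered AAC centred on zero through the full chain
  r0 <- vapply(1:100, function(s) {
    cfg <- sim_config(sampling_rate = 128, aac_rho = 0, seed = 3000 + s)
    pre <- preprocess_epochs(generate_aac_epochs(cfg))
    amplitude_correlation(pre$delta, pre$beta)$r
  }, numeric(1))
  expect_gt(mean(r0), -0.05)
  expect_lt(mean(r0), 0.05)
})

test_that("downstream AAC rank-orders the injected envelope correlation", {
  rhos <- c(0, 0.3, 0.6, 0.9)
  med <- vapply(rhos, function(rho) {
    median(vapply(1:50, function(s) {
      cfg <- sim_config(sampling_rate = 128, aac_rho = rho, seed = 500 + s)
      pre <- preprocess_epochs(generate_aac_epochs(cfg))
      amplitude_correlation(pre$delta, pre$beta)$r
    }, numeric(1)))
  }, numeric(1))
  expect_equal(cor(rhos, med, method = "spearman"), 1)
})

test_that("phase-clustering bias produces non-uniform extracted phases, monotonically", {
  # unbiased: near-uniform phases over full cycles
  cfg0 <- sim_config(sampling_rate = 128, seed = 61)
  pre0 <- preprocess_epochs(generate_aac_epochs(cfg0))
  expect_lt(Mod(phase_clustering(unlist(lapply(pre0$delta, `[[`, "phase")))),
            0.05)
  pc_at <- function(b, s) {
    cfg <- sim_config(sampling_rate = 128, phase_bias = b, seed = s)
    pre <- preprocess_epochs(generate_aac_epochs(cfg))
    Mod(phase_clustering(unlist(lapply(pre$delta, `[[`, "phase"))))
  }
  cmp <- vapply(1:100, function(s) pc_at(0.8, s) > pc_at(0.2, s), logical(1))
  expect_gte(mean(cmp), 0.95)
})

test_that("the standalone bias warp preserves geometry and injects clustering", {
  cfg <- sim_config(noise_sd = 0.3, seed = 17)
  ep <- generate_pac_epoch(cfg)
  cfgb <- sim_config(noise_sd = 0.3, phase_bias = 0.8, seed = 17)
  epw <- apply_phase_clustering_bias(ep, cfgb)
  expect_equal(length(epw$samples), length(ep$samples))
  expect_equal(epw$sampling_rate, ep$sampling_rate)
  pre <- preprocess_epochs(list(epw))
  pre0 <- preprocess_epochs(list(ep))
  expect_gt(Mod(phase_clustering(pre$delta[[1]]$phase)),
            Mod(phase_clustering(pre0$delta[[1]]$phase)))
  expect_error(apply_phase_clustering_bias(ep, cfg), "phase_bias")
})

test_that("cohort geometry and determinism match the study design", {
  cfg <- sim_config(sampling_rate = 128, pac_depth = 0.3, seed = NULL)
  cohort <- generate_cohort(cfg, master_seed = 5)
  expect_length(cohort$subjects, 52L)
  groups <- vapply(cohort$subjects, `[[`, character(1), "group")
  expect_equal(sum(groups == "LSA"), 32L)
  expect_equal(sum(groups == "HSA"), 20L)
  s1 <- cohort$subjects[[1]]
  expect_named(s1$data, c("resting", "early_anticipation",
                          "late_anticipation", "early_recovery",
                          "late_recovery"))
  expect_named(s1$data$resting, c("F3", "Fz", "F4"))
  expect_length(s1$data$resting$F3, 6L)
  # identical cohort under the same master seed
  cohort2 <- generate_cohort(cfg, master_seed = 5)
  expect_identical(cohort$subjects[[13]]$data$resting$Fz[[2]]$samples,
                   cohort2$subjects[[13]]$data$resting$Fz[[2]]$samples)
  # different master seed differs
  cohort3 <- generate_cohort(cfg, n_subjects = c(LSA = 2L, HSA = 2L),
                             conditions = "resting", master_seed = 6)
  expect_false(identical(cohort$subjects[[1]]$data$resting$F3[[1]]$samples,
                         cohort3$subjects[[1]]$data$resting$F3[[1]]$samples))
  # missing condition config rejected
  expect_error(
    generate_cohort(list(LSA = list(resting = cfg), HSA = cfg),
                    conditions = c("resting", "early_anticipation"),
                    n_subjects = c(LSA = 2L, HSA = 2L)),
    "missing config")
})

test_that("a one-epoch cohort builds but epoch shuffling then fails clearly", {
  cfg <- sim_config(sampling_rate = 128, n_epochs = 1L, seed = NULL)
  cohort <- generate_cohort(cfg, n_subjects = c(LSA = 2L, HSA = 2L),
                            conditions = "resting", master_seed = 2)
  expect_length(cohort$subjects[[1]]$data$resting$F3, 1L)
  expect_error(estimate_cohort(cohort, n_perm = 10L), "single epoch")
})

test_that("synthetic covariates correlate with injected coupling depth", {
  cfg <- sim_config(sampling_rate = 128, pac_depth = 0.5, seed = NULL)
  cohort <- generate_cohort(cfg, n_subjects = c(LSA = 15L, HSA = 15L),
                            conditions = "resting", master_seed = 9,
                            covariate_rho = 0.9, pac_depth_sd = 0.15)
  expect_s3_class(cohort$covariates, "data.frame")
  depths <- vapply(cohort$subjects, `[[`, numeric(1), "pac_depth")
  expect_gt(cor(depths, cohort$covariates$nervousness,
                method = "spearman"), 0.5)
})
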