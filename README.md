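# crossfreq

Cross-frequency coupling analysis of epoched EEG: **debiased
phase-amplitude coupling (dPAC)** between frontal delta phase and beta
amplitude, with phase-clustering correction, epoch-shuffled surrogate
inference, and within-subject **amplitude-envelope correlation (AAC)** —
plus everything needed around the estimators: the zero-phase
Butterworth/Hilbert preprocessing chain, a synthetic nested-oscillation
EEG generator, a nonparametric statistics layer, and a cohort-level study
pipeline.

It is written for EEG researchers studying delta-beta coupling as a
correlate of affect regulation (e.g. comparing high vs. low socially
anxious groups across resting and stress-task conditions), and for anyone
who needs a tested, reproducible dPAC/AAC implementation in R.

## The estimators

With beta amplitude *a<sub>t</sub>* and delta phase *φ<sub>t</sub>* over
the *n* samples of six concatenated, edge-trimmed 8-s epochs:

    PAC  = (1/n) Σ a_t e^{iφ_t}
    PC   = (1/n) Σ e^{iφ_t}                    (phase clustering)
    dPAC = | (1/n) Σ a_t (e^{iφ_t} − PC) |     (debiased PAC)
    dPACz = (dPAC − mean(dPAC_null)) / sd(dPAC_null)

where `dPAC_null` comes from 1,000 random re-pairings of phase epochs with
amplitude epochs. Subtracting the phase-clustering vector PC removes the
spurious coupling that a non-uniform delta phase distribution induces in
raw PAC. AAC is the Pearson correlation of the delta and beta Hilbert
envelopes over the same concatenation. Metrics are computed per electrode
(F3, Fz, F4) and averaged into a frontal composite.

Preprocessing follows the standard chain: decimation 512 → 128 Hz,
zero-phase Butterworth band-pass (delta 1–4 Hz order 8, beta 14–30 Hz
order 34, doubled by forward-backward filtering, realized as cascaded
second-order sections for numerical stability), Hilbert analytic signal,
16 samples trimmed per edge.

## Worked example

```r
library(crossfreq)

# six 8-s epochs at 512 Hz with moderate coupling injected
cfg <- sim_config(pac_depth = 0.5, aac_rho = 0.4, seed = 11)
fit <- cfc_fit(generate_aac_epochs(cfg), n_perm = 1000, seed = 2)
summary(fit)
#> Delta-beta cross-frequency coupling
#>   n_epochs = 6, n_samples = 5952
#>   raw |PAC|      = 0.1108
#>   |PC|           = 0.0094
#>   dPAC           = 0.1132 (preferred phase 0.11 rad)
#>   surrogate null = 0.0428 (sd 0.0190)
#>   dPACz          = 3.710 (empirical p = 0.0030)
#>   AAC r          = 0.1921
```

Reading the output: the six epochs concatenate to 5,952 samples after
trimming; the delta phase distribution is essentially uniform
(|PC| ≈ 0.01), so dPAC ≈ |PAC|; the observed dPAC of 0.113 sits 3.7 null
standard deviations above the epoch-shuffled surrogate mean (coupling
clearly present, empirical p = 0.003); and the injected envelope
correlation of 0.4 is attenuated by band-limited noise to a recovered
AAC r of 0.19.

A full study — 32 + 20 subjects, five conditions, three channels, composite
metrics, within-/between-group tests and Benjamini–Yekutieli FDR per
section — is one call:

```r
study <- run_study(configs = sim_config(pac_depth = 0.3),
                   n_perm = 1000, master_seed = 1)
print(study)
write_study(study, "results/")   # estimates.tsv, table2_dpac.tsv, ...
```

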