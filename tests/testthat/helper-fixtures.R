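# Shared fixtures: everything is generated in code, nothing on disk.

# small cohort for fast end-to-end runs
tiny_cohort <- function(seed = 7, noise_sd_force = 0.5, n_subjects = 3,
                        n_days = 3, session_length_s = 10) {
  ref <- pilot_cohort_fsi()[seq_len(n_subjects), ]
  subjects <- lapply(seq_len(n_subjects), function(i) {
    subject_profile(ref$subject_id[i], ref$day1[i], ref$day15[i],
                    base_force_n = 50)
  })
  cohort_config(subjects, n_days = n_days,
                session_length_s = session_length_s,
                noise_sd_force = noise_sd_force, seed = seed)
}

with_fixed_seed <- function(seed, expr) srwalker:::with_seed(seed, expr)

snr_db <- function(clean, noisy) {
  10 * log10(sum(clean^2) / sum((noisy - clean)^2))
}

# draw one exact GP sample y ~ N(0, K + sn2 I) on inputs x
simulate_gp <- function(x, sf2, l, sn2, seed) {
  hp <- gp_hyperparams(sf2, l, sn2)
  K <- rbf_kernel(x, x, hp) + diag(sn2 + 1e-10, length(x))
  set.seed(seed)
  drop(t(chol(K)) %*% rnorm(length(x)))
}
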