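# Shared fixtures: tiny layouts, grids, and cohorts built in code.

# two-ROI layout in one hemisphere, n sub-ROIs each
tiny_layout <- function(n_seed = 2, n_target = 2, extra_targets = 0) {
  names <- c("STC_rh", "IFG_rh")
  nsub <- c(n_seed, n_target)
  if (extra_targets > 0) {
    names <- c(names, paste0("ROI", seq_len(extra_targets), "_rh"))
    nsub <- c(nsub, rep(n_target, extra_targets))
  }
  roi_layout(data.frame(name = names, hemi = "rh", n_sub = nsub,
                        stringsAsFactors = FALSE),
             seed_rois = "STC_rh")
}

# reduced two-band grid (alpha/low gamma, 2 bins each): keeps wavelet
# support short and TFR cheap
tiny_grid <- function() {
  frequency_grid(list(alpha = c(8, 12), lowgamma = c(31, 60)),
                 c(alpha = 2, lowgamma = 2))
}

tiny_bands <- function() list(alpha = c(8, 12), lowgamma = c(31, 60))

# small null cohort (no couplings, no impulse patterns)
null_cohort <- function(seed = 1, n_subjects = 3, epochs = 16,
                        epoch_length = 1.5, sample_rate = 250,
                        layout = tiny_layout()) {
  simulate_cohort(layout, ground_truth(), n_subjects = n_subjects,
                  epochs_per_condition = epochs,
                  epoch_length = epoch_length,
                  sample_rate = sample_rate, bands = tiny_bands(),
                  seed = seed)
}

# cohort with one strongly planted alpha coupling between the first seed
# and first target sub-ROI
planted_cohort <- function(seed = 1, kappa = 20, amplitude = 2,
                           n_subjects = 3, epochs = 16,
                           epoch_length = 1.5, sample_rate = 250,
                           layout = tiny_layout(), band = "alpha",
                           sign_flip_prob = 0.5) {
  target_first <- roi_subs(layout, "IFG_rh")[1]
  cp <- coupling_spec(1, target_first, band,
                      dphi = seq(-2.5, 2.5, length.out = 6),
                      kappa = kappa, amplitude = amplitude)
  simulate_cohort(layout, ground_truth(list(cp)),
                  n_subjects = n_subjects,
                  epochs_per_condition = epochs,
                  epoch_length = epoch_length,
                  sample_rate = sample_rate, bands = tiny_bands(),
                  fidelity_range = c(0.9, 1),
                  sign_flip_prob = sign_flip_prob, seed = seed)
}

# balanced design matrix of random features for decoder plumbing tests
random_design <- function(n_subjects = 17, n_cond = 6, n_sub = 4,
                          n_feat = 8, seed = 1) {
  set.seed(seed)
  n <- n_subjects * n_cond * n_sub
  list(
    x = matrix(rnorm(n * n_feat), n, n_feat),
    labels = factor(rep(rep(seq_len(n_cond), each = n_sub), n_subjects)),
    subjects = rep(seq_len(n_subjects), each = n_cond * n_sub),
    subsample = rep(seq_len(n_sub), n_subjects * n_cond)
  )
}

expect_all_finite <- function(x) {
  testthat::expect_true(all(is.finite(x)))
}
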