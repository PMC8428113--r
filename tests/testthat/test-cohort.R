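test_that("the same seed reproduces the cohort bit-identically", {
  co1 <- null_cohort(seed = 42, n_subjects = 2, epochs = 8,
                     epoch_length = 1, sample_rate = 250)
  co2 <- null_cohort(seed = 42, n_subjects = 2, epochs = 8,
                     epoch_length = 1, sample_rate = 250)
  expect_identical(co1$epochs, co2$epochs)
  expect_identical(co1$behavior, co2$behavior)
  co3 <- null_cohort(seed = 43, n_subjects = 2, epochs = 8,
                     epoch_length = 1, sample_rate = 250)
  expect_false(identical(co1$epochs, co3$epochs))
})

test_that("cohort structure matches the requested design", {
  co <- null_cohort(seed = 1, n_subjects = 3, epochs = 12,
                    epoch_length = 1.2, sample_rate = 250)
  expect_length(co$epochs, 3)
  expect_length(co$epochs[[1]], 6)           # six stimulus classes
  d <- dim(co$epochs[[2]][[4]])
  expect_equal(d, c(12, co$layout$n_total, 300))
  expect_all_finite(co$epochs[[1]][[1]])
  # impulse flags only for maintenance, half the epochs
  expect_equal(sum(co$impulse[[1]][[1]]), 6)
  enc <- simulate_cohort(tiny_layout(), ground_truth(), n_subjects = 2,
                         epochs_per_condition = 8, epoch_length = 1,
                         sample_rate = 250, phase = "encoding",
                         bands = tiny_bands(), seed = 2)
  expect_null(enc$impulse)
  expect_equal(min(enc$times), -0.5)         # origin at sound onset
})

test_that("coupling validation rejects bad specs", {
  lay <- tiny_layout()
  bad_band <- ground_truth(list(coupling_spec(1, 3, "delta")))
  expect_error(simulate_cohort(lay, bad_band, n_subjects = 2,
                               epochs_per_condition = 8,
                               epoch_length = 1, sample_rate = 250,
                               bands = tiny_bands(), seed = 1),
               "configured bands")
  bad_sub <- ground_truth(list(coupling_spec(1, 99, "alpha")))
  expect_error(simulate_cohort(lay, bad_sub, n_subjects = 2,
                               epochs_per_condition = 8,
                               epoch_length = 1, sample_rate = 250,
                               bands = tiny_bands(), seed = 1),
               "outside the layout")
})

test_that("deterministic pi/2 coupling without noise gives ImCoh near 1", {
  lay <- tiny_layout()
  cp <- coupling_spec(1, 3, "alpha", dphi = rep(pi / 2, 6),
                      kappa = Inf, amplitude = 1)
  co <- simulate_cohort(lay, ground_truth(list(cp)), n_subjects = 1,
                        epochs_per_condition = 8, epoch_length = 2,
                        sample_rate = 250, bands = tiny_bands(),
                        noise_sd = 0, sign_flip_prob = 0,
                        fidelity_range = c(1, 1), seed = 5)
  g <- frequency_grid(list(alpha = c(8, 12)), c(alpha = 3))
  s1 <- morlet_tfr(co$epochs[[1]][[1]][, 1, ], 250, g, times = co$times)
  s3 <- morlet_tfr(co$epochs[[1]][[1]][, 3, ], 250, g, times = co$times)
  ic <- imcoh(s1, s3)
  mid <- s1$valid[1, ] & s1$valid[3, ]
  expect_equal(mean(ic[, mid]), 1, tolerance = 1e-2)
})

test_that("behavior link is exact without noise and monotone in fidelity", {
  tr <- ground_truth(behavior_link = list(intercept = 0.7, slope = 0,
                                          noise_sd = 0))
  b <- simulate_behavior(tr, fidelity = c(0.2, 0.5, 0.9), seed = 1)
  expect_equal(b$p_correct, rep(0.7, 3))
  tr2 <- ground_truth(behavior_link = list(intercept = 0.5, slope = 0.4,
                                           noise_sd = 0))
  fid <- runif(10, 0, 1)
  b2 <- simulate_behavior(tr2, fid, seed = 1)
  expect_equal(order(b2$p_correct), order(fid))
})

test_that("fidelity-behavior correlation matches the attenuation formula", {
  # linear link plus noise: cor = slope*sd(f) / sqrt(slope^2 var(f) + s^2)
  slope <- 0.3; noise_sd <- 0.05
  tr <- ground_truth(behavior_link = list(intercept = 0.6, slope = slope,
                                          noise_sd = noise_sd))
  set.seed(10)
  fid <- runif(4000, 0.6, 1)
  b <- simulate_behavior(tr, fid, seed = 11)
  theo <- slope * sd(fid) /
    sqrt(slope^2 * var(fid) + noise_sd^2)
  expect_equal(stats::cor(fid, b$p_correct), theo, tolerance = 0.05)
})

test_that("von Mises sampler matches theoretical resultant length", {
  set.seed(3)
  for (kappa in c(0.5, 2, 8)) {
    th <- rvonmises(4000, mu = 0.7, kappa = kappa)
    r_hat <- Mod(mean(exp(1i * th)))
    r_theo <- besselI(kappa, 1) / besselI(kappa, 0)
    expect_equal(r_hat, r_theo, tolerance = 0.05)
    expect_equal(Arg(mean(exp(1i * th))), 0.7, tolerance = 0.1)
  }
  expect_equal(rvonmises(3, 1.2, Inf), rep(1.2, 3))
})

test_that("sign alignment restores a common sign within a ROI", {
  lay <- roi_layout(data.frame(name = "STC_rh", hemi = "rh", n_sub = 6),
                    "STC_rh")
  # couple all sub-ROIs to a strong common alpha driver so the reference
  # waveform is meaningful
  cps <- lapply(2:6, function(r) {
    coupling_spec(1, r, "alpha", dphi = rep(0.2, 6), kappa = Inf,
                  amplitude = 4)
  })
  co <- simulate_cohort(lay, ground_truth(cps), n_subjects = 1,
                        epochs_per_condition = 8, epoch_length = 1,
                        sample_rate = 250, bands = tiny_bands(),
                        noise_sd = 0.3, seed = 21)
  al <- align_signs(co)
  # after alignment every coupled sub-ROI correlates positively with the
  # hub sub-ROI on the concatenated single-epoch series
  arr <- al$epochs[[1]][[1]]
  m <- matrix(aperm(arr, c(2, 3, 1)), dim(arr)[2])
  cors <- as.vector(stats::cor(t(m[2:6, ]), m[1, ]))
  expect_true(all(cors > 0))
})
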