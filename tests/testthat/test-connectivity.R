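# independent elementwise implementation of the ImCoh definition
imcoh_oracle <- function(sx, sy) {
  K <- dim(sx)[1]; F_len <- dim(sx)[2]; T_len <- dim(sx)[3]
  out <- matrix(0, F_len, T_len)
  for (f in seq_len(F_len)) for (t in seq_len(T_len)) {
    cross <- 0 + 0i; px <- 0; py <- 0
    for (k in seq_len(K)) {
      cross <- cross + sx[k, f, t] * Conj(sy[k, f, t])
      px <- px + Mod(sx[k, f, t])^2
      py <- py + Mod(sy[k, f, t])^2
    }
    out[f, t] <- Im(cross / K) / sqrt(px / K * py / K)
  }
  out
}

rand_tensor <- function(K = 20, F_len = 2, T_len = 25) {
  array(complex(real = rnorm(K * F_len * T_len),
                imaginary = rnorm(K * F_len * T_len)),
        dim = c(K, F_len, T_len))
}

test_that("imcoh satisfies its algebraic identities", {
  set.seed(1)
  sx <- rand_tensor(); sy <- rand_tensor()
  # self-coherence is real -> ImCoh identically 0
  expect_true(all(imcoh(sx, sx) == 0))
  # 90-degree rotation of the same signal -> unit imaginary coherence
  expect_equal(imcoh(sx, sx * exp(-1i * pi / 2)),
               matrix(1, 2, 25), tolerance = 1e-12)
  # bounded with no tolerance
  expect_true(all(abs(imcoh(sx, sy)) <= 1))
  # exact antisymmetry
  expect_identical(imcoh(sx, sy), -imcoh(sy, sx))
  # positive real gain invariance; sign flip flips sign
  expect_equal(imcoh(2.7 * sx, 0.3 * sy), imcoh(sx, sy),
               tolerance = 1e-12)
  expect_equal(imcoh(-sx, sy), -imcoh(sx, sy), tolerance = 1e-12)
  expect_error(imcoh(sx[1, , , drop = FALSE], sy[1, , , drop = FALSE]),
               "fewer than 2")
  z <- sx; z[, 1, 1] <- 0
  expect_error(imcoh(z, sy), "zero power")
})

test_that("imcoh matches the brute-force oracle and the lagged-driver
           expectation", {
  set.seed(7)
  K <- 200
  drv <- rand_tensor(K, 1, 30)
  nx <- rand_tensor(K, 1, 30); ny <- rand_tensor(K, 1, 30)
  sx <- drv + nx
  sy <- drv * exp(-1i * pi / 4) + ny
  got <- imcoh(sx, sy)
  expect_lt(max(abs(got - imcoh_oracle(sx, sy))), 1e-10)
  # expectation: coherence magnitude 1/2 (signal and noise equal power)
  # times sin(pi/4)
  expect_equal(mean(got), 0.5 * sin(pi / 4), tolerance = 0.05)
})

test_that("epoch equalization reduces every condition to the minimum", {
  co <- null_cohort(seed = 2, n_subjects = 1, epochs = 12,
                    epoch_length = 1, sample_rate = 250)
  counts <- c(10, 8, 12, 9, 8, 11)
  for (cc in 1:6) {
    co$epochs[[1]][[cc]] <-
      co$epochs[[1]][[cc]][seq_len(counts[cc]), , , drop = FALSE]
    co$impulse[[1]][[cc]] <- co$impulse[[1]][[cc]][seq_len(counts[cc])]
  }
  eq <- equalize_epochs(co, seed = 5)
  expect_equal(unname(vapply(eq$epochs[[1]], function(a) dim(a)[1], 0L)),
               rep(8L, 6))
  # condition already at the minimum is untouched
  expect_identical(eq$epochs[[1]][[2]], co$epochs[[1]][[2]])
  # seeded selection is reproducible
  eq2 <- equalize_epochs(co, seed = 5)
  expect_identical(eq$epochs, eq2$epochs)
  # already-equal cohorts pass through unchanged
  co_eq <- null_cohort(seed = 3, n_subjects = 1, epochs = 8,
                       epoch_length = 1, sample_rate = 250)
  expect_identical(equalize_epochs(co_eq, seed = 1)$epochs,
                   co_eq$epochs)
})

test_that("feature matrices have seed-major sub-ROI pair columns", {
  lay <- tiny_layout(n_seed = 2, n_target = 3)
  co <- null_cohort(seed = 4, n_subjects = 2, epochs = 8,
                    epoch_length = 1.5, sample_rate = 250, layout = lay)
  ft <- connectivity_features(co, tiny_grid(),
                              windows = list(mid = c(0.5, 1.25)),
                              seed = 9)
  expect_setequal(names(ft$tests),
                  paste0("STC_rh-IFG_rh|", c("alpha", "lowgamma"),
                         "|mid"))
  m <- ft$tests[["STC_rh-IFG_rh|alpha|mid"]]
  expect_equal(dim(m), c(2 * 6 * 4, 2 * 3))
  expect_true(all(abs(m) <= 1))
  expect_equal(nrow(ft$meta), nrow(m))
  # unequalized cohorts are rejected
  co2 <- co
  co2$epochs[[1]][[1]] <- co2$epochs[[1]][[1]][1:6, , , drop = FALSE]
  expect_error(connectivity_features(co2, tiny_grid()), "equalized")
})

test_that("band/window averages equal a per-bin brute-force oracle", {
  lay <- tiny_layout()
  co <- planted_cohort(seed = 6, n_subjects = 1, epochs = 8,
                       layout = lay, sign_flip_prob = 0)
  g <- tiny_grid()
  win <- list(mid = c(0.5, 1.25))
  ft <- connectivity_features(co, g, windows = win, seed = 31)
  # recompute subject 1 / condition 2 / quarter 1, feature (1, 1)
  arr <- co$epochs[[1]][[2]]
  set.seed(derive_seed(31, "quarters", 1, 2))
  perm <- sample(dim(arr)[1])
  q1 <- perm[1:2]
  s1 <- morlet_tfr(arr[, 1, ], co$sfreq, g, times = co$times)
  s3 <- morlet_tfr(arr[, 3, ], co$sfreq, g, times = co$times)
  ic <- imcoh(s1$coef[q1, , , drop = FALSE], s3$coef[q1, , , drop = FALSE])
  sel_bins <- band_bins(g, "alpha")
  sel_t <- co$times >= 0.5 & co$times < 1.25
  mask <- s1$valid
  vals <- c()
  for (b in sel_bins) for (t in which(sel_t)) {
    if (mask[b, t]) vals <- c(vals, ic[b, t])
  }
  row <- which(ft$meta$subject == "S01" & ft$meta$condition == 2 &
                 ft$meta$subsample == 1)
  expect_equal(ft$tests[["STC_rh-IFG_rh|alpha|mid"]][row, 1], mean(vals),
               tolerance = 1e-12)
})

test_that("null features shrink with quarter size like 1/sqrt(n)", {
  lay <- tiny_layout(n_seed = 1, n_target = 1)
  mean_abs <- function(epochs) {
    vals <- c()
    for (s in 1:4) {
      co <- null_cohort(seed = 100 + s, n_subjects = 1, epochs = epochs,
                        epoch_length = 1.5, sample_rate = 250,
                        layout = lay)
      ft <- connectivity_features(co, tiny_grid(),
                                  windows = list(mid = c(0.5, 1.25)),
                                  seed = s)
      vals <- c(vals, abs(ft$tests[[1]]))
    }
    mean(vals)
  }
  m8 <- mean_abs(8)    # quarters of 2
  m32 <- mean_abs(32)  # quarters of 8
  expect_gt(m8 / m32, 1.3)
  expect_lt(m8 / m32, 3.2)
})

test_that("planted-pair ImCoh increases monotonically with kappa", {
  lay <- tiny_layout(n_seed = 1, n_target = 1)
  mean_ic <- function(kappa) {
    co <- planted_cohort(seed = 50, kappa = kappa, amplitude = 2,
                         n_subjects = 1, epochs = 24, layout = lay,
                         sign_flip_prob = 0)
    # fixed lag pi/2 for every condition isolates the kappa effect
    cp <- coupling_spec(1, 2, "alpha", dphi = rep(pi / 2, 6),
                        kappa = kappa, amplitude = 2)
    co <- simulate_cohort(lay, ground_truth(list(cp)), n_subjects = 1,
                          epochs_per_condition = 24, epoch_length = 1.5,
                          sample_rate = 250, bands = tiny_bands(),
                          fidelity_range = c(1, 1), sign_flip_prob = 0,
                          seed = 50)
    ft <- connectivity_features(co, tiny_grid(),
                                windows = list(mid = c(0.5, 1.25)),
                                seed = 1)
    mean(ft$tests[["STC_rh-IFG_rh|alpha|mid"]])
  }
  ics <- vapply(c(0.5, 2, 8), mean_ic, 0)
  expect_true(all(diff(ics) > 0))
})
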