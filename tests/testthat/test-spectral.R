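# independent time-domain convolution oracle for the Morlet transform
morlet_oracle <- function(x, sfreq, f, n_cycles = 7) {
  T_len <- length(x)
  hw <- ceiling(n_cycles / (2 * f) * sfreq)
  tt <- (-hw:hw) / sfreq
  w <- exp(-tt^2 / (2 * (n_cycles / (2 * pi * f))^2)) *
    exp(1i * 2 * pi * f * tt)
  w <- w / sqrt(sum(Mod(w)^2))
  out <- complex(real = rep(0, T_len))
  for (t in seq_len(T_len)) {
    acc <- 0 + 0i
    for (u in -hw:hw) {
      src <- t - u
      if (src >= 1 && src <= T_len) acc <- acc + w[u + hw + 1] * x[src]
    }
    out[t] <- acc
  }
  out
}

test_that("frequency grid respects band structure and bin counts", {
  g <- frequency_grid()
  expect_length(g$freqs, 69)  # 5 + 5 + 18 + 20 + 21
  expect_equal(as.integer(table(g$band)[c("theta", "alpha", "beta",
                                          "lowgamma", "highgamma")]),
               c(5L, 5L, 18L, 20L, 21L))
  expect_true(all(diff(g$freqs) > 0))
  for (b in names(g$bands)) {
    f <- g$freqs[band_bins(g, b)]
    expect_true(all(f >= g$bands[[b]][1] - 1e-9 &
                      f <= g$bands[[b]][2] + 1e-9))
  }
  expect_error(frequency_grid(list(a = c(3, 10), b = c(8, 20)),
                              c(a = 2, b = 2)), "non-overlapping")
})

test_that("morlet transform is linear and zero on zero input", {
  g <- tiny_grid()
  x <- matrix(rnorm(3 * 250), 3, 250)
  st <- morlet_tfr(x, 250, g)
  st0 <- morlet_tfr(matrix(0, 3, 250), 250, g)
  expect_true(all(Mod(st0$coef) == 0))
  st3 <- morlet_tfr(3.5 * x, 250, g)
  expect_equal(st3$coef, 3.5 * st$coef, tolerance = 1e-12)
  expect_error(morlet_tfr(matrix(c(1, NA), 1, 2), 250, g),
               "non-finite")
})

test_that("morlet coefficients match the direct convolution oracle", {
  set.seed(8)
  x <- rnorm(500)
  for (f in c(6, 20)) {
    st <- morlet_tfr(matrix(x, 1), 250, f)
    oracle <- morlet_oracle(x, 250, f)
    expect_lt(max(Mod(st$coef[1, 1, ] - oracle)) / max(Mod(oracle)),
              1e-6)
  }
})

test_that("a pure cosine produces a sharp ridge at its frequency", {
  sfreq <- 250
  t <- (0:(2 * sfreq - 1)) / sfreq   # 2 s: supports the 5 Hz wavelet
  f_star <- 10
  x <- matrix(cos(2 * pi * f_star * t), 1)
  freqs <- c(5, 10, 20)  # one octave below/above
  st <- morlet_tfr(x, sfreq, freqs)
  mid <- which(apply(st$valid, 2, all))  # valid for every wavelet
  amp <- vapply(1:3, function(j) mean(Mod(st$coef[1, j, mid])), 0)
  expect_equal(which.max(amp), 2L)
  expect_gte(amp[2] / amp[1], 10)
  expect_gte(amp[2] / amp[3], 10)
})

test_that("edge mask covers half the wavelet support", {
  st <- morlet_tfr(matrix(rnorm(500), 1), 250, c(5, 25), n_cycles = 7)
  hw5 <- ceiling(7 / (2 * 5) * 250)
  expect_false(any(st$valid[1, c(seq_len(hw5), 500 - seq_len(hw5) + 1)]))
  expect_true(all(st$valid[1, (hw5 + 1):(500 - hw5)]))
  # lower frequency -> wider mask
  expect_gt(sum(st$valid[2, ]), sum(st$valid[1, ]))
  # support longer than the epoch -> fully masked
  st2 <- morlet_tfr(matrix(rnorm(100), 1), 250, 3, n_cycles = 7)
  expect_false(any(st2$valid))
})

test_that("masked samples never enter band power averages", {
  g <- tiny_grid()
  x <- matrix(rnorm(4 * 300), 4, 300)
  st <- morlet_tfr(x, 250, g)
  bp <- band_power_timecourse(st, g)
  # poison the masked coefficients: the result must not change
  st_poison <- st
  for (j in seq_along(st$freqs)) {
    st_poison$coef[, j, !st$valid[j, ]] <- NaN
  }
  bp2 <- band_power_timecourse(st_poison, g)
  expect_identical(is.na(bp), is.na(bp2))
  expect_equal(bp[!is.na(bp)], bp2[!is.na(bp2)])
})

test_that("wavelet energy response varies smoothly across the grid", {
  # L2-normalized wavelets respond to a unit sinusoid with energy
  # proportional to 1/f; after compensating that known trend, the
  # residual scalloping between neighboring grid bins must stay small
  sfreq <- 250
  t <- (0:(4 * sfreq - 1)) / sfreq
  g <- frequency_grid(list(alpha = c(8, 12)), c(alpha = 5))
  probe <- seq(9, 11, by = 0.125)    # interior bins: 8.85, 9.8, 10.84
  resp <- vapply(probe, function(f) {
    st <- morlet_tfr(matrix(sin(2 * pi * f * t), 1), sfreq, g)
    mid <- apply(st$valid, 2, all)
    f * mean(Mod(st$coef[1, , mid])^2)
  }, 0)
  expect_lt((max(resp) - min(resp)) / mean(resp), 0.2)
})

test_that("multitaper spectra are flat for white noise", {
  set.seed(12)
  x <- matrix(rnorm(250 * 400), 250, 400)
  p <- multitaper_power(x, sfreq = 200, fmin = 5, fmax = 90)
  avg <- colMeans(p)
  # bin into 10 coarse bands; flat within 3 dB
  bin <- cut(seq_along(avg), 10)
  e <- tapply(avg, bin, mean)
  expect_lt(max(e) / min(e), 2)
})

test_that("multitaper power concentrates at a sinusoid's frequency and
           satisfies Parseval", {
  sfreq <- 200; A <- 1.5; f_star <- 40
  t <- (0:511) / sfreq
  x <- matrix(A * sin(2 * pi * f_star * t), 1)
  p <- multitaper_power(x, sfreq, fmin = 2, fmax = 95,
                        time_bandwidth = 4)
  freqs <- attr(p, "freqs"); df <- attr(p, "df")
  total <- sum(p[1, ]) * df
  expect_equal(total, A^2 / 2, tolerance = 0.1)
  # >= 90% of power within +-2 Rayleigh-widened bandwidths of f*
  w <- 4 / (512 / sfreq)  # NW / T in Hz
  inband <- abs(freqs - f_star) <= 2 * w
  expect_gte(sum(p[1, inband]) / sum(p[1, ]), 0.9)
  # periodogram oracle for the total
  X <- fft(x[1, ])
  keep <- which(freqs[1] <= (0:511) * sfreq / 512 &
                  (0:511) * sfreq / 512 <= 95)
  perio <- sum(Mod(X[keep])^2 / 512 * 2 / sfreq) * df
  expect_equal(total, perio, tolerance = 0.1)
})

test_that("multitaper power handles edge cases", {
  expect_equal(max(multitaper_power(matrix(0, 2, 128), 100,
                                    fmin = 3, fmax = 45)), 0)
  expect_error(multitaper_power(matrix(rnorm(128), 1), 100,
                                fmin = 3, fmax = 60), "Nyquist")
  # epoch-order invariance
  set.seed(2)
  x <- matrix(rnorm(5 * 128), 5, 128)
  p1 <- multitaper_power(x, 100, fmin = 3, fmax = 45)
  p2 <- multitaper_power(x[5:1, ], 100, fmin = 3, fmax = 45)
  expect_equal(p1[5:1, ], p2, ignore_attr = TRUE)
})

test_that("power subsamples partition and average correctly", {
  spec_row <- runif(16)
  x <- matrix(spec_row, 8, 16, byrow = TRUE)  # identical epochs
  ps <- power_subsamples(x, n_groups = 4, seed = 1)
  expect_equal(dim(ps), c(4L, 16L))
  for (i in 1:4) expect_equal(ps[i, ], spec_row)
  # reproducible partition
  set.seed(99)
  y <- matrix(rnorm(12 * 5), 12, 5)
  g1 <- power_subsamples(y, seed = 7)
  g2 <- power_subsamples(y, seed = 7)
  expect_identical(g1, g2)
  # grand mean identity when group sizes exhaust the epochs
  g3 <- power_subsamples(y, n_groups = 4, seed = 3)
  expect_equal(colMeans(g3), colMeans(y), tolerance = 1e-12)
  expect_error(power_subsamples(y[1:3, ], n_groups = 4), "fewer epochs")
})

test_that("relative power change matches its definition", {
  times <- seq(-0.5, 2.495, by = 0.005)
  const <- rep(2, length(times))
  expect_equal(relative_power_change(const, times), 0)
  doubled <- ifelse(times < 0, 1, 2)
  expect_equal(relative_power_change(doubled, times,
                                     baseline = c(-0.4, -0.2),
                                     analysis = c(0, 2)), 1)
  # arbitrary course vs independent recomputation
  set.seed(5)
  p <- runif(length(times), 0.5, 2)
  got <- relative_power_change(p, times)
  bix <- times >= -0.4 & times < -0.2
  aix <- times >= 0 & times < 2
  expect_equal(got, (mean(p[aix]) - mean(p[bix])) / mean(p[bix]))
  expect_error(relative_power_change(rep(0, length(times)), times),
               "positive")
  expect_error(relative_power_change(p, times, baseline = c(5, 6)),
               "outside")
})
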