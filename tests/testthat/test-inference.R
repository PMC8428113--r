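test_that("label-permutation nulls center on chance and reproduce", {
  d <- random_design(n_subjects = 4, n_feat = 4, seed = 1)
  spec <- decoder_spec(n_repeats = 5, seed = 2)
  nd <- label_permutation_null(d$x, d$labels, spec, n_perm = 30,
                               splits_per_perm = 2, seed = 3)
  expect_length(nd$values, 30)
  expect_lt(abs(mean(nd$values) - 1 / 6), 0.05)
  nd2 <- label_permutation_null(d$x, d$labels, spec, n_perm = 30,
                                splits_per_perm = 2, seed = 3)
  expect_identical(nd$values, nd2$values)
  # more permutations than distinct label orders is an error
  tiny_x <- matrix(rnorm(8), 4, 2)
  tiny_lbl <- factor(c(1, 1, 2, 2))
  expect_error(label_permutation_null(tiny_x, tiny_lbl, spec,
                                      n_perm = 10, splits_per_perm = 1),
               "distinct label permutations")
})

test_that("null spread matches a binomial-plus-split oracle on a
           2-class toy", {
  # random-label training cannot beat chance; the accuracy of one split
  # with n_test Bernoulli(1/2) trials has SD sqrt(0.25 / n_test)
  set.seed(5)
  n <- 16
  x <- matrix(rnorm(n * 3), n, 3)
  lbl <- factor(rep(1:2, each = n / 2))
  spec <- decoder_spec(n_repeats = 1, seed = 6)
  nd <- label_permutation_null(x, lbl, spec, n_perm = 2000,
                               splits_per_perm = 1, seed = 7)
  n_test <- n - 2 * round(8 * 0.75)
  oracle_sd <- sqrt(0.25 / n_test)
  expect_lt(abs(sd(nd$values) - oracle_sd) / oracle_sd, 0.2)
  expect_lt(abs(mean(nd$values) - 0.5), 3 * oracle_sd / sqrt(2000))
})

test_that("max-stat correction follows its p-value conventions", {
  nulls <- rbind(t1 = c(0.2, 0.3, 0.25, 0.22), t2 = c(0.1, 0.15, 0.2, 0.12))
  # observed below the pooled minimum -> p = 1 everywhere
  rep1 <- maxstat_correct(c(t1 = 0.05, t2 = 0.01), nulls)
  expect_equal(rep1$table$p, c(1, 1))
  # observed above the pooled maximum -> p = 1 / (n_perm + 1)
  rep2 <- maxstat_correct(c(t1 = 0.9, t2 = 0.95), nulls)
  expect_equal(rep2$table$p, c(1 / 5, 1 / 5))
  expect_error(maxstat_correct(c(a = 1),
                               list(structure(list(values = 1:3,
                                                   n_perm = 3),
                                              class = "null_distribution"),
                                    structure(list(values = 1:4,
                                                   n_perm = 4),
                                              class = "null_distribution"))),
               "share n_perm")
})

test_that("max-stat p-values are monotone and never anti-conservative", {
  set.seed(8)
  nulls <- matrix(runif(6 * 200, 0.1, 0.3), 6, 200)
  obs <- sort(runif(6, 0.05, 0.4))
  names(obs) <- paste0("t", 1:6)
  pooled <- maxstat_correct(obs, nulls, pooling = "max")
  # monotone non-increasing p in the observed statistic
  expect_true(all(diff(pooled$table$p) <= 0))
  # pooled correction at least as conservative as per-test
  pertest <- maxstat_correct(obs, nulls, pooling = "per-test")
  expect_true(all(pooled$table$p >= pertest$table$p))
  # pooling over 60 tests: one pooled value per permutation
  nulls60 <- matrix(runif(60 * 50), 60, 50)
  rep60 <- maxstat_correct(setNames(runif(60), paste0("c", 1:60)),
                           nulls60)
  expect_length(rep60$pooled_null, 50)
  expect_equal(rep60$n_perm, 50)
})

test_that("impulse model degenerates gracefully at exact chance", {
  tab <- expand.grid(subject = paste0("S", 1:4),
                     band_cf = c(5, 10, 20), impulse = c(TRUE, FALSE))
  tab$accuracy <- 1 / 6
  res <- impulse_effect_model(tab)
  expect_true(res$degenerate)
  expect_equal(res$table$estimate, rep(0, 3))
  expect_equal(res$table$p_bonf, rep(1, 3))
  expect_error(impulse_effect_model(tab[tab$subject == "S1", ]),
               "2 subjects")
})

test_that("impulse model recovers a planted effect with near-nominal
           coverage", {
  # balanced within-subject design: beta_impulse = 0.05, subject
  # intercept SD 0.02, residual SD 0.03
  gen <- function(seed) {
    set.seed(seed)
    tab <- expand.grid(subject = paste0("S", 1:10),
                       band_cf = c(4.6, 9.8, 19.8, 43, 85),
                       impulse = c(TRUE, FALSE))
    u <- rnorm(10, 0, 0.02)
    tab$accuracy <- 1 / 6 + 0.05 * tab$impulse +
      0.01 * log2(tab$band_cf) +
      u[as.integer(factor(tab$subject))] + rnorm(nrow(tab), 0, 0.03)
    tab
  }
  cover <- 0L
  for (s in 1:200) {
    res <- impulse_effect_model(gen(s))
    row <- res$table[res$table$term == "impulseTRUE", ]
    ci <- row$estimate + c(-1, 1) * qt(0.975, row$df) * row$se
    if (ci[1] <= 0.05 && 0.05 <= ci[2]) cover <- cover + 1L
  }
  expect_gte(cover, 186)  # >= 93% of 200 simulations
})

test_that("impulse model fixed effects equal OLS on a balanced table", {
  # balanced within-subject designs make the mixed-model fixed-effect
  # estimates coincide with ordinary least squares
  set.seed(9)
  tab <- expand.grid(subject = paste0("S", 1:6),
                     band_cf = c(5, 10, 20), impulse = c(TRUE, FALSE))
  tab$accuracy <- 1 / 6 + 0.04 * tab$impulse + rnorm(nrow(tab), 0, 0.02)
  res <- impulse_effect_model(tab)
  ols <- lm(I(accuracy - 1 / 6) ~ impulse + log2(band_cf), data = tab)
  expect_equal(res$table$estimate, unname(coef(ols)), tolerance = 1e-6)
})

test_that("stepwise model growth keeps only supported terms", {
  set.seed(10)
  tab <- expand.grid(subject = paste0("S", 1:8),
                     band_cf = c(5, 10, 20, 45, 90),
                     impulse = c(TRUE, FALSE))
  tab$accuracy <- 1 / 6 + 0.1 * tab$impulse + rnorm(nrow(tab), 0, 0.02)
  res <- impulse_effect_model(tab, method = "stepwise")
  expect_true("impulseTRUE" %in% res$table$term)
  expect_false("log2_cf" %in% res$table$term)
})

test_that("SVR permutation null flags only both-window predictors", {
  set.seed(11)
  n_subj <- 8
  subsample <- rep(1:4, n_subj)
  x_sig_e <- matrix(rnorm(n_subj * 4 * 6), n_subj * 4, 6)
  x_sig_l <- matrix(rnorm(n_subj * 4 * 6), n_subj * 4, 6)
  x_noise <- matrix(rnorm(n_subj * 4 * 6), n_subj * 4, 6)
  behavior <- pmin(pmax(0.5 + 0.4 * x_sig_e[, 1], 0), 1)
  x_sig_l[, 1] <- x_sig_e[, 1]          # same signal in both windows
  tests <- list(
    coupled = list(early = x_sig_e, late = x_sig_l),
    noise = list(early = x_noise, late = matrix(rnorm(n_subj * 4 * 6),
                                                n_subj * 4, 6))
  )
  out <- svr_permutation_null(tests, behavior, subsample, n_perm = 120,
                              seed = 12)
  expect_true(out$report$table$significant[1])
  expect_false(out$report$table$significant[2])
  expect_length(out$null$values, 120)
  out2 <- svr_permutation_null(tests, behavior, subsample, n_perm = 120,
                               seed = 12)
  expect_identical(out$null$values, out2$null$values)
  expect_warning(svr_permutation_null(tests, behavior, subsample,
                                      n_perm = 50, seed = 1),
                 "unstable")
})

test_that("power variation test flags a strong band and degenerates on
           constant zero input", {
  set.seed(13)
  ch <- cbind(alpha_early = rnorm(12, 0.5, 0.1),
              beta_early = rnorm(12, 0, 0.1),
              alpha_late = rnorm(12, 0, 0.1))
  rep1 <- power_variation_test(ch, n_perm = 200, seed = 14)
  expect_true(rep1$table$significant[1])
  expect_false(any(rep1$table$significant[2:3]))
  z <- matrix(0, 5, 2)
  rep0 <- power_variation_test(z, n_perm = 50, seed = 15)
  expect_true(all(rep0$table$degenerate))
  expect_equal(rep0$table$p, c(1, 1))
})
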