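#' Family-wise error calibration of the max-stat decoding procedure
#'
#' Monte-Carlo estimate of the family-wise false-positive rate of the
#' maximum-statistic permutation procedure under a fully null design:
#' each replicate draws label-independent Gaussian feature matrices (the
#' exchangeable null of connectivity features), computes the observed
#' decoding accuracy and a label-permutation null for every test, applies
#' the pooled-max correction, and records whether any test was flagged.
#' The reported rate is the fraction of replicates with at least one
#' flag, which the correction must keep at or below `alpha`.
#'
#' The default design is deliberately reduced (4 tests, 100 permutations,
#' single-subsample rows, 3 features) so that hundreds of replicates run
#' in minutes; the procedure under test is exactly the production one.
#'
#' @param n_replicates number of null replicates.
#' @param n_tests tests entering the pooled maximum.
#' @param n_perm label permutations per test.
#' @param n_subjects subjects per replicate (rows = subjects x 6).
#' @param n_features features per test.
#' @param n_repeats_observed repeated splits for the observed statistic.
#' @param splits_per_perm repeated splits per permutation.
#' @param alpha nominal significance level.
#' @param seed integer seed.
#' @return list: `fwer` (fraction of replicates with any flag),
#'   `n_replicates`, `flags` (logical per replicate), `alpha`.
#' @export
maxstat_fwer_calibration <- function(n_replicates = 200, n_tests = 4,
                                     n_perm = 100, n_subjects = 8,
                                     n_features = 3,
                                     n_repeats_observed = 10,
                                     splits_per_perm = 1, alpha = 0.05,
                                     seed = 1) {
  n_rows <- n_subjects * 6
  labels <- factor(rep(seq_len(6), n_subjects))
  flags <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(derive_seed(seed, "fwer", r))
    observed <- numeric(n_tests)
    nulls <- matrix(0, n_tests, n_perm)
    for (j in seq_len(n_tests)) {
      x <- matrix(rnorm(n_rows * n_features), n_rows, n_features)
      spec <- decoder_spec(n_repeats = n_repeats_observed,
                           seed = derive_seed(seed, "obs", r, j))
      observed[j] <- cross_subject_decode(x, labels, spec)$accuracy
      nd <- label_permutation_null(x, labels, spec, n_perm = n_perm,
                                   splits_per_perm = splits_per_perm,
                                   seed = derive_seed(seed, "null", r, j))
      nulls[j, ] <- nd$values
    }
    rep_j <- maxstat_correct(setNames(observed,
                                      paste0("t", seq_len(n_tests))),
                             nulls, alpha = alpha)
    flags[r] <- any(rep_j$table$significant)
  }
  list(fwer = mean(flags), n_replicates = n_replicates, flags = flags,
       alpha = alpha)
}

#' Family-wise error calibration of the SVR both-windows rule
#'
#' Monte-Carlo estimate of the false-positive rate of the min-RMSE
#' permutation rule when behavior is independent of every feature: each
#' replicate draws Gaussian features for `n_tests` tests x two windows
#' and label-independent behavior, runs [svr_permutation_null()], and
#' records whether any test was flagged by the both-windows rule.
#'
#' @param n_replicates number of null replicates.
#' @param n_tests number of connectivity tests.
#' @param n_perm permutations per replicate.
#' @param n_subjects subjects (rows = subjects x 4 subsamples).
#' @param n_features features per test.
#' @param alpha two-tailed level.
#' @param seed integer seed.
#' @return list: `fpr` (fraction of replicates with any flag), `flags`.
#' @export
svr_fwer_calibration <- function(n_replicates = 200, n_tests = 2,
                                 n_perm = 100, n_subjects = 8,
                                 n_features = 4, alpha = 0.05,
                                 seed = 1) {
  subsample <- rep(1:4, n_subjects)
  n_rows <- n_subjects * 4
  flags <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(derive_seed(seed, "svrfwer", r))
    tests <- lapply(seq_len(n_tests), function(j) {
      list(early = matrix(rnorm(n_rows * n_features), n_rows),
           late = matrix(rnorm(n_rows * n_features), n_rows))
    })
    names(tests) <- paste0("t", seq_len(n_tests))
    behavior <- clip(rnorm(n_subjects, 0.84, 0.1), 0, 1)[
      rep(seq_len(n_subjects), each = 4)]
    # reduced permutation counts legitimately trigger the percentile-
    # stability warning; the calibration aggregates over replicates
    out <- suppressWarnings(
      svr_permutation_null(tests, behavior, subsample,
                           n_perm = n_perm, alpha = alpha,
                           seed = derive_seed(seed, "svrnull", r)))
    flags[r] <- any(out$report$table$significant)
  }
  list(fpr = mean(flags), n_replicates = n_replicates, flags = flags,
       alpha = alpha)
}
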