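#' Label-permutation null distribution of decoding accuracy
#'
#' For each permutation the condition labels are shuffled, the decoder is
#' refit, and its accuracy recorded. Permutations are unique and fully
#' reproducible from the seed. Following the study design, the shuffled
#' labels are applied to the training side of each split while the test
#' side is scored against the true labels. To keep the null tractable
#' each permutation may use a reduced number of splits
#' (`splits_per_perm`, default 10 of the 100).
#'
#' @param x row x feature matrix.
#' @param labels true condition labels.
#' @param spec a [decoder_spec()] used for the observed statistic; the
#'   null refits use the same settings with `splits_per_perm` repeats.
#' @param n_perm number of permutations (study design: 500).
#' @param splits_per_perm repeated splits per permutation.
#' @param subjects optional subject ids (for subject-level schemes).
#' @param seed integer seed.
#' @return object of class `null_distribution`: `values` (length
#'   `n_perm`), `statistic`, `pooling = "per-test"`, `n_perm`, `seed`.
#' @export
label_permutation_null <- function(x, labels, spec = decoder_spec(),
                                   n_perm = 500, splits_per_perm = 10,
                                   subjects = NULL, seed = 1) {
  stopifnot(is.matrix(x), nrow(x) == length(labels), n_perm >= 1)
  labels <- factor(labels)
  # number of distinct label permutations: n! / prod(class counts!)
  cnt <- table(labels)
  log_distinct <- lgamma(length(labels) + 1) - sum(lgamma(cnt + 1))
  if (log(n_perm) > log_distinct) {
    stop("n_perm exceeds the number of distinct label permutations")
  }
  values <- numeric(n_perm)
  seen <- new.env(parent = emptyenv())
  set.seed(derive_seed(seed, "perms"))
  perms <- vector("list", n_perm)
  i <- 1L
  while (i <= n_perm) {
    p <- sample(seq_along(labels))
    key <- paste(as.integer(labels)[p], collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      perms[[i]] <- p
      i <- i + 1L
    }
  }
  for (i in seq_len(n_perm)) {
    spec_p <- spec
    spec_p$n_repeats <- splits_per_perm
    spec_p$seed <- derive_seed(seed, "permfit", i)
    res <- cross_subject_decode(x, labels, spec_p, subjects = subjects,
                                perm_labels = labels[perms[[i]]])
    values[i] <- res$accuracy
  }
  structure(list(statistic = "accuracy", values = values,
                 pooling = "per-test", n_perm = n_perm, seed = seed),
            class = "null_distribution")
}

#' Maximum-statistic correction for multiple comparisons
#'
#' Pools the per-test permutation null distributions by taking, at each
#' permutation, the maximum statistic across all tests (e.g. all 60
#' connection x band decoding tests). Each observed statistic is compared
#' against this pooled null:
#' `p = (1 + #permutations with pooled >= observed) / (1 + n_perm)`,
#' a convention that can never return p = 0. Controlling the maximum
#' controls the family-wise error rate, and the pooled-max correction is
#' never less conservative than the per-test (uncorrected) p-values.
#' With `pooling = "min"` the dual rule for smaller-is-better statistics
#' (e.g. RMSE) is applied.
#'
#' @param observed named numeric vector of per-test observed statistics.
#' @param nulls tests x n_perm numeric matrix, or a list of
#'   `null_distribution` objects (one per test, equal `n_perm`).
#' @param pooling `"max"` (larger statistic = stronger effect), `"min"`,
#'   or `"per-test"` (no pooling; uncorrected).
#' @param alpha significance level.
#' @return object of class `inference_report`: `table` (test, statistic,
#'   p, significant), `pooled_null`, `alpha`, `n_perm`, `pooling`.
#' @export
maxstat_correct <- function(observed, nulls, pooling = c("max", "min",
                                                         "per-test"),
                            alpha = 0.05) {
  pooling <- match.arg(pooling)
  if (is.list(nulls) && !is.matrix(nulls)) {
    np <- vapply(nulls, function(d) d$n_perm, 0)
    if (length(unique(np)) != 1) stop("all tests must share n_perm")
    nulls <- do.call(rbind, lapply(nulls, function(d) d$values))
  }
  stopifnot(is.matrix(nulls), nrow(nulls) == length(observed))
  n_perm <- ncol(nulls)
  if (is.null(names(observed))) {
    names(observed) <- paste0("test", seq_along(observed))
  }
  pooled <- switch(pooling,
    max = apply(nulls, 2, max),
    min = apply(nulls, 2, min),
    `per-test` = NULL)
  p <- vapply(seq_along(observed), function(i) {
    ref <- pooled %||% nulls[i, ]
    exceed <- if (pooling == "min") {
      sum(ref <= observed[i])
    } else {
      sum(ref >= observed[i])
    }
    (1 + exceed) / (1 + n_perm)
  }, 0)
  tab <- data.frame(test = names(observed), statistic = unname(observed),
                    p = p, significant = p < alpha,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, pooled_null = pooled, alpha = alpha,
                 n_perm = n_perm, pooling = pooling),
            class = "inference_report")
}

#' @export
print.inference_report <- function(x, ...) {
  cat("<inference_report> ", nrow(x$table), " tests, n_perm = ", x$n_perm,
      ", pooling = ", x$pooling, ", alpha = ", x$alpha, "\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Linear mixed-effect model of the impulse-sound effect
#'
#' Tests whether decoding accuracy of memorized content is higher on
#' trials with a task-irrelevant impulse sound than without: a linear
#' mixed model with a random intercept per subject and fixed effects of
#' impulse presence and band center frequency (log2-transformed).
#' Accuracies are rescaled by subtracting the 1/6 chance level before
#' fitting. P-values are Bonferroni-adjusted across `n_tests`
#' comparisons (13 in the full ROI inventory). Degrees of freedom use
#' the residual convention (`n - p`) by default; Satterthwaite
#' approximation is available.
#'
#' @param data data.frame with columns `accuracy` (in \[0, 1\]),
#'   `subject`, `band_cf` (band center frequency, Hz), `impulse`
#'   (logical or two-level factor).
#' @param n_tests Bonferroni family size.
#' @param ddf `"residual"` or `"satterthwaite"`.
#' @param method `"full"` fits the main-effects model directly;
#'   `"stepwise"` grows the model from intercept-only by likelihood-ratio
#'   comparison and reports the selected model's terms.
#' @return object of class `lme_result`: `table` (term, estimate, se, t,
#'   df, p, p_bonf), `model` (the lmer fit or NULL when degenerate),
#'   `n_tests`, `degenerate`.
#' @export
impulse_effect_model <- function(data, n_tests = 13,
                                 ddf = c("residual", "satterthwaite"),
                                 method = c("full", "stepwise")) {
  ddf <- match.arg(ddf)
  method <- match.arg(method)
  stopifnot(all(c("accuracy", "subject", "band_cf", "impulse") %in%
                  names(data)))
  if (length(unique(data$subject)) < 2) stop("need at least 2 subjects")
  df <- data
  df$resp <- df$accuracy - 1 / 6
  df$impulse <- as.logical(df$impulse)
  df$log2_cf <- log2(df$band_cf)
  terms_tab <- function(fit, n_obs) {
    sm <- summary(fit)$coefficients
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    tval <- est / se
    dof <- if (ddf == "satterthwaite" && "df" %in% colnames(sm)) {
      sm[, "df"]
    } else {
      rep(n_obs - nrow(sm), nrow(sm))
    }
    p <- 2 * pt(-abs(tval), dof)
    data.frame(term = rownames(sm), estimate = unname(est),
               se = unname(se), t = unname(tval), df = unname(dof),
               p = unname(p), p_bonf = pmin(1, n_tests * unname(p)),
               stringsAsFactors = FALSE)
  }
  if (sd(df$resp) == 0) {
    tab <- data.frame(term = c("(Intercept)", "impulseTRUE", "log2_cf"),
                      estimate = 0, se = NA_real_, t = 0, df = NA_real_,
                      p = 1, p_bonf = 1, stringsAsFactors = FALSE)
    return(structure(list(table = tab, model = NULL, n_tests = n_tests,
                          degenerate = TRUE), class = "lme_result"))
  }
  fit_full <- suppressMessages(lmerTest::lmer(
    resp ~ impulse + log2_cf + (1 | subject), data = df))
  fit <- fit_full
  if (method == "stepwise") {
    # grow from intercept-only by likelihood-ratio tests (ML refits);
    # boundary (singular) fits are expected for null terms
    quiet_lmer <- function(...) suppressMessages(lme4::lmer(...))
    f0 <- quiet_lmer(resp ~ 1 + (1 | subject), data = df, REML = FALSE)
    f1 <- quiet_lmer(resp ~ impulse + (1 | subject), data = df,
                     REML = FALSE)
    keep_impulse <- suppressMessages(
      stats::anova(f0, f1))[2, "Pr(>Chisq)"] < 0.05
    base <- if (keep_impulse) f1 else f0
    f2 <- quiet_lmer(stats::update.formula(stats::formula(base),
                                           . ~ . + log2_cf),
                     data = df, REML = FALSE)
    keep_band <- suppressMessages(
      stats::anova(base, f2))[2, "Pr(>Chisq)"] < 0.05
    form <- resp ~ 1
    if (keep_impulse) form <- stats::update.formula(form, . ~ . + impulse)
    if (keep_band) form <- stats::update.formula(form, . ~ . + log2_cf)
    form <- stats::update.formula(form, . ~ . + (1 | subject))
    fit <- suppressMessages(lmerTest::lmer(form, data = df))
  }
  structure(list(table = terms_tab(fit, nrow(df)), model = fit,
                 n_tests = n_tests, degenerate = FALSE),
            class = "lme_result")
}

#' @export
print.lme_result <- function(x, ...) {
  cat("<lme_result> Bonferroni family size ", x$n_tests,
      if (x$degenerate) " (degenerate: constant response)", "\n",
      sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Min-RMSE permutation null for behavioral SVR
#'
#' Assesses which connectivity tests predict behavior better than
#' chance. For each permutation the behavior values are shuffled within
#' each subsample, the SVR procedure is re-run for every test and
#' window, and the minimum RMSE across all of them enters the pooled
#' null (controlling the family of comparisons). A test is flagged
#' significant at the two-tailed alpha when its observed RMSE falls
#' below the `alpha/2` quantile of the pooled null in **every** window
#' (the both-windows rule).
#'
#' @param tests named list; each element is a named list of row x
#'   feature matrices, one per window (e.g. `list(early = X1, late =
#'   X2)`), sharing row structure.
#' @param behavior proportion correct per row.
#' @param subsample subsample index per row.
#' @param n_perm number of permutations (study design: 1000).
#' @param folds,pca_variance,spec,epsilon passed to [behavioral_svr()].
#' @param alpha two-tailed significance level.
#' @param seed integer seed.
#' @return list with `null` (a `null_distribution`, pooling `"min"`),
#'   `report` (an `inference_report` whose table has one RMSE column
#'   per window plus the both-windows `significant` flag), and
#'   `threshold` (the `alpha/2` null quantile).
#' @export
svr_permutation_null <- function(tests, behavior, subsample,
                                 n_perm = 1000, folds = 4,
                                 pca_variance = 0.95,
                                 spec = decoder_spec(), epsilon = NULL,
                                 alpha = 0.05, seed = 1) {
  stopifnot(is.list(tests), length(tests) >= 1)
  if (n_perm < 100) {
    warning("n_perm < 100: the 2.5th-percentile threshold is unstable")
  }
  windows <- names(tests[[1]])
  rmse_of <- function(bhv) {
    vapply(tests, function(tw) {
      vapply(windows, function(w) {
        behavioral_svr(tw[[w]], bhv, subsample, folds = folds,
                       pca_variance = pca_variance, spec = spec,
                       epsilon = epsilon)$rmse
      }, 0)
    }, numeric(length(windows)))
  }
  observed <- rmse_of(behavior)        # windows x tests
  null_vals <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    set.seed(derive_seed(seed, "svrperm", i))
    bperm <- behavior
    for (q in unique(subsample)) {
      ix <- which(subsample == q)
      bperm[ix] <- behavior[sample(ix)]
    }
    null_vals[i] <- min(rmse_of(bperm))
  }
  thr <- unname(quantile(null_vals, alpha / 2))
  sig <- apply(observed, 2, function(v) all(v < thr))
  tab <- data.frame(test = names(tests), t(observed),
                    significant = unname(sig), stringsAsFactors = FALSE)
  names(tab)[1 + seq_along(windows)] <- paste0("rmse_", windows)
  null <- structure(list(statistic = "min RMSE", values = null_vals,
                         pooling = "min", n_perm = n_perm, seed = seed),
                    class = "null_distribution")
  report <- structure(list(table = tab, pooled_null = null_vals,
                           alpha = alpha, n_perm = n_perm,
                           pooling = "min"),
                      class = "inference_report")
  list(null = null, report = report, threshold = thr)
}

#' Sign-flip permutation test of power variation
#'
#' One-sample t-test of baseline-relative power changes against zero per
#' band/window, with family-wise correction by sign-flip permutation:
#' each permutation flips the sign of every subject's whole row of
#' changes, and the maximum |t| across all tests is pooled into the
#' null. Degenerate (zero-variance, zero-mean) tests are reported with
#' p = 1 and flagged.
#'
#' @param changes subjects x tests matrix of relative power changes
#'   (columns typically band x window combinations).
#' @param n_perm number of sign-flip permutations (study design: 500).
#' @param alpha significance level.
#' @param seed integer seed.
#' @return an `inference_report`; the table gains a `degenerate` column.
#' @export
power_variation_test <- function(changes, n_perm = 500, alpha = 0.05,
                                 seed = 1) {
  stopifnot(is.matrix(changes), nrow(changes) >= 2)
  if (is.null(colnames(changes))) {
    colnames(changes) <- paste0("test", seq_len(ncol(changes)))
  }
  n <- nrow(changes)
  tstat <- function(m) {
    mu <- colMeans(m)
    s <- apply(m, 2, sd)
    t <- mu / (s / sqrt(n))
    t[s == 0 & mu == 0] <- 0        # degenerate: no evidence either way
    t[s == 0 & mu != 0] <- Inf * sign(mu[s == 0 & mu != 0])
    t
  }
  t_obs <- tstat(changes)
  degen <- apply(changes, 2, sd) == 0 & colMeans(changes) == 0
  set.seed(derive_seed(seed, "signflip"))
  pooled <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    pooled[i] <- max(abs(tstat(changes * flips)))
  }
  p <- vapply(abs(t_obs), function(tv) {
    (1 + sum(pooled >= tv)) / (1 + n_perm)
  }, 0)
  p[degen] <- 1
  tab <- data.frame(test = colnames(changes), statistic = unname(t_obs),
                    p = unname(p), significant = unname(p < alpha),
                    degenerate = unname(degen), stringsAsFactors = FALSE)
  structure(list(table = tab, pooled_null = pooled, alpha = alpha,
                 n_perm = n_perm, pooling = "max"),
            class = "inference_report")
}
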