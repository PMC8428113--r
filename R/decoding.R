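#' Decoder specification
#'
#' Collects the classifier/regressor settings shared by all decoding
#' analyses. Defaults follow the study design: linear kernel, cost
#' `C = 1`, 100 repeated 75/25 splits. Features are always z-scored with
#' training-side statistics before fitting (C = 1 is scale-sensitive and
#' ImCoh features are small numbers). The RBF kernel uses
#' `gamma = 1 / (n_features * var(training matrix))`. Multiclass
#' classification is one-vs-one with voting; vote ties resolve to the
#' lowest class index (libsvm convention).
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param cost SVM cost parameter C.
#' @param scheme cross-subject split unit: `"row"` (stratified row-level
#'   75/25, the default, consistent with 306/102 train/test rows for 17
#'   subjects x 6 classes x 4 subsamples) or `"subject"` (all rows of a
#'   subject stay on one side).
#' @param train_fraction fraction of rows (or subjects) used for
#'   training.
#' @param n_repeats number of repeated random splits.
#' @param seed integer seed; all splits derive from it.
#' @return object of class `decoder_spec`.
#' @export
decoder_spec <- function(kernel = c("linear", "rbf"), cost = 1,
                         scheme = c("row", "subject"),
                         train_fraction = 0.75, n_repeats = 100,
                         seed = 1) {
  kernel <- match.arg(kernel)
  scheme <- match.arg(scheme)
  stopifnot(cost > 0, train_fraction > 0, train_fraction < 1,
            n_repeats >= 1)
  structure(list(kernel = kernel, cost = cost, scheme = scheme,
                 train_fraction = train_fraction, n_repeats = n_repeats,
                 seed = seed),
            class = "decoder_spec")
}

# fit an SVM on standardized features and predict the test side
svm_predict <- function(xtr, ytr, xte, spec) {
  z <- standardize_train_test(xtr, xte)
  if (spec$kernel == "rbf") {
    v <- var(as.vector(z$train))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(xtr) * v) else 1 / ncol(xtr)
    fit <- e1071::svm(z$train, ytr, kernel = "radial", cost = spec$cost,
                      gamma = gamma, scale = FALSE)
  } else {
    fit <- e1071::svm(z$train, ytr, kernel = "linear", cost = spec$cost,
                      scale = FALSE)
  }
  predict(fit, z$test)
}

new_decoding_result <- function(accuracy, per_repeat, confusion, n_train,
                                n_test, test_id = NA_character_,
                                extra = list()) {
  structure(c(list(accuracy = accuracy, per_repeat = per_repeat,
                   confusion = confusion, n_train = n_train,
                   n_test = n_test, test_id = test_id), extra),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result> ", if (!is.na(x$test_id)) paste0(x$test_id, ": "),
      "accuracy = ", round(x$accuracy, 4), " (", length(x$per_repeat),
      " folds/repeats, ", x$n_train, "/", x$n_test, " train/test rows)\n",
      sep = "")
  invisible(x)
}

#' Cross-subject decoding of stimulus class from connectivity patterns
#'
#' Pools all subjects' rows (subject x condition x subsample) for one
#' (ROI pair, band, window) test and repeatedly splits them 75/25,
#' fitting a linear SVM on the training side and scoring accuracy on the
#' held-out side. With the default row-level stratified scheme every
#' class contributes `train_fraction` of its rows to training, so a
#' balanced 17-subject design yields 306 training and 102 test rows. The
#' mean accuracy over repeats and the summed confusion matrix are
#' returned.
#'
#' `perm_labels` supports permutation inference: when given, training
#' rows are fit against the permuted labels while the test side is still
#' scored against the true labels.
#'
#' @param x row x feature matrix (see [connectivity_features()]).
#' @param labels condition label per row (coercible to factor).
#' @param spec a [decoder_spec()].
#' @param subjects subject id per row; required for the
#'   `"subject"`-level scheme.
#' @param perm_labels optional permuted label vector for null fits.
#' @param test_id optional identifier stored with the result.
#' @return a `decoding_result`: mean `accuracy`, `per_repeat`
#'   accuracies, summed `confusion` (true x predicted counts), and split
#'   bookkeeping `n_train` / `n_test`.
#' @export
cross_subject_decode <- function(x, labels, spec = decoder_spec(),
                                 subjects = NULL, perm_labels = NULL,
                                 test_id = NA_character_) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  labels <- factor(labels)
  if (!is.null(perm_labels)) {
    perm_labels <- factor(perm_labels, levels = levels(labels))
    stopifnot(length(perm_labels) == length(labels))
  }
  if (spec$scheme == "subject" && is.null(subjects)) {
    stop("subject-level splitting requires subject ids")
  }
  n <- nrow(x)
  per_repeat <- numeric(spec$n_repeats)
  confusion <- matrix(0L, nlevels(labels), nlevels(labels),
                      dimnames = list(true = levels(labels),
                                      pred = levels(labels)))
  n_train <- n_test <- NA_integer_
  for (r in seq_len(spec$n_repeats)) {
    set.seed(derive_seed(spec$seed, "split", r))
    if (spec$scheme == "row") {
      tr <- unlist(lapply(split(seq_len(n), labels), function(ix) {
        sample(ix, round(length(ix) * spec$train_fraction))
      }), use.names = FALSE)
    } else {
      subj <- unique(subjects)
      tr_subj <- sample(subj, round(length(subj) * spec$train_fraction))
      tr <- which(subjects %in% tr_subj)
      if (nlevels(droplevels(labels[tr])) < nlevels(labels)) {
        # a class absent from training: reshuffle (rare; row scheme
        # prevents this by stratification)
        next_try <- 0L
        while (nlevels(droplevels(labels[tr])) < nlevels(labels) &&
               next_try < 20L) {
          next_try <- next_try + 1L
          tr_subj <- sample(subj, round(length(subj) * spec$train_fraction))
          tr <- which(subjects %in% tr_subj)
        }
      }
    }
    te <- setdiff(seq_len(n), tr)
    n_train <- length(tr); n_test <- length(te)
    ytr <- if (is.null(perm_labels)) labels[tr] else perm_labels[tr]
    pred <- svm_predict(x[tr, , drop = FALSE], ytr,
                        x[te, , drop = FALSE], spec)
    per_repeat[r] <- mean(pred == labels[te])
    confusion <- confusion + unclass(table(labels[te], pred))
  }
  new_decoding_result(mean(per_repeat), per_repeat, confusion, n_train,
                      n_test, test_id)
}

#' Within-subject decoding of stimulus class from power patterns
#'
#' Decodes the six stimulus classes from band-restricted sub-ROI power
#' patterns with an RBF-kernel SVM, separately within each subject:
#' four-fold cross-validation over the four epoch subsamples (each fold
#' trains on 3 subsamples x 6 classes = 18 rows and tests on the 6
#' held-out rows). Accuracy is averaged over folds and then over
#' subjects.
#'
#' @param x row x feature matrix (rows = subject x condition x
#'   subsample; features = sub-ROIs x band bins).
#' @param labels condition label per row.
#' @param subsample subsample index per row (1..4).
#' @param subject subject id per row.
#' @param spec a [decoder_spec()]; kernel forced to `"rbf"` by default
#'   configuration of the analysis.
#' @param test_id optional identifier.
#' @return a `decoding_result` with per-subject accuracies in
#'   `per_subject` and fold bookkeeping.
#' @export
power_pattern_decode <- function(x, labels, subsample, subject,
                                 spec = decoder_spec(kernel = "rbf"),
                                 test_id = NA_character_) {
  stopifnot(is.matrix(x), nrow(x) == length(labels),
            length(subsample) == nrow(x), length(subject) == nrow(x))
  labels <- factor(labels)
  folds <- sort(unique(subsample))
  subj_ids <- unique(subject)
  per_subject <- numeric(length(subj_ids))
  confusion <- matrix(0L, nlevels(labels), nlevels(labels),
                      dimnames = list(true = levels(labels),
                                      pred = levels(labels)))
  n_train <- n_test <- NA_integer_
  for (si in seq_along(subj_ids)) {
    rows <- which(subject == subj_ids[si])
    accs <- numeric(length(folds))
    for (fi in seq_along(folds)) {
      te <- rows[subsample[rows] == folds[fi]]
      tr <- rows[subsample[rows] != folds[fi]]
      if (length(te) == 0) stop("missing subsample ", folds[fi],
                                " for subject ", subj_ids[si])
      n_train <- length(tr); n_test <- length(te)
      pred <- svm_predict(x[tr, , drop = FALSE], labels[tr],
                          x[te, , drop = FALSE], spec)
      accs[fi] <- mean(pred == labels[te])
      confusion <- confusion + unclass(table(labels[te], pred))
    }
    per_subject[si] <- mean(accs)
  }
  new_decoding_result(mean(per_subject), per_subject, confusion, n_train,
                      n_test, test_id,
                      extra = list(per_subject = setNames(per_subject,
                                                          subj_ids)))
}

#' Temporal-pattern decoding with PCA-reduced time courses
#'
#' Decodes stimulus class from single-trial time courses: band-pass
#' filters each trial (default 0.5-12 Hz, 4th-order Butterworth,
#' zero-phase), reduces the time dimension with PCA fit on the training
#' folds only (at most `n_components` components, capped at the matrix
#' rank), and classifies with an RBF SVM under stratified k-fold
#' cross-validation.
#'
#' @param x trials x T matrix of time courses.
#' @param labels condition label per trial.
#' @param sfreq sampling rate (Hz).
#' @param n_components maximum retained principal components.
#' @param folds number of CV folds.
#' @param spec a [decoder_spec()] (kernel `"rbf"` by default here).
#' @param bandpass filter band `c(low, high)` in Hz; `NULL` disables.
#' @param seed integer seed for fold assignment.
#' @param test_id optional identifier.
#' @return a `decoding_result` with `n_components_used` per fold.
#' @export
temporal_pca_decode <- function(x, labels, sfreq, n_components = 100,
                                folds = 10,
                                spec = decoder_spec(kernel = "rbf"),
                                bandpass = c(0.5, 12), seed = 1,
                                test_id = NA_character_) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  labels <- factor(labels)
  n <- nrow(x)
  if (n < folds) stop("fewer samples than folds")
  if (!is.null(bandpass)) {
    ny <- sfreq / 2
    bf <- signal::butter(4, c(bandpass[1] / ny, bandpass[2] / ny),
                         type = "pass")
    x <- t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
  }
  set.seed(derive_seed(seed, "folds"))
  fold_of <- integer(n)
  for (lv in levels(labels)) {
    ix <- sample(which(labels == lv))
    fold_of[ix] <- rep_len(seq_len(folds), length(ix))
  }
  per_fold <- numeric(folds)
  ncomp_used <- integer(folds)
  confusion <- matrix(0L, nlevels(labels), nlevels(labels),
                      dimnames = list(true = levels(labels),
                                      pred = levels(labels)))
  n_train <- n_test <- NA_integer_
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    n_train <- length(tr); n_test <- length(te)
    pc <- prcomp(x[tr, , drop = FALSE], center = TRUE, scale. = FALSE)
    ncomp <- min(n_components, ncol(pc$rotation))
    ncomp_used[f] <- ncomp
    str <- pc$x[, seq_len(ncomp), drop = FALSE]
    ste <- scale(x[te, , drop = FALSE], center = pc$center,
                 scale = FALSE) %*% pc$rotation[, seq_len(ncomp),
                                                drop = FALSE]
    pred <- svm_predict(str, labels[tr], ste, spec)
    per_fold[f] <- mean(pred == labels[te])
    confusion <- confusion + unclass(table(labels[te], pred))
  }
  new_decoding_result(mean(per_fold), per_fold, confusion, n_train,
                      n_test, test_id,
                      extra = list(n_components_used = ncomp_used))
}

#' Encoding-to-maintenance generalization
#'
#' Tests whether the connectivity pattern that codes stimulus content
#' during encoding also codes it during maintenance: a linear SVM is
#' trained on encoding-phase features and tested on maintenance-phase
#' features, within each subject, with 4-fold cross-validation over the
#' epoch subsamples (train on 3 encoding subsamples, test on the held-out
#' maintenance subsample).
#'
#' @param x_encode,x_maintain row x feature matrices sharing row
#'   structure (same subject/condition/subsample ordering and feature
#'   count).
#' @param labels condition label per row.
#' @param subsample subsample index per row.
#' @param subject subject id per row.
#' @param spec a [decoder_spec()].
#' @param test_id optional identifier.
#' @return a `decoding_result` with per-subject accuracies.
#' @export
cross_phase_generalize <- function(x_encode, x_maintain, labels,
                                   subsample, subject,
                                   spec = decoder_spec(),
                                   test_id = NA_character_) {
  if (!identical(dim(x_encode), dim(x_maintain))) {
    stop("encoding and maintenance features must share row structure")
  }
  stopifnot(nrow(x_encode) == length(labels),
            length(subsample) == length(labels),
            length(subject) == length(labels))
  labels <- factor(labels)
  folds <- sort(unique(subsample))
  subj_ids <- unique(subject)
  per_subject <- numeric(length(subj_ids))
  confusion <- matrix(0L, nlevels(labels), nlevels(labels),
                      dimnames = list(true = levels(labels),
                                      pred = levels(labels)))
  n_train <- n_test <- NA_integer_
  for (si in seq_along(subj_ids)) {
    rows <- which(subject == subj_ids[si])
    accs <- numeric(length(folds))
    for (fi in seq_along(folds)) {
      tr <- rows[subsample[rows] != folds[fi]]
      te <- rows[subsample[rows] == folds[fi]]
      n_train <- length(tr); n_test <- length(te)
      pred <- svm_predict(x_encode[tr, , drop = FALSE], labels[tr],
                          x_maintain[te, , drop = FALSE], spec)
      accs[fi] <- mean(pred == labels[te])
      confusion <- confusion + unclass(table(labels[te], pred))
    }
    per_subject[si] <- mean(accs)
  }
  new_decoding_result(mean(per_subject), per_subject, confusion,
                      n_train, n_test, test_id,
                      extra = list(per_subject = setNames(per_subject,
                                                          subj_ids)))
}

#' Support vector regression of behavioral performance
#'
#' Predicts each subject's proportion-correct score from connectivity
#' features. Rows are subject x subsample (the condition dimension is
#' averaged out upstream or ignored); behavior is replicated across a
#' subject's rows. Four-fold cross-validation over subsamples: in each
#' fold the training rows are PCA-reduced to the components explaining
#' `pca_variance` of the variance, the test rows are projected with the
#' training loadings, and a linear SVR (C = 1, epsilon = 0.1 x the
#' training behavior SD) predicts the held-out behavior. The reported
#' statistic is the RMSE of predicted versus actual proportion correct,
#' averaged over the four folds.
#'
#' @param x row x feature matrix.
#' @param behavior proportion correct per row, in \[0, 1\].
#' @param subsample subsample index per row.
#' @param folds number of folds (must equal the number of distinct
#'   subsamples).
#' @param pca_variance variance fraction retained by the PCA.
#' @param spec a [decoder_spec()] (linear kernel).
#' @param epsilon SVR epsilon; default 0.1 x SD of the training
#'   behavior.
#' @return object of class `behavior_prediction`: `rmse` (fold
#'   average), `per_fold`, `n_pc` (retained components per fold), and
#'   `predictions` (data.frame fold/actual/predicted).
#' @export
behavioral_svr <- function(x, behavior, subsample, folds = 4,
                           pca_variance = 0.95, spec = decoder_spec(),
                           epsilon = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(behavior),
            length(subsample) == length(behavior))
  if (any(behavior < 0 | behavior > 1)) {
    stop("behavior must be proportions in [0, 1]")
  }
  fold_ids <- sort(unique(subsample))
  if (length(fold_ids) != folds) {
    stop("number of distinct subsamples must equal folds")
  }
  per_fold <- numeric(folds)
  n_pc <- integer(folds)
  preds <- list()
  for (fi in seq_along(fold_ids)) {
    tr <- which(subsample != fold_ids[fi])
    te <- which(subsample == fold_ids[fi])
    pc <- prcomp(x[tr, , drop = FALSE], center = TRUE, scale. = FALSE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    ncomp <- max(1L, which(cum >= pca_variance)[1])
    n_pc[fi] <- ncomp
    str <- pc$x[, seq_len(ncomp), drop = FALSE]
    ste <- scale(x[te, , drop = FALSE], center = pc$center,
                 scale = FALSE) %*% pc$rotation[, seq_len(ncomp),
                                                drop = FALSE]
    yhat <- if (sd(behavior[tr]) == 0) {
      # constant training target: the SVR solution is the constant
      rep(behavior[tr][1], length(te))
    } else {
      eps <- epsilon %||% max(0.1 * sd(behavior[tr]), 1e-6)
      fit <- e1071::svm(str, behavior[tr], type = "eps-regression",
                        kernel = "linear", cost = spec$cost,
                        epsilon = eps, scale = FALSE)
      unname(predict(fit, ste))
    }
    per_fold[fi] <- sqrt(mean((yhat - behavior[te])^2))
    preds[[fi]] <- data.frame(fold = fold_ids[fi],
                              actual = behavior[te], predicted = yhat)
  }
  structure(list(rmse = mean(per_fold), per_fold = per_fold,
                 n_pc = n_pc, predictions = do.call(rbind, preds)),
            class = "behavior_prediction")
}

#' @export
print.behavior_prediction <- function(x, ...) {
  cat("<behavior_prediction> RMSE = ", round(x$rmse, 4), " (folds: ",
      paste(round(x$per_fold, 4), collapse = ", "), "; PCs: ",
      paste(x$n_pc, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
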