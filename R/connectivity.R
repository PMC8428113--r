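#' Imaginary part of coherence between two spectral tensors
#'
#' `ImCoh(f, t) = Im[ mean_k(Sx conj(Sy)) / sqrt(mean_k |Sx|^2 mean_k
#' |Sy|^2) ]`, the imaginary part of the complex coherency averaged over
#' epochs at every (frequency, time) bin. ImCoh is insensitive to
#' zero-lag (instantaneous) mixing, which makes it robust to MEG field
#' spread. Sign convention: positive when `y` lags `x` (a target
#' phase-lagged by +pi/2 relative to the seed gives +1);
#' `imcoh(x, y) = -imcoh(y, x)` exactly.
#'
#' @param sx,sy complex K x F x T coefficient arrays (or
#'   [morlet_tfr()] results) sharing epoch count, grid, and time axis.
#' @return F x T numeric matrix of ImCoh values in \[-1, 1\].
#' @export
imcoh <- function(sx, sy) {
  if (inherits(sx, "spectral_tensor")) sx <- sx$coef
  if (inherits(sy, "spectral_tensor")) sy <- sy$coef
  stopifnot(length(dim(sx)) == 3, identical(dim(sx), dim(sy)))
  d <- dim(sx)
  K <- d[1]
  if (K < 2) stop("coherence undefined for fewer than 2 epochs")
  # epoch means via reshaped colMeans (K x F*T), then back to F x T
  cross <- matrix(colMeans(matrix(sx * Conj(sy), K)), d[2], d[3])
  px <- matrix(colMeans(matrix(Mod(sx)^2, K)), d[2], d[3])
  py <- matrix(colMeans(matrix(Mod(sy)^2, K)), d[2], d[3])
  denom <- sqrt(px * py)
  if (any(denom == 0)) stop("coherence undefined: zero power in an input")
  Im(cross) / denom
}

#' Equalize epoch counts across conditions
#'
#' Downsamples every condition of every subject (seeded, without
#' replacement) to that subject's minimum condition epoch count, keeping
#' the signal-to-noise ratio of coherence estimates constant across
#' conditions. Conditions already at the minimum are left untouched.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param seed integer seed for the epoch selection.
#' @return the equalized cohort.
#' @export
equalize_epochs <- function(cohort, seed = 1) {
  stopifnot(inherits(cohort, "cohort"))
  for (s in seq_along(cohort$epochs)) {
    ks <- vapply(cohort$epochs[[s]], function(a) dim(a)[1], 0L)
    kmin <- min(ks)
    for (cc in seq_along(cohort$epochs[[s]])) {
      k <- ks[cc]
      if (k > kmin) {
        set.seed(derive_seed(seed, "equalize", s, cc))
        keep <- sort(sample(k, kmin))
        cohort$epochs[[s]][[cc]] <-
          cohort$epochs[[s]][[cc]][keep, , , drop = FALSE]
        if (!is.null(cohort$impulse)) {
          cohort$impulse[[s]][[cc]] <- cohort$impulse[[s]][[cc]][keep]
        }
      }
    }
  }
  cohort
}

# epoch counts per subject x condition
epoch_counts <- function(cohort) {
  t(vapply(cohort$epochs, function(s) vapply(s, function(a) dim(a)[1], 0L),
           integer(length(cohort$epochs[[1]]))))
}

#' Imaginary-coherence feature matrices for decoding
#'
#' For every (seed ROI, target ROI) pair, frequency band, and time
#' window, builds the feature matrix used by the decoders: one row per
#' subject x condition x subsample, one column per (seed sub-ROI, target
#' sub-ROI) pair (seed-major order, `N_seed * N_target` columns). Within
#' each subject and condition the (equalized) epochs are partitioned into
#' `n_subsamples` disjoint, equal-sized, seeded quarters (remainder
#' epochs dropped); ImCoh is computed per quarter at every (frequency,
#' time) bin and then the signed values are averaged over the band's bins
#' and the window's valid (non-edge-masked) samples.
#'
#' @param cohort an equalized cohort (see [equalize_epochs()]; unequal
#'   condition counts are an error).
#' @param grid a [frequency_grid()].
#' @param windows named list of half-open `c(tmin, tmax)` windows in
#'   epoch time (defaults: maintenance early 0.5-1.25 s and late
#'   1.25-2 s; use `list(encoding = c(0, 1))` for encoding cohorts).
#' @param seed_rois seed ROI names (default: the layout's seed ROIs).
#' @param target_rois target ROI names (default: every non-seed ROI in
#'   the same hemisphere as its seed).
#' @param n_subsamples epoch quarters per condition (default 4).
#' @param n_cycles Morlet wavelet cycles.
#' @param seed integer seed for the quarter partition.
#' @return object of class `connectivity_features`: `tests` (named list
#'   of row x feature matrices, names `"seed-target|band|window"`),
#'   `meta` (data.frame subject/condition/subsample aligned with rows),
#'   `pairs`, `bands`, `windows`, `grid`.
#' @export
connectivity_features <- function(cohort, grid,
                                  windows = list(early = c(0.5, 1.25),
                                                 late = c(1.25, 2)),
                                  seed_rois = NULL, target_rois = NULL,
                                  n_subsamples = 4, n_cycles = 7,
                                  seed = 1) {
  stopifnot(inherits(cohort, "cohort"), inherits(grid, "frequency_grid"))
  counts <- epoch_counts(cohort)
  if (any(counts != counts[, 1])) {
    stop("cohort must be equalized first (see equalize_epochs)")
  }
  quarter <- floor(counts[, 1] / n_subsamples)
  if (any(quarter < 2)) {
    stop("quarter size below 2: coherence undefined")
  }
  layout <- cohort$layout
  if (is.null(seed_rois)) seed_rois <- layout$seed_rois
  pairs <- list()
  for (sr in seed_rois) {
    hemi <- layout$rois$hemi[layout$rois$name == sr]
    tg <- if (is.null(target_rois)) {
      setdiff(layout$rois$name[layout$rois$hemi == hemi], seed_rois)
    } else {
      intersect(target_rois, layout$rois$name)
    }
    for (t in tg) pairs[[length(pairs) + 1]] <- c(sr, t)
  }
  bands <- unique(grid$band)
  n_subj <- length(cohort$epochs)
  n_cond <- length(cohort$epochs[[1]])
  # precompute band x window bin/time selections
  win_ix <- lapply(windows, function(w) which(in_window(cohort$times, w)))
  if (any(vapply(win_ix, length, 0L) == 0)) {
    stop("a window lies outside the epoch time axis")
  }
  needed_subs <- sort(unique(unlist(lapply(pairs, function(p) {
    c(roi_subs(layout, p[1]), roi_subs(layout, p[2]))
  }))))

  n_rows <- n_subj * n_cond * n_subsamples
  tests <- list()
  for (p in pairs) {
    nf <- length(roi_subs(layout, p[1])) * length(roi_subs(layout, p[2]))
    for (b in bands) for (w in names(windows)) {
      tests[[paste0(p[1], "-", p[2], "|", b, "|", w)]] <-
        matrix(NA_real_, n_rows, nf)
    }
  }
  meta <- data.frame(
    subject = rep(names(cohort$epochs), each = n_cond * n_subsamples),
    condition = rep(rep(seq_len(n_cond), each = n_subsamples), n_subj),
    subsample = rep(seq_len(n_subsamples), n_subj * n_cond)
  )
  row_of <- function(s, cc, q) {
    (s - 1) * n_cond * n_subsamples + (cc - 1) * n_subsamples + q
  }

  for (s in seq_len(n_subj)) {
    for (cc in seq_len(n_cond)) {
      arr <- cohort$epochs[[s]][[cc]]
      k <- dim(arr)[1]
      set.seed(derive_seed(seed, "quarters", s, cc))
      perm <- sample(k)
      qsize <- floor(k / n_subsamples)
      qix <- split(perm[seq_len(qsize * n_subsamples)],
                   rep(seq_len(n_subsamples), each = qsize))
      # one TFR per needed sub-ROI, kept only at the window columns
      # (the band/window averages never look outside them)
      win_cols <- sort(unique(unlist(win_ix)))
      stc <- list()
      vmask <- NULL
      for (r in needed_subs) {
        st <- morlet_tfr(arr[, r, , drop = TRUE], cohort$sfreq, grid,
                         n_cycles = n_cycles, times = cohort$times)
        stc[[as.character(r)]] <- st$coef[, , win_cols, drop = FALSE]
        if (is.null(vmask)) vmask <- st$valid[, win_cols, drop = FALSE]
      }
      Fn <- length(grid$freqs)
      Tw <- length(win_cols)
      sel <- list()  # per band x window: valid (bin, time) logical
      for (b in bands) for (w in names(windows)) {
        m <- matrix(FALSE, Fn, Tw)
        m[band_bins(grid, b), match(win_ix[[w]], win_cols)] <- TRUE
        sel[[paste0(b, "|", w)]] <- m & vmask
      }
      for (q in seq_len(n_subsamples)) {
        ix <- qix[[q]]
        # flatten quarter slices to K_q x (F*T) and hoist per-signal
        # mean power out of the pair loop (same math as imcoh())
        sl <- lapply(stc, function(cf) {
          matrix(cf[ix, , , drop = FALSE], length(ix))
        })
        pw <- lapply(sl, function(m) colMeans(Mod(m)^2))
        for (p in pairs) {
          s_subs <- roi_subs(layout, p[1])
          t_subs <- roi_subs(layout, p[2])
          col <- 0L
          vals <- matrix(NA_real_, length(s_subs) * length(t_subs),
                         length(bands) * length(windows))
          for (a in s_subs) for (bsub in t_subs) {
            col <- col + 1L
            sa <- sl[[as.character(a)]]
            sb <- sl[[as.character(bsub)]]
            denom <- sqrt(pw[[as.character(a)]] * pw[[as.character(bsub)]])
            if (any(denom == 0)) {
              stop("coherence undefined: zero power in an input")
            }
            ic <- matrix(Im(colMeans(sa * Conj(sb))) / denom, Fn, Tw)
            jj <- 0L
            for (b in bands) for (w in names(windows)) {
              jj <- jj + 1L
              m <- sel[[paste0(b, "|", w)]]
              vals[col, jj] <- if (any(m)) mean(ic[m]) else NA_real_
            }
          }
          jj <- 0L
          for (b in bands) for (w in names(windows)) {
            jj <- jj + 1L
            key <- paste0(p[1], "-", p[2], "|", b, "|", w)
            tests[[key]][row_of(s, cc, q), ] <- vals[, jj]
          }
        }
      }
    }
  }
  structure(list(tests = tests, meta = meta,
                 pairs = vapply(pairs, paste, "", collapse = "-"),
                 bands = bands, windows = windows, grid = grid,
                 n_subsamples = n_subsamples, seed = seed),
            class = "connectivity_features")
}

#' Extract one feature matrix
#' @param features a [connectivity_features()] result.
#' @param test test key `"seed-target|band|window"` (see
#'   `names(features$tests)`).
#' @return the row x feature matrix for that test.
#' @export
feature_matrix <- function(features, test) {
  stopifnot(inherits(features, "connectivity_features"))
  m <- features$tests[[test]]
  if (is.null(m)) stop("unknown test: ", test)
  m
}

#' Export connectivity features to CSV
#'
#' One row per subject x condition x subsample with the test's feature
#' columns; one file per test, or a single long file when `long = TRUE`.
#'
#' @param features a [connectivity_features()] result.
#' @param path output CSV path.
#' @param tests tests to include (default all).
#' @return `path`, invisibly.
#' @export
features_to_csv <- function(features, path, tests = NULL) {
  stopifnot(inherits(features, "connectivity_features"))
  tests <- tests %||% names(features$tests)
  out <- do.call(rbind, lapply(tests, function(key) {
    m <- features$tests[[key]]
    data.frame(test = key,
               features$meta[rep(seq_len(nrow(m)), ncol(m)), ],
               feature = rep(seq_len(ncol(m)), each = nrow(m)),
               value = as.vector(m), row.names = NULL)
  }))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
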