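#' Analysis frequency grid
#'
#' Log-spaced frequency bins inside each band. Bin counts per band default
#' to theta 5, alpha 5, beta 18, low gamma 20, high gamma 21; bands must
#' be non-overlapping and the resulting global grid strictly increasing.
#'
#' @param bands named list of `c(fmin, fmax)` band edges (Hz); see
#'   [default_bands()].
#' @param bins_per_band named integer vector of bin counts, aligned with
#'   `bands`.
#' @return object of class `frequency_grid`: `freqs` (Hz), `band` (band
#'   name per bin), `bands`, `bins_per_band`.
#' @export
#' @examples
#' g <- frequency_grid()
#' length(g$freqs)  # 69
frequency_grid <- function(bands = default_bands(),
                           bins_per_band = c(theta = 5, alpha = 5,
                                             beta = 18, lowgamma = 20,
                                             highgamma = 21)) {
  stopifnot(length(bands) >= 1, !is.null(names(bands)))
  if (is.null(names(bins_per_band))) {
    stopifnot(length(bins_per_band) == length(bands))
    names(bins_per_band) <- names(bands)
  }
  stopifnot(all(names(bands) %in% names(bins_per_band)),
            all(bins_per_band[names(bands)] >= 1))
  # non-overlap check on sorted band edges
  edges <- do.call(rbind, bands)
  ord <- order(edges[, 1])
  edges <- edges[ord, , drop = FALSE]
  if (any(edges[, 2] <= edges[, 1])) stop("band fmax must exceed fmin")
  if (nrow(edges) > 1 &&
      any(edges[-1, 1] <= edges[-nrow(edges), 2] - 1e-9)) {
    stop("bands must be non-overlapping")
  }
  freqs <- numeric(0)
  band <- character(0)
  for (nm in names(bands)[order(vapply(bands, `[`, 0, 1))]) {
    m <- bins_per_band[[nm]]
    f <- if (m == 1) {
      sqrt(prod(bands[[nm]]))
    } else {
      exp(seq(log(bands[[nm]][1]), log(bands[[nm]][2]), length.out = m))
    }
    freqs <- c(freqs, f)
    band <- c(band, rep(nm, m))
  }
  stopifnot(all(diff(freqs) > 0))
  structure(list(freqs = freqs, band = band, bands = bands,
                 bins_per_band = bins_per_band),
            class = "frequency_grid")
}

#' Band membership indices of a frequency grid
#' @param grid a [frequency_grid()].
#' @param band band name.
#' @return integer indices of the band's bins.
#' @export
band_bins <- function(grid, band) {
  stopifnot(inherits(grid, "frequency_grid"))
  idx <- which(grid$band == band)
  if (length(idx) == 0) stop("unknown or empty band: ", band)
  idx
}

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves each epoch with a dictionary of complex Morlet wavelets
#' (default 7 cycles each, unit L2 norm), producing a complex
#' epoch x frequency x time coefficient tensor. Samples within half the
#' wavelet support (`n_cycles / (2 f)` seconds) of either epoch edge are
#' flagged invalid in the `valid` mask; window averages downstream must
#' exclude them. The transform is linear in the input; epochs are
#' zero-padded rather than trimmed.
#'
#' @param x K x T numeric matrix of epochs (rows) by time samples.
#' @param sfreq sampling rate (Hz).
#' @param grid a [frequency_grid()] or numeric vector of frequencies (Hz).
#' @param n_cycles wavelet length in cycles.
#' @param times optional time axis (s); defaults to `0, 1/sfreq, ...`.
#' @return object of class `spectral_tensor`: complex `coef` (K x F x T),
#'   `freqs`, `times`, `valid` (F x T logical), `sfreq`, `n_cycles`.
#' @export
morlet_tfr <- function(x, sfreq, grid, n_cycles = 7, times = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  stopifnot(is.matrix(x), sfreq > 0)
  if (!all(is.finite(x))) stop("non-finite values in input epochs")
  freqs <- if (inherits(grid, "frequency_grid")) grid$freqs else grid
  stopifnot(all(freqs > 0), all(freqs <= sfreq / 2))
  K <- nrow(x); T_len <- ncol(x); F_len <- length(freqs)
  if (is.null(times)) times <- (seq_len(T_len) - 1) / sfreq
  half_w <- ceiling(n_cycles / (2 * freqs) * sfreq)  # samples
  L <- stats::nextn(T_len + 2 * max(half_w) + 1, c(2, 3))
  # FFT of zero-padded epochs, once
  xpad <- matrix(0, L, K)
  xpad[seq_len(T_len), ] <- t(x)
  FX <- stats::mvfft(xpad)
  coef <- array(complex(real = 0), dim = c(K, F_len, T_len))
  valid <- matrix(TRUE, F_len, T_len)
  for (j in seq_len(F_len)) {
    f <- freqs[j]; hw <- half_w[j]
    sigma_t <- n_cycles / (2 * pi * f)
    tt <- (-hw:hw) / sfreq
    w <- exp(-tt^2 / (2 * sigma_t^2)) * exp(1i * 2 * pi * f * tt)
    w <- w / sqrt(sum(Mod(w)^2))                    # unit L2 norm
    kpad <- complex(real = rep(0, L))
    kpad[1:(hw + 1)] <- w[(hw + 1):(2 * hw + 1)]    # u = 0..hw
    kpad[(L - hw + 1):L] <- w[1:hw]                 # u = -hw..-1
    FW <- fft(kpad)
    Y <- stats::mvfft(FX * FW, inverse = TRUE) / L  # y[t] = sum_u w[u] x[t-u]
    coef[, j, ] <- t(Y[seq_len(T_len), , drop = FALSE])
    if (hw >= 1) {
      edge <- seq_len(min(hw, T_len))
      valid[j, edge] <- FALSE
      valid[j, T_len + 1 - edge] <- FALSE
    }
    if (2 * hw >= T_len) valid[j, ] <- FALSE        # support exceeds epoch
  }
  structure(list(coef = coef, freqs = freqs, times = times, valid = valid,
                 sfreq = sfreq, n_cycles = n_cycles),
            class = "spectral_tensor")
}

# ---- DPSS (Slepian) tapers ------------------------------------------------

.dpss_cache <- new.env(parent = emptyenv())

# DPSS via the symmetric tridiagonal formulation. For long windows the
# tapers are computed on a coarser grid and spline-interpolated (they are
# smooth, slowly varying functions), then re-orthonormalized.
dpss_tapers <- function(n, time_bandwidth = 4, n_tapers = NULL,
                        max_exact = 1024) {
  if (is.null(n_tapers)) n_tapers <- max(1, floor(2 * time_bandwidth) - 1)
  key <- paste(n, time_bandwidth, n_tapers, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  exact <- function(N) {
    W <- time_bandwidth / N
    t <- 0:(N - 1)
    d <- ((N - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
    e <- t[-1] * (N - t[-1]) / 2
    A <- diag(d)
    A[cbind(1:(N - 1), 2:N)] <- e
    A[cbind(2:N, 1:(N - 1))] <- e
    ev <- eigen(A, symmetric = TRUE)
    v <- ev$vectors[, seq_len(n_tapers), drop = FALSE]
    # sign convention: symmetric tapers positive mean, antisymmetric
    # positive initial slope
    for (k in seq_len(n_tapers)) {
      if (k %% 2 == 1) {
        if (sum(v[, k]) < 0) v[, k] <- -v[, k]
      } else if (v[2, k] - v[1, k] < 0) v[, k] <- -v[, k]
    }
    v
  }
  tapers <- if (n <= max_exact) {
    exact(n)
  } else {
    v0 <- exact(max_exact)
    g0 <- seq(0, 1, length.out = max_exact)
    g1 <- seq(0, 1, length.out = n)
    v <- apply(v0, 2, function(col) stats::spline(g0, col, xout = g1)$y)
    # re-orthonormalize (Gram-Schmidt) after interpolation
    v <- qr.Q(qr(v)) * sqrt(1)
    for (k in seq_len(ncol(v))) {
      if (k %% 2 == 1) {
        if (sum(v[, k]) < 0) v[, k] <- -v[, k]
      } else if (v[2, k] - v[1, k] < 0) v[, k] <- -v[, k]
    }
    v
  }
  # unit L2 norm per taper
  tapers <- sweep(tapers, 2, sqrt(colSums(tapers^2)), "/")
  .dpss_cache[[key]] <- tapers
  tapers
}

#' Multitaper power spectrum of single epochs
#'
#' Estimates a power spectrum (no temporal resolution) per epoch using
#' Slepian (DPSS) tapers: each epoch is multiplied by each taper,
#' Fourier-transformed, and the squared magnitudes are averaged across
#' tapers. One-sided density scaling: integrating the returned spectrum
#' over frequency (bin width `sfreq / T`) recovers the signal variance.
#'
#' @param x K x T numeric matrix of epochs.
#' @param sfreq sampling rate (Hz).
#' @param fmin,fmax analysis range (Hz); `fmax` must not exceed Nyquist.
#' @param time_bandwidth taper time-bandwidth product (NW).
#' @param n_tapers number of tapers (default `2 NW - 1`).
#' @return K x n_bins matrix of nonnegative power values with attributes
#'   `freqs` (Hz) and `df` (bin width, Hz).
#' @export
multitaper_power <- function(x, sfreq, fmin = 3, fmax = 120,
                             time_bandwidth = 4, n_tapers = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  stopifnot(is.matrix(x), nrow(x) >= 1)
  if (!all(is.finite(x))) stop("non-finite values in input epochs")
  if (fmax > sfreq / 2) stop("fmax exceeds the Nyquist frequency")
  T_len <- ncol(x)
  tapers <- dpss_tapers(T_len, time_bandwidth, n_tapers)
  nk <- ncol(tapers)
  freqs_all <- (seq_len(T_len) - 1) * sfreq / T_len
  keep <- which(freqs_all >= fmin & freqs_all <= fmax)
  out <- matrix(0, nrow(x), length(keep))
  for (k in seq_len(nk)) {
    xt <- x * matrix(tapers[, k], nrow(x), T_len, byrow = TRUE)
    X <- t(stats::mvfft(t(xt)))
    out <- out + (Mod(X[, keep, drop = FALSE])^2)
  }
  out <- out / nk * 2 / sfreq   # one-sided density, unit-norm tapers
  attr(out, "freqs") <- freqs_all[keep]
  attr(out, "df") <- sfreq / T_len
  out
}

#' Average epoch spectra into seeded subsample groups
#'
#' Partitions the epochs of one condition into `n_groups` disjoint,
#' equal-sized, seeded groups (remainder epochs dropped) and averages the
#' spectra within each group. Four groups per condition support four-fold
#' cross-validation in power-pattern decoding.
#'
#' @param spectra K x F matrix of per-epoch spectra (rows = epochs).
#' @param n_groups number of groups (default 4).
#' @param seed integer seed for the partition.
#' @return n_groups x F matrix of group-mean spectra with attribute
#'   `groups` (list of epoch indices).
#' @export
power_subsamples <- function(spectra, n_groups = 4, seed = 1) {
  stopifnot(is.matrix(spectra))
  K <- nrow(spectra)
  if (K < n_groups) stop("fewer epochs than subsample groups")
  per <- floor(K / n_groups)
  set.seed(seed)
  perm <- sample(K)
  groups <- split(perm[seq_len(per * n_groups)],
                  rep(seq_len(n_groups), each = per))
  out <- t(vapply(groups,
                  function(ix) colMeans(spectra[ix, , drop = FALSE]),
                  numeric(ncol(spectra))))
  attr(out, "groups") <- groups
  out
}

#' Baseline-relative power change
#'
#' `(mean(analysis window) - mean(baseline)) / mean(baseline)` per row of
#' a band (or frequency) x time power matrix. Windows are half-open
#' `[tmin, tmax)` in seconds on the epoch time axis. `NA` samples
#' (e.g. masked wavelet edges) are excluded from both means.
#'
#' @param power numeric vector (one time course) or rows x T matrix.
#' @param times time axis (s), length T.
#' @param baseline baseline window, default c(-0.4, -0.2) s.
#' @param analysis analysis window, default c(0, 2) s.
#' @return numeric vector of relative changes (one per row).
#' @export
relative_power_change <- function(power, times,
                                  baseline = c(-0.4, -0.2),
                                  analysis = c(0, 2)) {
  if (is.vector(power)) power <- matrix(power, nrow = 1)
  stopifnot(ncol(power) == length(times))
  bix <- in_window(times, baseline)
  aix <- in_window(times, analysis)
  if (!any(bix)) stop("baseline window lies outside the epoch")
  if (!any(aix)) stop("analysis window lies outside the epoch")
  apply(power, 1, function(p) {
    b <- mean(p[bix], na.rm = TRUE)
    a <- mean(p[aix], na.rm = TRUE)
    if (!is.finite(b) || b <= 0) stop("baseline power must be positive")
    (a - b) / b
  })
}

#' Epoch-averaged band power time courses from a spectral tensor
#'
#' Mean over epochs of squared coefficient magnitude, averaged over each
#' band's bins; masked (edge) samples are returned as `NA`.
#'
#' @param st a [morlet_tfr()] result.
#' @param grid the [frequency_grid()] used for the decomposition.
#' @return bands x T matrix (rownames = band names) of power, `NA` where
#'   every contributing bin is edge-masked.
#' @export
band_power_timecourse <- function(st, grid) {
  stopifnot(inherits(st, "spectral_tensor"),
            inherits(grid, "frequency_grid"),
            length(grid$freqs) == length(st$freqs))
  pow <- apply(Mod(st$coef)^2, c(2, 3), mean)   # F x T
  pow[!st$valid] <- NA
  bands <- unique(grid$band)
  out <- matrix(NA_real_, length(bands), ncol(pow),
                dimnames = list(bands, NULL))
  for (b in bands) {
    rows <- pow[grid$band == b, , drop = FALSE]
    mu <- colMeans(rows, na.rm = TRUE)
    mu[!is.finite(mu)] <- NA
    out[b, ] <- mu
  }
  out
}
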