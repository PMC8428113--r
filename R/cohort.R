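#' Default frequency band definitions
#'
#' Canonical MEG bands used throughout the pipeline: theta 3-7 Hz, alpha
#' 8-12 Hz, beta 13-30 Hz, low gamma 31-60 Hz, high gamma 61-120 Hz.
#'
#' @return named list of `c(fmin, fmax)` pairs (Hz).
#' @export
default_bands <- function() {
  list(theta = c(3, 7), alpha = c(8, 12), beta = c(13, 30),
       lowgamma = c(31, 60), highgamma = c(61, 120))
}

# band-limited analytic driver: m complex exponentials spread over the
# band with random phases, normalized so the real part has unit variance
narrowband_driver <- function(t, band, n_comp = NULL) {
  if (is.null(n_comp)) {
    n_comp <- max(3, min(12, round(band[2] - band[1])))
  }
  freqs <- seq(band[1], band[2], length.out = n_comp)
  theta <- runif(n_comp, 0, 2 * pi)
  z <- complex(real = numeric(length(t)), imaginary = numeric(length(t)))
  for (j in seq_len(n_comp)) {
    z <- z + exp(1i * (2 * pi * freqs[j] * t + theta[j]))
  }
  z / sqrt(n_comp / 2)
}

#' Simulate a multi-subject cohort of sub-ROI source time series
#'
#' Generates epoched, condition-labeled sub-ROI time series for a cohort
#' of subjects. Every sub-ROI carries 1/f (slope -1) background noise.
#' For each planted [coupling_spec()], the seed and target sub-ROIs share
#' a band-limited oscillatory driver; the target copy is phase-lagged by
#' the condition's lag plus per-epoch von Mises jitter, so the imaginary
#' coherence of the pair is condition-specific while oscillatory power is
#' not. Per-subject coupling fidelity (drawn uniform on
#' `fidelity_range`) scales coupling amplitude and drives behavior
#' through the truth's behavior link. Per-sub-ROI random sign flips
#' emulate the surface-normal sign ambiguity of source-space data.
#'
#' In the maintenance phase, half of the epochs (rounded down) carry an
#' "impulse": from `impulse_latency` seconds into the epoch, the
#' condition's power-gain pattern (truth's `impulse_patterns`) adds
#' band-limited signal to the flagged sub-ROIs, emulating the readout of
#' activity-silent memory traces by a task-irrelevant noise burst.
#'
#' @param layout a [roi_layout()].
#' @param truth a [ground_truth()].
#' @param n_subjects number of subjects.
#' @param epochs_per_condition mean epochs per condition per subject
#'   (defaults: 58 maintenance, 115 encoding).
#' @param epoch_sd SD of the per-subject-condition epoch count (0 =
#'   identical counts; 7 emulates realistic rejection variability).
#' @param epoch_length epoch duration in seconds (default 2.5 for
#'   maintenance, 1.5 for encoding).
#' @param sample_rate sampling rate, Hz (500 after typical MEG
#'   downsampling).
#' @param phase `"maintenance"` (time 0 = memory cue) or `"encoding"`
#'   (epoch starts 0.5 s before sound onset).
#' @param impulse_latency impulse onset in epoch time (s); only epochs
#'   longer than this can express impulse patterns.
#' @param bands band definitions (name -> c(fmin, fmax)); coupling and
#'   impulse band names must appear here.
#' @param fidelity_range range of the per-subject coupling fidelity.
#' @param noise_sd standard deviation of the 1/f background noise
#'   (0 = noiseless, useful for analytic-limit checks).
#' @param sign_flip_prob probability that a sub-ROI's waveform sign is
#'   flipped (0 disables the surface-normal ambiguity).
#' @param seed master integer seed; all randomness derives from it.
#' @return object of class `cohort`: `epochs[[subject]][[condition]]` is
#'   a K x N x T array, plus `sfreq`, `times`, `phase`, `layout`,
#'   `impulse` flags (maintenance only), `behavior` table, `fidelity`,
#'   `sign_flips`, `truth`, `bands`, `seed`.
#' @export
simulate_cohort <- function(layout, truth, n_subjects = 17,
                            epochs_per_condition = NULL, epoch_sd = 0,
                            epoch_length = NULL, sample_rate = 500,
                            phase = c("maintenance", "encoding"),
                            impulse_latency = 2.5,
                            bands = default_bands(),
                            fidelity_range = c(0.6, 1),
                            noise_sd = 1, sign_flip_prob = 0.5,
                            seed = 1) {
  phase <- match.arg(phase)
  stopifnot(inherits(layout, "roi_layout"), inherits(truth, "ground_truth"))
  if (is.null(epochs_per_condition)) {
    epochs_per_condition <- if (phase == "maintenance") 58 else 115
  }
  if (is.null(epoch_length)) {
    epoch_length <- if (phase == "maintenance") 2.5 else 1.5
  }
  t_start <- if (phase == "maintenance") 0 else -0.5
  n_cond <- 6L
  n_sub <- layout$n_total
  T_len <- round(epoch_length * sample_rate)
  times <- t_start + (seq_len(T_len) - 1) / sample_rate
  band_names <- names(bands)
  for (cp in truth$couplings) {
    if (!cp$band %in% band_names) {
      stop("coupling band '", cp$band, "' is not in the configured bands")
    }
    if (cp$seed_sub > n_sub || cp$target_sub > n_sub) {
      stop("coupling references a sub-ROI outside the layout")
    }
    if (length(cp$dphi) != n_cond) {
      stop("coupling must specify one phase lag per condition")
    }
  }
  if (!is.null(truth$impulse_patterns)) {
    bad <- !truth$impulse_patterns$band %in% band_names
    if (any(bad)) stop("impulse pattern band outside configured bands")
    if (any(truth$impulse_patterns$sub > n_sub)) {
      stop("impulse pattern references a sub-ROI outside the layout")
    }
  }

  # subject-level draws: fidelity and sign flips
  set.seed(derive_seed(seed, "subjects"))
  fidelity <- runif(n_subjects, fidelity_range[1], fidelity_range[2])
  sign_flips <- matrix(ifelse(runif(n_subjects * n_sub) < sign_flip_prob,
                              -1, 1),
                       n_subjects, n_sub)
  # per-subject-condition epoch counts
  set.seed(derive_seed(seed, "counts"))
  K <- matrix(pmax(8L, round(rnorm(n_subjects * n_cond,
                                   epochs_per_condition, epoch_sd))),
              n_subjects, n_cond)

  impulse_mask <- times >= impulse_latency
  epochs <- vector("list", n_subjects)
  impulse <- if (phase == "maintenance") vector("list", n_subjects) else NULL
  for (s in seq_len(n_subjects)) {
    econd <- vector("list", n_cond)
    icond <- vector("list", n_cond)
    for (cc in seq_len(n_cond)) {
      k <- K[s, cc]
      set.seed(derive_seed(seed, "epochs", s, cc))
      arr <- array(0, dim = c(k, n_sub, T_len))
      flags <- rep(FALSE, k)
      if (phase == "maintenance") {
        flags[sample(k, floor(k / 2))] <- TRUE
      }
      for (e in seq_len(k)) {
        # background 1/f noise, independent per sub-ROI
        if (noise_sd > 0) {
          for (r in seq_len(n_sub)) {
            arr[e, r, ] <- noise_sd * pink_noise(T_len)
          }
        }
        # planted couplings: shared driver, lagged target copy
        for (cp in truth$couplings) {
          z <- narrowband_driver(times, bands[[cp$band]])
          lag <- rvonmises(1, cp$dphi[cc], cp$kappa)
          a <- cp$amplitude * fidelity[s]
          arr[e, cp$seed_sub, ] <- arr[e, cp$seed_sub, ] + a * Re(z)
          arr[e, cp$target_sub, ] <- arr[e, cp$target_sub, ] +
            a * Re(z * exp(-1i * lag))
        }
        # impulse power patterns on flagged epochs, after the latency
        if (flags[e] && !is.null(truth$impulse_patterns) &&
            any(impulse_mask)) {
          pat <- truth$impulse_patterns[
            truth$impulse_patterns$condition == cc, , drop = FALSE]
          for (j in seq_len(nrow(pat))) {
            zb <- narrowband_driver(times, bands[[pat$band[j]]])
            arr[e, pat$sub[j], ] <- arr[e, pat$sub[j], ] +
              pat$gain[j] * Re(zb) * impulse_mask
          }
        }
      }
      # surface-normal sign ambiguity
      for (r in seq_len(n_sub)) arr[, r, ] <- arr[, r, ] * sign_flips[s, r]
      econd[[cc]] <- arr
      icond[[cc]] <- flags
    }
    names(econd) <- paste0("C", seq_len(n_cond))
    epochs[[s]] <- econd
    if (phase == "maintenance") {
      names(icond) <- paste0("C", seq_len(n_cond))
      impulse[[s]] <- icond
    }
  }
  names(epochs) <- sprintf("S%02d", seq_len(n_subjects))
  if (!is.null(impulse)) names(impulse) <- names(epochs)

  behavior <- simulate_behavior(truth, fidelity,
                                seed = derive_seed(seed, "behavior"))

  structure(list(epochs = epochs, sfreq = sample_rate, times = times,
                 phase = phase, layout = layout, impulse = impulse,
                 behavior = behavior, fidelity = fidelity,
                 sign_flips = sign_flips, truth = truth, bands = bands,
                 impulse_latency = impulse_latency, seed = seed),
            class = "cohort")
}

#' Simulate behavioral performance from coupling fidelity
#'
#' Maps each subject's coupling fidelity to a proportion-correct score
#' via the truth's linear behavior link:
#' `p = clip(intercept + slope * fidelity + noise, 0, 1)`.
#'
#' @param truth a [ground_truth()] (supplies the link parameters).
#' @param fidelity numeric vector of per-subject coupling fidelities.
#' @param seed integer seed for the behavioral noise.
#' @return data.frame with columns `subject`, `fidelity`, `p_correct`.
#' @export
simulate_behavior <- function(truth, fidelity, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"), all(is.finite(fidelity)))
  bl <- truth$behavior_link
  set.seed(seed)
  p <- clip(bl$intercept + bl$slope * fidelity +
              rnorm(length(fidelity), 0, bl$noise_sd), 0, 1)
  data.frame(subject = sprintf("S%02d", seq_along(fidelity)),
             fidelity = fidelity, p_correct = p,
             stringsAsFactors = FALSE)
}

#' Align sub-ROI waveform signs within each ROI
#'
#' Source-space sub-ROI time series have an arbitrary sign (surface-normal
#' ambiguity). This heuristic flips each sub-ROI so that its concatenated
#' single-epoch time series correlates positively with the ROI's mean
#' reference waveform, iterating a few times so the majority sign
#' dominates. With few or mutually incoherent sub-ROIs the reference is
#' weak and alignment may fail, a known limitation of sign-alignment
#' heuristics.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param n_iter reference/flip refinement iterations.
#' @return the cohort with aligned signs and an `alignment` matrix
#'   (subject x sub-ROI, the applied flips).
#' @export
align_signs <- function(cohort, n_iter = 3) {
  stopifnot(inherits(cohort, "cohort"))
  n_subj <- length(cohort$epochs)
  n_sub <- cohort$layout$n_total
  applied <- matrix(1, n_subj, n_sub)
  for (s in seq_len(n_subj)) {
    # concatenate epochs (all conditions) into one series per sub-ROI
    X <- do.call(cbind, lapply(cohort$epochs[[s]], function(arr) {
      matrix(aperm(arr, c(2, 3, 1)), n_sub)
    }))
    for (roi in cohort$layout$rois$name) {
      subs <- roi_subs(cohort$layout, roi)
      if (length(subs) < 2) next
      flips <- rep(1, length(subs))
      for (it in seq_len(n_iter)) {
        # leave-one-out reference: a row must not vote for its own sign
        new_flips <- flips
        for (j in seq_along(subs)) {
          ref <- colSums(X[subs, , drop = FALSE] * flips) -
            flips[j] * X[subs[j], ]
          if (sd(ref) == 0) next
          cr <- suppressWarnings(stats::cor(X[subs[j], ], ref))
          new_flips[j] <- if (is.finite(cr) && cr < 0) -1 else 1
        }
        if (identical(new_flips, flips)) break
        flips <- new_flips
      }
      applied[s, subs] <- flips
      for (j in seq_along(subs)) {
        if (flips[j] < 0) {
          for (cc in seq_along(cohort$epochs[[s]])) {
            cohort$epochs[[s]][[cc]][, subs[j], ] <-
              -cohort$epochs[[s]][[cc]][, subs[j], ]
          }
        }
      }
    }
  }
  cohort$alignment <- applied
  cohort
}

#' Save / load a cohort
#'
#' Cohorts are persisted with R's native serialization. The ground truth
#' and metadata travel with the epoch arrays so an analysis can always be
#' audited against what was planted.
#'
#' @param cohort a `cohort` object.
#' @param path file path (conventionally `.rds`).
#' @return `save_cohort`: `path` invisibly; `load_cohort`: the cohort.
#' @export
save_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  saveRDS(cohort, path)
  invisible(path)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "cohort"))
  obj
}

#' @export
print.cohort <- function(x, ...) {
  ks <- vapply(x$epochs, function(s) sum(vapply(s, function(a) dim(a)[1],
                                                0L)), 0L)
  cat("<cohort> ", length(x$epochs), " subjects, 6 conditions, phase=",
      x$phase, "\n  sub-ROIs: ", x$layout$n_total, ", sfreq: ", x$sfreq,
      " Hz, epoch: [", round(min(x$times), 3), ", ",
      round(max(x$times) + 1 / x$sfreq, 3), ") s\n  epochs/subject: ",
      paste(range(ks), collapse = "-"), ", planted couplings: ",
      length(x$truth$couplings), "\n", sep = "")
  invisible(x)
}
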