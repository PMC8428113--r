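#' ROI layout of a simulated cortical parcellation
#'
#' Describes the abstract region-of-interest (ROI) geometry of a simulated
#' cohort: each ROI has a name, a hemisphere, and a number of sub-ROIs
#' (approximately equal-size subdivisions that expose spatial pattern
#' structure). Seed ROIs are the regions whose sub-ROIs anchor all
#' connectivity features (auditory superior temporal cortex in the default
#' layout).
#'
#' @param rois data.frame with columns `name`, `hemi`, `n_sub`.
#' @param seed_rois character vector of seed ROI names (must appear in
#'   `rois$name`).
#' @return object of class `roi_layout` with the ROI table, seed names,
#'   and a global sub-ROI index map (`index`, a named list of integer
#'   vectors forming a bijection onto `1..n_total`).
#' @export
#' @examples
#' lay <- roi_layout()
#' lay$n_total
roi_layout <- function(rois = NULL, seed_rois = NULL) {
  if (is.null(rois)) {
    # default layout mirroring an auditory working-memory study: STC seed
    # (12 left / 13 right sub-ROIs) plus frontoparietal targets per
    # hemisphere; non-STC counts are plausible stand-ins
    rois <- data.frame(
      name = c("STC_lh", "IFG_lh", "CMF_lh", "LOF_lh", "RMF_lh", "PC_lh",
               "SM_lh",
               "STC_rh", "IFG_rh", "CMF_rh", "LOF_rh", "RMF_rh", "PC_rh",
               "SM_rh"),
      hemi = rep(c("lh", "rh"), each = 7),
      n_sub = c(12, 9, 6, 7, 8, 9, 8,
                13, 9, 6, 7, 8, 9, 8),
      stringsAsFactors = FALSE
    )
    seed_rois <- c("STC_lh", "STC_rh")
  }
  stopifnot(is.data.frame(rois),
            all(c("name", "hemi", "n_sub") %in% names(rois)),
            all(rois$n_sub >= 1), !anyDuplicated(rois$name))
  if (is.null(seed_rois)) seed_rois <- rois$name[1]
  stopifnot(all(seed_rois %in% rois$name))
  idx <- list()
  offset <- 0L
  for (i in seq_len(nrow(rois))) {
    idx[[rois$name[i]]] <- offset + seq_len(rois$n_sub[i])
    offset <- offset + as.integer(rois$n_sub[i])
  }
  structure(list(rois = rois, seed_rois = seed_rois, index = idx,
                 n_total = offset),
            class = "roi_layout")
}

#' Sub-ROI indices of one ROI
#' @param layout a [roi_layout()].
#' @param roi ROI name.
#' @return integer vector of global sub-ROI indices.
#' @export
roi_subs <- function(layout, roi) {
  stopifnot(inherits(layout, "roi_layout"))
  out <- layout$index[[roi]]
  if (is.null(out)) stop("unknown ROI: ", roi)
  out
}

#' Specification of one planted interregional coupling
#'
#' A coupling plants a shared band-limited oscillatory driver in one seed
#' sub-ROI and one target sub-ROI; the target copy is phase-lagged by a
#' condition-specific lag with per-epoch von Mises jitter of concentration
#' `kappa`. This implements content-specific phase synchronization: each
#' stimulus class corresponds to a different phase lag, so the imaginary
#' coherence between the pair carries class information.
#'
#' @param seed_sub global index of the seed sub-ROI.
#' @param target_sub global index of the target sub-ROI.
#' @param band band name (must exist in the analysis frequency grid).
#' @param dphi per-condition phase lags (radians, in (-pi, pi]), one per
#'   stimulus class.
#' @param kappa von Mises concentration of the per-epoch lag jitter
#'   (>= 0; `Inf` = deterministic lag).
#' @param amplitude driver amplitude (a.u.) relative to the unit-variance
#'   1/f background noise.
#' @return object of class `coupling_spec`.
#' @export
coupling_spec <- function(seed_sub, target_sub, band,
                          dphi = seq(-2.5, 2.5, length.out = 6),
                          kappa = 10, amplitude = 1) {
  stopifnot(kappa >= 0, all(dphi > -pi & dphi <= pi),
            length(seed_sub) == 1, length(target_sub) == 1)
  structure(list(seed_sub = as.integer(seed_sub),
                 target_sub = as.integer(target_sub),
                 band = band, dphi = dphi, kappa = kappa,
                 amplitude = amplitude),
            class = "coupling_spec")
}

#' Ground truth of a simulated cohort
#'
#' Bundles everything the generator plants and the recovery tests must
#' find: the coupling inventory, condition-specific impulse power
#' patterns, and the linear link from per-subject coupling fidelity to
#' behavioral proportion correct.
#'
#' @param couplings list of [coupling_spec()] objects (empty = null
#'   cohort).
#' @param impulse_patterns data.frame with columns `condition`, `sub`
#'   (global sub-ROI index), `band`, `gain` (> 0, amplitude of the
#'   band-limited power perturbation added after the impulse latency on
#'   impulse trials), or `NULL` for none.
#' @param behavior_link list with `intercept`, `slope`, `noise_sd` mapping
#'   subject coupling fidelity to proportion correct. Defaults give a
#'   cohort mean proportion correct of 0.84 when fidelity ~ U(0.6, 1).
#' @param master_seed integer master seed recorded with the truth.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(couplings = list(), impulse_patterns = NULL,
                         behavior_link = list(intercept = 0.6, slope = 0.3,
                                              noise_sd = 0.08),
                         master_seed = 1) {
  stopifnot(is.list(couplings),
            all(vapply(couplings, inherits, TRUE, "coupling_spec")))
  if (!is.null(impulse_patterns)) {
    stopifnot(is.data.frame(impulse_patterns),
              all(c("condition", "sub", "band", "gain") %in%
                    names(impulse_patterns)),
              all(impulse_patterns$gain > 0))
  }
  stopifnot(all(c("intercept", "slope", "noise_sd") %in%
                  names(behavior_link)))
  structure(list(couplings = couplings,
                 impulse_patterns = impulse_patterns,
                 behavior_link = behavior_link,
                 master_seed = master_seed),
            class = "ground_truth")
}
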