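#' Build and validate a run configuration
#'
#' A run configuration collects every parameter of an end-to-end
#' experiment: cohort geometry and ground truth, band and window
#' definitions, decoder settings, inference settings, and the master
#' seed. Unspecified fields take the study-design defaults. Validation
#' rejects malformed configurations with the offending field path;
#' band definitions must be non-overlapping and lie within 3-120 Hz.
#'
#' @param config named list (or path to a YAML file) overriding
#'   defaults; see the vignette for the full schema.
#' @return validated configuration, class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    schema_version = 1,
    seed = 1,
    layout = NULL,                    # NULL = default roi_layout()
    truth = list(couplings = list(), impulse_patterns = NULL,
                 behavior_link = list(intercept = 0.6, slope = 0.3,
                                      noise_sd = 0.08)),
    cohort = list(n_subjects = 17, epochs_per_condition = 58,
                  epoch_sd = 0, epoch_length = 2.5, sample_rate = 500,
                  phase = "maintenance", impulse_latency = 2.5,
                  fidelity_range = c(0.6, 1)),
    bands = default_bands(),
    bins_per_band = c(theta = 5, alpha = 5, beta = 18, lowgamma = 20,
                      highgamma = 21),
    windows = list(early = c(0.5, 1.25), late = c(1.25, 2)),
    decoder = list(kernel = "linear", cost = 1, scheme = "row",
                   train_fraction = 0.75, n_repeats = 100),
    inference = list(n_perm = 500, splits_per_perm = 10, alpha = 0.05),
    behavior = list(enabled = FALSE, n_perm = 1000, pca_variance = 0.95)
  )
  # parameter groups merge field-by-field; structural fields (bands,
  # windows, layout, truth, bins_per_band) replace wholesale
  cfg <- defaults
  merge_groups <- c("cohort", "decoder", "inference", "behavior", "truth")
  for (nm in names(config)) {
    cfg[[nm]] <- if (nm %in% merge_groups && is.list(config[[nm]])) {
      modifyList(defaults[[nm]], config[[nm]])
    } else {
      config[[nm]]
    }
  }
  fail <- function(path, msg) stop("config error at ", path, ": ", msg,
                                   call. = FALSE)
  # bands: inside 3-120 Hz, non-overlapping
  if (!is.list(cfg$bands) || is.null(names(cfg$bands))) {
    fail("bands", "must be a named list of c(fmin, fmax)")
  }
  for (nm in names(cfg$bands)) {
    b <- cfg$bands[[nm]]
    if (length(b) != 2 || b[1] >= b[2]) {
      fail(paste0("bands.", nm), "must be c(fmin, fmax) with fmin < fmax")
    }
    if (b[1] < 3 || b[2] > 120) {
      fail(paste0("bands.", nm), "must lie within 3-120 Hz")
    }
  }
  edges <- do.call(rbind, cfg$bands[order(vapply(cfg$bands, `[`, 0, 1))])
  if (nrow(edges) > 1 &&
      any(edges[-1, 1] <= edges[-nrow(edges), 2] - 1e-9)) {
    fail("bands", "bands must be non-overlapping")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    fail("seed", "must be a single integer")
  }
  if (cfg$cohort$n_subjects < 2) fail("cohort.n_subjects", "need >= 2")
  if (!cfg$cohort$phase %in% c("maintenance", "encoding")) {
    fail("cohort.phase", "must be 'maintenance' or 'encoding'")
  }
  if (cfg$inference$n_perm < 1) fail("inference.n_perm", "need >= 1")
  for (w in names(cfg$windows)) {
    ww <- cfg$windows[[w]]
    if (length(ww) != 2 || ww[1] >= ww[2]) {
      fail(paste0("windows.", w), "must be c(tmin, tmax), tmin < tmax")
    }
  }
  structure(cfg, class = "run_config")
}

# materialize layout/truth objects from a config
config_layout <- function(cfg) {
  if (is.null(cfg$layout)) return(roi_layout())
  rois <- as.data.frame(do.call(rbind, lapply(cfg$layout$rois, as.data.frame)))
  rois$n_sub <- as.integer(rois$n_sub)
  roi_layout(rois, cfg$layout$seed_rois)
}

config_truth <- function(cfg) {
  cps <- lapply(cfg$truth$couplings, function(cp) {
    coupling_spec(cp$seed_sub, cp$target_sub, cp$band,
                  dphi = cp$dphi %||% seq(-2.5, 2.5, length.out = 6),
                  kappa = cp$kappa %||% 10,
                  amplitude = cp$amplitude %||% 1)
  })
  ip <- cfg$truth$impulse_patterns
  if (!is.null(ip) && !is.data.frame(ip)) {
    ip <- do.call(rbind, lapply(ip, as.data.frame))
  }
  ground_truth(cps, ip, cfg$truth$behavior_link, master_seed = cfg$seed)
}

stage_log <- function(verbose, stage, ...) {
  if (verbose) {
    kv <- paste(vapply(list(...), as.character, ""), collapse = " ")
    message(sprintf("stage=%s %s", stage, kv))
  }
}

#' Run a full experiment from a configuration
#'
#' Executes simulate -> equalize -> connectivity features -> decode ->
#' permutation inference (-> behavioral SVR) in order, persisting every
#' stage's output under `out_dir` and recording a manifest (config hash,
#' per-stage file digests, wall-clock, seed ledger) sufficient to re-run
#' bit-identically. Stages already persisted are reused when `resume =
#' TRUE`.
#'
#' @param config a [run_config()] (or list/path accepted by it).
#' @param out_dir output directory (created if missing).
#' @param resume reuse persisted intermediates when present.
#' @param verbose emit structured progress logs.
#' @return the manifest, invisibly; result files land in `out_dir`
#'   (`cohort.rds`, `features.rds`, `results.csv`, `nulls.csv`,
#'   `behavior.csv` when enabled, `manifest.json`).
#' @export
run_experiment <- function(config, out_dir, resume = FALSE,
                           verbose = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(schema_version = cfg$schema_version,
                   package_version =
                     as.character(utils::packageVersion("syncdecode")),
                   seed = cfg$seed, stages = list())
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       null = "null", digits = NA, pretty = TRUE)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  timing <- function(stage, expr) {
    t0 <- Sys.time()
    res <- expr
    manifest$stages[[stage]]$seconds <<-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }
  layout <- config_layout(cfg)
  truth <- config_truth(cfg)

  # --- simulate -----------------------------------------------------------
  cohort_path <- file.path(out_dir, "cohort.rds")
  seed_sim <- derive_seed(cfg$seed, "simulate")
  cohort <- if (resume && file.exists(cohort_path)) {
    stage_log(verbose, "simulate", "resumed=true")
    load_cohort(cohort_path)
  } else {
    timing("simulate", {
      co <- simulate_cohort(
        layout, truth, n_subjects = cfg$cohort$n_subjects,
        epochs_per_condition = cfg$cohort$epochs_per_condition,
        epoch_sd = cfg$cohort$epoch_sd,
        epoch_length = cfg$cohort$epoch_length,
        sample_rate = cfg$cohort$sample_rate, phase = cfg$cohort$phase,
        impulse_latency = cfg$cohort$impulse_latency,
        bands = cfg$bands, fidelity_range = cfg$cohort$fidelity_range,
        seed = seed_sim)
      save_cohort(co, cohort_path)
      stage_log(verbose, "simulate", paste0("subjects=",
                                            cfg$cohort$n_subjects),
                paste0("seed=", seed_sim))
      co
    })
  }
  manifest$stages$simulate$seed <- seed_sim
  manifest$stages$simulate$file <- unname(tools::md5sum(cohort_path))

  # --- features -----------------------------------------------------------
  feat_path <- file.path(out_dir, "features.rds")
  seed_eq <- derive_seed(cfg$seed, "equalize")
  seed_feat <- derive_seed(cfg$seed, "features")
  grid <- frequency_grid(cfg$bands, cfg$bins_per_band)
  features <- if (resume && file.exists(feat_path)) {
    stage_log(verbose, "features", "resumed=true")
    readRDS(feat_path)
  } else {
    timing("features", {
      co_eq <- equalize_epochs(cohort, seed = seed_eq)
      ft <- connectivity_features(co_eq, grid, windows = cfg$windows,
                                  seed = seed_feat)
      saveRDS(ft, feat_path)
      stage_log(verbose, "features", paste0("tests=", length(ft$tests)),
                paste0("seed=", seed_feat))
      ft
    })
  }
  manifest$stages$features$seed <- c(equalize = seed_eq,
                                     features = seed_feat)
  manifest$stages$features$file <- unname(tools::md5sum(feat_path))

  # --- decode + inference -------------------------------------------------
  timing("decode", {
    labels <- factor(features$meta$condition)
    rows <- list()
    null_rows <- list()
    for (key in names(features$tests)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      spec <- decoder_spec(kernel = cfg$decoder$kernel,
                           cost = cfg$decoder$cost,
                           scheme = cfg$decoder$scheme,
                           train_fraction = cfg$decoder$train_fraction,
                           n_repeats = cfg$decoder$n_repeats,
                           seed = derive_seed(cfg$seed, "decode", key))
      res <- cross_subject_decode(features$tests[[key]], labels, spec,
                                  subjects = features$meta$subject,
                                  test_id = key)
      nd <- label_permutation_null(
        features$tests[[key]], labels, spec,
        n_perm = cfg$inference$n_perm,
        splits_per_perm = cfg$inference$splits_per_perm,
        subjects = features$meta$subject,
        seed = derive_seed(cfg$seed, "null", key))
      rows[[key]] <- data.frame(test = key, pair = parts[1],
                                band = parts[2], window = parts[3],
                                accuracy = res$accuracy,
                                n_train = res$n_train,
                                n_test = res$n_test,
                                stringsAsFactors = FALSE)
      null_rows[[key]] <- nd$values
      stage_log(verbose, "decode", paste0("test=", key),
                paste0("accuracy=", round(res$accuracy, 4)))
    }
    results <- do.call(rbind, rows)
    nulls <- do.call(rbind, null_rows)
    report <- maxstat_correct(setNames(results$accuracy, results$test),
                              nulls, pooling = "max",
                              alpha = cfg$inference$alpha)
    results$p <- report$table$p
    results$significant <- report$table$significant
    write.csv(results, file.path(out_dir, "results.csv"),
              row.names = FALSE)
    write.csv(data.frame(test = rownames(nulls), nulls,
                         row.names = NULL),
              file.path(out_dir, "nulls.csv"), row.names = FALSE)
  })
  manifest$stages$decode$file <-
    unname(tools::md5sum(file.path(out_dir, "results.csv")))

  # --- behavioral SVR (optional) ------------------------------------------
  if (isTRUE(cfg$behavior$enabled)) {
    timing("behavior", {
      meta <- features$meta
      bhv_tab <- cohort$behavior
      bhv <- bhv_tab$p_correct[match(meta$subject, bhv_tab$subject)]
      # rows for the SVR: subject x subsample, conditions averaged
      svr_tests <- list()
      for (pair in unique(vapply(strsplit(names(features$tests), "|",
                                          fixed = TRUE), `[`, "", 1))) {
        for (b in features$bands) {
          wnames <- names(features$windows)
          keys <- paste0(pair, "|", b, "|", wnames)
          if (!all(keys %in% names(features$tests))) next
          per_win <- list()
          for (i in seq_along(wnames)) {
            m <- features$tests[[keys[i]]]
            agg <- aggregate(m, by = list(subject = meta$subject,
                                          subsample = meta$subsample),
                             FUN = mean)
            per_win[[wnames[i]]] <-
              as.matrix(agg[, -(1:2), drop = FALSE])
          }
          svr_tests[[paste0(pair, "|", b)]] <- per_win
        }
      }
      agg_meta <- aggregate(seq_along(meta$subject),
                            by = list(subject = meta$subject,
                                      subsample = meta$subsample),
                            FUN = length)
      bhv_rows <- bhv_tab$p_correct[match(agg_meta$subject,
                                          bhv_tab$subject)]
      svr <- svr_permutation_null(svr_tests, bhv_rows,
                                  agg_meta$subsample,
                                  n_perm = cfg$behavior$n_perm,
                                  pca_variance = cfg$behavior$pca_variance,
                                  alpha = cfg$inference$alpha,
                                  seed = derive_seed(cfg$seed, "svr"))
      write.csv(svr$report$table, file.path(out_dir, "behavior.csv"),
                row.names = FALSE)
      stage_log(verbose, "behavior",
                paste0("threshold=", round(svr$threshold, 4)))
    })
    manifest$stages$behavior$file <-
      unname(tools::md5sum(file.path(out_dir, "behavior.csv")))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Render a human-readable summary of a completed run
#'
#' Writes `report.md` under the results directory: the accuracy table
#' per connection x band x window with the max-stat null threshold and
#' the significant set, plus the behavioral SVR table when present.
#' Incomplete runs produce a listing of the missing stages.
#'
#' @param out_dir a [run_experiment()] output directory.
#' @return path to `report.md`, invisibly.
#' @export
export_report <- function(out_dir) {
  path <- file.path(out_dir, "report.md")
  lines <- c("# syncdecode run report", "")
  needed <- c(cohort = "cohort.rds", features = "features.rds",
              results = "results.csv")
  missing <- needed[!file.exists(file.path(out_dir, needed))]
  if (length(missing) == length(needed)) {
    lines <- c(lines, "No completed stages found in this directory.")
    writeLines(lines, path)
    return(invisible(path))
  }
  if (length(missing) > 0) {
    lines <- c(lines, "Incomplete run; missing stages:",
               paste0("- ", names(missing), " (", missing, ")"), "")
  }
  res_path <- file.path(out_dir, "results.csv")
  if (file.exists(res_path)) {
    res <- read.csv(res_path, stringsAsFactors = FALSE)
    nulls_path <- file.path(out_dir, "nulls.csv")
    thr <- NA_real_
    if (file.exists(nulls_path)) {
      nulls <- read.csv(nulls_path, stringsAsFactors = FALSE)
      pooled <- apply(as.matrix(nulls[, -1, drop = FALSE]), 2, max)
      thr <- unname(quantile(pooled, 0.95))
    }
    lines <- c(lines, "## Decoding accuracy per connection, band, window",
               "",
               "| test | accuracy | p | significant |",
               "|---|---|---|---|",
               sprintf("| %s | %.4f | %.4g | %s |", res$test,
                       res$accuracy, res$p, res$significant),
               "")
    if (is.finite(thr)) {
      lines <- c(lines, sprintf(
        "Max-stat null threshold (95th percentile): %.4f", thr), "")
    }
    sig <- res$test[res$significant]
    lines <- c(lines, if (length(sig) > 0) {
      c("Significant tests:", paste0("- ", sig))
    } else {
      "No test exceeded the family-wise threshold."
    }, "")
  }
  bhv_path <- file.path(out_dir, "behavior.csv")
  if (file.exists(bhv_path)) {
    bhv <- read.csv(bhv_path, stringsAsFactors = FALSE)
    lines <- c(lines, "## Behavioral SVR", "",
               paste0("| ", paste(names(bhv), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(bhv)), collapse = "|"),
                      "|"),
               apply(bhv, 1, function(r) {
                 paste0("| ", paste(r, collapse = " | "), " |")
               }), "")
  }
  writeLines(lines, path)
  invisible(path)
}
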