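#' Default pipeline configuration
#'
#' One document with per-stage blocks; defaults follow the method's
#' stated constants: 15/80 HU window, 192-pixel slices, 1 cm2 area
#' filter, 2 HU augmentation steps over 3 rounds, 60-pixel HD cap, 0.1
#' DSC and 0.5 |RAAD| acceptability bounds, 10 k-means restarts, and a
#' 0.005..0.30 threshold grid with step 0.005 (resolving the critical
#' contrast to two significant figures).
#'
#' @param ... Named overrides merged (recursively) over the defaults.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(...) {
  base <- list(
    seed = 17L,
    simulate = list(enabled = TRUE, n = 400L, patients = 40L,
                    cliff = 0.05, distribution = "uniform", side = 192L,
                    steepness = 300, dsc_floor = 0.05, dsc_ceiling = 0.75,
                    detection_floor = 0.4, noise_sd = 0.3),
    input = list(manifest = NULL),
    contrast = list(low_hu = 15, high_hu = 80, bin_width = 0.025),
    augment = list(enabled = FALSE, rounds = 3L, step_hu = 2, delta_hu = 2,
                   floor_quantile = 0.5),
    evaluate = list(source = "surrogate", pred_dir = NULL,
                    dsc_min = 0.1, hd_max = 60, raad_max = 0.5),
    threshold = list(grid_min = 0.005, grid_max = 0.3, grid_step = 0.005,
                     restarts = 10L, include_detection = FALSE,
                     min_slices_fraction = 0.5),
    validate = list(enabled = TRUE, n_seeds = 3L, test_fraction = 0.25,
                    cutoff_grid_size = 64L))
  merge_config(base, list(...))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    cg_assert(file.exists(config), "cg_error_unreadable_file",
              "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cg_assert(is.list(config), "cg_error_bad_config",
            "config must be a list or a YAML file path")
  cfg <- do.call(default_pipeline_config, config)
  # an explicit input manifest overrides the simulate default
  if (!is.null(cfg$input$manifest) && is.null(config$simulate$enabled)) {
    cfg$simulate$enabled <- FALSE
  }
  has_sim <- isTRUE(cfg$simulate$enabled)
  has_input <- !is.null(cfg$input$manifest)
  cg_assert(has_sim || has_input, "cg_error_bad_config",
            "config must provide either a simulate block or input$manifest")
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full contrast quality-control pipeline
#'
#' Executes profile, optional augmentation, evaluation, threshold
#' estimation and validation in order, from a single configuration (list
#' or YAML path). Every stochastic stage derives its seed from the config
#' seed, so two runs with the same configuration produce identical
#' reports.
#'
#' @param config Configuration list or YAML file path (see
#'   [default_pipeline_config()]).
#' @return A threshold report: list with `config`, `config_hash`, stage
#'   tables (`f_histogram`, `bin_table`, `failure_share`, `roc_sweep`,
#'   `cluster_table`, `r2_curve`), `elbow_threshold`,
#'   `selected_threshold`, `validation`, and slice counts.
#' @export
run_full_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  hash <- config_hash(cfg)
  stage <- "simulate"
  result <- tryCatch({
    if (isTRUE(cfg$simulate$enabled)) {
      pc <- phantom_config(side = cfg$simulate$side)
      ds <- generate_synthetic_dataset(
        pc, n_slices = cfg$simulate$n, n_patients = cfg$simulate$patients,
        seed = cfg$seed, distribution = cfg$simulate$distribution)
      samples <- ds$samples
      truth <- ds$truth
    } else {
      ds <- read_slice_dataset(dirname(cfg$input$manifest))
      samples <- ds$samples
      truth <- NULL
    }

    stage <- "profile"
    prof <- contrast_profile(samples, cfg$contrast$low_hu,
                             cfg$contrast$high_hu, cfg$contrast$bin_width)
    cg_assert(nrow(prof$records) >= 2, "cg_error_empty_dataset",
              "fewer than 2 non-degenerate slices")
    keep <- vapply(samples, slice_id, character(1)) %in%
      prof$records$slice_id
    samples <- samples[keep]
    contrasts <- prof$records[, c("slice_id", "fisher")]

    augment_report <- NULL
    if (isTRUE(cfg$augment$enabled)) {
      stage <- "augment"
      aug <- augment_dataset(samples, prof$records,
                             floor_quantile = cfg$augment$floor_quantile,
                             step_hu = cfg$augment$step_hu,
                             rounds = cfg$augment$rounds,
                             delta_hu = cfg$augment$delta_hu,
                             low_hu = cfg$contrast$low_hu,
                             high_hu = cfg$contrast$high_hu)
      before <- fisher_histogram(prof$records$fisher,
                                 cfg$contrast$bin_width)
      after <- fisher_histogram(aug$fisher, cfg$contrast$bin_width)
      augment_report <- list(
        n_original = length(samples), n_augmented = length(aug$samples),
        imbalance_before = max(before$counts) / sum(before$counts),
        imbalance_after = max(after$counts) / sum(after$counts),
        report = aug$report)
    }

    stage <- "evaluate"
    fisher <- contrasts$fisher
    if (identical(cfg$evaluate$source, "surrogate")) {
      sc <- surrogate_config(
        critical_contrast = cfg$simulate$cliff,
        steepness = cfg$simulate$steepness,
        dsc_floor = cfg$simulate$dsc_floor,
        dsc_ceiling = cfg$simulate$dsc_ceiling,
        detection_floor = cfg$simulate$detection_floor,
        noise_sd = cfg$simulate$noise_sd)
      preds <- surrogate_segment_dataset(samples, fisher, sc,
                                         seed = derive_seed(cfg$seed, 1L))
    } else {
      cg_assert(!is.null(cfg$evaluate$pred_dir), "cg_error_bad_config",
                "evaluate$pred_dir is required when source is not surrogate")
      preds <- lapply(samples, function(s) {
        readRDS(file.path(cfg$evaluate$pred_dir,
                          paste0(slice_id(s), ".rds")))
      })
    }
    evals <- evaluate_dataset(samples, preds,
                              dsc_min = cfg$evaluate$dsc_min,
                              hd_max = cfg$evaluate$hd_max,
                              raad_max = cfg$evaluate$raad_max)
    confusions <- lapply(seq_along(samples), function(i) {
      confusion_counts(preds[[i]], samples[[i]]$lesion_mask)
    })

    stage <- "threshold"
    grid <- seq(cfg$threshold$grid_min, cfg$threshold$grid_max,
                by = cfg$threshold$grid_step)
    sweep <- roc_sweep(confusions, fisher, grid)
    elbow <- elbow_threshold(
      sweep,
      min_slices = ceiling(cfg$threshold$min_slices_fraction *
                           length(samples)))
    feats <- cluster_feature_matrix(
      evals, contrasts,
      include_detection = isTRUE(cfg$threshold$include_detection))
    cluster_results <- cluster_all_combos(
      feats$features, restarts = cfg$threshold$restarts,
      seed = derive_seed(cfg$seed, 2L))
    sweep_r2 <- r2_threshold_sweep(cluster_results, feats$fisher, grid)
    selected <- sweep_r2$selected_threshold
    if (!is.finite(selected)) selected <- elbow
    cluster_table <- do.call(rbind, lapply(cluster_results, function(cr) {
      q <- cluster_quality(cr, feats$fisher, selected)
      data.frame(algorithm = cr$algorithm, distance = cr$distance,
                 silhouette = cr$silhouette, purity = q$purity,
                 fisher_mean_low = mean(feats$fisher[cr$labels == 0L]),
                 fisher_mean_high = mean(feats$fisher[cr$labels == 1L]),
                 stringsAsFactors = FALSE)
    }))
    bin_edges <- prof$histogram$breaks
    bins <- bin_performance(evals, contrasts, bin_edges)
    shares <- failure_share_below(evals, contrasts, selected)

    validation <- NULL
    if (isTRUE(cfg$validate$enabled)) {
      stage <- "validate"
      manifest <- data.frame(
        slice_id = contrasts$slice_id,
        patient_id = vapply(samples, function(s) s$patient_id,
                            character(1)),
        split = NA_character_, stringsAsFactors = FALSE)
      manifest <- assign_patient_split(manifest, cfg$validate$test_fraction,
                                       seed = derive_seed(cfg$seed, 3L))
      is_test <- manifest$split == "test"
      seg <- baseline_segmenter(
        cutoff_grid_size = cfg$validate$cutoff_grid_size,
        low_hu = cfg$contrast$low_hu, high_hu = cfg$contrast$high_hu)
      val <- validate_threshold(
        samples[!is_test], samples[is_test], contrasts, selected,
        segmenter = seg,
        seeds = seq_len(cfg$validate$n_seeds))
      validation <- list(comparison = val$comparison,
                         reduction_fraction = val$reduction_fraction,
                         n_train = sum(!is_test), n_test = sum(is_test))
    }

    list(config = cfg, config_hash = hash, seed = cfg$seed,
         n_slices = length(samples),
         truth = truth,
         f_histogram = prof$histogram,
         degenerate = prof$degenerate,
         augment = augment_report,
         evals = evals,
         bin_table = bins,
         failure_share = shares,
         roc_sweep = sweep,
         elbow_threshold = elbow,
         cluster_table = cluster_table,
         r2_curve = sweep_r2$r2_curve,
         selected_threshold = selected,
         validation = validation)
  }, cg_error = function(e) {
    cg_abort("cg_error_pipeline",
             "pipeline failed in stage '%s': %s", stage,
             conditionMessage(e))
  })
  result
}

#' Write a threshold report to disk
#'
#' Emits `report.json` (the full report, deterministic for a fixed config
#' and seed) plus flat CSV tables (`roc_sweep.csv`, `r2_curve.csv`,
#' `bin_table.csv`, `cluster_table.csv`, `evals.csv`) for spreadsheet
#' inspection.
#'
#' @param report List from [run_full_pipeline()].
#' @param directory Output directory (created if missing).
#' @return Invisibly, the path of `report.json`.
#' @export
write_report <- function(report, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(directory, "report.json")
  keep <- setdiff(names(report), c("evals", "truth"))
  jsonlite::write_json(report[keep], json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  for (nm in c("roc_sweep", "r2_curve", "bin_table", "cluster_table",
               "evals")) {
    if (!is.null(report[[nm]])) {
      utils::write.csv(report[[nm]],
                       file.path(directory, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(json_path)
}
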