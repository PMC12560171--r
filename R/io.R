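# Dataset manifest I/O and the end-to-end pipeline driver. A dataset on disk
# is a directory with phenotypes.csv (one row per session), one NIfTI volume
# per session named <subject_id>_<session_id>.nii.gz, and the atlas
# (atlas.nii.gz + atlas_names.json). All stage randomness flows from named
# seeds in the config; there are no hidden entropy sources.

MANIFEST_COLUMNS <- c("subject_id", "session_id", "group", "age",
                      "abeta", "ptau", "tau", "imaging_date", "clinical_date")

#' Write a generated dataset to a directory
#'
#' @param dataset list with `volumes`, `records`, `atlas` as returned by
#'   [generate_dataset()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$volumes)) {
    v <- dataset$volumes[[i]]
    write_nifti(v, file.path(out_dir, sprintf("%s_%s.nii.gz", v$subject_id,
                                              v$session_id)))
  }
  write.csv(dataset$records, file.path(out_dir, "phenotypes.csv"),
            row.names = FALSE)
  write_atlas(dataset$atlas, file.path(out_dir, "atlas.nii.gz"),
              file.path(out_dir, "atlas_names.json"))
  invisible(out_dir)
}

#' Read a dataset directory back into memory
#'
#' Validates the phenotype table (required columns, four-level diagnostic
#' groups, finite positive marker concentrations) and loads all volumes onto
#' a common grid; validation errors name the offending row or file.
#'
#' @param dir dataset directory written by [write_dataset()] /
#'   [generate_dataset()].
#' @return list with `volumes`, `records`, and `atlas` (NULL when absent).
#' @export
read_dataset <- function(dir) {
  csv <- file.path(dir, "phenotypes.csv")
  if (!file.exists(csv)) stop("missing phenotype table: ", csv, call. = FALSE)
  records <- read.csv(csv, stringsAsFactors = FALSE)
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(records))
  if (length(missing_cols) > 0L) {
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(records))) {
    g <- records$group[i]
    if (!g %in% DIAGNOSTIC_GROUPS) {
      stop("row ", i, ": invalid diagnostic group '", g,
           "' (expected CN, sMCI, pMCI or AD)", call. = FALSE)
    }
    for (m in MARKERS) {
      v <- records[[m]][i]
      if (!is.finite(v) || v <= 0) {
        stop("row ", i, ": non-finite or non-positive ", m, " value", call. = FALSE)
      }
    }
  }
  key <- paste(records$subject_id, records$session_id, sep = "_")
  if (anyDuplicated(key)) {
    stop("duplicated subject/session row(s): ",
         paste(key[duplicated(key)], collapse = ", "), call. = FALSE)
  }
  volumes <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    p <- file.path(dir, paste0(key[i], ".nii.gz"))
    if (!file.exists(p)) stop("row ", i, ": missing volume file ", p, call. = FALSE)
    volumes[[i]] <- read_nifti(p, subject_id = records$subject_id[i],
                               session_id = records$session_id[i])
  }
  check_same_grid(volumes)
  atlas <- NULL
  if (file.exists(file.path(dir, "atlas.nii.gz"))) {
    atlas <- read_atlas(file.path(dir, "atlas.nii.gz"),
                        file.path(dir, "atlas_names.json"))
  }
  list(volumes = volumes, records = records, atlas = atlas)
}

#' Default pipeline configuration
#'
#' Desk-scale settings: a 32^3 grid, a narrow three-block network and few
#' repetitions, so the full pipeline runs in minutes on one CPU. The
#' reference-scale architecture (channels 64-128-192-192-128) and grid are
#' available by overriding `conv_channels` / `grid_dims`.
#'
#' @param ... overrides of the default keys.
#' @return named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L, n_per_group = 20L, qc_fail_fraction = 0,
    grid_dims = c(32L, 32L, 32L), n_rois = 6L, n_signal = 3L,
    markers = "abeta", model = "so", loss = "mse",
    conv_channels = c(8L, 16L, 32L), head_hidden = 64L,
    n_repetitions = 2L, fractions = c(train = 0.7, val = 0.1, test = 0.2),
    learning_rate = 0.001, max_epochs = 15L, batch_size = 8L,
    attribution_steps = 32L, attribution_subjects_per_group = 5L,
    out_dir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  cfg
}

read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> QC -> stratified Monte-Carlo splits -> per-repetition
#' regressor training -> latent-embedding transfer (diagnosis CN-vs-AD and
#' progression sMCI-vs-pMCI) -> CSF cutoff / threshold-sweep baselines ->
#' integrated-gradients attribution with group differences and regional
#' summaries. Deterministic for a fixed config. When `out_dir` is set,
#' metrics tables (CSV) and a provenance log (JSON) are written.
#'
#' @param config a [pipeline_config()] list, or a path to a JSON file of
#'   overrides.
#' @return list with `regression` (per repetition x marker metrics),
#'   `classification` (Marker, Context, Acc, Sens, Spec, AUC, F1 per
#'   repetition), `baselines`, `attribution` (ranking + regional summaries),
#'   `qc_reports` and the realized `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stage <- "simulate"
  result <- tryCatch({
    ds <- generate_dataset(config$n_per_group, effect_config(),
                           qc_fail_fraction = config$qc_fail_fraction,
                           seed = config$seed, grid_dims = config$grid_dims,
                           n_rois = config$n_rois, n_signal = config$n_signal)

    stage <- "qc"
    qc <- apply_qc(ds$volumes)
    keep <- which(qc$reports$passed)
    volumes <- ds$volumes[keep]
    records <- ds$records[keep, , drop = FALSE]

    stage <- "split"
    splits <- monte_carlo_splits(records, n_repetitions = config$n_repetitions,
                                 fractions = config$fractions,
                                 seed = derive_seed(config$seed, "splits"))

    stage <- "train"
    n_heads <- if (config$model == "mo") 3L else 1L
    markers <- if (n_heads == 3L) MARKERS else config$markers[1L]
    net_cfg <- mrinet_config(conv_channels = config$conv_channels,
                             head_hidden = config$head_hidden,
                             n_heads = n_heads, input_dims = config$grid_dims,
                             markers = markers)
    targets <- as.matrix(records[, markers, drop = FALSE])
    reg_rows <- list(); cls_rows <- list(); models <- list()
    for (rep_i in seq_along(splits)) {
      sp <- splits[[rep_i]]
      idx <- function(ids) which(records$subject_id %in% ids)
      tc <- train_config(loss = config$loss,
                         learning_rate = config$learning_rate,
                         max_epochs = config$max_epochs,
                         batch_size = config$batch_size,
                         seed = derive_seed(config$seed, paste0("train", rep_i)))
      fit <- train_regressor(mrinet(net_cfg, seed = derive_seed(config$seed,
                                                                paste0("init", rep_i))),
                             volumes, targets, idx(sp$train), idx(sp$val), tc)
      models[[rep_i]] <- fit$model
      pred <- mrinet_predict(fit$model, volumes[idx(sp$test)])$pred
      for (m in markers) {
        rm_ <- regression_metrics(records[[m]][idx(sp$test)], pred[, m])
        reg_rows[[length(reg_rows) + 1L]] <-
          cbind(data.frame(repetition = rep_i, marker = m), rm_)
      }

      emb <- extract_embeddings(fit$model, volumes)
      for (ctx in list(list(name = "Diagnosis", pos = "AD", neg = "CN"),
                       list(name = "Progression", pos = "pMCI", neg = "sMCI"))) {
        rows_ctx <- which(records$group %in% c(ctx$pos, ctx$neg))
        labs <- as.integer(records$group[rows_ctx] == ctx$pos)
        tr <- which(records$subject_id[rows_ctx] %in% sp$train)
        te <- which(records$subject_id[rows_ctx] %in% sp$test)
        clf <- fit_proxy_classifier(emb[rows_ctx, , drop = FALSE], labs, tr, te)
        cm <- classification_metrics(labs[te], clf$scores)
        cls_rows[[length(cls_rows) + 1L]] <- data.frame(
          Marker = paste(markers, collapse = "+"), Context = ctx$name,
          Acc = cm$acc, Sens = cm$sens, Spec = cm$spec, AUC = cm$auc,
          F1 = cm$f1, repetition = rep_i)
      }
    }

    stage <- "baseline"
    base_rows <- list()
    for (ctx in list(list(name = "Diagnosis", pos = "AD", neg = "CN"),
                     list(name = "Progression", pos = "pMCI", neg = "sMCI"))) {
      rows_ctx <- which(records$group %in% c(ctx$pos, ctx$neg))
      labs <- as.integer(records$group[rows_ctx] == ctx$pos)
      for (m in MARKERS) {
        spec <- cutoff_spec(m)
        cm <- cutoff_classifier(records[[m]][rows_ctx], labs, spec)
        sw <- threshold_sweep(records[[m]][rows_ctx], labs, spec$orientation)
        base_rows[[length(base_rows) + 1L]] <- data.frame(
          Context = ctx$name, Marker = m, cutoff = spec$value,
          cutoff_acc = cm$acc, cutoff_auc = cm$auc,
          sweep_best_threshold = sw$best_threshold,
          sweep_best_acc = sw$best_accuracy)
      }
    }

    stage <- "attribute"
    att <- NULL
    if (config$attribution_subjects_per_group > 0L) {
      model1 <- models[[1L]]
      sel <- unlist(lapply(DIAGNOSTIC_GROUPS, function(g) {
        utils::head(which(records$group == g), config$attribution_subjects_per_group)
      }))
      raw_maps <- lapply(sel, function(i) {
        integrated_gradients(model1, volumes[[i]], target_head = 1L,
                             n_steps = config$attribution_steps)
      })
      scaled_maps <- lapply(raw_maps, postprocess_attribution)
      gd <- group_difference_maps(scaled_maps, records$group[sel])
      ranking <- rank_pair_magnitudes(gd$pair_diffs, ds$atlas)
      regional <- do.call(rbind, lapply(names(gd$pair_diffs), function(p) {
        cbind(pair = p, regional_summary(gd$pair_diffs[[p]], ds$atlas))
      }))
      att <- list(ranking = ranking, regional = regional,
                  dominant_sign = dominant_sign(raw_maps, ds$atlas))
    }

    list(regression = do.call(rbind, reg_rows),
         classification = do.call(rbind, cls_rows),
         baselines = do.call(rbind, base_rows),
         attribution = att, qc_reports = qc$reports,
         config = config)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(result$regression,
              file.path(config$out_dir, "regression_metrics.csv"), row.names = FALSE)
    write.csv(result$classification,
              file.path(config$out_dir, "classification_metrics.csv"), row.names = FALSE)
    write.csv(result$baselines,
              file.path(config$out_dir, "baseline_metrics.csv"), row.names = FALSE)
    if (!is.null(result$attribution)) {
      write.csv(result$attribution$regional,
                file.path(config$out_dir, "attribution_regional.csv"),
                row.names = FALSE)
    }
    write.csv(result$qc_reports, file.path(config$out_dir, "qc_reports.csv"),
              row.names = FALSE)
    provenance <- list(config = config,
                       r_version = as.character(getRversion()),
                       package_version = as.character(utils::packageVersion("csfproxy")),
                       timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(provenance, file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  result
}
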