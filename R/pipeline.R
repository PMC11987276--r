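#' Pipeline configuration
#'
#' Per-module parameter blocks plus a single global seed from which every
#' module derives its own stream (see [derive_seed()]). Unknown keys in a
#' block are rejected.
#'
#' @param seed global integer seed.
#' @param strict abort on the first per-image failure instead of isolating it.
#' @param preprocess,morphometry,features,model named lists overriding the
#'   per-module defaults.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, strict = FALSE, preprocess = list(),
                            morphometry = list(), features = list(),
                            model = list()) {
  defaults <- list(
    preprocess = list(mode = "green", clip_limit = 0.01, tile_grid = c(8, 8),
                      background_scale = 0.25),
    morphometry = list(min_length_px = 10, sigma_px = 2, spacing_px = 1),
    features = list(),
    model = list(k = 4, folds = 5, nca_iters = 500))
  merge_block <- function(name, user) {
    base <- defaults[[name]]
    unknown <- setdiff(names(user), names(base))
    if (length(unknown))
      pq_stop(sprintf("unknown key(s) in %s block: %s", name,
                      paste(unknown, collapse = ", ")))
    utils::modifyList(base, user)
  }
  structure(list(seed = seed, strict = strict,
                 preprocess = merge_block("preprocess", preprocess),
                 morphometry = merge_block("morphometry", morphometry),
                 features = merge_block("features", features),
                 model = merge_block("model", model)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

new_manifest <- function(command, config, inputs = character()) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(command = command, config_hash = config_hash(config),
       input_checksums = sums,
       software_version = as.character(utils::packageVersion("plusquant")),
       seed = config$seed, started = format(Sys.time(), usetz = TRUE),
       images = list(), outputs = character())
}

manifest_record <- function(manifest, image_id, status, reason = NULL) {
  manifest$images[[image_id]] <- list(status = status, reason = reason)
  manifest
}

write_manifest <- function(manifest, path) {
  manifest$finished <- format(Sys.time(), usetz = TRUE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Quantify vessel morphometry for a batch of images
#'
#' For every image id in the disc table, loads the vessel mask, runs the
#' morphometry chain and computes the 10-feature vector. Failures are
#' isolated per image (recorded in the manifest) unless `config$strict`.
#'
#' @param cohort_dir directory in the cohort layout (`masks/<id>.png`,
#'   `discs.csv`).
#' @param out_dir output directory; receives `features.csv` and
#'   `manifest_quantify.json`.
#' @param config a [pipeline_config()].
#' @return Invisibly, the feature data frame (one row per image, feature
#'   columns plus `image_id`).
#' @export
run_quantify <- function(cohort_dir, out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  discs_csv <- file.path(cohort_dir, "discs.csv")
  if (!file.exists(discs_csv)) pq_stop("missing discs.csv in ", cohort_dir)
  discs <- read_disc_annotations(discs_csv)
  manifest <- new_manifest("quantify", config, discs_csv)
  rows <- list()
  for (id in names(discs)) {
    mask_path <- file.path(cohort_dir, "masks", paste0(id, ".png"))
    res <- tryCatch({
      if (!file.exists(mask_path)) pq_stop("missing mask for ", id)
      mask <- read_mask_png(mask_path)
      mp <- config$morphometry
      graph <- analyze_vessels(mask, min_length_px = mp$min_length_px,
                               sigma_px = mp$sigma_px,
                               spacing_px = mp$spacing_px)
      fv <- compute_feature_vector(graph, mask, discs[[id]], dim(mask),
                                   strict = config$strict)
      as.data.frame(as.list(fv))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (config$strict) pq_stop("image ", id, " failed: ",
                                 conditionMessage(res))
      manifest <- manifest_record(manifest, id, "failed",
                                  conditionMessage(res))
    } else {
      manifest <- manifest_record(manifest, id, "ok")
      rows[[id]] <- cbind(data.frame(image_id = id), res)
    }
  }
  if (!length(rows)) pq_stop("no image quantified successfully")
  feats <- do.call(rbind, rows)
  rownames(feats) <- NULL
  out_csv <- file.path(out_dir, "features.csv")
  write.csv(feats, out_csv, row.names = FALSE)
  manifest$outputs <- out_csv
  write_manifest(manifest, file.path(out_dir, "manifest_quantify.json"))
  invisible(feats)
}

#' Fit and evaluate the severity model on a quantified cohort
#'
#' Reads (or computes) the feature table, joins it with the grade table,
#' builds the average-score target, selects `k` features by NCA, fits the
#' linear severity model, and evaluates it by k-fold cross-validation.
#' Predictions (raw and clamped) are written per image. A cohort without
#' grades yields predictions only when a fitted `model` is supplied.
#'
#' @param cohort_dir cohort directory (see [generate_cohort()] layout).
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @param features optional precomputed feature data frame (skips
#'   [run_quantify()]).
#' @param model optional prefitted `severity_model` (skip fitting; predict
#'   only).
#' @return List with `features`, `model`, `cv` (`cv_report` or NULL),
#'   `predictions` (data frame), `nca` (or NULL).
#' @export
run_end_to_end <- function(cohort_dir, out_dir, config = pipeline_config(),
                           features = NULL, model = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(features))
    features <- run_quantify(cohort_dir, out_dir, config)
  manifest <- new_manifest("end_to_end", config)
  grades_csv <- file.path(cohort_dir, "grades.csv")
  cv <- NULL; nca <- NULL
  if (is.null(model) && !file.exists(grades_csv))
    pq_stop("no grades.csv and no prefitted model: nothing to fit or predict")
  grid_cols <- c("max_diameter_3dd", "mean_diameter_3dd",
                 "mean_sdc_tortuosity_3dd", "top1pct_curvature_3dd",
                 "vessel_density_3dd", "max_diameter_whole",
                 "mean_diameter_whole", "mean_sdc_tortuosity_whole",
                 "top1pct_curvature_whole", "vessel_density_whole")
  if (is.null(model)) {
    grades <- read_grade_table(grades_csv)
    orphans_f <- setdiff(features$image_id, grades$image_id)
    orphans_g <- setdiff(grades$image_id, features$image_id)
    if (length(orphans_f) || length(orphans_g))
      pq_stop("grade/feature image-id mismatch; orphans: ",
              paste(c(orphans_f, orphans_g), collapse = ", "))
    grades <- grades[match(features$image_id, grades$image_id), ]
    y <- apply(grade_matrix(grades), 1, average_score)
    X <- as.matrix(features[, grid_cols])
    ok_rows <- stats::complete.cases(X)
    X <- X[ok_rows, , drop = FALSE]; y <- y[ok_rows]
    if (nrow(X) >= 10) {
      nca <- nca_regression_weights(X, y, iters = config$model$nca_iters,
                                    seed = derive_seed(config$seed, "nca"))
      sel <- select_features(nca, config$model$k)
    } else {
      # too few samples for NCA: fall back to the canonical selected quartet
      sel <- match(c("max_diameter_3dd", "mean_sdc_tortuosity_3dd",
                     "vessel_density_whole", "top1pct_curvature_whole"),
                   grid_cols)[seq_len(min(config$model$k, 4))]
    }
    model <- fit_linear(X[, sel, drop = FALSE], y,
                        feature_names = grid_cols[sel])
    cv <- kfold_cv(X[, sel, drop = FALSE], y, k = config$model$folds,
                   seed = config$seed)
    save_severity_model(model, file.path(out_dir, "model.json"))
    jsonlite::write_json(
      list(mse_mean = cv$mse_mean, mse_sd = cv$mse_sd,
           mae_mean = cv$mae_mean, mae_sd = cv$mae_sd, seed = cv$seed),
      file.path(out_dir, "cv_report.json"), auto_unbox = TRUE, digits = NA)
  }
  preds <- do.call(rbind, lapply(seq_len(nrow(features)), function(i) {
    x <- unlist(features[i, model$selected_features])
    if (anyNA(x))
      return(data.frame(image_id = features$image_id[i], raw = NA_real_,
                        clamped = NA_real_))
    p <- predict_severity(model, x)
    data.frame(image_id = features$image_id[i], raw = p$raw,
               clamped = p$clamped)
  }))
  pred_csv <- file.path(out_dir, "predictions.csv")
  write.csv(preds, pred_csv, row.names = FALSE)
  manifest$outputs <- c(pred_csv, file.path(out_dir, "features.csv"))
  for (id in preds$image_id)
    manifest <- manifest_record(manifest, id,
                                if (anyNA(preds[preds$image_id == id, ]))
                                  "failed" else "ok")
  write_manifest(manifest, file.path(out_dir, "manifest_end_to_end.json"))
  list(features = features, model = model, cv = cv, predictions = preds,
       nca = nca)
}
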