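#' Detect bifurcation points on a skeleton
#'
#' Bifurcations are skeleton pixels with three or more neighbours in
#' 8-connectivity. The input must be a 1-px-wide skeleton (re-thinning must be
#' a no-op), otherwise neighbour counts are unreliable and an error is raised.
#' Results are sorted row-major for determinism.
#'
#' @param skeleton binary skeleton matrix.
#' @return Integer n x 2 matrix of 0-based (row, col) bifurcation pixels.
#' @export
detect_bifurcations <- function(skeleton) {
  m <- assert_skeleton(skeleton)
  nb <- neighbor_count_cpp(m)
  rc <- arrayInd(which(nb >= 3 & m > 0), dim(m))
  rc <- rc[order(rc[, 1], rc[, 2]), , drop = FALSE]
  rc - 1L
}

#' Sample training patches around given centers
#'
#' Draws `n` centers without replacement (seeded), excluding centers closer
#' than `size/2` to the image border, and cuts `size x size` patches using the
#' half-open window `[c - size/2, c + size/2)` in each dimension.
#'
#' @param img `working_image` or matrix in `[0, 1]`.
#' @param mask binary vessel mask of the same shape.
#' @param centers n x 2 matrix of 0-based (row, col) candidate centers
#'   (typically [detect_bifurcations()] output).
#' @param n number of patches.
#' @param size even patch side length (default 128).
#' @param seed integer seed.
#' @param source_id identifier recorded with each patch.
#' @return List of `training_patch` objects: `image_patch`, `mask_patch`,
#'   `center`, `source_id`.
#' @export
sample_patches <- function(img, mask, centers, n, size = 128, seed = 1,
                           source_id = "img") {
  stopifnot(size %% 2 == 0, size >= 8)
  m <- unclass_matrix(img)
  msk <- as_binary_matrix(mask)
  stopifnot(all(dim(m) == dim(msk)))
  centers <- matrix(as.numeric(centers), ncol = 2)
  h <- size %/% 2
  H <- nrow(m); W <- ncol(m)
  # center c keeps rows [c-h, c+h-1] inside [0, H-1]
  ok <- centers[, 1] >= h & centers[, 1] <= H - h - 1 + 1e-9 &
        centers[, 2] >= h & centers[, 2] <= W - h - 1 + 1e-9
  valid <- centers[ok, , drop = FALSE]
  if (nrow(valid) == 0)
    pq_stop("no valid centers after border exclusion; ",
            "fall back to random vessel-pixel centers")
  if (n > nrow(valid))
    pq_stop(sprintf("requested %d patches but only %d valid centers", n,
                    nrow(valid)))
  set.seed(seed)
  pick <- sort(sample.int(nrow(valid), n))
  lapply(pick, function(i) {
    r0 <- round(valid[i, 1]) - h + 1 # 1-based start
    c0 <- round(valid[i, 2]) - h + 1
    structure(list(image_patch = m[r0:(r0 + size - 1), c0:(c0 + size - 1)],
                   mask_patch = msk[r0:(r0 + size - 1), c0:(c0 + size - 1)],
                   center = valid[i, ], source_id = source_id),
              class = "training_patch")
  })
}

#' Split patches into training and validation sets
#'
#' Seeded shuffle, then a disjoint, exhaustive split with
#' `floor(train_fraction * n)` training patches.
#'
#' @param patches list of patches.
#' @param train_fraction fraction in (0, 1); 0.8 by default.
#' @param seed integer seed.
#' @return List with `train` and `val`.
#' @export
split_patches <- function(patches, train_fraction = 0.8, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- length(patches)
  if (n < 2) pq_stop("need at least 2 patches to split")
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- max(1, floor(train_fraction * n))
  list(train = patches[sort(idx[seq_len(n_train)])],
       val = patches[sort(idx[(n_train + 1):n])])
}

#' Soft Tversky index
#'
#' `TI = sum(p*t) / (sum(p*t) + alpha*sum((1-p)*t) + beta*sum(p*(1-t)) + eps)`.
#' With `alpha = beta = 0.5` this is the (soft) Dice coefficient. The Tversky
#' loss used for training is `1 - TI`; weighting false negatives more than
#' false positives (`alpha > beta`) favours recall of thin vessels.
#'
#' @param pred numeric array of probabilities in `[0, 1]`.
#' @param target binary array of the same shape.
#' @param alpha false-negative weight.
#' @param beta false-positive weight.
#' @param eps numerical stabiliser.
#' @return Index in `[0, 1]`; 1 when both prediction and target are empty.
#' @export
tversky_index <- function(pred, target, alpha = 0.7, beta = 0.3, eps = 1e-7) {
  stopifnot(all(dim(pred) == dim(target)) || length(pred) == length(target),
            alpha >= 0, beta >= 0)
  p <- as.numeric(pred); t <- as.numeric(target)
  if (!all(t %in% c(0, 1))) pq_stop("target must be binary")
  inter <- sum(p * t)
  fn <- sum((1 - p) * t)
  fp <- sum(p * (1 - t))
  if (inter + fn + fp == 0) return(1) # both empty: perfect by convention
  inter / (inter + alpha * fn + beta * fp + eps)
}

#' Segmenter configuration
#'
#' @param depth number of U-Net resolution levels (>= 2).
#' @param base_channels channels at the finest level (doubled per level).
#' @param tversky_alpha,tversky_beta Tversky loss weights (defaults 0.7/0.3,
#'   emphasising recall of thin vessels).
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param seed integer seed for weight init and shuffling.
#' @param threshold probability threshold at inference.
#' @return `segmenter_config` list.
#' @export
segmenter_config <- function(depth = 3, base_channels = 16, tversky_alpha = 0.7,
                             tversky_beta = 0.3, learning_rate = 1e-3,
                             epochs = 10, batch_size = 8, seed = 1,
                             threshold = 0.5) {
  stopifnot(depth >= 2, tversky_alpha >= 0, tversky_beta >= 0,
            threshold > 0, threshold < 1)
  structure(list(depth = depth, base_channels = base_channels,
                 tversky_alpha = tversky_alpha, tversky_beta = tversky_beta,
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, seed = seed, threshold = threshold),
            class = "segmenter_config")
}

patches_to_mat <- function(patches, field) {
  do.call(cbind, lapply(patches, function(p) as.numeric(p[[field]])))
}

#' Train the vessel segmenter
#'
#' Trains the encoder/decoder network with the Tversky loss (Adam,
#' seeded shuffling; deterministic on a fixed BLAS/thread configuration).
#'
#' @param train,val lists of patches from [sample_patches()]/[split_patches()].
#' @param config a [segmenter_config()].
#' @return `segmenter_model`: list with `weights` (numeric vector), `config`,
#'   and `training_log` (data frame of per-epoch train/val Tversky loss).
#' @export
train_segmenter <- function(train, val, config = segmenter_config()) {
  if (!length(train) || !length(val)) pq_stop("train and val must be non-empty")
  if (all(vapply(train, function(p) sum(p$mask_patch) == 0, TRUE)))
    pq_stop("degenerate labels: all training masks are empty")
  ph <- nrow(train[[1]]$image_patch); pw <- ncol(train[[1]]$image_patch)
  if (ph %% 2^(config$depth - 1) != 0 || pw %% 2^(config$depth - 1) != 0)
    pq_stop("patch size must be divisible by 2^(depth-1)")
  w0 <- unet_init_cpp(config$depth, config$base_channels,
                      derive_seed(config$seed, "unet-init"))
  fit <- unet_train_cpp(patches_to_mat(train, "image_patch"),
                        patches_to_mat(train, "mask_patch"),
                        patches_to_mat(val, "image_patch"),
                        patches_to_mat(val, "mask_patch"),
                        w0, ph, pw, config$depth, config$base_channels,
                        config$tversky_alpha, config$tversky_beta,
                        config$learning_rate, config$epochs, config$batch_size,
                        derive_seed(config$seed, "unet-shuffle"), 1e-7)
  if (isTRUE(fit$diverged))
    pq_stop("training diverged (non-finite loss); lower the learning rate")
  structure(list(weights = as.numeric(fit$weights), config = config,
                 training_log = data.frame(epoch = seq_along(fit$train_loss),
                                           train_loss = fit$train_loss,
                                           val_loss = fit$val_loss)),
            class = "segmenter_model")
}

#' Predict a vessel mask for a full image
#'
#' Sliding-window inference with overlap averaging, thresholded at
#' `config$threshold`. Images smaller than the tile (or with a trailing
#' partial tile) are reflect-padded and cropped back.
#'
#' @param model a `segmenter_model`.
#' @param img `working_image` or matrix in `[0, 1]`.
#' @param tile tile side (>= 128 recommended; must be divisible by
#'   `2^(depth-1)`).
#' @param overlap overlap between neighbouring tiles (px).
#' @return Logical mask of the image shape.
#' @export
predict_mask <- function(model, img, tile = 256, overlap = 32) {
  m <- unclass_matrix(img)
  prob <- predict_probability(model, m, tile, overlap)
  prob >= model$config$threshold
}

#' @rdname predict_mask
#' @export
predict_probability <- function(model, img, tile = 256, overlap = 32) {
  m <- unclass_matrix(img)
  cfg <- model$config
  div <- 2^(cfg$depth - 1)
  tile <- max(div, (tile %/% div) * div)
  H <- nrow(m); W <- ncol(m)
  padH <- max(0, tile - H); padW <- max(0, tile - W)
  if (padH > 0 || padW > 0) m <- reflect_pad(m, padH, padW)
  Hp <- nrow(m); Wp <- ncol(m)
  step <- tile - overlap
  starts <- function(total) {
    if (total <= tile) return(1)
    s <- seq(1, total - tile + 1, by = step)
    if (s[length(s)] + tile - 1 < total) s <- c(s, total - tile + 1)
    s
  }
  acc <- matrix(0, Hp, Wp); cnt <- matrix(0, Hp, Wp)
  for (r in starts(Hp)) {
    for (c in starts(Wp)) {
      sub <- m[r:(r + tile - 1), c:(c + tile - 1)]
      p <- unet_predict_cpp(model$weights, sub, cfg$depth, cfg$base_channels)
      acc[r:(r + tile - 1), c:(c + tile - 1)] <-
        acc[r:(r + tile - 1), c:(c + tile - 1)] + p
      cnt[r:(r + tile - 1), c:(c + tile - 1)] <-
        cnt[r:(r + tile - 1), c:(c + tile - 1)] + 1
    }
  }
  (acc / cnt)[1:H, 1:W]
}

reflect_pad <- function(m, padH, padW) {
  H <- nrow(m); W <- ncol(m)
  if (padH > 0) m <- rbind(m, m[H:(H - padH + 1), , drop = FALSE])
  if (padW > 0) m <- cbind(m, m[, W:(W - padW + 1), drop = FALSE])
  m
}

#' Remove small connected components from a mask
#'
#' Area opening: connected components (8-connectivity) smaller than
#' `min_area` pixels are removed; everything else is untouched. This realises
#' the post-segmentation cleanup that eliminates small false-positive
#' regions; `literal_disk = TRUE` instead applies a classical morphological
#' opening with a disc structuring element of `min_area` px diameter (which
#' at 200 px would erase all vessels — provided for comparison only).
#'
#' @param mask binary matrix.
#' @param min_area minimum component area kept (default 200 px).
#' @param literal_disk use a disc-opening instead of area opening.
#' @return Logical mask.
#' @export
clean_mask <- function(mask, min_area = 200, literal_disk = FALSE) {
  m <- as_binary_matrix(mask)
  stopifnot(min_area >= 0)
  if (literal_disk) {
    k <- EBImage::makeBrush(max(3, 2 * (min_area %/% 2) + 1), shape = "disc")
    return(t(EBImage::imageData(EBImage::opening(EBImage::Image(t(m)), k))) > 0)
  }
  lab <- EBImage::bwlabel(EBImage::Image(t(m)))
  a <- t(EBImage::imageData(lab))
  if (max(a) == 0) return(m > 0)
  sizes <- tabulate(a[a > 0], nbins = max(a))
  keep <- which(sizes >= min_area)
  out <- matrix(a %in% keep, nrow(m), ncol(m))
  out
}

#' Boundary-F1 (BF) score
#'
#' Precision/recall of boundary pixels matched within `tolerance_px`
#' (default 0.75% of the image diagonal), combined as `F = 2PR/(P+R)`.
#' Returns 1 when both masks are empty and 0 when exactly one boundary is
#' empty.
#'
#' @param pred,truth binary masks of equal shape.
#' @param tolerance_px matching tolerance; `NULL` for the default.
#' @return Score in `[0, 1]`.
#' @export
bf_score <- function(pred, truth, tolerance_px = NULL) {
  p <- as_binary_matrix(pred); t <- as_binary_matrix(truth)
  stopifnot(all(dim(p) == dim(t)))
  if (is.null(tolerance_px))
    tolerance_px <- 0.0075 * sqrt(sum(dim(p)^2))
  bp <- boundary_pixels(p); bt <- boundary_pixels(t)
  if (!any(bp) && !any(bt)) return(1)
  if (!any(bp) || !any(bt)) return(0)
  dp <- dist_to_set(bp); dtt <- dist_to_set(bt)
  precision <- mean(dtt[bp] <= tolerance_px)
  recall <- mean(dp[bt] <= tolerance_px)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

boundary_pixels <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  er <- pad[2:(H + 1), 2:(W + 1)] &
        pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
        pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  m > 0 & !er
}

# Euclidean distance from every pixel to the nearest TRUE pixel of `set`
dist_to_set <- function(set) {
  t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(1 - set)))))
}

#' Save / load a segmenter model
#'
#' The model is written as a JSON config plus a plain-text weight vector.
#'
#' @param model a `segmenter_model`.
#' @param path base path (without extension).
#' @return `save_segmenter`: invisibly the base path; `load_segmenter`: the
#'   model.
#' @export
save_segmenter <- function(model, path) {
  jsonlite::write_json(unclass(model$config), paste0(path, "_config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(format(model$weights, digits = 17), paste0(path, "_weights.txt"))
  write.csv(model$training_log, paste0(path, "_log.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  cfg <- jsonlite::read_json(paste0(path, "_config.json"), simplifyVector = TRUE)
  cfg <- do.call(segmenter_config, cfg[names(cfg) %in% names(formals(segmenter_config))])
  w <- as.numeric(readLines(paste0(path, "_weights.txt")))
  log <- read.csv(paste0(path, "_log.csv"))
  structure(list(weights = w, config = cfg, training_log = log),
            class = "segmenter_model")
}
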