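test_that("bifurcation detection finds junctions and rejects thick input", {
  line <- matrix(0L, 20, 20); line[10, 3:18] <- 1L
  expect_equal(nrow(detect_bifurcations(line)), 0)

  y <- matrix(0L, 41, 41)
  y[21, 1:21] <- 1L
  for (i in 0:14) { y[21 - i - 1, 21 + i + 1] <- 1L; y[21 + i + 1, 21 + i + 1] <- 1L }
  b <- detect_bifurcations(y)
  expect_equal(nrow(b), 1)
  expect_equal(b[1, ], c(20, 20)) # 0-based junction pixel

  thick <- matrix(0L, 20, 20); thick[8:12, 3:18] <- 1L
  expect_error(detect_bifurcations(thick), "skeleton")

  # synthetic branching tree: one detection cluster per generated branch point
  ph <- generate_phantom(phantom_spec(seed = 13, branch_prob = 1))
  sk <- skeletonize_mask(ph$truth$mask)
  b2 <- detect_bifurcations(sk)
  nb <- plusquant:::neighbor_count_cpp(sk * 1L)
  brute <- which(nb >= 3 & sk, arr.ind = TRUE) - 1
  expect_setequal(paste(b2[, 1], b2[, 2]), paste(brute[, 1], brute[, 2]))
})

test_that("patch sampling respects borders, centering and determinism", {
  img <- plusquant:::new_working_image(matrix(runif(256 * 256), 256, 256))
  mask <- matrix(rbinom(256 * 256, 1, 0.1), 256, 256)
  centers <- rbind(c(64, 64), c(128, 128), c(10, 128), c(191, 191))
  p <- sample_patches(img, mask, centers, 3, size = 128, seed = 7)
  expect_length(p, 3) # center (10,128) excluded by the border rule
  p1 <- sample_patches(img, mask, centers, 3, size = 128, seed = 7)
  expect_identical(lapply(p, `[[`, "center"), lapply(p1, `[[`, "center"))
  # center (64, 64) with size 128 covers rows/cols 0..127 exactly
  p64 <- sample_patches(img, mask, rbind(c(64, 64)), 1, size = 128, seed = 1)
  expect_equal(p64[[1]]$image_patch, unclass(img)[1:128, 1:128],
               ignore_attr = TRUE)
  expect_error(sample_patches(img, mask, rbind(c(5, 5)), 1, 128, 1), "centers")
})

test_that("train/val split is disjoint, exhaustive and seed-stable", {
  patches <- replicate(10, list(structure(list(x = runif(1)), class = "training_patch")))
  sp <- split_patches(patches, 0.8, seed = 3)
  expect_length(sp$train, 8)
  expect_length(sp$val, 2)
  sp5 <- split_patches(patches[1:5], 0.8, seed = 3)
  expect_length(sp5$train, 4)
  expect_identical(split_patches(patches, 0.8, seed = 3), sp)
  expect_error(split_patches(patches[1], 0.8, 1), "2 patches")
})

test_that("Tversky index matches hand-enumerated counts and edge conventions", {
  t <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 0), 3, 3)
  p_exact <- t
  expect_equal(tversky_index(p_exact, t, 0.5, 0.5), 1, tolerance = 1e-6)
  expect_equal(tversky_index(matrix(0, 3, 3), t, 0.5, 0.5), 0)
  # TP=2 FN=2 FP=2 at alpha=beta=0.5 equals Dice = 0.5
  pred <- matrix(c(1, 0, 1, 1, 0, 1, 0, 0, 0), 3, 3)
  targ <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 0), 3, 3)
  expect_equal(tversky_index(pred, targ, 0.5, 0.5), 0.5, tolerance = 1e-6)
  expect_equal(tversky_index(matrix(0, 2, 2), matrix(0, 2, 2)), 1)
})

test_that("network gradients match finite differences on a tiny patch", {
  set.seed(5)
  img <- matrix(runif(144), 12, 12)
  tgt <- matrix(rbinom(144, 1, 0.4), 12, 12)
  w <- plusquant:::unet_init_cpp(2, 4, 11)
  g <- plusquant:::unet_grad_cpp(w, img, tgt, 2, 4, 0.7, 0.3, 1e-7)
  idx <- sample(length(w), 25)
  fd <- vapply(idx, function(i) {
    e <- 1e-3; wp <- w; wp[i] <- wp[i] + e; wm <- w; wm[i] <- wm[i] - e
    (plusquant:::unet_loss_cpp(wp, img, tgt, 2, 4, 0.7, 0.3, 1e-7) -
     plusquant:::unet_loss_cpp(wm, img, tgt, 2, 4, 0.7, 0.3, 1e-7)) / (2 * e)
  }, numeric(1))
  big <- abs(fd) > 1e-3
  expect_gt(sum(big), 5)
  expect_lt(max(abs(g[idx][big] - fd[big]) / abs(fd[big])), 0.02)
})

test_that("a tiny segmenter trains, improves, predicts deterministically", {
  set.seed(9)
  mk_patch <- function() {
    m <- matrix(0, 32, 32)
    r <- sample(8:24, 1)
    m[r + (-1:1), ] <- 1
    img <- 0.8 - 0.5 * m + matrix(rnorm(1024, 0, 0.03), 32, 32)
    structure(list(image_patch = pmin(pmax(img, 0), 1), mask_patch = m,
                   center = c(16, 16), source_id = "toy"),
              class = "training_patch")
  }
  patches <- replicate(30, mk_patch(), simplify = FALSE)
  sp <- split_patches(patches, 0.8, seed = 1)
  cfg <- segmenter_config(depth = 2, base_channels = 8, epochs = 6, seed = 4,
                          batch_size = 4)
  model <- train_segmenter(sp$train, sp$val, cfg)
  log <- model$training_log
  expect_lt(log$val_loss[nrow(log)], log$val_loss[1])
  model2 <- train_segmenter(sp$train, sp$val, cfg)
  expect_identical(model$training_log, model2$training_log)

  pimg <- sp$val[[1]]$image_patch
  m1 <- predict_mask(model, plusquant:::new_working_image(pimg), tile = 32, overlap = 0)
  m2 <- predict_mask(model, plusquant:::new_working_image(pimg), tile = 32, overlap = 0)
  expect_identical(m1, m2)

  bad <- lapply(patches[1:4], function(p) { p$mask_patch[] <- 0; p })
  expect_error(train_segmenter(bad, sp$val, cfg), "degenerate")

  d <- withr::local_tempdir()
  save_segmenter(model, file.path(d, "m"))
  model3 <- load_segmenter(file.path(d, "m"))
  p3 <- predict_mask(model3, plusquant:::new_working_image(pimg), tile = 32, overlap = 0)
  expect_identical(m1, p3)
})

test_that("mask cleanup removes small components only and is idempotent", {
  m <- matrix(0L, 100, 100)
  m[10:30, 10:30] <- 1L # 441 px blob
  specks <- matrix(0L, 100, 100)
  set.seed(2)
  for (i in 1:20) {
    r <- sample(40:95, 1); c <- sample(5:95, 1)
    specks[r + 0:1, c + 0:1] <- 1L
  }
  cleaned <- clean_mask((m | specks) * 1L, min_area = 200)
  expect_equal(sum(cleaned), 441)
  expect_true(all(cleaned[m == 1]))
  expect_identical(clean_mask(cleaned * 1L, 200), cleaned)

  blob199 <- matrix(0L, 50, 50); blob199[1:199] <- 1L
  expect_equal(sum(clean_mask(blob199, 200)), 0)
  blob200 <- matrix(0L, 50, 50); blob200[1:200] <- 1L
  expect_equal(sum(clean_mask(blob200, 200)), 200)
})

test_that("BF score honours the matching tolerance and symmetry", {
  sq <- matrix(0L, 60, 60); sq[20:40, 20:40] <- 1L
  expect_equal(bf_score(sq, sq), 1)
  # displaced beyond its own size: no boundary pixel within tolerance
  far <- matrix(0L, 60, 60); far[46:56, 46:56] <- 1L
  sm <- matrix(0L, 60, 60); sm[20:30, 20:30] <- 1L
  expect_equal(bf_score(far, sm, tolerance_px = 2), 0)
  dil <- matrix(0L, 60, 60); dil[19:41, 19:41] <- 1L
  expect_equal(bf_score(dil, sq, tolerance_px = 2), 1)
  expect_equal(bf_score(sq, dil, tolerance_px = 2), 1)
  expect_equal(bf_score(matrix(0L, 10, 10), matrix(0L, 10, 10)), 1)
  expect_equal(bf_score(sq, matrix(0L, 60, 60)), 0)
})
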