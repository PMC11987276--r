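test_that("skeletonization thins bars to lines and preserves topology", {
  m <- matrix(0L, 40, 60)
  m[18:22, 5:55] <- 1L
  sk <- skeletonize_mask(m)
  expect_true(all(rowSums(sk)[c(1:16, 24:40)] == 0))
  expect_true(sum(sk) >= 40) # a single thin line remains
  expect_warning(empty <- skeletonize_mask(matrix(0L, 10, 10)), "empty")
  expect_equal(sum(empty), 0)

  ph <- phantom_fixture()
  sk2 <- skeletonize_mask(ph$truth$mask)
  expect_equal(n_components8(sk2), n_components8(ph$truth$mask))
})

test_that("segment extraction handles open curves, Y junctions and covers the skeleton", {
  # single open curve
  m <- matrix(0L, 30, 30)
  for (c in 5:25) m[15, c] <- 1L
  g <- extract_segments(m)
  expect_length(g$segments, 1)

  # perfect Y: three arms meeting at one pixel
  y <- matrix(0L, 41, 41)
  y[21, 1:21] <- 1L                      # west arm
  for (i in 0:14) { y[21 - i - 1, 21 + i + 1] <- 1L } # NE arm
  for (i in 0:14) { y[21 + i + 1, 21 + i + 1] <- 1L } # SE arm
  g2 <- extract_segments(y, min_length_px = 5)
  expect_length(g2$segments, 3)
  expect_equal(nrow(g2$junctions), 1)

  # coverage: segments + junctions + discarded + isolated = skeleton
  ph <- phantom_fixture()
  sk <- skeletonize_mask(ph$truth$mask)
  g3 <- extract_segments(sk)
  jset <- paste(g3$junctions[, 1], g3$junctions[, 2])
  seg_px <- unique(do.call(rbind, lapply(g3$segments, `[[`, "pixels")))
  seg_keys <- setdiff(paste(seg_px[, 1], seg_px[, 2]), jset)
  disc_keys <- if (nrow(g3$discarded_pixels))
    setdiff(paste(g3$discarded_pixels[, 1], g3$discarded_pixels[, 2]), jset)
  else character()
  nbc <- plusquant:::neighbor_count_cpp(sk * 1L)
  iso <- which(sk & nbc == 0, arr.ind = TRUE) - 1
  iso_keys <- if (nrow(iso)) paste(iso[, 1], iso[, 2]) else character()
  covered <- unique(c(seg_keys, disc_keys, jset, iso_keys))
  all_px <- which(sk, arr.ind = TRUE) - 1
  expect_setequal(covered, paste(all_px[, 1], all_px[, 2]))

  expect_error(extract_segments(ph$truth$mask), "skeleton")
})

test_that("smoothing preserves straight lines and yields uniform spacing", {
  p <- cbind(seq(0, 40, by = 1), seq(0, 80, by = 2)) # straight line
  out <- smooth_and_resample(p)
  v <- sweep(out$points, 2, out$points[1, ])
  cross <- v[, 1] * v[nrow(v), 2] - v[, 2] * v[nrow(v), 1]
  expect_lt(max(abs(cross)) / out$length^2, 1e-9)

  s <- sine_arc_samples(5, 0.08, 150, 0.5)
  out2 <- smooth_and_resample(s$points, sigma_px = 1, spacing_px = 1)
  steps <- sqrt(rowSums(diff(out2$points)^2))
  expect_lt(max(abs(steps - out2$arc_step)) / out2$arc_step, 0.01)
  expect_identical(out2, smooth_and_resample(s$points, sigma_px = 1, spacing_px = 1))
  expect_error(smooth_and_resample(p[1:3, ]), "5 points")
})

test_that("curvature is exact on lines and circles", {
  line <- cbind(0:50, 2 * (0:50))
  k <- curvature_profile(line, sqrt(5))
  expect_true(all(abs(k) < 1e-12))

  R <- 50
  th <- seq(0, pi, length.out = 315)
  circ <- cbind(R * cos(th), R * sin(th))
  step <- R * (th[2] - th[1])
  kc <- curvature_profile(circ, step)
  interior <- 3:(length(kc) - 2)
  expect_lt(max(abs(abs(kc[interior]) - 1 / R)) * R, 0.02)
})

test_that("curvature estimator converges at first order or better", {
  errs <- vapply(c(0.5, 0.25), function(h) {
    s <- sine_arc_samples(10, 0.1, 120, h)
    k <- curvature_profile(s$points, s$spacing)
    ka <- sine_kappa_analytic(s$x_at, 10, 0.1)
    interior <- 4:(length(k) - 3)
    max(abs(k[interior] - ka[interior]))
  }, numeric(1))
  expect_lt(errs[2], errs[1] / 1.9) # halving spacing at least halves error
})

test_that("radius profile recovers bar width and flags off-mask points", {
  m <- matrix(0L, 40, 60)
  m[17:23, 5:55] <- 1L # 7 px wide bar
  pts <- cbind(rep(19, 41), 10:50) # 0-based midline row 19 = 1-based 20
  r <- radius_profile(pts, m)
  expect_true(all(abs(2 * r - 7) <= 1))
  expect_warning(radius_profile(cbind(2, 10:20), m), "outside")
  expect_error(radius_profile(pts, matrix(0L, 40, 60)), "empty")
})

test_that("full morphometry on a phantom matches generator truth", {
  sp <- phantom_spec(seed = 31, sine_amplitude_px = 4, base_width_px = 6,
                     width_decay = 0, branch_prob = 0)
  ph <- generate_phantom(sp)
  g <- analyze_vessels(ph$truth$mask)
  expect_gt(length(g$segments), 0)
  summ <- segment_summary(g)
  # constant-width vessels: mean recovered diameter within 10% of rendered width
  long <- summ[summ$length_px > 60, ]
  expect_lt(abs(mean(long$mean_diameter_px) - 6) / 6, 0.1)
  d <- withr::local_tempdir()
  write_vessel_graph(g, file.path(d, "graph.json"))
  j <- jsonlite::read_json(file.path(d, "graph.json"))
  expect_length(j$segments, length(g$segments))
})
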