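test_that("phantom generation is deterministic and straight in the zero-amplitude limit", {
  sp <- phantom_spec(seed = 8, sine_amplitude_px = 0, branch_prob = 0)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$mask, b$truth$mask)
  # all generating curves are straight: quadrature tau ~ 0
  taus <- vapply(a$truth$curves, `[[`, numeric(1), "tau")
  expect_true(all(taus < 1e-8))
})

test_that("phantom truth density equals the pixel-count ratio on its stencil", {
  ph <- phantom_fixture()
  d <- vessel_density(ph$truth$mask * 1L, ph$truth$stencil)
  expect_equal(d, ph$truth$true_density, tolerance = 1e-12)
})

test_that("severity scaling is anchored and monotone", {
  base <- phantom_spec(seed = 1)
  s1 <- severity_to_spec(1, base)
  expect_equal(s1$sine_amplitude_px, base$sine_amplitude_px)
  expect_equal(s1$base_width_px, base$base_width_px)
  s5 <- severity_to_spec(5, base)
  expect_gt(s5$sine_amplitude_px, s1$sine_amplitude_px)
  expect_gt(s5$base_width_px, s1$base_width_px)
  expect_gte(s5$n_main_vessels, s1$n_main_vessels)
})

test_that("quadrature tortuosity truth matches morphometry on rendered vessels", {
  # isolated tubes: per-curve analytic tau against the extracted segment;
  # binary-mask quantisation limits agreement to about a factor of 2 at
  # these widths, with strict monotonicity in amplitude
  tau_hat <- vapply(c(4, 8), function(A) {
    cv <- plusquant:::phantom_curve(c(100, 10), 0, pi / 2, 280, A, 80, 0, 5, 0)
    alpha <- plusquant:::render_tubes_cpp(220, 300, cv$row, cv$col,
                                          cv$halfwidth,
                                          rep(1L, length(cv$row)))
    g <- analyze_vessels(alpha >= 0.5, min_length_px = 40)
    s <- segment_summary(g)
    est <- s$sdc_tortuosity[which.max(s$length_px)]
    truth <- cv$tau
    expect_gt(est / truth, 0.5)
    expect_lt(est / truth, 2)
    est
  }, numeric(1))
  expect_true(all(diff(tau_hat) > 0))

  # full phantom: length-weighted tortuosity within a factor 2 of the
  # generator's median curve tau
  sp <- phantom_spec(seed = 77, sine_amplitude_px = 4, sine_wavelength_px = 80,
                     base_width_px = 5, width_decay = 0, branch_prob = 0,
                     n_main_vessels = 3)
  ph <- generate_phantom(sp)
  s2 <- segment_summary(analyze_vessels(ph$truth$mask, min_length_px = 40))
  ok <- !is.na(s2$sdc_tortuosity)
  wm <- sum(s2$sdc_tortuosity[ok] * s2$length_px[ok]) / sum(s2$length_px[ok])
  med_true <- median(vapply(ph$truth$curves, `[[`, numeric(1), "tau"))
  expect_gt(wm / med_true, 0.4)
  expect_lt(wm / med_true, 2.5)
})

test_that("simulated panels bin severities through ordered cut-points", {
  p <- simulated_panel(n_experts = 4, cutpoint_jitter_sd = 0, noise_sd = 0,
                       seed = 1)
  for (cp in p$cut_points) expect_equal(cp, c(1.5, 2.5, 3.5, 4.5))
  theta <- c(1.1, 1.9, 2.6, 3.4, 4.6, 5.0)
  g <- simulate_grades(theta, p)
  gm <- plusquant:::grade_matrix(g)
  for (e in 1:4) expect_equal(gm[, e], c(1, 2, 3, 3, 5, 5), ignore_attr = TRUE)
  # noiseless grades are monotone in theta
  expect_true(all(apply(gm, 2, function(col) all(diff(col[order(theta)]) >= 0))))

  p2 <- simulated_panel(n_experts = 2, cutpoint_jitter_sd = 0.6, noise_sd = 0,
                        seed = 4)
  g2 <- plusquant:::grade_matrix(simulate_grades(runif(120, 1, 5), p2))
  expect_lt(weighted_kappa_linear(g2[, 1], g2[, 2]), 1)

  theta3 <- runif(200, 1, 5)
  g3 <- simulate_grades(theta3, simulated_panel(seed = 5))
  avg <- apply(plusquant:::grade_matrix(g3), 1, average_score)
  expect_gte(cor(avg, theta3), 0.9)
})

test_that("cohorts render to disk in the pipeline layout, reproducibly", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  co <- generate_cohort(3, base_spec = phantom_spec(image_shape = c(320, 320)),
                        seed = 6, dir = d1)
  generate_cohort(3, base_spec = phantom_spec(image_shape = c(320, 320)),
                  seed = 6, dir = d2)
  expect_length(co$images, 3)
  for (f in c("discs.csv", "grades.csv", "truth.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_identical(tools::md5sum(list.files(file.path(d1, "images"), full.names = TRUE)),
                   tools::md5sum(list.files(file.path(d1, "images"), full.names = TRUE)))
  m <- read_mask_png(file.path(d1, "masks", "img_001.png"))
  expect_identical(m, co$truths[[1]]$mask)
  discs <- read_disc_annotations(file.path(d1, "discs.csv"))
  expect_named(discs, co$discs$image_id)
})
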