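test_that("channel extraction normalises and preserves shape", {
  px <- array(128, c(130, 140, 3))
  r <- raw_image(px, "gray")
  w <- to_working_channel(r)
  expect_equal(dim(w), c(130, 140))
  expect_true(all(abs(unclass(w) - 128 / 255) < 1e-12))

  px[, , 2] <- 255
  w2 <- to_working_channel(raw_image(px))
  expect_true(all(unclass(w2) == 1))

  ph <- phantom_fixture()
  wg <- to_working_channel(ph$image)
  expect_equal(unclass(wg), ph$image$pixels[, , 2] / 255,
               ignore_attr = TRUE)
  expect_error(to_working_channel(list(pixels = 1)), "raw_image")
})

test_that("CLAHE is range-safe, skips constant images, and widens the vessel gap", {
  const <- plusquant:::new_working_image(matrix(0.4, 128, 128))
  expect_warning(out <- clahe_enhance(const), "constant")
  expect_equal(unclass(out), unclass(const), ignore_attr = TRUE)

  ph <- generate_phantom(phantom_spec(seed = 21, vessel_contrast = 0.07))
  wi <- to_working_channel(ph$image)
  mask <- ph$truth$mask
  gap <- function(m) mean(m[!mask]) - mean(m[mask])
  enh <- clahe_enhance(wi)
  expect_gt(gap(unclass(enh)), gap(unclass(wi)))
  expect_gte(min(enh), 0)
  expect_lte(max(enh), 1)
  expect_gte(sd(unclass(enh)), sd(unclass(wi)) * 0.99)
})

test_that("illumination correction flattens an analytic vignette", {
  H <- 200; W <- 300
  rr <- outer(seq_len(H) - (H + 1) / 2, rep(1, W))
  cc <- outer(rep(1, H), seq_len(W) - (W + 1) / 2)
  vig <- 1 - 0.4 * (rr^2 + cc^2) / ((H / 2)^2 + (W / 2)^2)
  img <- plusquant:::new_working_image(0.8 * vig)
  out <- unclass(correct_illumination(img))
  expect_lt((max(out) - min(out)) / mean(out), 0.02)

  flat <- plusquant:::new_working_image(matrix(0.5, 128, 128))
  expect_equal(unclass(correct_illumination(flat)), matrix(0.5, 128, 128),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("illumination correction preserves vessel contrast and is idempotent", {
  ph <- generate_phantom(phantom_spec(seed = 22, vignette_strength = 0.45))
  wi <- to_working_channel(ph$image)
  c1 <- correct_illumination(wi)
  mask <- ph$truth$mask
  m1 <- unclass(c1)
  expect_gt(mean(m1[!mask]) - mean(m1[mask]), 0)
  c2 <- correct_illumination(c1)
  expect_lt(sqrt(mean((unclass(c2) - m1)^2)), 0.01)
})

test_that("provenance grows by one entry per operation", {
  ph <- phantom_fixture()
  w <- to_working_channel(ph$image)
  expect_length(provenance(w), 1)
  w <- clahe_enhance(w)
  expect_length(provenance(w), 2)
  w <- correct_illumination(w)
  expect_length(provenance(w), 3)
  expect_equal(vapply(provenance(w), `[[`, "", "step"),
               c("to_working_channel", "clahe_enhance", "correct_illumination"))
})

test_that("images round-trip through disk with provenance sidecar", {
  ph <- phantom_fixture()
  d <- withr::local_tempdir()
  img_path <- file.path(d, "img.png")
  EBImage::writeImage(EBImage::Image(aperm(ph$image$pixels / 255, c(2, 1, 3)),
                                     colormode = "Color"), img_path)
  r <- read_fundus_image(img_path)
  expect_equal(dim(r$pixels), dim(ph$image$pixels))
  expect_equal(r$pixels, ph$image$pixels, tolerance = 1.01 / 255)
  w <- preprocess_image(r)
  out_path <- file.path(d, "work.png")
  write_working_image(w, out_path)
  expect_true(file.exists(out_path))
  side <- jsonlite::read_json(file.path(d, "work.json"))
  expect_length(side, 3)
})
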