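test_that("RSD takes the strict majority and flags ties", {
  expect_equal(compute_rsd(c(2, 2, 2, 3)), list(rsd = 2L, tie = FALSE))
  expect_equal(compute_rsd(c(1, 1, 1, 1)), list(rsd = 1L, tie = FALSE))
  r <- compute_rsd(c(2, 2, 3, 3))
  expect_true(r$tie)
  expect_equal(r$rsd, 3L) # round-half-up of mean 2.5
  expect_equal(compute_rsd(c(2, 2, 3, 3), tie_rule = "min")$rsd, 2L)
  expect_error(compute_rsd(5), "2 grades")
})

test_that("average score is the arithmetic mean of present grades", {
  expect_equal(average_score(c(1, 2, 3, 4)), 2.5)
  expect_equal(average_score(c(5, 5, 5, 5)), 5)
  expect_equal(average_score(c(1, 1, 2, 3)), 1.75)
  expect_equal(average_score(c(2, NA, 4)), 3)
})

test_that("3-level collapse aggregates all Plus grades", {
  expect_equal(collapse_3level(1:5), c(1L, 2L, 3L, 3L, 3L))
  expect_error(collapse_3level(6), "1..5")
  g <- grade_table(data.frame(image_id = c("a", "b"),
                              E1 = c(4L, 1L), E2 = c(5L, 2L)))
  collapsed <- as.data.frame(lapply(g[c("E1", "E2")], collapse_3level))
  expect_true(all(unlist(collapsed) %in% 1:3))
})

test_that("weighted kappa matches hand cases and is symmetric", {
  a <- c(1, 2, 3, 4, 5, 1, 2, 3)
  expect_equal(weighted_kappa_linear(a, a), 1)
  expect_equal(weighted_kappa_linear(c(1, 1, 2, 2), c(2, 2, 1, 1), n_levels = 2), -1)
  set.seed(1)
  b <- sample(1:5, 8, replace = TRUE)
  expect_equal(weighted_kappa_linear(a, b), weighted_kappa_linear(b, a))
  expect_equal(weighted_kappa_linear(c(2, 2, 2), c(2, 2, 2)), 1) # degenerate
  # missing grades dropped pairwise
  expect_equal(weighted_kappa_linear(c(1, NA, 2, 2), c(1, 3, 2, 2)), 1)
})

test_that("kappa is invariant under distance-preserving relabeling", {
  set.seed(3)
  a <- sample(1:5, 60, replace = TRUE)
  b <- pmin(5, pmax(1, a + sample(-1:1, 60, replace = TRUE)))
  k1 <- weighted_kappa_linear(a, b)
  k2 <- weighted_kappa_linear(6 - a, 6 - b) # reverse the scale
  expect_equal(k1, k2, tolerance = 1e-12)
})

test_that("rater losses reproduce hand-computed MSE/MAE against the average", {
  g <- grade_table(data.frame(image_id = c("i1", "i2"),
                              E1 = c(2L, 3L), E2 = c(3L, 2L)))
  rep <- rater_losses(g)
  # avg scores are 2.5, 2.5; both experts deviate by 0.5 everywhere
  expect_equal(unname(rep$mse_vs_avg), c(0.25, 0.25))
  expect_equal(unname(rep$mae_vs_avg), c(0.5, 0.5))
  expect_true(all(rep$mse_vs_avg >= rep$mae_vs_avg^2 - 1e-12)) # Jensen
  expect_equal(rep$pairwise_kappa, t(rep$pairwise_kappa))

  p <- simulated_panel(seed = 2)
  gt <- simulate_grades(runif(80, 1, 5), p)
  rep2 <- rater_losses(gt)
  expect_true(all(rep2$pairwise_kappa >= -1 & rep2$pairwise_kappa <= 1))
  expect_true(all(rep2$mse_vs_avg >= 0))
  d <- withr::local_tempdir()
  write_agreement_report(rep2, file.path(d, "agree"))
  expect_true(file.exists(file.path(d, "agree.json")))
  expect_true(file.exists(file.path(d, "agree_per_expert.csv")))
})

test_that("grade tables validate input and round-trip CSV", {
  expect_error(grade_table(data.frame(E1 = 1L)), "image_id")
  expect_error(grade_table(data.frame(image_id = "a", E1 = 7L)), "1..5")
  d <- withr::local_tempdir()
  g <- simulate_grades(runif(10, 1, 5), simulated_panel(seed = 9))
  write.csv(as.data.frame(g), file.path(d, "g.csv"), row.names = FALSE)
  g2 <- read_grade_table(file.path(d, "g.csv"))
  expect_equal(plusquant:::grade_matrix(g2), plusquant:::grade_matrix(g))
})
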