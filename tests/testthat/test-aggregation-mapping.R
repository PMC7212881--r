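test_that("sample aggregation takes the median and applies the threshold rule", {
  r1 <- aggregate_sample(c(0.1, 0.2, 0.9), "s")
  expect_equal(r1$median_p, 0.2)
  expect_equal(r1$predicted_class, "nontumor")

  r2 <- aggregate_sample(c(0.4, 0.6), "s")  # even n: mean of middle two
  expect_equal(r2$median_p, 0.5)
  expect_equal(r2$predicted_class, "indeterminate")

  p <- c(rep(0.9, 97), rep(0.1, 3))
  r3 <- aggregate_sample(p, "s")
  expect_equal(r3$median_p, 0.9)
  expect_equal(r3$predicted_class, "tumor")
  expect_equal(r3$fraction_fovs_tumor_call, 0.97)

  expect_error(aggregate_sample(numeric(0)), class = "mptexture_validation_error")
  expect_error(aggregate_sample(c(0.2, 1.4)), class = "mptexture_validation_error")
})

test_that("aggregation is order-invariant and median-robust to minority outliers", {
  set.seed(7)
  p <- runif(31)
  expect_equal(aggregate_sample(p)$median_p, aggregate_sample(sample(p))$median_p)

  # fewer than half arbitrary outliers cannot cross 0.5 when the majority is unanimous
  for (k in 1:10) {
    n_major <- 21; n_out <- 10
    major <- runif(n_major, 0.8, 1)
    outliers <- runif(n_out, 0, 0.5)
    r <- aggregate_sample(c(major, outliers))
    expect_equal(r$predicted_class, "tumor")
  }
})

test_that("fraction of correct FoVs counts ties as incorrect", {
  expect_equal(fraction_correct_fovs(rep(0.9, 4), "tumor"), 1)
  expect_equal(fraction_correct_fovs(c(0.9, 0.9, 0.1, 0.9), "tumor"), 0.75)
  expect_equal(fraction_correct_fovs(rep(0.5, 5), "tumor"), 0)
  expect_equal(fraction_correct_fovs(rep(0.5, 5), "nontumor"), 0)
  expect_error(fraction_correct_fovs(numeric(0), "tumor"),
               class = "mptexture_validation_error")
})

test_that("evaluation arithmetic reproduces rates from per-type counts", {
  counts <- tibble::tibble(
    type = c("t1", "t2", "normal"),
    class = c("tumor", "tumor", "nontumor"),
    n = c(10, 10, 10),
    n_correct = c(10, 10, 10))
  ev <- evaluate_counts(counts)
  expect_equal(c(ev$sensitivity, ev$specificity, ev$correct_rate), c(100, 100, 100))

  # pooled correct rate is the prevalence-weighted mix of sens and spec
  counts2 <- tibble::tibble(type = c("a", "n"), class = c("tumor", "nontumor"),
                            n = c(30, 10), n_correct = c(24, 9))
  ev2 <- evaluate_counts(counts2)
  expect_equal(ev2$correct_rate,
               (ev2$sensitivity * 30 + ev2$specificity * 10) / 40)

  # a class absent -> its rate is undefined, not 0
  ev3 <- evaluate_counts(tibble::tibble(type = "a", class = "tumor", n = 5, n_correct = 4))
  expect_true(is.na(ev3$specificity))
  expect_equal(ev3$sensitivity, 80)

  expect_error(evaluate_counts(tibble::tibble(type = "a", class = "tumor",
                                              n = 3, n_correct = 4)),
               class = "mptexture_validation_error")
})

test_that("coin-flip predictions give ~50% rates at large n", {
  set.seed(19)
  n <- 4000
  truth <- rep(c("tumor", "nontumor"), each = n / 2)
  pred <- ifelse(runif(n) < 0.5, "tumor", "nontumor")
  ratings <- tibble::tibble(sample_id = as.character(seq_len(n)),
                            predicted_class = pred, label = truth)
  ev <- evaluate_ratings(ratings)
  sigma3 <- 3 * 50 / sqrt(n / 2)  # binomial 3-sigma in percentage points
  expect_lt(abs(ev$sensitivity - 50), sigma3)
  expect_lt(abs(ev$specificity - 50), sigma3)
})

test_that("evaluating ratings counts indeterminate as misclassified", {
  ratings <- tibble::tibble(
    sample_id = c("a", "b", "c", "d"),
    predicted_class = c("tumor", "indeterminate", "nontumor", "nontumor"),
    label = c("tumor", "tumor", "nontumor", "nontumor"),
    type = c("gbm", "gbm", "normal", "normal"))
  ev <- evaluate_ratings(ratings)
  expect_equal(ev$sensitivity, 50)
  expect_equal(ev$specificity, 100)
  expect_equal(tidy(ev)$n_correct[tidy(ev)$type == "gbm"], 1L)
  expect_equal(glance(ev)$correct_rate_pct, 75)
})

test_that("probability maps use the blue-gray-red code and render deterministically", {
  grid <- tidyr::expand_grid(grid_row = 0:1, grid_col = 0:3)
  grid$p_tumor <- rep(c(0, 1), each = 4)
  pm <- prob_map(grid)
  plt <- autoplot(pm)
  expect_s3_class(plt, "ggplot")

  expect_equal(prob_color(0), "#0000FF")
  expect_equal(prob_color(1), "#FF0000")
  expect_equal(prob_color(0.5), "#808080")
  # continuous monotone: red component non-decreasing in p
  reds <- grDevices::col2rgb(prob_color(seq(0, 1, 0.1)))["red", ]
  expect_true(all(diff(reds) >= 0))

  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "m1.png"); p2 <- file.path(dir, "m2.png")
  render_map(pm, p1)
  render_map(pm, p2)
  expect_true(file.exists(p1))
  side <- jsonlite::read_json(paste0(p1, ".json"), simplifyVector = TRUE)
  expect_equal(side$p_tumor, grid$p_tumor)
  # identical grids -> identical raw grid sidecars (rendering is a pure function)
  expect_identical(readBin(paste0(p1, ".json"), "raw", 1e6),
                   readBin(paste0(p2, ".json"), "raw", 1e6))
})
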