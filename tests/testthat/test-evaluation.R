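test_that("LOSO plan follows the fixed-validation-subject rule", {
  subjects <- sprintf("S%02d", 1:18)
  plan <- make_loso_plan(subjects, "S08", "S03")
  expect_length(plan$folds, 18)
  holds <- vapply(plan$folds, `[[`, character(1), "holdout")
  expect_identical(sort(holds), sort(subjects))
  f8 <- plan$folds[[which(holds == "S08")]]
  expect_equal(f8$validation, "S03")
  for (f in plan$folds) {
    expect_false(f$holdout %in% f$train)
    expect_false(f$validation %in% f$train)
    expect_false(f$holdout == f$validation)
    expect_length(f$train, 16)
  }
})

test_that("LOSO plan smallest case and input validation", {
  plan <- make_loso_plan(c("A", "B", "C"), "B", "C")
  expect_length(plan$folds, 3)
  expect_true(all(lengths(lapply(plan$folds, `[[`, "train")) == 1))
  expect_error(make_loso_plan(c("A", "B"), "A", "B"), ">= 3")
  expect_error(make_loso_plan(c("A", "B", "C"), "Z", "B"), "roster")
  expect_error(make_loso_plan(c("A", "B", "C"), "B", "B"), "fallback")
})

test_that("marker RMSE: zeros for perfect prediction and exact constant offsets", {
  set.seed(5)
  true <- array(stats::rnorm(4 * 101 * 16 * 3, 0, 100), c(4, 101, 16, 3))
  r0 <- marker_rmse(true, true)
  expect_true(all(r0$mean == 0))

  pred <- true
  pred[, , 5, 1] <- pred[, , 5, 1] + 10   # +10 mm on X of marker 5
  r1 <- marker_rmse(pred, true)
  expect_equal(unname(r1$mean[5, 1]), 1)
  expect_equal(sum(r1$mean != 0), 1L)

  # independent two-line oracle on a random residual field
  resid <- array(stats::rnorm(length(true), 0, 5), dim(true))
  r2 <- marker_rmse(true + resid, true)
  oracle <- sqrt(apply(resid^2, c(1, 3, 4), mean)) / 10
  expect_lt(max(abs(r2$per_cycle - oracle)), 1e-12)
  expect_error(marker_rmse(true[1:2, , , ], true), "shape")
})

test_that("DTW equals the exhaustive path-enumeration oracle on short integer series", {
  set.seed(23)
  for (trial in 1:40) {
    n <- sample(3:8, 1); m <- sample(3:8, 1)
    ref <- sample(0:4, n, replace = TRUE)
    query <- sample(0:4, m, replace = TRUE)
    d <- dtw_align(ref, query)
    expect_equal(d$cost, dtw_oracle(ref, query), tolerance = 1e-12)
  }
  # worked small instance
  d <- dtw_align(c(0, 1, 2), c(0, 0, 1, 2))
  expect_equal(d$cost, dtw_oracle(c(0, 1, 2), c(0, 0, 1, 2)))
  expect_equal(d$cost, 0)
})

test_that("DTW path properties: identity on equal series, monotone continuous steps", {
  x <- sin(seq(0, 2 * pi, length.out = 101))
  d <- dtw_align(x, x)
  expect_equal(d$cost, 0)
  expect_identical(d$path, cbind(1:101, 1:101))
  y <- sin(seq(0, 2 * pi, length.out = 101) + 0.4)
  d2 <- dtw_align(x, y)
  steps <- diff(d2$path)
  expect_true(all(steps %in% 0:1))
  expect_true(all(rowSums(steps) >= 1))
  expect_identical(d2$path[1, ], c(1L, 1L))
  expect_identical(unname(d2$path[nrow(d2$path), ]), c(101L, 101L))
})

test_that("DTW-aligned RMSE never exceeds unaligned RMSE", {
  set.seed(9)
  for (trial in 1:25) {
    ref <- stats::rnorm(101)
    query <- stats::rnorm(101)
    d <- dtw_align(ref, query)
    expect_lte(sqrt(mean((d$warped - ref)^2)), sqrt(mean((query - ref)^2)) + 1e-12)
  }
})

test_that("angle RMSE semantics: offsets survive DTW, time shifts do not", {
  base <- 30 * sin(seq(0, 2 * pi, length.out = 101)) + 10
  mk_series <- function(v) {
    s <- stats::setNames(rep(list(v), 6), imumocap:::joint_names())
    s$n_frames <- 101
    class(s) <- "joint_angle_series"
    s
  }
  truth <- list(mk_series(base))
  expect_equal(unname(angle_rmse(truth, truth)$mean), rep(0, 6))

  # a pure amplitude offset: unaligned RMSE is exactly the offset; warping
  # can trade time against amplitude on curved segments but cannot remove
  # the offset where the curve turns, so a substantial error must remain
  off <- list(mk_series(base + 5))
  expect_equal(unname(angle_rmse(off, truth, use_dtw = FALSE)$mean),
               rep(5, 6), tolerance = 1e-9)
  dtw_off <- angle_rmse(off, truth, use_dtw = TRUE)$mean
  expect_gt(min(dtw_off), 1)
  expect_lte(max(dtw_off), 5 + 1e-9)

  # a timing discrepancy: DTW removes most of it
  shifted <- list(mk_series(c(base[6:101], base[1:5])))
  nod <- angle_rmse(shifted, truth, use_dtw = FALSE)$mean
  dtw <- angle_rmse(shifted, truth, use_dtw = TRUE)$mean
  expect_gt(min(nod), 0.5)
  expect_lt(max(dtw), min(nod) / 3)
  expect_error(angle_rmse(truth, c(truth, truth)), "mismatched")
})

test_that("foot-shank swap is an involution and is skipped for untrained models", {
  cs <- fix_cycles()
  x <- stack_inputs(cs$cycles[1:3])
  expect_identical(swap_foot_shank(swap_foot_shank(x)), x)
  sw1 <- swap_foot_shank(cs$cycles[[1]]$inputs)
  expect_identical(sw1[, , 4], cs$cycles[[1]]$inputs[, , 6])
  expect_identical(sw1[, , 12], cs$cycles[[1]]$inputs[, , 14])

  m <- build_model(model_config(encoder_lstm_units = 4,
                                decoder_lstm_units = integer(0),
                                attention_heads = 1, attention_key_dim = 2,
                                conv_filters = 4, seed = 1))
  expect_message(res <- sensor_swap_check(m, cs$cycles[1:2]), "skipped")
  expect_equal(res$status, "SKIPPED")
})

test_that("swapping foot and shank streams degrades an overfit model's predictions", {
  ov <- fix_overfit()
  res <- sensor_swap_check(ov$model, ov$train)
  expect_true(res$status %in% c("PASS", "FAIL"))
  expect_gt(res$swapped_rmse, res$nominal_rmse)
  expect_gte(res$ratio, res$factor)   # overfit models are placement-specific
})

test_that("a small LOSO experiment is leakage-free, reproducible, and satisfies dtw <= nodtw", {
  cs <- fix_cycles()
  plan <- make_loso_plan(c("S01", "S02", "S03"), "S02", "S03")
  cfg <- model_config(encoder_lstm_units = 32, decoder_lstm_units = integer(0),
                      attention_heads = 2, attention_key_dim = 4,
                      conv_filters = 16, epochs = 15, batch_size = 4, seed = 2)
  rep1 <- suppressWarnings(
    run_experiment(cs, plan, cfg, early_stop_config(min_epochs = 15),
                   loss_weights(), verbose = FALSE))
  rep2 <- suppressWarnings(
    run_experiment(cs, plan, cfg, early_stop_config(min_epochs = 15),
                   loss_weights(), verbose = FALSE))
  expect_length(rep1$folds, 3)
  expect_true(all(vapply(rep1$folds, `[[`, logical(1), "ok")))
  expect_identical(rep1$marker$mean, rep2$marker$mean)
  expect_identical(rep1$angle_dtw$mean, rep2$angle_dtw$mean)
  expect_true(all(rep1$angle_dtw$per_cycle <=
                    rep1$angle_nodtw$per_cycle + 1e-9))
  expect_true(all(rep1$marker$mean >= 0))
  expect_error(run_experiment(cs, make_loso_plan(c("S01", "S02", "S09"),
                                                 "S02", "S01"),
                              cfg, verbose = FALSE),
               "S09")
})
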