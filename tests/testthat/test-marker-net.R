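test_that("biomech loss is zero iff prediction equals truth", {
  set.seed(3)
  y <- array(stats::runif(2 * 101 * 3 * 16, 1, 10), c(2, 101, 3, 16))
  l0 <- biomech_loss(y, y)
  expect_equal(as.numeric(l0), 0)
  expect_true(all(attr(l0, "components") == 0))
  yp <- y + 0.01
  expect_gt(as.numeric(biomech_loss(y, yp)), 0)
  expect_error(biomech_loss(y, y[1, , , , drop = FALSE]), "shape")
})

test_that("a constant offset error has zero smoothness component and c^2 MSE terms", {
  set.seed(4)
  y <- array(stats::runif(3 * 101 * 3 * 16, 1, 10), c(3, 101, 3, 16))
  cc <- 0.37
  l <- biomech_loss(y, y + cc)
  comp <- attr(l, "components")
  expect_equal(unname(comp["smooth"]), 0)
  expect_equal(unname(comp["mse"]), cc^2, tolerance = 1e-12)
  expect_equal(unname(comp["foot"]), cc^2, tolerance = 1e-12)
  expect_equal(unname(comp["topk"]), cc^2, tolerance = 1e-12)
})

test_that("top-k component matches a brute-force sort oracle for k in {1, 24, 48}", {
  set.seed(11)
  yt <- array(stats::rnorm(4 * 101 * 3 * 16), c(4, 101, 3, 16))
  yp <- yt + array(stats::rnorm(length(yt), 0, 0.5), dim(yt))
  # independent brute force: all 48 per-feature MSEs, sorted, top-k averaged
  err <- yp - yt
  msej <- numeric(48)
  for (ax in 1:3) for (mk in 1:16) {
    msej[ax + 3 * (mk - 1)] <- mean(err[, , ax, mk]^2)
  }
  sorted <- sort(msej, decreasing = TRUE)
  for (k in c(1L, 24L, 48L)) {
    l <- biomech_loss(yt, yp, loss_weights(foot_weight = 0, topk_k = k,
                                           smooth_weight = 0))
    expect_equal(unname(attr(l, "components")["topk"]), mean(sorted[1:k]),
                 tolerance = 1e-12)
  }
})

test_that("loss is invariant to permuting items within a batch", {
  set.seed(12)
  yt <- array(stats::rnorm(6 * 101 * 3 * 16), c(6, 101, 3, 16))
  yp <- yt + array(stats::rnorm(length(yt), 0, 0.3), dim(yt))
  perm <- sample(6)
  expect_equal(as.numeric(biomech_loss(yt, yp)),
               as.numeric(biomech_loss(yt[perm, , , ], yp[perm, , , ])),
               tolerance = 1e-12)
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(13)
  T_ <- 6; B <- 2; F_ <- 6
  yt <- array(stats::rnorm(T_ * B * F_), c(T_, B, F_))
  yp <- array(stats::rnorm(T_ * B * F_), c(T_, B, F_))
  w <- loss_weights(foot_weight = 0.8, topk_k = 3, topk_weight = 1.2,
                    smooth_weight = 0.6)
  foot <- c(2L, 5L)
  r <- imumocap:::loss_core(yt, yp, w, foot, want_grad = TRUE)
  eps <- 1e-6
  idx <- cbind(sample(T_, 25, TRUE), sample(B, 25, TRUE), sample(F_, 25, TRUE))
  for (i in seq_len(nrow(idx))) {
    yph <- yp; yph[idx[i, 1], idx[i, 2], idx[i, 3]] <- yp[idx[i, , drop = FALSE]] + eps
    ypl <- yp; ypl[idx[i, 1], idx[i, 2], idx[i, 3]] <- yp[idx[i, , drop = FALSE]] - eps
    num <- (imumocap:::loss_core(yt, yph, w, foot)$loss -
              imumocap:::loss_core(yt, ypl, w, foot)$loss) / (2 * eps)
    an <- r$grad[idx[i, 1], idx[i, 2], idx[i, 3]]
    expect_lt(abs(num - an) / max(1e-8, abs(num) + abs(an)), 1e-4)
  }
})

test_that("model builds deterministically and has the contract shapes", {
  cfg <- model_config(encoder_lstm_units = 8, decoder_lstm_units = 8,
                      attention_heads = 2, attention_key_dim = 4,
                      conv_filters = 8, seed = 21)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  x <- array(0, c(3, 101, 4, 14))
  p1 <- predict(m1, x)
  p2 <- predict(m2, x)
  expect_identical(dim(p1), c(3L, 101L, 3L, 16L))
  expect_true(all(is.finite(p1)))
  expect_identical(p1, p2)
  expect_equal(nrow(m1$params$head$W), 8)
  expect_length(m1$params$head$b, 48)   # 3 axes x 16 markers per frame
})

test_that("early stopping walks the stated rule on a frozen model", {
  cs <- fix_cycles()
  subj <- vapply(cs$cycles, `[[`, character(1), "subject_id")
  train <- cs$cycles[subj == "S01"][1:4]
  val <- cs$cycles[subj == "S02"][1:2]
  cfg <- model_config(encoder_lstm_units = 4, decoder_lstm_units = integer(0),
                      attention_heads = 1, attention_key_dim = 2,
                      conv_filters = 4, epochs = 50, batch_size = 100,
                      learning_rate = 0, seed = 2)  # frozen: loss never improves
  m <- train_model(build_model(cfg), train, val,
                   early_stop_config(min_epochs = 2, patience = 1))
  expect_equal(nrow(m$history), 3)  # min_epochs + patience
  expect_match(m$stop_reason, "no val improvement")
  expect_equal(m$best_epoch, 1)
})

test_that("restore_best returns the parameters of the best validation epoch", {
  ov <- fix_overfit()
  m <- ov$model
  expect_equal(m$best_val_loss, min(m$history$val_loss), tolerance = 1e-12)
})

test_that("prediction is batch-invariant and duplicates map to duplicates", {
  ov <- fix_overfit()
  x <- stack_inputs(ov$train[1:3])
  joint <- predict(ov$model, x)
  single <- predict(ov$model, x[2, , , ])
  expect_lt(max(abs(joint[2, , , ] - single[1, , , ])), 1e-6)
  xdup <- x[c(1, 1, 3), , , ]
  pd <- predict(ov$model, xdup)
  expect_identical(pd[1, , , ], pd[2, , , ])
})

test_that("ensemble prediction is the element-wise mean of member predictions", {
  ov <- fix_overfit()
  x <- stack_inputs(ov$train[1:2])
  p1 <- predict(ov$model, x)
  expect_identical(ensemble_predict(list(ov$model), x), p1)
  expect_equal(ensemble_predict(list(ov$model, ov$model, ov$model), x), p1,
               tolerance = 1e-12)
  # negating only the linear head negates the whole output exactly
  m_neg <- ov$model
  m_neg$params$head$W <- -m_neg$params$head$W
  m_neg$params$head$b <- -m_neg$params$head$b
  zero <- ensemble_predict(list(ov$model, m_neg), x)
  expect_lt(max(abs(zero)), 1e-12)
  expect_error(ensemble_predict(list(), x), "empty")
})

test_that("the network can drive training loss below 1e-3 on a 10-cycle subset", {
  ov <- fix_overfit()
  expect_lt(min(ov$model$history$train_loss), 1e-3)
})

test_that("training rejects leakage between training and validation subjects", {
  cs <- fix_cycles()
  subj <- vapply(cs$cycles, `[[`, character(1), "subject_id")
  train <- cs$cycles[subj == "S01"]
  cfg <- model_config(encoder_lstm_units = 4, decoder_lstm_units = integer(0),
                      attention_heads = 1, attention_key_dim = 2,
                      conv_filters = 4, epochs = 1, seed = 1)
  expect_error(train_model(build_model(cfg), train, train[1:2],
                           early_stop_config(1, 1)),
               "validation subject appears")
  expect_error(train_model(build_model(cfg), list(), train[1:2],
                           early_stop_config(1, 1)),
               "empty")
})
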