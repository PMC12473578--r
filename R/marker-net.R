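#' Network configuration
#'
#' The sequence model maps per-cycle IMU tensors (101 x 4 x 14, flattened to
#' 56 features per frame) to transformed marker tensors (101 x 3 x 16, i.e.
#' 48 features per frame): stacked LSTM encoder (tanh), residual multi-head
#' self-attention over the 101-step sequence, a same-padded 1-D convolution
#' block (relu), an LSTM decoder stack, and a per-frame linear head.
#' Training defaults: 200 epochs, batch size 200, learning rate 0.005, Adam.
#'
#' @param encoder_lstm_units,decoder_lstm_units Integer vectors of layer
#'   widths.
#' @param attention_heads,attention_key_dim Multi-head attention geometry.
#' @param conv_filters,conv_kernel Convolution block geometry.
#' @param epochs,batch_size,learning_rate Optimization settings.
#' @param lr_decay Multiplicative factor reached by the learning rate at the
#'   final epoch (exponential schedule; 1 = constant rate).
#' @param seed Integer seed for initialization and shuffling.
#' @param input_dim,output_dim Per-frame feature counts (56 and 48 for the
#'   standard tensors; exposed for small-scale testing).
#' @export
model_config <- function(encoder_lstm_units = c(128, 128),
                         decoder_lstm_units = 128,
                         attention_heads = 4, attention_key_dim = 32,
                         conv_filters = 64, conv_kernel = 3,
                         epochs = 200, batch_size = 200,
                         learning_rate = 0.005, lr_decay = 1,
                         seed = 1L,
                         input_dim = 4L * 14L, output_dim = 3L * 16L) {
  if (any(c(encoder_lstm_units, decoder_lstm_units) <= 0)) {
    stop("model_config: layer widths must be > 0")
  }
  structure(list(encoder_lstm_units = encoder_lstm_units,
                 decoder_lstm_units = decoder_lstm_units,
                 attention_heads = attention_heads,
                 attention_key_dim = attention_key_dim,
                 conv_filters = conv_filters, conv_kernel = conv_kernel,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 lr_decay = lr_decay,
                 lstm_activation = "tanh", conv_activation = "relu",
                 head_activation = "linear", optimizer = "adam",
                 seed = as.integer(seed),
                 input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim)),
            class = "model_config")
}

#' Reduced configuration for small synthetic experiments
#'
#' A single 128-unit encoder layer with a purely convolutional decoder (the
#' attention + convolution blocks feed the linear head directly), 60 epochs,
#' batch size 8: the configuration used for the desk-scale
#' leave-one-subject-out runs on synthetic cohorts. On cohorts of tens of
#' cycles the small batch keeps the number of optimizer steps comparable to
#' full-scale training, and the convolutional decoder trains markedly faster
#' than a recurrent one at equal accuracy.
#'
#' @param epochs,seed Overridable settings.
#' @export
reduced_model_config <- function(epochs = 60, seed = 1L) {
  model_config(encoder_lstm_units = 128, decoder_lstm_units = integer(0),
               attention_heads = 4, attention_key_dim = 16,
               conv_filters = 64, conv_kernel = 3,
               epochs = epochs, batch_size = 8, seed = seed)
}

#' Early-stopping configuration
#'
#' Training runs at least `min_epochs`, then stops once the validation loss
#' has not improved for `patience` consecutive epochs; with `restore_best`
#' the returned parameters are those of the epoch with minimum validation
#' loss.
#'
#' @param min_epochs,patience,restore_best Stopping rule settings.
#' @export
early_stop_config <- function(min_epochs = 100, patience = 5,
                              restore_best = TRUE) {
  if (patience < 1) stop("early_stop_config: patience must be >= 1")
  structure(list(min_epochs = as.integer(min_epochs),
                 patience = as.integer(patience),
                 restore_best = isTRUE(restore_best),
                 monitored = "val_loss"),
            class = "early_stop_config")
}

#' Weights of the biomechanics-aware composite loss
#'
#' @param foot_weight Extra multiplier on the foot-marker MSE (ankle, heel,
#'   toe bilaterally by default).
#' @param topk_k Number of worst per-feature MSEs averaged by the top-k term
#'   (features = the 48 axis-marker pairs).
#' @param topk_weight,smooth_weight Term weights.
#' @param foot_markers Labels of the foot markers.
#' @export
loss_weights <- function(foot_weight = 1, topk_k = 24, topk_weight = 1,
                         smooth_weight = 1,
                         foot_markers = FOOT_MARKER_LABELS) {
  if (topk_k < 1 || topk_k > 48) stop("loss_weights: topk_k must be in 1..48")
  if (any(c(foot_weight, topk_weight, smooth_weight) < 0)) {
    stop("loss_weights: weights must be >= 0")
  }
  structure(list(foot_weight = foot_weight, topk_k = as.integer(topk_k),
                 topk_weight = topk_weight, smooth_weight = smooth_weight,
                 foot_markers = foot_markers),
            class = "loss_weights")
}

#' Build the marker-prediction network
#'
#' Parameter initialization (Glorot uniform) is fully determined by
#' `config$seed`.
#'
#' @param config A `model_config`.
#' @return Object of class `marker_net`.
#' @export
build_model <- function(config = model_config()) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  params <- list()
  nin <- config$input_dim
  params$enc <- list()
  for (u in config$encoder_lstm_units) {
    params$enc[[length(params$enc) + 1]] <- lstm_init(nin, u)
    nin <- u
  }
  params$att <- attention_init(nin, config$attention_heads,
                               config$attention_key_dim)
  params$conv <- conv_init(nin, config$conv_filters, config$conv_kernel)
  nin <- config$conv_filters
  # layer normalization keeps a recurrent decoder from cell-state drift
  # driven by the nonnegative conv outputs, and conditions the head input
  params$ln <- layernorm_init(nin)
  params$dec <- list()
  for (u in config$decoder_lstm_units) {
    params$dec[[length(params$dec) + 1]] <- lstm_init(nin, u)
    nin <- u
  }
  params$head <- dense_init(nin, config$output_dim)
  structure(list(config = config, params = params, trained = FALSE),
            class = "marker_net")
}

model_forward <- function(model, x, keep_cache = TRUE) {
  p <- model$params; cfg <- model$config
  caches <- list(enc = list(), dec = list())
  h <- x
  for (i in seq_along(p$enc)) {
    r <- lstm_forward(p$enc[[i]], h)
    h <- r$out
    if (keep_cache) caches$enc[[i]] <- r$cache
  }
  r <- attention_forward(p$att, h, cfg$attention_heads, cfg$attention_key_dim)
  h <- r$out
  if (keep_cache) caches$att <- r$cache
  r <- conv_forward(p$conv, h)
  h <- r$out
  if (keep_cache) caches$conv <- r$cache
  if (!is.null(p$ln)) {
    r <- layernorm_forward(p$ln, h)
    h <- r$out
    if (keep_cache) caches$ln <- r$cache
  }
  for (i in seq_along(p$dec)) {
    r <- lstm_forward(p$dec[[i]], h)
    h <- r$out
    if (keep_cache) caches$dec[[i]] <- r$cache
  }
  r <- dense_forward(p$head, h)
  if (keep_cache) caches$head <- r$cache
  list(out = r$out, caches = caches)
}

model_backward <- function(model, caches, dY) {
  p <- model$params; cfg <- model$config
  grads <- list()
  r <- dense_backward(p$head, caches$head, dY)
  grads$head <- r$grads; d <- r$dx
  grads$dec <- vector("list", length(p$dec))
  for (i in rev(seq_along(p$dec))) {
    r <- lstm_backward(p$dec[[i]], caches$dec[[i]], d)
    grads$dec[[i]] <- r$grads; d <- r$dx
  }
  if (!is.null(p$ln)) {
    r <- layernorm_backward(p$ln, caches$ln, d)
    grads$ln <- r$grads; d <- r$dx
  }
  r <- conv_backward(p$conv, caches$conv, d)
  grads$conv <- r$grads; d <- r$dx
  r <- attention_backward(p$att, caches$att, d)
  grads$att <- r$grads; d <- r$dx
  grads$enc <- vector("list", length(p$enc))
  for (i in rev(seq_along(p$enc))) {
    r <- lstm_backward(p$enc[[i]], caches$enc[[i]], d)
    grads$enc[[i]] <- r$grads; d <- r$dx
  }
  # reorder to match params structure
  grads[intersect(c("enc", "att", "conv", "ln", "dec", "head"), names(grads))]
}

# Composite loss on (T, B, F) tensors; returns value, the four components
# and optionally the gradient with respect to the prediction.
loss_core <- function(yt, yp, w, feature_foot, want_grad = FALSE) {
  d <- dim(yt); T_ <- d[1]; B <- d[2]; F_ <- d[3]
  e <- yp - yt
  em <- tbmat(e)
  mse_all <- mean(em^2)
  n_foot <- length(feature_foot) * T_ * B
  mse_foot <- sum(em[, feature_foot]^2) / n_foot
  msej <- colMeans(em^2)
  k <- min(w$topk_k, F_)
  topk_idx <- order(msej, decreasing = TRUE)[seq_len(k)]
  mse_topk <- mean(msej[topk_idx])
  dE <- e[2:T_, , , drop = FALSE] - e[1:(T_ - 1), , , drop = FALSE]
  mse_smooth <- mean(dE^2)
  loss <- mse_all + w$foot_weight * mse_foot + w$topk_weight * mse_topk +
    w$smooth_weight * mse_smooth
  out <- list(loss = loss,
              components = c(mse = mse_all, foot = mse_foot,
                             topk = mse_topk, smooth = mse_smooth))
  if (want_grad) {
    g <- 2 * em / length(em)
    g[, feature_foot] <- g[, feature_foot] +
      w$foot_weight * 2 * em[, feature_foot] / n_foot
    g[, topk_idx] <- g[, topk_idx] +
      w$topk_weight * 2 * em[, topk_idx] / (k * T_ * B)
    g <- untbmat(g, T_, B)
    gd <- w$smooth_weight * 2 * dE / length(dE)
    g[2:T_, , ] <- g[2:T_, , , drop = FALSE] + gd
    g[1:(T_ - 1), , ] <- g[1:(T_ - 1), , , drop = FALSE] - gd
    out$grad <- g
  }
  out
}

#' Biomechanics-aware composite loss
#'
#' Four terms: (1) mean squared error over all entries plus an extra
#' foot-marker MSE, (2) the mean of the `topk_k` largest per-feature MSEs
#' (each of the 48 axis-marker pairs averaged over batch and time), and
#' (3) an MSE between the first temporal differences of prediction and truth,
#' penalizing abrupt frame-to-frame deviations. Component values are attached
#' as the `"components"` attribute.
#'
#' @param y_true,y_pred Arrays `batch x 101 x 3 x 16` (a single cycle
#'   `101 x 3 x 16` is also accepted).
#' @param w A `loss_weights`.
#' @return Nonnegative scalar with attribute `components`.
#' @export
biomech_loss <- function(y_true, y_pred, w = loss_weights()) {
  if (!identical(dim(y_true), dim(y_pred))) {
    stop("biomech_loss: shape mismatch between y_true and y_pred")
  }
  if (length(dim(y_true)) == 3) {
    dim(y_true) <- c(1, dim(y_true))
    dim(y_pred) <- c(1, dim(y_pred))
  }
  if (!all(is.finite(y_true)) || !all(is.finite(y_pred))) {
    stop("biomech_loss: non-finite values")
  }
  yt <- batch_to_tbf(y_true)
  yp <- batch_to_tbf(y_pred)
  foot <- foot_feature_indices(w$foot_markers)
  r <- loss_core(yt, yp, w, foot)
  structure(r$loss, components = r$components)
}

# (B, T, A, M) -> (T, B, A*M) with axis varying fastest in the feature index
batch_to_tbf <- function(x) {
  d <- dim(x)
  y <- aperm(x, c(2, 1, 3, 4))
  dim(y) <- c(d[2], d[1], d[3] * d[4])
  y
}

tbf_to_batch <- function(x, axes = 3L, markers = N_MARKERS) {
  d <- dim(x)
  dim(x) <- c(d[1], d[2], axes, markers)
  aperm(x, c(2, 1, 3, 4))
}

cycles_to_input_tensor <- function(cycles) {
  B <- length(cycles)
  T_ <- N_FRAMES_CYCLE
  x <- array(0, c(T_, B, dim(cycles[[1]]$inputs)[2] * dim(cycles[[1]]$inputs)[3]))
  for (i in seq_len(B)) x[, i, ] <- matrix(cycles[[i]]$inputs, T_)
  x
}

cycles_to_target_tensor <- function(cycles) {
  B <- length(cycles)
  T_ <- N_FRAMES_CYCLE
  y <- array(0, c(T_, B, 48))
  for (i in seq_len(B)) y[, i, ] <- matrix(cycles[[i]]$targets, T_)
  y
}

#' Train the marker-prediction network
#'
#' Full-gradient Adam on minibatches with validation-loss early stopping:
#' training runs at least `early$min_epochs` epochs and stops once the
#' validation loss has not improved for `early$patience` consecutive epochs
#' beyond that point; with `restore_best` the parameters of the best
#' validation epoch are returned. Deterministic given the config seed.
#'
#' @param model A `marker_net` from [build_model()].
#' @param train_cycles,val_cycles Lists of `gait_cycle` objects; validation
#'   cycles must come from a single designated subject disjoint from
#'   training.
#' @param early An `early_stop_config`.
#' @param w A `loss_weights`.
#' @param verbose Print per-epoch losses.
#' @return The trained model, with `history` (data frame) and `stop_reason`.
#' @export
train_model <- function(model, train_cycles, val_cycles,
                        early = early_stop_config(), w = loss_weights(),
                        verbose = FALSE) {
  if (!length(train_cycles)) stop("train_model: empty training set")
  cfg <- model$config
  if (length(unique(vapply(val_cycles, `[[`, character(1), "subject_id"))) > 1) {
    stop("train_model: validation cycles must come from one subject")
  }
  if (length(intersect(vapply(train_cycles, `[[`, character(1), "subject_id"),
                       vapply(val_cycles, `[[`, character(1), "subject_id")))) {
    stop("train_model: validation subject appears in the training set")
  }
  xt <- cycles_to_input_tensor(train_cycles)
  yt <- cycles_to_target_tensor(train_cycles)
  xv <- cycles_to_input_tensor(val_cycles)
  yv <- cycles_to_target_tensor(val_cycles)
  # per-feature input standardization from the training set (stored with the
  # model and applied identically at prediction time)
  model$input_center <- apply(xt, 3, mean)
  model$input_scale <- pmax(apply(xt, 3, stats::sd), 1e-6)
  xt <- standardize_tensor(xt, model$input_center, model$input_scale)
  xv <- standardize_tensor(xv, model$input_center, model$input_scale)
  foot <- foot_feature_indices(w$foot_markers)
  B <- dim(xt)[2]
  state <- adam_init(model$params)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(cfg$seed + 1L)
  best_val <- Inf; best_params <- model$params; best_epoch <- 0L
  wait <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  stop_reason <- "max_epochs"
  min_epochs <- min(early$min_epochs, cfg$epochs)
  lr_decay <- cfg$lr_decay %||% 1
  for (epoch in seq_len(cfg$epochs)) {
    lr_epoch <- cfg$learning_rate * lr_decay^(epoch / cfg$epochs)
    idx <- sample.int(B)
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    tl <- 0
    for (bi in batches) {
      xb <- xt[, bi, , drop = FALSE]
      yb <- yt[, bi, , drop = FALSE]
      fwd <- model_forward(model, xb, keep_cache = TRUE)
      lo <- loss_core(yb, fwd$out, w, foot, want_grad = TRUE)
      grads <- model_backward(model, fwd$caches, lo$grad)
      st <- adam_step(model$params, grads, state, lr_epoch)
      model$params <- st$params; state <- st$state
      tl <- tl + lo$loss * length(bi)
    }
    tl <- tl / B
    vout <- model_forward(model, xv, keep_cache = FALSE)$out
    vl <- loss_core(yv, vout, w, foot)$loss
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl,
                                   val_loss = vl))
    if (verbose) message(sprintf("epoch %3d train %.5f val %.5f", epoch, tl, vl))
    if (vl < best_val) {
      best_val <- vl; best_params <- model$params; best_epoch <- epoch
      wait <- 0L
    } else if (epoch > min_epochs) {
      wait <- wait + 1L
      if (wait >= early$patience) {
        stop_reason <- sprintf("no val improvement for %d epochs after epoch %d",
                               early$patience, best_epoch)
        break
      }
    }
  }
  if (early$restore_best) model$params <- best_params
  model$trained <- TRUE
  model$history <- hist
  model$stop_reason <- stop_reason
  model$best_epoch <- best_epoch
  model$best_val_loss <- best_val
  model
}

#' Predict transformed marker tensors from IMU tensors
#'
#' A pure function of inputs and parameters (no training-mode
#' stochasticity).
#'
#' @param object A `marker_net`.
#' @param inputs `n x 101 x 4 x 14` array, a single `101 x 4 x 14` cycle
#'   input, or a list of `gait_cycle` objects.
#' @param ... Unused.
#' @return `n x 101 x 3 x 16` array of predictions.
#' @export
predict.marker_net <- function(object, inputs, ...) {
  x <- inputs_to_tensor(inputs)
  if (!is.null(object$input_center)) {
    x <- standardize_tensor(x, object$input_center, object$input_scale)
  }
  B <- dim(x)[2]
  out <- array(NA_real_, c(B, N_FRAMES_CYCLE, 3, N_MARKERS))
  for (chunk in split(seq_len(B), ceiling(seq_len(B) / 64))) {
    y <- model_forward(object, x[, chunk, , drop = FALSE],
                       keep_cache = FALSE)$out
    out[chunk, , , ] <- tbf_to_batch(y)
  }
  out
}

standardize_tensor <- function(x, center, scale) {
  for (f in seq_len(dim(x)[3])) x[, , f] <- (x[, , f] - center[f]) / scale[f]
  x
}

inputs_to_tensor <- function(inputs) {
  if (is.list(inputs) && !is.array(inputs)) {
    return(cycles_to_input_tensor(inputs))
  }
  d <- dim(inputs)
  if (length(d) == 3) {
    dim(inputs) <- c(1, d)
    d <- dim(inputs)
  }
  if (length(d) != 4 || d[2] != N_FRAMES_CYCLE) {
    stop("predict: inputs must be n x 101 x 4 x 14")
  }
  x <- array(0, c(d[2], d[1], d[3] * d[4]))
  for (i in seq_len(d[1])) x[, i, ] <- matrix(inputs[i, , , ], d[2])
  x
}

#' Ensemble prediction: element-wise mean over member models
#'
#' @param models Non-empty list of `marker_net` models.
#' @param inputs As in [predict.marker_net()].
#' @export
ensemble_predict <- function(models, inputs) {
  if (!length(models)) stop("ensemble_predict: empty model list")
  preds <- lapply(models, predict, inputs = inputs)
  Reduce(`+`, preds) / length(preds)
}
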