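# Leave-one-subject-out experiment management, marker/angle RMSE with and
# without dynamic-time-warping alignment, and the sensor-swap robustness
# probe.

#' Build a leave-one-subject-out plan with a fixed validation subject
#'
#' Each subject is held out once; early stopping always monitors the same
#' designated validation subject, except in the fold that holds out the
#' validation subject itself, where the designated fallback subject is used.
#' Training sets exclude both the holdout and the validation subject.
#'
#' @param subjects Ordered subject ids.
#' @param validation_subject The fixed validation id.
#' @param fallback Validation id used when the holdout is the fixed
#'   validation subject.
#' @return Object of class `loso_plan`.
#' @export
make_loso_plan <- function(subjects, validation_subject, fallback) {
  if (length(subjects) < 3) stop("make_loso_plan: need >= 3 subjects")
  if (!validation_subject %in% subjects) {
    stop("make_loso_plan: validation subject not in roster")
  }
  if (!fallback %in% subjects || fallback == validation_subject) {
    stop("make_loso_plan: fallback must be a different roster subject")
  }
  folds <- lapply(subjects, function(holdout) {
    val <- if (holdout == validation_subject) fallback else validation_subject
    list(holdout = holdout, validation = val,
         train = setdiff(subjects, c(holdout, val)))
  })
  structure(list(subjects = subjects,
                 validation_subject = validation_subject,
                 fallback = fallback, folds = folds),
            class = "loso_plan")
}

#' Per-marker, per-axis RMSE of predicted marker positions
#'
#' RMSE is computed over the 101 frames of each cycle for every marker-axis
#' pair in raw marker space (mm in, reported in cm), then aggregated as
#' subject means and mean +/- SD across subjects (across cycles when no
#' subject ids are given).
#'
#' @param pred,true `n x 101 x 16 x 3` arrays of marker positions, mm.
#' @param subjects Optional length-`n` subject ids for the aggregation.
#' @return List with `per_cycle` (n x 16 x 3, cm), `mean` and `sd`
#'   (16 x 3, cm), and `grand_mean` (scalar, cm).
#' @export
marker_rmse <- function(pred, true, subjects = NULL) {
  if (!identical(dim(pred), dim(true))) stop("marker_rmse: shape mismatch")
  n <- dim(pred)[1]
  per_cycle <- sqrt(apply((pred - true)^2, c(1, 3, 4), mean)) / 10
  agg <- per_cycle
  if (!is.null(subjects)) {
    groups <- split(seq_len(n), subjects)
    agg <- array(NA_real_, c(length(groups), dim(per_cycle)[2], 3))
    for (i in seq_along(groups)) {
      agg[i, , ] <- apply(per_cycle[groups[[i]], , , drop = FALSE], c(2, 3), mean)
    }
  }
  mean_tab <- apply(agg, c(2, 3), mean)
  sd_tab <- apply(agg, c(2, 3), stats::sd)
  dimnames(mean_tab) <- dimnames(sd_tab) <- list(MARKER_LABELS, AXIS_LABELS)
  list(per_cycle = per_cycle, mean = mean_tab, sd = sd_tab,
       grand_mean = mean(mean_tab))
}

#' Dynamic time warping alignment of two equal-length series
#'
#' Classic dynamic programming with squared-difference local cost and steps
#' from \{(1,0), (0,1), (1,1)\}; the optimal path is monotone, continuous and
#' boundary-complete. The warped query maps each reference index to the mean
#' of its matched query samples, yielding a comparable series of the same
#' length whose RMSE to the reference never exceeds the unwarped RMSE.
#'
#' @param ref,query Numeric vectors (same length).
#' @param band Optional Sakoe-Chiba band half-width (frames); NULL = none.
#' @return List with `path` (m x 2 index matrix), `warped` (aligned query),
#'   `cost` (accumulated squared-difference cost).
#' @export
dtw_align <- function(ref, query, band = NULL) {
  n <- length(ref); m <- length(query)
  stopifnot(all(is.finite(ref)), all(is.finite(query)))
  D <- matrix(Inf, n, m)
  local <- outer(ref, query, function(a, b) (a - b)^2)
  if (!is.null(band)) {
    mask <- abs(outer(seq_len(n), seq_len(m), `-`)) > band
    local[mask] <- Inf
  }
  D[1, 1] <- local[1, 1]
  for (j in 2:m) D[1, j] <- D[1, j - 1] + local[1, j]
  for (i in 2:n) {
    D[i, 1] <- D[i - 1, 1] + local[i, 1]
    prev_row <- D[i - 1, ]
    row <- D[i, ]
    for (j in 2:m) {
      row[j] <- local[i, j] + min(prev_row[j], row[j - 1], prev_row[j - 1])
    }
    D[i, ] <- row
  }
  # backtrack (prefer the diagonal on ties)
  i <- as.integer(n); j <- as.integer(m)
  path <- matrix(NA_integer_, n + m, 2)
  k <- 1L
  path[k, ] <- c(i, j)
  while (i > 1 || j > 1) {
    if (i == 1L) j <- j - 1L
    else if (j == 1L) i <- i - 1L
    else {
      cands <- c(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
      pick <- which.min(cands)
      if (pick == 1) { i <- i - 1L; j <- j - 1L }
      else if (pick == 2) i <- i - 1L
      else j <- j - 1L
    }
    k <- k + 1L
    path[k, ] <- c(i, j)
  }
  path <- path[k:1, , drop = FALSE]
  warped <- vapply(seq_len(n), function(ii) {
    mean(query[path[path[, 1] == ii, 2]])
  }, numeric(1))
  list(path = path, warped = warped, cost = D[n, m])
}

joint_names <- function() c("hip_l", "hip_r", "knee_l", "knee_r",
                            "ankle_l", "ankle_r")

#' Per-joint RMSE between predicted and reference joint angles
#'
#' With `use_dtw`, each predicted curve is first aligned to its reference
#' counterpart by [dtw_align()] (per joint, univariate). Aggregation follows
#' [marker_rmse()]: per-cycle RMSE, subject means when ids are given, then
#' mean +/- SD.
#'
#' @param pred_angles,true_angles Lists of `joint_angle_series` (one per
#'   cycle, 101 frames).
#' @param use_dtw Align before computing RMSE.
#' @param subjects Optional subject ids per cycle.
#' @return List with `per_cycle` (n x 6 matrix, deg), `mean`, `sd` (named
#'   per joint), `correlation` (Pearson r per joint over concatenated
#'   cycles).
#' @export
angle_rmse <- function(pred_angles, true_angles, use_dtw = FALSE,
                       subjects = NULL) {
  if (length(pred_angles) != length(true_angles)) {
    stop("angle_rmse: mismatched cycle counts")
  }
  n <- length(pred_angles)
  jn <- joint_names()
  per_cycle <- matrix(NA_real_, n, length(jn), dimnames = list(NULL, jn))
  cat_pred <- stats::setNames(vector("list", length(jn)), jn)
  cat_true <- cat_pred
  for (i in seq_len(n)) {
    for (j in jn) {
      truth <- true_angles[[i]][[j]]
      est <- pred_angles[[i]][[j]]
      if (use_dtw) est <- dtw_align(truth, est)$warped
      per_cycle[i, j] <- sqrt(mean((truth - est)^2))
      cat_pred[[j]] <- c(cat_pred[[j]], est)
      cat_true[[j]] <- c(cat_true[[j]], truth)
    }
  }
  agg <- per_cycle
  if (!is.null(subjects)) {
    agg <- do.call(rbind, lapply(split(seq_len(n), subjects), function(ix) {
      colMeans(per_cycle[ix, , drop = FALSE])
    }))
  }
  list(per_cycle = per_cycle,
       mean = colMeans(agg),
       sd = apply(agg, 2, stats::sd),
       correlation = vapply(jn, function(j) {
         stats::cor(cat_pred[[j]], cat_true[[j]])
       }, numeric(1)))
}

#' Swap the foot and shank sensor streams of an input tensor
#'
#' Exchanges the left foot with the left shank and the right foot with the
#' right shank in both the accelerometer and gyroscope stream blocks. An
#' involution: applying it twice restores the input.
#'
#' @param inputs `101 x 4 x 14` tensor (or `n x 101 x 4 x 14`).
#' @export
swap_foot_shank <- function(inputs) {
  nd <- length(dim(inputs))
  shank <- sensor_index(c("shank_l", "shank_r"))
  foot <- sensor_index(c("foot_l", "foot_r"))
  from <- c(shank, foot, N_SENSORS + c(shank, foot))
  to <- c(foot, shank, N_SENSORS + c(foot, shank))
  out <- inputs
  if (nd == 3) out[, , to] <- inputs[, , from]
  else out[, , , to] <- inputs[, , , from]
  out
}

#' Sensor-swap robustness probe
#'
#' Predicts the given cycles with nominal inputs and with foot and shank
#' sensor streams interchanged, and compares marker RMSE (raw space, cm). A
#' model that has learned placement-specific structure must degrade markedly
#' under the swap; the probe passes when the swapped RMSE exceeds the nominal
#' RMSE by at least `factor`. Untrained models are skipped (no meaningful
#' baseline).
#'
#' @param model A trained `marker_net`.
#' @param cycles List of `gait_cycle` objects.
#' @param factor Required degradation ratio.
#' @export
sensor_swap_check <- function(model, cycles, factor = 1.5) {
  if (!isTRUE(model$trained)) {
    message("sensor_swap_check: model not trained; check skipped")
    return(list(status = "SKIPPED", reason = "untrained model"))
  }
  true_mm <- invert_cycle_list(stack_targets(cycles), cycles)
  nominal <- invert_cycle_list(predict(model, cycles), cycles)
  x <- stack_inputs(cycles)
  swapped <- invert_cycle_list(predict(model, swap_foot_shank(x)), cycles)
  r_nom <- marker_rmse(nominal, true_mm)
  r_swp <- marker_rmse(swapped, true_mm)
  ratio <- r_swp$grand_mean / r_nom$grand_mean
  list(status = if (ratio >= factor) "PASS" else "FAIL",
       nominal_rmse = r_nom$grand_mean, swapped_rmse = r_swp$grand_mean,
       ratio = ratio, factor = factor)
}

# transformed (n x 101 x 3 x 16) predictions -> raw mm (n x 101 x 16 x 3)
invert_cycle_list <- function(pred, cycles) {
  n <- dim(pred)[1]
  out <- array(NA_real_, c(n, N_FRAMES_CYCLE, N_MARKERS, 3))
  for (i in seq_len(n)) {
    out[i, , , ] <- inverse_transform(pred[i, , , ], cycles[[i]]$factor)
  }
  out
}

#' Run a leave-one-subject-out experiment
#'
#' Trains one model per fold of the plan, predicts the holdout subject's
#' cycles, and aggregates per-marker RMSE (cm) and per-joint sagittal angle
#' RMSE (deg) with and without DTW alignment into a report. A failing fold is
#' recorded and the experiment continues.
#'
#' @param cycleset A `cycle_set` covering all plan subjects.
#' @param plan A `loso_plan`.
#' @param config A `model_config` (the fold index is added to its seed so
#'   each fold trains a distinct model).
#' @param early An `early_stop_config`.
#' @param w A `loss_weights`.
#' @param return_models Keep the per-fold models (e.g. for ensembling).
#' @param verbose Progress messages.
#' @return Object of class `eval_report`.
#' @export
run_experiment <- function(cycleset, plan, config = reduced_model_config(),
                           early = early_stop_config(), w = loss_weights(),
                           return_models = FALSE, verbose = TRUE) {
  subj <- cycle_subjects(cycleset)
  missing <- setdiff(plan$subjects, unique(subj))
  if (length(missing)) {
    stop("run_experiment: no cycles for subject(s) ",
         paste(missing, collapse = ", "))
  }
  folds <- list()
  models <- list()
  all_pred <- NULL; all_true <- NULL; all_subj <- character()
  ang_pred <- list(); ang_true <- list(); ang_subj <- character()
  for (fi in seq_along(plan$folds)) {
    fold <- plan$folds[[fi]]
    res <- tryCatch({
      cfg <- config
      cfg$seed <- config$seed + fi
      train_cyc <- cycleset$cycles[subj %in% fold$train]
      val_cyc <- cycleset$cycles[subj == fold$validation]
      hold_cyc <- cycleset$cycles[subj == fold$holdout]
      model <- build_model(cfg)
      model <- train_model(model, train_cyc, val_cyc, early, w)
      pred <- predict(model, hold_cyc)
      pred_mm <- invert_cycle_list(pred, hold_cyc)
      true_mm <- invert_cycle_list(stack_targets(hold_cyc), hold_cyc)
      cal <- cycleset$statics[[fold$holdout]]
      # predicted markers from a poorly fit model can defeat the joint-center
      # geometry; such cycles are excluded from the angle tables and counted
      ap <- list(); at <- list(); n_angle_failed <- 0L
      for (i in seq_along(hold_cyc)) {
        res_i <- tryCatch({
          list(p = angles_from_predictions(pred[i, , , ],
                                           hold_cyc[[i]]$factor, cal),
               t = angles_from_predictions(hold_cyc[[i]]$targets,
                                           hold_cyc[[i]]$factor, cal))
        }, error = function(e) NULL)
        if (is.null(res_i)) {
          n_angle_failed <- n_angle_failed + 1L
        } else {
          ap[[length(ap) + 1]] <- res_i$p
          at[[length(at) + 1]] <- res_i$t
        }
      }
      list(ok = TRUE, model = model, pred_mm = pred_mm, true_mm = true_mm,
           ap = ap, at = at, n = length(hold_cyc),
           n_angle = length(ap), n_angle_failed = n_angle_failed,
           best_epoch = model$best_epoch, stop_reason = model$stop_reason)
    }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    if (res$ok) {
      all_pred <- if (is.null(all_pred)) res$pred_mm else
        abind1(all_pred, res$pred_mm)
      all_true <- if (is.null(all_true)) res$true_mm else
        abind1(all_true, res$true_mm)
      all_subj <- c(all_subj, rep(fold$holdout, res$n))
      ang_subj <- c(ang_subj, rep(fold$holdout, res$n_angle))
      ang_pred <- c(ang_pred, res$ap)
      ang_true <- c(ang_true, res$at)
      if (return_models) models[[fold$holdout]] <- res$model
      folds[[fi]] <- list(holdout = fold$holdout, ok = TRUE,
                          n_cycles = res$n,
                          n_angle_failed = res$n_angle_failed,
                          best_epoch = res$best_epoch,
                          stop_reason = res$stop_reason)
      if (verbose) message("fold ", fold$holdout, ": ok (", res$n, " cycles)")
    } else {
      folds[[fi]] <- list(holdout = fold$holdout, ok = FALSE,
                          error = res$error)
      if (verbose) message("fold ", fold$holdout, " FAILED: ", res$error)
    }
  }
  if (is.null(all_pred)) stop("run_experiment: every fold failed")
  mrk <- marker_rmse(all_pred, all_true, all_subj)
  nodtw <- angle_rmse(ang_pred, ang_true, use_dtw = FALSE, subjects = ang_subj)
  dtw <- angle_rmse(ang_pred, ang_true, use_dtw = TRUE, subjects = ang_subj)
  structure(list(marker = mrk,
                 angle_nodtw = nodtw, angle_dtw = dtw,
                 folds = folds, models = models,
                 plan = plan,
                 provenance = list(seed = config$seed,
                                   epochs = config$epochs,
                                   batch_size = config$batch_size,
                                   n_cycles = length(all_subj))),
            class = "eval_report")
}

abind1 <- function(a, b) {
  d <- dim(a)
  out <- array(NA_real_, c(d[1] + dim(b)[1], d[-1]))
  ix <- seq_len(d[1])
  out[ix, , , ] <- a
  out[-ix, , , ] <- b
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Leave-one-subject-out report (", length(x$folds), " folds, ",
      x$provenance$n_cycles, " holdout cycles)\n\n", sep = "")
  cat("Marker RMSE (cm), mean over subjects:\n")
  print(round(x$marker$mean, 2))
  cat(sprintf("\nGrand mean marker RMSE: %.2f cm\n", x$marker$grand_mean))
  cat("\nSagittal angle RMSE (deg), mean +/- SD over subjects:\n")
  tab <- rbind(`non-DTW` = x$angle_nodtw$mean, DTW = x$angle_dtw$mean)
  print(round(tab, 2))
  cat("\nPearson r per joint (concatenated cycles):\n")
  print(round(x$angle_nodtw$correlation, 4))
  invisible(x)
}
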