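# Filtering, gait-cycle segmentation, 101-frame time normalization and the
# shift-and-scale marker transform that conditions network targets.

# steady-state initial filter state is unnecessary here: odd-reflection
# padding long enough for the slowest pole to decay gives machine-precision
# behaviour at the series edges.
zero_phase_1d <- function(b, a, x, padlen) {
  n <- length(x)
  head_ext <- 2 * x[1] - x[seq(padlen + 1, 2)]
  tail_ext <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  ext <- c(head_ext, x, tail_ext)
  y <- as.numeric(signal::filter(b, a, ext))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(padlen + 1):(padlen + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a low-pass Butterworth filter and applies it forward and backward
#' (zero phase lag, unit DC gain), with odd-reflection padding so edges are
#' transient-free. Defaults follow standard gait practice: 4th order, 6 Hz.
#'
#' @param x Numeric vector, or frames x channels matrix (filtered per
#'   column).
#' @param fs Sampling rate, Hz. Must exceed twice the cutoff.
#' @param cutoff Cutoff frequency, Hz.
#' @param order Filter order.
#' @return Filtered data, same shape as `x`.
#' @export
butterworth_lowpass <- function(x, fs, cutoff = 6, order = 4) {
  if (fs <= 2 * cutoff) stop("butterworth_lowpass: need fs > 2 * cutoff")
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  n <- nrow(xm)
  if (n <= 3 * order) {
    stop("butterworth_lowpass: signal too short for order ", order,
         " (need > ", 3 * order, " frames)")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  padlen <- min(n - 1, max(3 * (order + 1), ceiling(15 * fs / cutoff)))
  out <- apply(xm, 2, function(col) zero_phase_1d(bf$b, bf$a, col, padlen))
  if (vec) as.numeric(out) else out
}

filter_marker_set <- function(set, cutoff = 6, order = 4) {
  d <- dim(set$positions)
  m <- matrix(set$positions, d[1], d[2] * d[3])
  set$positions <- array(butterworth_lowpass(m, set$frame_rate, cutoff, order),
                         dim = d, dimnames = dimnames(set$positions))
  set
}

filter_imu <- function(imu, cutoff = 6, order = 4) {
  d <- dim(imu$accel)
  for (field in c("accel", "gyro")) {
    m <- matrix(imu[[field]], d[1], d[2] * d[3])
    imu[[field]] <- array(butterworth_lowpass(m, imu$frame_rate, cutoff, order),
                          dim = d, dimnames = dimnames(imu[[field]]))
  }
  imu
}

#' Detect heel strikes from marker trajectories
#'
#' Coordinate-based method suited to treadmill gait: heel strikes are local
#' maxima of the heel marker's anterior position relative to the pelvis
#' centroid, with a minimum peak separation of 0.6 s.
#'
#' @param markers A `marker_set` (ideally low-pass filtered).
#' @param side `"left"` or `"right"`.
#' @param min_separation Minimum inter-event time, s.
#' @return Strictly increasing frame indices.
#' @export
detect_heel_strikes <- function(markers, side = c("left", "right"),
                                min_separation = 0.6) {
  side <- match.arg(side)
  pre <- if (side == "left") "L" else "R"
  heel_i <- marker_index(paste0(pre, "HEE"))
  pelvis_i <- marker_index(c("LASI", "RASI", "LPSI", "RPSI"))
  if (any(markers$gap_mask[, c(heel_i, pelvis_i)])) {
    stop("detect_heel_strikes: heel or pelvis markers contain gaps")
  }
  sig <- markers$positions[, heel_i, 1] -
    rowMeans(markers$positions[, pelvis_i, 1])
  n <- length(sig)
  cand <- which(sig[2:(n - 1)] > sig[1:(n - 2)] &
                  sig[2:(n - 1)] >= sig[3:n]) + 1L
  if (length(cand) > 1) {
    min_gap <- min_separation * markers$frame_rate
    keep <- logical(length(cand))
    for (i in order(sig[cand], decreasing = TRUE)) {
      if (!any(keep & abs(cand - cand[i]) < min_gap)) keep[i] <- TRUE
    }
    cand <- sort(cand[keep])
  }
  if (length(cand) < 2) {
    stop("detect_heel_strikes: fewer than 2 heel strikes found (side ", side, ")")
  }
  gaps_s <- diff(cand) / markers$frame_rate
  if (any(gaps_s < 0.6 | gaps_s > 2.0)) {
    warning("detect_heel_strikes: inter-event interval outside 0.6-2.0 s")
  }
  cand
}

resample_101 <- function(y, grid = seq(0, 1, length.out = N_FRAMES_CYCLE)) {
  x <- seq(0, 1, length.out = length(y))
  stats::spline(x, y, xout = grid, method = "fmm")$y
}

#' Segment a trial into time-normalized gait cycles
#'
#' Each cycle spans one heel strike to the next ipsilateral heel strike
#' (inclusive); all marker and IMU channels are resampled by cubic spline
#' onto 101 uniformly spaced samples over the cycle (0..100% of the gait
#' cycle). The first and last native samples are preserved exactly. Cycles
#' containing marker gaps are dropped with a message.
#'
#' @param bundle A `trial_bundle`, or any list with `markers` and `imu`.
#' @param events List with `left`/`right` heel-strike frame indices (defaults
#'   to `bundle$events`).
#' @return List of raw cycles: `side`, `markers` (101 x 16 x 3), `accel` and
#'   `gyro` (101 x 7 x 3), `raw_duration` (s), `start_frame`.
#' @export
segment_and_normalize <- function(bundle, events = bundle$events) {
  out <- list()
  fs <- bundle$markers$frame_rate
  for (side in c("left", "right")) {
    ev <- events[[side]]
    if (length(ev) < 2) stop("segment_and_normalize: need >= 2 events per side")
    for (k in seq_len(length(ev) - 1)) {
      i0 <- ev[k]; i1 <- ev[k + 1]
      idx <- i0:i1
      if (any(bundle$markers$gap_mask[idx, ])) {
        message("dropping ", side, " cycle ", k, ": marker gaps")
        next
      }
      mk_cyc <- array(NA_real_, c(N_FRAMES_CYCLE, N_MARKERS, 3),
                      dimnames = list(NULL, MARKER_LABELS, AXIS_LABELS))
      for (j in seq_len(N_MARKERS)) for (ax in 1:3) {
        mk_cyc[, j, ax] <- resample_101(bundle$markers$positions[idx, j, ax])
      }
      acc_cyc <- array(NA_real_, c(N_FRAMES_CYCLE, N_SENSORS, 3))
      gyr_cyc <- array(NA_real_, c(N_FRAMES_CYCLE, N_SENSORS, 3))
      for (j in seq_len(N_SENSORS)) for (ax in 1:3) {
        acc_cyc[, j, ax] <- resample_101(bundle$imu$accel[idx, j, ax])
        gyr_cyc[, j, ax] <- resample_101(bundle$imu$gyro[idx, j, ax])
      }
      out[[length(out) + 1]] <- list(side = side, markers = mk_cyc,
                                     accel = acc_cyc, gyro = gyr_cyc,
                                     raw_duration = (i1 - i0) / fs,
                                     start_frame = i0)
    }
  }
  out
}

#' Shift-and-scale marker transform for network targets
#'
#' Subtracts the per-axis midpoint of the two toe markers at the cycle's
#' first frame (the `factor`), adds 700 mm to guarantee positivity, and
#' divides by 100 to express positions on the decimeter scale:
#' `new = (old - factor + 700) / 100`. A pure affine shift/scale: inter-marker
#' geometry is preserved (up to the 1/100 scale).
#'
#' @param positions 101 x 16 x 3 cycle marker positions, mm.
#' @return List with `targets` (101 x 3 x 16, decimeter scale) and `factor`
#'   (length-3, mm).
#' @export
transform_markers <- function(positions) {
  stopifnot(length(dim(positions)) == 3, dim(positions)[2] == N_MARKERS)
  lt <- positions[1, marker_index("LTOE"), ]
  rt <- positions[1, marker_index("RTOE"), ]
  factor <- (lt + rt) / 2
  shifted <- sweep(positions, 3, factor)
  new <- (shifted + 700) / 100
  if (any(new <= 0)) {
    stop("transform_markers: positivity violated; coordinates beyond 700 mm ",
         "of the toe midpoint")
  }
  list(targets = aperm(new, c(1, 3, 2)), factor = factor)
}

#' Inverse of the marker transform
#'
#' @param targets 101 x 3 x 16 transformed markers (decimeter scale).
#' @param factor Length-3 factor, mm.
#' @return 101 x 16 x 3 positions, mm.
#' @export
inverse_transform <- function(targets, factor) {
  stopifnot(length(dim(targets)) == 3, dim(targets)[2] == 3)
  old <- aperm(targets, c(1, 3, 2)) * 100 - 700
  sweep(old, 3, factor, "+")
}

#' Assemble the per-cycle network input tensor
#'
#' Layout `101 x 4 x 14`: component axis = (x, y, z, Euclidean magnitude);
#' stream axis = the 7 sensors' accelerometers in canonical order followed by
#' the 7 gyroscopes.
#'
#' @param accel,gyro 101 x 7 x 3 normalized cycle arrays.
#' @return 101 x 4 x 14 array.
#' @export
assemble_inputs <- function(accel, gyro) {
  if (is.null(accel) || is.null(gyro)) {
    stop("assemble_inputs: both accelerometer and gyroscope cycles are required")
  }
  stopifnot(identical(dim(accel), c(N_FRAMES_CYCLE, N_SENSORS, 3L)) ||
              identical(dim(accel), as.integer(c(N_FRAMES_CYCLE, N_SENSORS, 3))))
  inputs <- array(NA_real_, c(N_FRAMES_CYCLE, 4, 2 * N_SENSORS))
  for (s in seq_len(N_SENSORS)) {
    inputs[, 1:3, s] <- accel[, s, ]
    inputs[, 4, s] <- sqrt(rowSums(accel[, s, ]^2))
    inputs[, 1:3, N_SENSORS + s] <- gyro[, s, ]
    inputs[, 4, N_SENSORS + s] <- sqrt(rowSums(gyro[, s, ]^2))
  }
  inputs
}

#' Per-cycle tensor pair
#'
#' @param subject_id,side Identifiers.
#' @param inputs 101 x 4 x 14 IMU tensor.
#' @param targets 101 x 3 x 16 transformed marker tensor.
#' @param factor Length-3 transform factor, mm.
#' @param raw_duration Cycle duration before normalization, s.
#' @export
gait_cycle <- function(subject_id, side, inputs, targets, factor,
                       raw_duration) {
  stopifnot(identical(dim(inputs)[1], N_FRAMES_CYCLE) ||
              dim(inputs)[1] == N_FRAMES_CYCLE,
            all(is.finite(inputs)), all(is.finite(targets)),
            all(targets > 0))
  structure(list(subject_id = subject_id, side = side, inputs = inputs,
                 targets = targets, factor = factor,
                 raw_duration = raw_duration),
            class = "gait_cycle")
}

#' Run the full preprocessing chain on a synthetic dataset
#'
#' Filters markers and IMU (zero-phase Butterworth), finds heel strikes (or
#' takes the simulator's ground-truth events), segments both streams into
#' 101-frame cycles per side, applies the marker transform and assembles the
#' input tensors, and builds each subject's static calibration.
#'
#' @param dataset A `gait_dataset`.
#' @param cutoff,order Filter parameters.
#' @param events `"detect"` (coordinate-based detection) or `"truth"`
#'   (simulator ground truth).
#' @return Object of class `cycle_set`: `cycles` (list of `gait_cycle`),
#'   `statics` (per-subject `static_calibration`), `meta`.
#' @export
prepare_cycles <- function(dataset, cutoff = 6, order = 4,
                           events = c("detect", "truth")) {
  events <- match.arg(events)
  cycles <- list()
  statics <- list()
  for (sub in dataset$subjects) {
    markers_f <- filter_marker_set(sub$markers, cutoff, order)
    imu_f <- filter_imu(sub$imu, cutoff, order)
    ev <- if (events == "truth") sub$events else {
      list(left = detect_heel_strikes(markers_f, "left"),
           right = detect_heel_strikes(markers_f, "right"))
    }
    raw <- segment_and_normalize(list(markers = markers_f, imu = imu_f), ev)
    for (rc in raw) {
      tr <- transform_markers(rc$markers)
      cycles[[length(cycles) + 1]] <-
        gait_cycle(sub$subject_id, rc$side,
                   assemble_inputs(rc$accel, rc$gyro),
                   tr$targets, tr$factor, rc$raw_duration)
    }
    statics[[sub$subject_id]] <- static_calibration(sub$static_markers,
                                                    sub$anthro)
  }
  structure(list(cycles = cycles, statics = statics,
                 meta = list(cutoff = cutoff, order = order, events = events,
                             fs = dataset$fs, offset = 700, scale = 100)),
            class = "cycle_set")
}

cycle_subjects <- function(cycleset) {
  vapply(cycleset$cycles, `[[`, character(1), "subject_id")
}

subset_cycles <- function(cycleset, subjects) {
  keep <- cycle_subjects(cycleset) %in% subjects
  cycleset$cycles <- cycleset$cycles[keep]
  cycleset
}

#' Stack cycle tensors into batch arrays
#'
#' @param cycles List of `gait_cycle` objects (or a `cycle_set`).
#' @return `stack_inputs`: n x 101 x 4 x 14; `stack_targets`: n x 101 x 3 x 16.
#' @name stack-cycles
#' @export
stack_inputs <- function(cycles) {
  if (inherits(cycles, "cycle_set")) cycles <- cycles$cycles
  n <- length(cycles)
  out <- array(NA_real_, c(n, N_FRAMES_CYCLE, 4, 2 * N_SENSORS))
  for (i in seq_len(n)) out[i, , , ] <- cycles[[i]]$inputs
  out
}

#' @rdname stack-cycles
#' @export
stack_targets <- function(cycles) {
  if (inherits(cycles, "cycle_set")) cycles <- cycles$cycles
  n <- length(cycles)
  out <- array(NA_real_, c(n, N_FRAMES_CYCLE, 3, N_MARKERS))
  for (i in seq_len(n)) out[i, , , ] <- cycles[[i]]$targets
  out
}
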