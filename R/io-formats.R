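#' Marker trajectory container
#'
#' Positions are stored in mm in the lab frame (x antero-posterior, y
#' medio-lateral, z vertical) for the 16 canonical markers in canonical
#' order.
#'
#' @param positions frames x 16 x 3 array, mm.
#' @param frame_rate Hz.
#' @param gap_mask frames x 16 logical (TRUE = missing); NULL means gap-free.
#' @export
marker_set <- function(positions, frame_rate, gap_mask = NULL) {
  d <- dim(positions)
  if (length(d) != 3 || d[2] != N_MARKERS || d[3] != 3) {
    stop("marker_set: positions must be frames x 16 x 3")
  }
  if (is.null(gap_mask)) {
    gap_mask <- matrix(FALSE, d[1], N_MARKERS)
  }
  if (!all(is.finite(positions[!array(gap_mask, dim = d)]))) {
    stop("marker_set: non-finite positions outside gaps")
  }
  dimnames(positions) <- list(NULL, MARKER_LABELS, AXIS_LABELS)
  structure(list(positions = positions, frame_rate = frame_rate,
                 labels = MARKER_LABELS, gap_mask = gap_mask),
            class = "marker_set")
}

#' IMU recording container
#'
#' @param accel,gyro frames x 7 x 3 arrays (m/s^2 and deg/s) in canonical
#'   sensor order.
#' @param frame_rate Hz.
#' @export
imu_recording <- function(accel, gyro, frame_rate) {
  da <- dim(accel); dg <- dim(gyro)
  if (length(da) != 3 || da[2] != N_SENSORS || da[3] != 3 ||
      !identical(da, dg)) {
    stop("imu_recording: accel and gyro must both be frames x 7 x 3")
  }
  if (max(abs(accel)) > 160) stop("imu_recording: accelerometer exceeds +/-160 m/s^2")
  if (max(abs(gyro)) > 2000) stop("imu_recording: gyroscope exceeds +/-2000 deg/s")
  dimnames(accel) <- dimnames(gyro) <- list(NULL, SENSOR_SITES, AXIS_LABELS)
  structure(list(accel = accel, gyro = gyro, frame_rate = frame_rate,
                 sensors = SENSOR_SITES),
            class = "imu_recording")
}

#' A synchronized trial: markers, IMU and events
#'
#' @param markers A `marker_set`. @param imu An `imu_recording`.
#' @param events List with `left` and `right` heel-strike frame indices.
#' @param subject_id,trial_id Identifiers.
#' @export
trial_bundle <- function(markers, imu, events, subject_id = "S01",
                         trial_id = "T01") {
  for (side in c("left", "right")) {
    ev <- events[[side]]
    if (is.unsorted(ev, strictly = TRUE)) {
      stop("trial_bundle: events must be strictly increasing (side ", side, ")")
    }
  }
  structure(list(markers = markers, imu = imu, events = events,
                 subject_id = subject_id, trial_id = trial_id),
            class = "trial_bundle")
}

# --- TRC ------------------------------------------------------------------

#' Read a TRC marker file
#'
#' Parses the standard TRC header and data table; converts units to mm if the
#' header declares m; reorders columns to the canonical 16-marker order and
#' ignores any additional markers. Blank fields become gaps.
#'
#' @param path File path.
#' @return A `marker_set`.
#' @export
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6 || !startsWith(lines[1], "PathFileType")) {
    stop("read_trc: malformed TRC header in ", path)
  }
  hdr_keys <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  hdr_vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  hdr <- stats::setNames(as.list(hdr_vals), hdr_keys)
  frame_rate <- as.numeric(hdr[["DataRate"]])
  n_frames <- as.integer(hdr[["NumFrames"]])
  units <- hdr[["Units"]]
  if (is.na(frame_rate) || is.na(n_frames) || is.null(units)) {
    stop("read_trc: malformed TRC header in ", path)
  }
  label_row <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  labels <- label_row[-(1:2)]
  labels <- labels[labels != ""]
  missing <- setdiff(MARKER_LABELS, labels)
  if (length(missing)) {
    stop("read_trc: required marker(s) missing: ", paste(missing, collapse = ", "))
  }
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  cells <- strsplit(data_lines, "\t", fixed = TRUE)
  n_cols <- 2 + 3 * length(labels)
  vals <- t(vapply(cells, function(x) {
    x <- c(x, rep("", max(0, n_cols - length(x))))[seq_len(n_cols)]
    suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  }, numeric(n_cols)))
  scale <- if (identical(tolower(units), "m")) 1000 else 1
  pos <- array(NA_real_, dim = c(nrow(vals), N_MARKERS, 3))
  gap <- matrix(FALSE, nrow(vals), N_MARKERS)
  for (j in seq_len(N_MARKERS)) {
    src <- match(MARKER_LABELS[j], labels)
    cols <- 2 + (src - 1) * 3 + (1:3)
    xyz <- vals[, cols, drop = FALSE] * scale
    pos[, j, ] <- xyz
    gap[, j] <- !is.finite(xyz[, 1]) | !is.finite(xyz[, 2]) | !is.finite(xyz[, 3])
  }
  marker_set(pos, frame_rate, gap)
}

#' Write a TRC marker file
#'
#' @param set A `marker_set`. @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(set, path) {
  n <- dim(set$positions)[1]
  if (n == 0) stop("write_trc: empty marker set")
  fr <- set$frame_rate
  hdr1 <- sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path))
  hdr2 <- "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames"
  hdr3 <- sprintf("%g\t%g\t%d\t%d\tmm\t%g\t1\t%d", fr, fr, n, N_MARKERS, fr, n)
  hdr4 <- paste(c("Frame#", "Time",
                  as.vector(rbind(MARKER_LABELS, "", ""))), collapse = "\t")
  hdr5 <- paste(c("", "", paste0(rep(c("X", "Y", "Z"), N_MARKERS),
                                 rep(seq_len(N_MARKERS), each = 3))),
                collapse = "\t")
  fmt_num <- function(x) ifelse(is.na(x), "", formatC(x, digits = 8, format = "f"))
  rows <- vapply(seq_len(n), function(i) {
    xyz <- t(set$positions[i, , ])         # 3 x 16, axis fastest
    xyz[, set$gap_mask[i, ]] <- NA
    paste(c(i, formatC((i - 1) / fr, digits = 6, format = "f"),
            fmt_num(as.vector(xyz))), collapse = "\t")
  }, character(1))
  writeLines(c(hdr1, hdr2, hdr3, hdr4, hdr5, "", rows), path)
  invisible(path)
}

# --- IMU CSV --------------------------------------------------------------

imu_col_names <- function() {
  as.vector(vapply(SENSOR_SITES, function(s) {
    c(paste0(s, "_acc_", AXIS_LABELS), paste0(s, "_gyr_", AXIS_LABELS))
  }, character(6)))
}

#' Read IMU data from CSV
#'
#' Accepts either one wide table (columns `time` plus
#' `<sensor>_<acc|gyr>_<x|y|z>` for the 7 canonical sensors) or a named
#' vector of 7 per-sensor files (names = sensor sites, columns
#' `acc_x..gyr_z`), which must share frame counts.
#'
#' @param paths One wide CSV path, or a named character vector of 7 paths.
#' @param frame_rate Hz; if NULL, inferred from a `time` column.
#' @return An `imu_recording`.
#' @export
read_imu_csv <- function(paths, frame_rate = NULL) {
  if (length(paths) == 1) {
    tab <- utils::read.csv(paths, check.names = FALSE)
    need <- imu_col_names()
    missing <- setdiff(need, names(tab))
    if (length(missing)) {
      stop("read_imu_csv: missing channel(s): ", paste(missing, collapse = ", "))
    }
    if (is.null(frame_rate)) {
      if (!"time" %in% names(tab)) stop("read_imu_csv: no time column and no frame_rate")
      frame_rate <- 1 / stats::median(diff(tab$time))
    }
    n <- nrow(tab)
    accel <- array(NA_real_, c(n, N_SENSORS, 3))
    gyro <- array(NA_real_, c(n, N_SENSORS, 3))
    for (si in seq_len(N_SENSORS)) {
      s <- SENSOR_SITES[si]
      for (ai in 1:3) {
        accel[, si, ai] <- tab[[paste0(s, "_acc_", AXIS_LABELS[ai])]]
        gyro[, si, ai] <- tab[[paste0(s, "_gyr_", AXIS_LABELS[ai])]]
      }
    }
    return(imu_recording(accel, gyro, frame_rate))
  }
  missing <- setdiff(SENSOR_SITES, names(paths))
  if (length(missing)) {
    stop("read_imu_csv: missing sensor(s): ", paste(missing, collapse = ", "))
  }
  tabs <- lapply(SENSOR_SITES, function(s) utils::read.csv(paths[[s]]))
  ns <- vapply(tabs, nrow, integer(1))
  if (length(unique(ns)) != 1) {
    stop("read_imu_csv: per-sensor frame counts differ (sync error): ",
         paste(ns, collapse = ", "))
  }
  if (is.null(frame_rate)) {
    if (!"time" %in% names(tabs[[1]])) stop("read_imu_csv: no time column and no frame_rate")
    frame_rate <- 1 / stats::median(diff(tabs[[1]]$time))
  }
  n <- ns[1]
  accel <- array(NA_real_, c(n, N_SENSORS, 3))
  gyro <- array(NA_real_, c(n, N_SENSORS, 3))
  for (si in seq_len(N_SENSORS)) {
    for (ai in 1:3) {
      accel[, si, ai] <- tabs[[si]][[paste0("acc_", AXIS_LABELS[ai])]]
      gyro[, si, ai] <- tabs[[si]][[paste0("gyr_", AXIS_LABELS[ai])]]
    }
  }
  imu_recording(accel, gyro, frame_rate)
}

#' Write an IMU recording to one wide CSV
#'
#' @param imu An `imu_recording`. @param path Output path.
#' @export
write_imu_csv <- function(imu, path) {
  n <- dim(imu$accel)[1]
  tab <- data.frame(time = (seq_len(n) - 1) / imu$frame_rate)
  for (si in seq_len(N_SENSORS)) {
    s <- SENSOR_SITES[si]
    for (ai in 1:3) {
      tab[[paste0(s, "_acc_", AXIS_LABELS[ai])]] <- imu$accel[, si, ai]
      tab[[paste0(s, "_gyr_", AXIS_LABELS[ai])]] <- imu$gyro[, si, ai]
    }
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

# --- JSON sidecars --------------------------------------------------------

#' @rdname dataset-io
#' @export
write_events_json <- function(events, path) {
  jsonlite::write_json(lapply(events, as.integer), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname dataset-io
#' @export
read_events_json <- function(path) {
  ev <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(ev, as.integer)
}

#' @rdname dataset-io
#' @export
write_anthro_json <- function(anthro, path) {
  jsonlite::write_json(unclass(anthro), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname dataset-io
#' @export
read_anthro_json <- function(path) {
  a <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(anthropometrics, as.list(a))
}

#' Write a synthetic dataset to disk
#'
#' One directory per subject with TRC markers (walking and static), a wide
#' IMU CSV, heel-strike events JSON and anthropometrics JSON, plus a manifest
#' JSON listing files and seeds.
#'
#' @param dataset A `gait_dataset` from [generate_dataset()].
#' @param dir Output directory.
#' @name dataset-io
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(master_seed = dataset$master_seed, fs = dataset$fs,
                   noise = unclass(dataset$noise), subjects = list())
  for (sub in dataset$subjects) {
    sd <- file.path(dir, sub$subject_id)
    dir.create(sd, showWarnings = FALSE)
    files <- list(markers = file.path(sd, "markers.trc"),
                  static = file.path(sd, "static.trc"),
                  imu = file.path(sd, "imu.csv"),
                  events = file.path(sd, "events.json"),
                  anthro = file.path(sd, "anthro.json"))
    write_trc(sub$markers, files$markers)
    write_trc(sub$static_markers, files$static)
    write_imu_csv(sub$imu, files$imu)
    write_events_json(sub$events, files$events)
    write_anthro_json(sub$anthro, files$anthro)
    manifest$subjects[[sub$subject_id]] <-
      c(lapply(files, basename), list(seed = sub$seed))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# --- packed cycle container ----------------------------------------------

CYCLE_FORMAT_VERSION <- "imumocap-cycles-1"

#' Save / load packed gait-cycle sets
#'
#' The container stores the cycle list, per-subject static calibrations and
#' the transform parameters (offset 700 mm, scale 100) under a format-version
#' attribute so the inverse transform is always recoverable. Round trips are
#' lossless.
#'
#' @param cycleset A `cycle_set` from [prepare_cycles()].
#' @param path File path.
#' @name cycle-io
#' @export
save_cycles <- function(cycleset, path) {
  stopifnot(inherits(cycleset, "cycle_set"))
  obj <- list(version = CYCLE_FORMAT_VERSION,
              transform = list(offset = 700, scale = 100),
              cycleset = cycleset)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname cycle-io
#' @export
load_cycles <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, CYCLE_FORMAT_VERSION)) {
    stop("load_cycles: format version mismatch: ",
         obj$version %||% "<missing>")
  }
  obj$cycleset
}
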