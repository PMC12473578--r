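#' Canonical marker and sensor orderings
#'
#' Every module uses these single-sourced constants; nothing redeclares them.
#'
#' `MARKER_LABELS` lists the 16 lower-limb conventional-gait-model (Plug-in
#' Gait) markers in canonical order: pelvis (LASI, RASI, LPSI, RPSI), then the
#' left leg (thigh wand, knee, tibia wand, ankle, heel, toe), then the right.
#' `SENSOR_SITES` lists the 7 inertial sensor sites: fifth lumbar vertebra
#' (pelvis), lateral mid-thigh and mid-shank bilaterally, and both foot dorsa.
#' `FOOT_MARKER_LABELS` are the six foot-complex markers given extra weight in
#' the biomech loss.
#'
#' @format Character vectors.
#' @name canonical-orderings
NULL

#' @rdname canonical-orderings
#' @export
MARKER_LABELS <- c("LASI", "RASI", "LPSI", "RPSI",
                   "LTHI", "LKNE", "LTIB", "LANK", "LHEE", "LTOE",
                   "RTHI", "RKNE", "RTIB", "RANK", "RHEE", "RTOE")

#' @rdname canonical-orderings
#' @export
SENSOR_SITES <- c("pelvis", "thigh_l", "thigh_r", "shank_l", "shank_r",
                  "foot_l", "foot_r")

#' @rdname canonical-orderings
#' @export
FOOT_MARKER_LABELS <- c("LANK", "LHEE", "LTOE", "RANK", "RHEE", "RTOE")

#' @rdname canonical-orderings
#' @export
AXIS_LABELS <- c("x", "y", "z")  # x antero-posterior, y medio-lateral (to the
                                 # subject's left), z vertical

N_MARKERS <- 16L
N_SENSORS <- 7L
N_FRAMES_CYCLE <- 101L  # gait cycle time-normalized to 0..100%

GRAVITY <- 9.81  # m/s^2

#' Index of marker labels in the canonical ordering
#'
#' @param labels Character vector of canonical marker labels.
#' @return Integer indices; unknown labels are an error.
#' @export
marker_index <- function(labels) {
  idx <- match(labels, MARKER_LABELS)
  if (anyNA(idx)) {
    stop("unknown marker label(s): ", paste(labels[is.na(idx)], collapse = ", "))
  }
  idx
}

sensor_index <- function(sites) {
  idx <- match(sites, SENSOR_SITES)
  if (anyNA(idx)) {
    stop("unknown sensor site(s): ", paste(sites[is.na(idx)], collapse = ", "))
  }
  idx
}

# feature index (1..48) of an (axis, marker) pair in the flattened target
# layout used by the network and the loss: axis varies fastest.
feature_index <- function(axis, marker) axis + 3L * (marker - 1L)

foot_feature_indices <- function(foot_labels = FOOT_MARKER_LABELS) {
  mk <- marker_index(foot_labels)
  sort(as.integer(outer(1:3, mk, feature_index)))
}
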