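# Conventional-gait-model (Plug-in-Gait style) sagittal kinematics from the
# 16-marker lower-limb set. The identical code path serves measured and
# network-predicted markers, which is what makes the two comparable.

vnorm <- function(m) sqrt(rowSums(m * m))

vnormalize <- function(m, what = "axis") {
  n <- vnorm(m)
  if (any(!is.finite(n)) || any(n < 1e-9)) {
    stop("degenerate geometry: zero-length ", what)
  }
  m / n
}

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

vdot <- function(a, b) rowSums(a * b)

as_marker_array <- function(markers) {
  if (inherits(markers, "marker_set")) return(markers$positions)
  if (is.array(markers) && length(dim(markers)) == 3 && dim(markers)[2] == N_MARKERS) {
    return(markers)
  }
  stop("expected a marker_set or a frames x 16 x 3 array")
}

mk <- function(pos, label) {
  m <- pos[, marker_index(label), , drop = FALSE]
  dim(m) <- c(dim(pos)[1], 3)
  m
}

#' Pelvis anatomical frame from the four pelvis markers
#'
#' Origin is the ASIS midpoint; the medio-lateral axis lies along RASI-LASI
#' (pointing to the subject's left); the antero-posterior axis points from the
#' PSIS midpoint toward the ASIS midpoint, orthogonalized; the vertical axis
#' completes a right-handed frame.
#'
#' @param lasi,rasi,lpsi,rpsi Frames x 3 marker trajectories, mm.
#' @return List with `origin` (n x 3) and axis matrices `ex`, `ey`, `ez`.
#' @export
pelvis_frame <- function(lasi, rasi, lpsi, rpsi) {
  origin <- (lasi + rasi) / 2
  ey <- vnormalize(lasi - rasi, "pelvis medio-lateral axis")
  v <- origin - (lpsi + rpsi) / 2
  v_perp <- v - ey * vdot(v, ey)
  ex <- vnormalize(v_perp, "pelvis antero-posterior axis (collinear markers?)")
  ez <- vcross(ex, ey)
  list(origin = origin, ex = ex, ey = ey, ez = ez)
}

# Hip-joint-center regression offsets in the pelvis frame (mm), Davis et al.
# (1991) as used by the conventional gait model: anterior (x), lateral from
# the midline (y_lat) and inferior (z) offsets from the ASIS midpoint,
# parameterized by leg length and inter-ASIS distance.
hip_center_offsets <- function(anthro) {
  L <- anthro$leg_length
  C <- 0.115 * L - 15.3
  aa <- anthro$inter_asis_distance / 2
  mr <- anthro$marker_diameter / 2
  theta <- 0.5
  beta <- 0.314
  asis_troc <- 0.1288 * L - 48.56
  list(x = C * cos(theta) * sin(beta) - (asis_troc + mr) * cos(beta),
       y_lat = aa - C * sin(theta),
       z = -C * cos(theta) * cos(beta) - (asis_troc + mr) * sin(beta))
}

#' Static calibration from a standing trial
#'
#' Computes static marker means, the hip-joint-center regression offsets, the
#' chord radii for knee and ankle, and the static plantar/dorsiflexion offset
#' per side that defines 0 degrees of dorsiflexion in the neutral stance.
#'
#' @param static_markers A `marker_set` (at least 0.5 s recommended) or a
#'   16 x 3 matrix of marker positions.
#' @param anthro An `anthropometrics` object.
#' @return Object of class `static_calibration`.
#' @export
static_calibration <- function(static_markers, anthro) {
  if (is.null(anthro)) stop("static_calibration: anthropometrics are required")
  if (inherits(static_markers, "marker_set")) {
    if (nrow(static_markers$positions) / static_markers$frame_rate < 0.5) {
      warning("static trial shorter than 0.5 s; marker means may be unstable")
    }
    mean_pos <- apply(static_markers$positions, c(2, 3), mean)
  } else if (is.matrix(static_markers) && nrow(static_markers) == N_MARKERS) {
    mean_pos <- static_markers
  } else {
    stop("static_calibration: expected a marker_set or 16 x 3 matrix")
  }
  dimnames(mean_pos) <- list(MARKER_LABELS, AXIS_LABELS)
  cal <- structure(list(static_markers = mean_pos,
                        anthro = anthro,
                        hip_offsets = hip_center_offsets(anthro),
                        ankle_offset = c(l = 0, r = 0)),
                   class = "static_calibration")
  static_arr <- array(NA_real_, dim = c(1, N_MARKERS, 3))
  static_arr[1, , ] <- mean_pos
  ang <- compute_joint_angles(static_arr, cal)
  cal$ankle_offset <- c(l = ang$ankle_l[1], r = ang$ankle_r[1])
  cal
}

#' Hip joint centers from the pelvis frame and calibration
#'
#' Expresses the regression offsets in the lab frame at every frame.
#'
#' @param cal A `static_calibration`.
#' @param pelvis Output of [pelvis_frame()].
#' @return List with `l` and `r` (n x 3 trajectories, mm).
#' @export
hip_joint_center <- function(cal, pelvis) {
  if (is.null(cal$anthro)) stop("hip_joint_center: calibration lacks anthropometrics")
  off <- cal$hip_offsets
  place <- function(y_lat) {
    pelvis$origin + off$x * pelvis$ex + y_lat * pelvis$ey + off$z * pelvis$ez
  }
  list(l = place(off$y_lat), r = place(-off$y_lat))
}

#' Chord construction for knee and ankle joint centers
#'
#' The joint center lies in the plane of the proximal center, the lateral
#' joint marker and the wand marker, at distance
#' `(joint_width + marker_diameter) / 2` from the lateral marker, positioned
#' so that the line from the joint center to the lateral marker is
#' perpendicular to the segment's longitudinal axis, on the side of the plane
#' opposite the wand (the segment-medial side, with wands placed lateral).
#'
#' @param proximal_center,lateral_marker,wand_marker n x 3 trajectories, mm.
#' @param joint_width Joint width, mm.
#' @param marker_diameter Marker diameter, mm.
#' @return n x 3 joint-center trajectory, mm.
#' @export
chord_joint_center <- function(proximal_center, lateral_marker, wand_marker,
                               joint_width, marker_diameter) {
  r <- (joint_width + marker_diameter) / 2
  u <- proximal_center - lateral_marker
  d <- vnorm(u)
  if (any(d < 1e-9)) stop("chord_joint_center: proximal center coincides with lateral marker")
  if (any(r / d > 1)) stop("chord_joint_center: chord radius exceeds proximal distance")
  u <- u / d
  v <- wand_marker - lateral_marker
  v_perp <- v - u * vdot(v, u)
  nv <- vnorm(v_perp)
  if (any(nv < 1e-9)) stop("chord_joint_center: collinear defining points")
  w <- v_perp / nv
  cos_phi <- r / d
  sin_phi <- sqrt(pmax(0, 1 - cos_phi^2))
  lateral_marker + r * (cos_phi * u - sin_phi * w)
}

make_frame <- function(ez_raw, ey_raw, what) {
  ez <- vnormalize(ez_raw, paste(what, "longitudinal axis"))
  ex <- vnormalize(vcross(ey_raw, ez), paste(what, "anterior axis"))
  ey <- vcross(ez, ex)
  list(ex = ex, ey = ey, ez = ez)
}

#' Segment anatomical frames from joint centers and markers
#'
#' Femur: longitudinal axis from knee center up to the hip center; tibia:
#' ankle center up to the knee center; foot: heel-to-toe anterior axis. The
#' medio-lateral axis of every frame points to the subject's left, so the
#' same Cardan extraction serves both sides.
#'
#' @param centers List with `hjc_l`, `hjc_r`, `kjc_l`, `kjc_r`, `ajc_l`,
#'   `ajc_r` (n x 3 trajectories).
#' @param markers A `marker_set` or frames x 16 x 3 array, mm.
#' @return Nested list of frames: `femur`, `tibia`, `foot` per side.
#' @export
segment_frames <- function(centers, markers) {
  pos <- as_marker_array(markers)
  out <- list()
  for (side in c("l", "r")) {
    s <- if (side == "l") 1 else -1
    hjc <- centers[[paste0("hjc_", side)]]
    kjc <- centers[[paste0("kjc_", side)]]
    ajc <- centers[[paste0("ajc_", side)]]
    pre <- if (side == "l") "L" else "R"
    kne <- mk(pos, paste0(pre, "KNE"))
    ank <- mk(pos, paste0(pre, "ANK"))
    hee <- mk(pos, paste0(pre, "HEE"))
    toe <- mk(pos, paste0(pre, "TOE"))
    ml_femur <- s * (kne - kjc)   # toward the subject's left
    ml_tibia <- s * (ank - ajc)
    femur <- make_frame(hjc - kjc, ml_femur, "femur")
    tibia <- make_frame(kjc - ajc, ml_tibia, "tibia")
    fx <- vnormalize(toe - hee, "foot axis")
    fz <- vnormalize(vcross(fx, tibia$ey), "foot vertical axis")
    foot <- list(ex = fx, ey = vcross(fz, fx), ez = fz)
    out[[side]] <- list(femur = femur, tibia = tibia, foot = foot)
  }
  out
}

# Cardan decomposition (flexion first, about the proximal medio-lateral axis)
# of the relative rotation proximal -> distal; returns the three angles in
# degrees. Warns near gimbal lock of the second angle.
cardan_yxz <- function(prox, dist) {
  r13 <- vdot(prox$ex, dist$ez)
  r33 <- vdot(prox$ez, dist$ez)
  r23 <- vdot(prox$ey, dist$ez)
  r21 <- vdot(prox$ey, dist$ex)
  r22 <- vdot(prox$ey, dist$ey)
  b <- asin(pmin(1, pmax(-1, -r23)))
  if (any(abs(b) > 85 * pi / 180)) {
    warning("cardan_yxz: second rotation near gimbal lock; angles unreliable")
  }
  list(a = atan2(r13, r33) * 180 / pi,
       b = b * 180 / pi,
       c = atan2(r21, r22) * 180 / pi)
}

#' Sagittal joint angles from pelvis and segment frames
#'
#' Flexion is the first Cardan rotation about the proximal medio-lateral
#' axis. Hip and knee flexion are positive; ankle dorsiflexion is positive
#' after subtracting the static offset (90-degree anatomical convention:
#' neutral standing is 0 degrees of dorsiflexion).
#'
#' @param pelvis Output of [pelvis_frame()].
#' @param frames Output of [segment_frames()].
#' @param ankle_offset Named vector `c(l = , r = )`, degrees, from the static
#'   calibration.
#' @return Object of class `joint_angle_series` with `hip_l`, `hip_r`,
#'   `knee_l`, `knee_r`, `ankle_l`, `ankle_r` (degrees) and `n_frames`.
#' @export
sagittal_angles <- function(pelvis, frames, ankle_offset = c(l = 0, r = 0)) {
  out <- list()
  for (side in c("l", "r")) {
    fr <- frames[[side]]
    hip <- cardan_yxz(pelvis, fr$femur)
    knee <- cardan_yxz(fr$femur, fr$tibia)
    ankle <- cardan_yxz(fr$tibia, fr$foot)
    out[[paste0("hip_", side)]] <- -hip$a
    out[[paste0("knee_", side)]] <- knee$a
    out[[paste0("ankle_", side)]] <- -ankle$a - ankle_offset[[side]]
  }
  out$n_frames <- length(out$hip_l)
  structure(out, class = "joint_angle_series")
}

#' Sagittal hip, knee and ankle angles from 16-marker trajectories
#'
#' Runs the full conventional-gait-model chain: pelvis frame, hip-joint-center
#' regression, chord knee and ankle centers, segment frames, Cardan angles.
#'
#' @param markers A `marker_set` or frames x 16 x 3 array, mm.
#' @param cal A `static_calibration`.
#' @return A `joint_angle_series`.
#' @export
compute_joint_angles <- function(markers, cal) {
  pos <- as_marker_array(markers)
  pelvis <- pelvis_frame(mk(pos, "LASI"), mk(pos, "RASI"),
                         mk(pos, "LPSI"), mk(pos, "RPSI"))
  hjc <- hip_joint_center(cal, pelvis)
  a <- cal$anthro
  centers <- list(hjc_l = hjc$l, hjc_r = hjc$r)
  for (side in c("l", "r")) {
    pre <- if (side == "l") "L" else "R"
    kjc <- chord_joint_center(centers[[paste0("hjc_", side)]],
                              mk(pos, paste0(pre, "KNE")),
                              mk(pos, paste0(pre, "THI")),
                              a$knee_width, a$marker_diameter)
    ajc <- chord_joint_center(kjc,
                              mk(pos, paste0(pre, "ANK")),
                              mk(pos, paste0(pre, "TIB")),
                              a$ankle_width, a$marker_diameter)
    centers[[paste0("kjc_", side)]] <- kjc
    centers[[paste0("ajc_", side)]] <- ajc
  }
  frames <- segment_frames(centers, pos)
  sagittal_angles(pelvis, frames, cal$ankle_offset)
}

#' Joint angles from network predictions in transformed space
#'
#' Applies the inverse marker transform (decimeter scale back to lab mm using
#' the stored per-cycle factor) and then the identical conventional-gait-model
#' chain used for measured markers.
#'
#' @param targets 101 x 3 x 16 predicted (or true) transformed markers.
#' @param factor Length-3 translation factor, mm, stored with the cycle.
#' @param cal A `static_calibration`.
#' @return A `joint_angle_series` (101 frames).
#' @export
angles_from_predictions <- function(targets, factor, cal) {
  compute_joint_angles(inverse_transform(targets, factor), cal)
}
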