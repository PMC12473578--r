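#' Subject anthropometrics for the conventional gait model
#'
#' All dimensions in millimetres. `leg_length` is the clinical ASIS-to-medial
#' malleolus measure used by the hip-joint-center regression; `knee_width` and
#' `ankle_width` feed the chord joint-center constructions.
#'
#' @param leg_length,inter_asis_distance,thigh_length,shank_length,foot_length
#'   Segment and landmark dimensions, mm.
#' @param pelvis_depth ASIS-to-PSIS depth, mm.
#' @param knee_width,ankle_width Joint widths, mm.
#' @param marker_diameter Physical marker diameter, mm.
#' @return An object of class `anthropometrics`.
#' @export
anthropometrics <- function(leg_length, inter_asis_distance, thigh_length,
                            shank_length, foot_length, pelvis_depth,
                            knee_width, ankle_width, marker_diameter = 14) {
  a <- list(leg_length = leg_length,
            inter_asis_distance = inter_asis_distance,
            thigh_length = thigh_length,
            shank_length = shank_length,
            foot_length = foot_length,
            pelvis_depth = pelvis_depth,
            knee_width = knee_width,
            ankle_width = ankle_width,
            marker_diameter = marker_diameter)
  vals <- unlist(a)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("anthropometrics: all lengths must be finite and > 0")
  }
  if (thigh_length + shank_length >= leg_length * 1.1) {
    stop("anthropometrics: thigh_length + shank_length must be < 1.1 * leg_length")
  }
  if (knee_width >= thigh_length) stop("anthropometrics: knee_width must be < thigh_length")
  if (ankle_width >= shank_length) stop("anthropometrics: ankle_width must be < shank_length")
  structure(a, class = "anthropometrics")
}

#' Default adult anthropometrics, optionally uniformly scaled
#'
#' Dimensions correspond to an adult of roughly 170 cm stature; `scale`
#' multiplies every length uniformly so limb proportions are preserved.
#'
#' @param scale Uniform scale factor (1 = default subject).
#' @export
default_anthropometrics <- function(scale = 1) {
  anthropometrics(leg_length = 900 * scale,
                  inter_asis_distance = 240 * scale,
                  thigh_length = 450 * scale,
                  shank_length = 430 * scale,
                  foot_length = 250 * scale,
                  pelvis_depth = 140 * scale,
                  knee_width = 100 * scale,
                  ankle_width = 70 * scale,
                  marker_diameter = 14)
}

# Default walking joint-angle profiles: 6-harmonic Fourier series fit to
# textbook normative sagittal gait curves (hip/knee flexion and ankle
# dorsiflexion positive, degrees, phase 0 = ipsilateral heel strike), with
# harmonic amplitudes scaled to 0.85 of the overground fit to reflect the
# smaller sagittal excursions of treadmill walking at preferred speed.
DEFAULT_HIP_FOURIER <- c(12.2, 17.328, -3.1247, -1.6952, -1.6314, -0.158,
                         0.3671, -0.1748, 0.109, -0.17, 0.5054, 0, 0)
DEFAULT_KNEE_FOURIER <- c(21.4742, -4.9428, -17.6509, -10.0278, 8.8283,
                          0.7094, 4.1548, 0.613, -0.6599, 0, 0.2542,
                          -0.3262, -0.7766)
DEFAULT_ANKLE_FOURIER <- c(-0.0978, -0.7208, 5.3162, 1.8394, -5.5013, -2.4286,
                           0.2875, 1.9963, -0.7871, -0.255, -1.8822, -0.3488,
                           -0.291)

#' Parametric walking profile for the synthetic gait simulator
#'
#' Joint-angle curves are periodic Fourier series over the gait cycle. With
#' `align_phase = TRUE` (default) the three coefficient sets are jointly
#' phase-rolled so that the right heel's anterior position peaks exactly at
#' phase 0, making cycle starts coincide with coordinate-based heel-strike
#' detection.
#'
#' @param cadence Steps per minute (two steps per gait cycle).
#' @param n_cycles Number of gait cycles per side in a generated trial.
#' @param hip_fourier,knee_fourier,ankle_fourier Coefficient vectors
#'   `c(a0, a1, b1, ...)`, degrees.
#' @param pelvis_sway_amplitude Medio-lateral pelvis sway amplitude, mm.
#'   Vertical pelvis oscillation (two per cycle) uses 0.4 x this value.
#' @param phase_offset_left Left-side phase lag in cycle fractions.
#' @param seed Integer seed stored with the profile.
#' @param align_phase Roll profiles so heel strike is at phase 0.
#' @export
gait_profile <- function(cadence = 110, n_cycles = 8,
                         hip_fourier = DEFAULT_HIP_FOURIER,
                         knee_fourier = DEFAULT_KNEE_FOURIER,
                         ankle_fourier = DEFAULT_ANKLE_FOURIER,
                         pelvis_sway_amplitude = 25,
                         phase_offset_left = 0.5,
                         seed = 42L,
                         align_phase = TRUE) {
  if (cadence <= 0) stop("gait_profile: cadence must be > 0")
  if (n_cycles < 2) stop("gait_profile: n_cycles must be >= 2")
  if (!length(hip_fourier) || !length(knee_fourier) || !length(ankle_fourier)) {
    stop("gait_profile: Fourier coefficient vectors must be non-empty")
  }
  p <- structure(list(cadence = cadence,
                      cycle_duration = 120 / cadence,
                      n_cycles = as.integer(n_cycles),
                      hip_fourier = hip_fourier,
                      knee_fourier = knee_fourier,
                      ankle_fourier = ankle_fourier,
                      pelvis_sway_amplitude = pelvis_sway_amplitude,
                      phase_offset_left = phase_offset_left,
                      seed = as.integer(seed)),
                 class = "gait_profile")
  if (align_phase) p <- align_profile_phase(p)
  p
}

# Anterior heel position of the right leg as a function of cycle phase, for a
# reference subject; used only to locate the heel-strike phase.
heel_anterior_curve <- function(profile, anthro = default_anthropometrics(),
                                phase = seq(0, 1, length.out = 2001)) {
  deg2rad <- pi / 180
  thF <- fourier_eval(profile$hip_fourier, phase) * deg2rad
  thT <- thF - fourier_eval(profile$knee_fourier, phase) * deg2rad
  thP <- thT + fourier_eval(profile$ankle_fourier, phase) * deg2rad
  geom <- body_geometry(anthro)
  hx <- geom$hip_local_l[1]
  px <- geom$heel_local[1]; pz <- geom$heel_local[3]
  hx + anthro$thigh_length * sin(thF) + anthro$shank_length * sin(thT) +
    px * cos(thP) - pz * sin(thP)
}

align_profile_phase <- function(profile) {
  phase <- seq(0, 1 - 1 / 2000, length.out = 2000)
  hx <- heel_anterior_curve(profile, phase = phase)
  delta <- phase[which.max(hx)]
  if (delta > 0) {
    profile$hip_fourier <- fourier_shift(profile$hip_fourier, delta)
    profile$knee_fourier <- fourier_shift(profile$knee_fourier, delta)
    profile$ankle_fourier <- fourier_shift(profile$ankle_fourier, delta)
  }
  profile
}

#' IMU and marker noise model
#'
#' Gaussian measurement noise for the simulator: white accelerometer and
#' gyroscope noise, a constant per-channel gyroscope bias, and isotropic
#' marker jitter (emulating residual soft-tissue/reconstruction error).
#'
#' @param preset One of `"default"`, `"low"`, `"none"`; explicit sigmas
#'   override preset values.
#' @param accel_sigma m/s^2; @param gyro_sigma deg/s;
#' @param gyro_bias_sigma deg/s; @param marker_jitter_sigma mm.
#' @param seed Integer seed for the noise stream.
#' @export
noise_model <- function(preset = c("default", "low", "none"),
                        accel_sigma = NULL, gyro_sigma = NULL,
                        gyro_bias_sigma = NULL, marker_jitter_sigma = NULL,
                        seed = 1L) {
  preset <- match.arg(preset)
  base <- switch(preset,
                 none    = c(0, 0, 0, 0),
                 low     = c(0.15, 1.0, 0.2, 1.0),
                 default = c(0.5, 3.0, 0.5, 2.0))
  nm <- list(accel_sigma = accel_sigma %||% base[1],
             gyro_sigma = gyro_sigma %||% base[2],
             gyro_bias_sigma = gyro_bias_sigma %||% base[3],
             marker_jitter_sigma = marker_jitter_sigma %||% base[4],
             seed = as.integer(seed))
  if (any(unlist(nm[1:4]) < 0)) stop("noise_model: sigmas must be >= 0")
  structure(nm, class = "noise_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Body geometry: marker and sensor coordinates in segment frames (mm).
# Sagittal convention: segment frames pitch about the medio-lateral (y) axis;
# a local point (px, py, pz) at pitch theta maps to world
#   x = ox + px cos(theta) - pz sin(theta)
#   y = oy + py
#   z = oz + px sin(theta) + pz cos(theta)
body_geometry <- function(anthro) {
  W <- anthro$inter_asis_distance
  rk <- (anthro$knee_width + anthro$marker_diameter) / 2
  ra <- (anthro$ankle_width + anthro$marker_diameter) / 2
  hip_off <- hip_center_offsets(anthro)
  hf <- 60 * (anthro$shank_length / 430)  # ankle center height above sole
  list(
    # pelvis-frame locals (origin mid-ASIS, frame = lab when standing)
    pelvis_markers = list(
      LASI = c(0,  W / 2, 0), RASI = c(0, -W / 2, 0),
      LPSI = c(-anthro$pelvis_depth,  0.3 * W, 0),
      RPSI = c(-anthro$pelvis_depth, -0.3 * W, 0)),
    hip_local_l = c(hip_off$x,  hip_off$y_lat, hip_off$z),
    hip_local_r = c(hip_off$x, -hip_off$y_lat, hip_off$z),
    # femur-frame locals (origin hip joint center); s = +1 left, -1 right
    knee_center_local = function(Lt) c(0, 0, -Lt),
    kne_local = function(s) c(0, s * rk, -anthro$thigh_length),
    thi_local = function(s) c(0, s * (rk + 40), -0.5 * anthro$thigh_length),
    # tibia-frame locals (origin knee joint center)
    ank_local = function(s) c(0, s * ra, -anthro$shank_length),
    tib_local = function(s) c(0, s * (ra + 40), -0.5 * anthro$shank_length),
    # foot-frame locals (origin ankle joint center)
    heel_local = c(-0.25 * anthro$foot_length, 0, -hf),
    toe_local  = c( 0.45 * anthro$foot_length, 0, -hf),
    ankle_height = hf,
    knee_radius = rk, ankle_radius = ra)
}

#' Default IMU placement on the seven body segments
#'
#' Each sensor is rigidly fixed to one segment with axes aligned to the
#' segment frame: L5/pelvis (posterior), lateral mid-thigh and mid-shank
#' bilaterally, and the foot dorsum.
#'
#' @param anthro An `anthropometrics` object.
#' @return Named list (canonical sensor order) of `list(segment, local)`.
#' @export
default_sensor_placement <- function(anthro) {
  geom <- body_geometry(anthro)
  lat <- function(s, r) c(0, s * r, 0)
  list(
    pelvis  = list(segment = "pelvis",
                   local = c(-0.9 * anthro$pelvis_depth, 0, 40)),
    thigh_l = list(segment = "femur_l",
                   local = c(0,  geom$knee_radius + 25, -0.5 * anthro$thigh_length)),
    thigh_r = list(segment = "femur_r",
                   local = c(0, -(geom$knee_radius + 25), -0.5 * anthro$thigh_length)),
    shank_l = list(segment = "tibia_l",
                   local = c(0,  geom$ankle_radius + 25, -0.5 * anthro$shank_length)),
    shank_r = list(segment = "tibia_r",
                   local = c(0, -(geom$ankle_radius + 25), -0.5 * anthro$shank_length)),
    foot_l  = list(segment = "foot_l",
                   local = c(0.35 * anthro$foot_length, 0, 20 - geom$ankle_height)),
    foot_r  = list(segment = "foot_r",
                   local = c(0.35 * anthro$foot_length, 0, 20 - geom$ankle_height)))
}

#' Generate per-side sagittal joint-angle time series for a walking trial
#'
#' The trial spans `n_cycles + 1.5` cycle durations so that both sides carry
#' `n_cycles + 1` interior heel strikes (the trial starts half a cycle before
#' the first right heel strike). The left side is the right side delayed by
#' `phase_offset_left` of a cycle.
#'
#' @param profile A `gait_profile`.
#' @param fs Sampling frequency, Hz.
#' @return List with `time`, `fs`, per-side angle series (`deg`), per-side
#'   global phase vectors, and ground-truth heel-strike frame indices.
#' @export
generate_joint_profiles <- function(profile, fs = 100) {
  if (!is.finite(fs) || fs <= 0) stop("generate_joint_profiles: fs must be > 0")
  if (!length(profile$hip_fourier) || !length(profile$knee_fourier) ||
      !length(profile$ankle_fourier)) {
    stop("generate_joint_profiles: empty Fourier coefficients")
  }
  T_cyc <- profile$cycle_duration
  n_samp <- round((profile$n_cycles + 1.5) * T_cyc * fs) + 1L
  time <- (seq_len(n_samp) - 1L) / fs
  psi_r <- time / T_cyc - 0.5                      # right global phase
  psi_l <- psi_r - profile$phase_offset_left       # left global phase
  side_angles <- function(psi) {
    ph <- psi %% 1
    list(hip = fourier_eval(profile$hip_fourier, ph),
         knee = fourier_eval(profile$knee_fourier, ph),
         ankle = fourier_eval(profile$ankle_fourier, ph),
         hip_rate = fourier_deriv(profile$hip_fourier, ph) / T_cyc,
         knee_rate = fourier_deriv(profile$knee_fourier, ph) / T_cyc,
         ankle_rate = fourier_deriv(profile$ankle_fourier, ph) / T_cyc,
         phase = psi)
  }
  ks <- 0:profile$n_cycles
  ev_r <- round(((ks + 0.5) * T_cyc) * fs) + 1L
  ev_l <- round(((ks + profile$phase_offset_left + 0.5) * T_cyc) * fs) + 1L
  list(time = time, fs = fs, cycle_duration = T_cyc,
       n_cycles = profile$n_cycles,
       right = side_angles(psi_r), left = side_angles(psi_l),
       events = list(left = ev_l[ev_l > 1 & ev_l < n_samp],
                     right = ev_r[ev_r > 1 & ev_r < n_samp]))
}

#' Forward kinematics: markers and segment kinematics from joint angles
#'
#' Drives a seven-segment lower-body chain (pelvis, femora, tibiae, feet) with
#' sagittal joint rotations plus parametric pelvis medio-lateral sway and
#' vertical oscillation, and emits the 16 canonical markers together with the
#' per-segment origin/pitch/angular-velocity series needed to derive IMU
#' signals. All intra-segment marker distances are rigid by construction.
#'
#' @param angles Output of [generate_joint_profiles()].
#' @param anthro An `anthropometrics` object.
#' @param profile The `gait_profile` that produced `angles` (for sway).
#' @return List with `markers` (a `marker_set`), `segments`, `fs`, `events`.
#' @export
forward_kinematics <- function(angles, anthro, profile) {
  for (side in c("left", "right")) {
    if (is.null(angles[[side]]) ||
        !all(c("hip", "knee", "ankle") %in% names(angles[[side]]))) {
      stop("forward_kinematics: missing angle channel for side ", side)
    }
  }
  geom <- body_geometry(anthro)
  n <- length(angles$time)
  deg2rad <- pi / 180
  psi <- angles$right$phase
  sway <- profile$pelvis_sway_amplitude
  h0 <- geom$ankle_height + anthro$thigh_length + anthro$shank_length -
    geom$hip_local_l[3]
  pelvis_origin <- cbind(x = rep(0, n),
                         y = -sway * sinpi(2 * psi),
                         z = h0 + 0.4 * sway * cospi(4 * psi))
  pelvis <- list(origin = pelvis_origin, theta = rep(0, n),
                 omega = rep(0, n))

  place_point <- function(origin, theta, local) {
    ct <- cos(theta); st <- sin(theta)
    cbind(origin[, 1] + local[1] * ct - local[3] * st,
          origin[, 2] + local[2],
          origin[, 3] + local[1] * st + local[3] * ct)
  }

  side_chain <- function(side) {
    s <- if (side == "left") 1 else -1
    a <- angles[[side]]
    thF <- a$hip * deg2rad
    thT <- (a$hip - a$knee) * deg2rad
    thP <- (a$hip - a$knee + a$ankle) * deg2rad
    wF <- a$hip_rate * deg2rad
    wT <- (a$hip_rate - a$knee_rate) * deg2rad
    wP <- (a$hip_rate - a$knee_rate + a$ankle_rate) * deg2rad
    hip_local <- if (s > 0) geom$hip_local_l else geom$hip_local_r
    hjc <- sweep(pelvis_origin, 2, -hip_local)  # pelvis frame = lab frame
    kjc <- place_point(hjc, thF, c(0, 0, -anthro$thigh_length))
    ajc <- place_point(kjc, thT, c(0, 0, -anthro$shank_length))
    list(femur = list(origin = hjc, theta = thF, omega = wF),
         tibia = list(origin = kjc, theta = thT, omega = wT),
         foot  = list(origin = ajc, theta = thP, omega = wP),
         s = s, kjc = kjc, ajc = ajc, hjc = hjc)
  }
  L <- side_chain("left"); R <- side_chain("right")

  pos <- array(NA_real_, dim = c(n, N_MARKERS, 3),
               dimnames = list(NULL, MARKER_LABELS, AXIS_LABELS))
  for (m in c("LASI", "RASI", "LPSI", "RPSI")) {
    pos[, m, ] <- place_point(pelvis_origin, pelvis$theta,
                              geom$pelvis_markers[[m]])
  }
  put_leg <- function(ch, pre) {
    s <- ch$s
    pos[, paste0(pre, "THI"), ] <<- place_point(ch$femur$origin, ch$femur$theta,
                                                geom$thi_local(s))
    pos[, paste0(pre, "KNE"), ] <<- place_point(ch$femur$origin, ch$femur$theta,
                                                geom$kne_local(s))
    pos[, paste0(pre, "TIB"), ] <<- place_point(ch$tibia$origin, ch$tibia$theta,
                                                geom$tib_local(s))
    pos[, paste0(pre, "ANK"), ] <<- place_point(ch$tibia$origin, ch$tibia$theta,
                                                geom$ank_local(s))
    pos[, paste0(pre, "HEE"), ] <<- place_point(ch$foot$origin, ch$foot$theta,
                                                geom$heel_local)
    pos[, paste0(pre, "TOE"), ] <<- place_point(ch$foot$origin, ch$foot$theta,
                                                geom$toe_local)
  }
  put_leg(L, "L"); put_leg(R, "R")

  segments <- list(pelvis = pelvis,
                   femur_l = L$femur, tibia_l = L$tibia, foot_l = L$foot,
                   femur_r = R$femur, tibia_r = R$tibia, foot_r = R$foot)
  list(markers = marker_set(pos, angles$fs),
       segments = segments,
       joint_centers = list(hjc_l = L$hjc, kjc_l = L$kjc, ajc_l = L$ajc,
                            hjc_r = R$hjc, kjc_r = R$kjc, ajc_r = R$ajc),
       fs = angles$fs, events = angles$events)
}

# rotation matrix stack (3x3xN) for a sagittal pitch series
pitch_rotation <- function(theta) {
  n <- length(theta)
  R <- array(0, dim = c(3, 3, n))
  ct <- cos(theta); st <- sin(theta)
  R[1, 1, ] <- ct; R[1, 3, ] <- -st
  R[2, 2, ] <- 1
  R[3, 1, ] <- st; R[3, 3, ] <- ct
  R
}

#' Derive IMU signals analytically from segment kinematics
#'
#' The gyroscope channel is the segment angular velocity expressed in the
#' sensor frame (deg/s); the accelerometer channel is the specific force at
#' the sensor point — the second derivative of its position minus gravity —
#' expressed in the sensor frame (m/s^2, strapdown convention: a motionless
#' sensor reads +g along its upward axis). Gaussian noise and constant
#' gyroscope biases are added per the noise model.
#'
#' @param segments Named list of segment kinematics (`origin` n x 3 mm,
#'   `theta` rad, `omega` rad/s about the medio-lateral axis; alternatively a
#'   full rotation stack `R` (3 x 3 x n), which must be orthonormal).
#' @param placement Sensor placement map, see [default_sensor_placement()].
#' @param noise A `noise_model`.
#' @param fs Sampling frequency, Hz.
#' @return An `imu_recording`.
#' @export
derive_imu_signals <- function(segments, placement, noise = noise_model("none"),
                               fs = 100) {
  n <- nrow(segments[[1]]$origin)
  accel <- array(NA_real_, dim = c(n, N_SENSORS, 3),
                 dimnames = list(NULL, SENSOR_SITES, AXIS_LABELS))
  gyro <- array(NA_real_, dim = c(n, N_SENSORS, 3),
                dimnames = list(NULL, SENSOR_SITES, AXIS_LABELS))
  g_world <- c(0, 0, -GRAVITY)
  for (si in seq_along(SENSOR_SITES)) {
    site <- SENSOR_SITES[si]
    pl <- placement[[site]]
    if (is.null(pl)) stop("derive_imu_signals: no placement for sensor ", site)
    seg <- segments[[pl$segment]]
    if (is.null(seg)) stop("derive_imu_signals: unknown segment ", pl$segment)
    if (!is.null(seg$R)) {
      ortho_err <- max(vapply(seq_len(dim(seg$R)[3]), function(i) {
        max(abs(crossprod(seg$R[, , i]) - diag(3)))
      }, numeric(1)))
      if (ortho_err > 1e-6 ||
          abs(det(seg$R[, , 1]) - 1) > 1e-6) {
        stop("derive_imu_signals: segment rotations are not proper rotations")
      }
      # general path: sensor position via full rotations
      p <- t(vapply(seq_len(n), function(i) seg$R[, , i] %*% pl$local,
                    numeric(3))) + seg$origin
      # angular velocity from finite differences of R: [w]x = Rdot R^T
      omega_w <- matrix(0, n, 3)
      for (i in 2:(n - 1)) {
        Rdot <- (seg$R[, , i + 1] - seg$R[, , i - 1]) * fs / 2
        S <- Rdot %*% t(seg$R[, , i])
        omega_w[i, ] <- c(S[3, 2], S[1, 3], S[2, 1])
      }
      omega_w[1, ] <- omega_w[2, ]; omega_w[n, ] <- omega_w[n - 1, ]
      acc_w <- second_derivative(p, fs)
      for (i in seq_len(n)) {
        Rt <- t(seg$R[, , i])
        gyro[i, si, ] <- (Rt %*% omega_w[i, ]) * 180 / pi
        accel[i, si, ] <- Rt %*% ((acc_w[i, ] / 1000) - g_world)
      }
    } else {
      theta <- seg$theta
      ct <- cos(theta); st <- sin(theta)
      p <- cbind(seg$origin[, 1] + pl$local[1] * ct - pl$local[3] * st,
                 seg$origin[, 2] + pl$local[2],
                 seg$origin[, 3] + pl$local[1] * st + pl$local[3] * ct)
      acc_w <- second_derivative(p, fs) / 1000  # mm/s^2 -> m/s^2
      sp_w <- sweep(acc_w, 2, g_world)          # specific force, world frame
      # world -> segment frame: R^T v
      accel[, si, 1] <- ct * sp_w[, 1] + st * sp_w[, 3]
      accel[, si, 2] <- sp_w[, 2]
      accel[, si, 3] <- -st * sp_w[, 1] + ct * sp_w[, 3]
      # pitching forward (theta increasing) is a negative rotation about the
      # medio-lateral (y, leftward) axis; the y axis is shared by world and
      # segment frames in the sagittal chain
      gyro[, si, 1] <- 0
      gyro[, si, 2] <- -seg$omega * 180 / pi
      gyro[, si, 3] <- 0
    }
  }
  if (noise$accel_sigma > 0 || noise$gyro_sigma > 0 || noise$gyro_bias_sigma > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(noise$seed)
    bias <- array(stats::rnorm(N_SENSORS * 3, 0, noise$gyro_bias_sigma),
                  dim = c(1, N_SENSORS, 3))
    gyro <- gyro + array(stats::rnorm(length(gyro), 0, noise$gyro_sigma),
                         dim = dim(gyro)) +
      bias[rep(1, n), , , drop = FALSE]
    accel <- accel + array(stats::rnorm(length(accel), 0, noise$accel_sigma),
                           dim = dim(accel))
  }
  imu_recording(accel, gyro, fs)
}

second_derivative <- function(p, fs) {
  n <- nrow(p)
  a <- matrix(0, n, 3)
  if (n >= 3) {
    a[2:(n - 1), ] <- (p[3:n, ] - 2 * p[2:(n - 1), ] + p[1:(n - 2), ]) * fs^2
    a[1, ] <- a[2, ]; a[n, ] <- a[n - 1, ]
  }
  a
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Standing calibration pose
#'
#' Forward kinematics of the motionless neutral pose (all joint angles zero,
#' no pelvis sway), used as the synthetic static trial.
#'
#' @param anthro An `anthropometrics` object.
#' @param fs Sampling rate, Hz.
#' @param duration Seconds of static data.
#' @export
static_pose <- function(anthro, fs = 100, duration = 1) {
  profile <- gait_profile(n_cycles = 2, hip_fourier = c(0), knee_fourier = c(0),
                          ankle_fourier = c(0), pelvis_sway_amplitude = 0,
                          align_phase = FALSE)
  n <- max(2L, round(duration * fs))
  angles <- generate_joint_profiles(profile, fs)
  idx <- seq_len(min(n, length(angles$time)))
  angles$time <- angles$time[idx]
  for (side in c("left", "right")) {
    angles[[side]] <- lapply(angles[[side]], function(v) v[idx])
  }
  forward_kinematics(angles, anthro, profile)
}

#' Generate a complete synthetic gait study
#'
#' Draws per-subject anthropometrics (uniform body scale around the template,
#' emulating a cohort of roughly 170 +/- 8 cm stature), cadence (+/-10%),
#' per-joint amplitude variability and pelvis sway, then simulates markers,
#' IMU signals, heel-strike events, the static calibration pose and
#' ground-truth joint angles for each subject. Fully deterministic given
#' `master_seed`.
#'
#' @param n_subjects Number of subjects (>= 3; leave-one-subject-out needs
#'   train, validation and test subjects).
#' @param profile Template `gait_profile`.
#' @param anthro Template `anthropometrics`.
#' @param noise A `noise_model`.
#' @param master_seed Integer master seed.
#' @param fs Sampling rate, Hz (markers and IMU).
#' @return Object of class `gait_dataset`: list of subjects, each carrying
#'   `subject_id`, `anthro`, `markers`, `imu`, `events`, `angles`,
#'   `static_markers`, `profile`.
#' @export
generate_dataset <- function(n_subjects, profile = gait_profile(),
                             anthro = default_anthropometrics(),
                             noise = noise_model("default"),
                             master_seed = 1L, fs = 100) {
  if (n_subjects < 3) stop("generate_dataset: n_subjects must be >= 3")
  subjects <- vector("list", n_subjects)
  base_scale <- anthro$leg_length / 900
  for (i in seq_len(n_subjects)) {
    seed_i <- (as.integer(master_seed) * 131L + i * 7919L) %% 2147483647L
    set.seed(seed_i)
    scale <- min(1.09, max(0.91, stats::rnorm(1, 1, 0.046))) * base_scale
    anthro_i <- default_anthropometrics(scale)
    cad_i <- profile$cadence * stats::runif(1, 0.9, 1.1)
    amp <- stats::rnorm(3, 1, 0.03)
    prof_i <- gait_profile(cadence = cad_i, n_cycles = profile$n_cycles,
                           hip_fourier = profile$hip_fourier * amp[1],
                           knee_fourier = profile$knee_fourier * amp[2],
                           ankle_fourier = profile$ankle_fourier * amp[3],
                           pelvis_sway_amplitude =
                             profile$pelvis_sway_amplitude * stats::runif(1, 0.8, 1.2),
                           phase_offset_left = profile$phase_offset_left,
                           seed = seed_i, align_phase = TRUE)
    angles <- generate_joint_profiles(prof_i, fs)
    fk <- forward_kinematics(angles, anthro_i, prof_i)
    noise_i <- noise
    noise_i$seed <- (seed_i + 500009L) %% 2147483647L
    imu <- derive_imu_signals(fk$segments, default_sensor_placement(anthro_i),
                              noise_i, fs)
    markers <- fk$markers
    if (noise$marker_jitter_sigma > 0) {
      set.seed((seed_i + 900001L) %% 2147483647L)
      markers$positions <- markers$positions +
        array(stats::rnorm(length(markers$positions), 0,
                           noise$marker_jitter_sigma),
              dim = dim(markers$positions))
    }
    static_fk <- static_pose(anthro_i, fs)
    subjects[[i]] <- list(subject_id = sprintf("S%02d", i),
                          seed = seed_i,
                          anthro = anthro_i,
                          profile = prof_i,
                          markers = markers,
                          imu = imu,
                          events = fk$events,
                          angles = angles,
                          static_markers = static_fk$markers,
                          joint_centers = fk$joint_centers)
  }
  names(subjects) <- vapply(subjects, `[[`, character(1), "subject_id")
  structure(list(subjects = subjects, master_seed = as.integer(master_seed),
                 noise = noise, fs = fs),
            class = "gait_dataset")
}
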