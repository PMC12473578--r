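test_that("pelvis frame equals lab axes for markers on a horizontal square", {
  one <- matrix(1, 4, 1)
  pf <- pelvis_frame(lasi = one %*% c(1, 1, 0), rasi = one %*% c(1, -1, 0),
                     lpsi = one %*% c(-1, 1, 0), rpsi = one %*% c(-1, -1, 0))
  expect_equal(pf$ex[1, ], c(1, 0, 0), tolerance = 1e-12)
  expect_equal(pf$ey[1, ], c(0, 1, 0), tolerance = 1e-12)
  expect_equal(pf$ez[1, ], c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pf$origin[1, ], c(1, 0, 0), tolerance = 1e-12)
  # degenerate collinear markers
  expect_error(pelvis_frame(one %*% c(1, 1, 0), one %*% c(1, 1, 0),
                            one %*% c(0, 1, 0), one %*% c(0, 1, 0)),
               "degenerate")
})

test_that("pelvis frame is equivariant under a global rotation", {
  fk <- fix_noiseless()$fk
  pos <- fk$markers$positions[1:20, , ]
  R <- random_rotation(31)
  pf <- pelvis_frame(pos[, 1, ], pos[, 2, ], pos[, 3, ], pos[, 4, ])
  rot <- function(m) m %*% t(R)
  pfr <- pelvis_frame(rot(pos[, 1, ]), rot(pos[, 2, ]), rot(pos[, 3, ]),
                      rot(pos[, 4, ]))
  expect_lt(max(abs(pfr$ex - rot(pf$ex))), 1e-9)
  expect_lt(max(abs(pfr$ez - rot(pf$ez))), 1e-9)
})

test_that("hip joint centers are symmetric, monotone in inter-ASIS distance, and match the simulator pivot", {
  anthro <- default_anthropometrics()
  st <- static_pose(anthro)
  cal <- static_calibration(st$markers, anthro)
  pos <- st$markers$positions
  pf <- pelvis_frame(pos[, 1, ], pos[, 2, ], pos[, 3, ], pos[, 4, ])
  hjc <- hip_joint_center(cal, pf)
  mid_y <- pf$origin[, 2]
  expect_lt(max(abs(abs(hjc$l[, 2] - mid_y) - abs(hjc$r[, 2] - mid_y))), 1e-9)

  wide <- anthro; wide$inter_asis_distance <- anthro$inter_asis_distance * 2
  expect_gt(imumocap:::hip_center_offsets(wide)$y_lat, imumocap:::hip_center_offsets(anthro)$y_lat)

  nl <- fix_noiseless()
  posw <- nl$fk$markers$positions
  pfw <- pelvis_frame(posw[, 1, ], posw[, 2, ], posw[, 3, ], posw[, 4, ])
  hjcw <- hip_joint_center(nl$cal, pfw)
  expect_lt(max(abs(hjcw$l - nl$fk$joint_centers$hjc_l)), 10)
  expect_error(hip_joint_center(list(anthro = NULL), pf), "anthropometrics")
})

test_that("chord joint center satisfies its distance and coplanarity contracts", {
  n <- 1
  prox <- matrix(c(0, 0, 0), n, 3, byrow = TRUE)
  lat <- matrix(c(0, 120, -400), n, 3, byrow = TRUE)
  wand <- matrix(c(0, 180, -200), n, 3, byrow = TRUE)
  jc <- chord_joint_center(prox, lat, wand, 100, 14)
  expect_equal(sqrt(sum((jc - lat)^2)), 57, tolerance = 1e-9)
  # coplanarity: jc in the plane spanned by the three points
  nrm <- c((lat - prox)[2] * (wand - prox)[3] - (lat - prox)[3] * (wand - prox)[2],
           (lat - prox)[3] * (wand - prox)[1] - (lat - prox)[1] * (wand - prox)[3],
           (lat - prox)[1] * (wand - prox)[2] - (lat - prox)[2] * (wand - prox)[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  expect_lt(abs(sum((jc - prox) * nrm)), 1e-9)
  # perpendicularity of chord: (jc - lat) . (prox - jc) = 0
  expect_lt(abs(sum((jc - lat) * (prox - jc))), 1e-6)
  expect_error(chord_joint_center(prox, lat, lat + (prox - lat) * 0.5, 100, 14),
               "collinear")
})

test_that("chord knee and ankle centers match the simulator pivots within 10 mm", {
  nl <- fix_noiseless()
  ang <- compute_joint_angles(nl$fk$markers, nl$cal)
  pos <- nl$fk$markers$positions
  pf <- pelvis_frame(pos[, 1, ], pos[, 2, ], pos[, 3, ], pos[, 4, ])
  hjc <- hip_joint_center(nl$cal, pf)
  a <- nl$anthro
  kjc <- chord_joint_center(hjc$l, pos[, marker_index("LKNE"), ],
                            pos[, marker_index("LTHI"), ],
                            a$knee_width, a$marker_diameter)
  expect_lt(max(sqrt(rowSums((kjc - nl$fk$joint_centers$kjc_l)^2))), 10)
  ajc <- chord_joint_center(kjc, pos[, marker_index("LANK"), ],
                            pos[, marker_index("LTIB"), ],
                            a$ankle_width, a$marker_diameter)
  expect_lt(max(sqrt(rowSums((ajc - nl$fk$joint_centers$ajc_l)^2))), 10)
})

test_that("neutral standing pose yields zero joint angles", {
  nl <- fix_noiseless()
  st <- static_pose(nl$anthro)
  ang <- compute_joint_angles(st$markers, nl$cal)
  for (j in c("hip_l", "hip_r", "knee_l", "knee_r", "ankle_l", "ankle_r")) {
    expect_lt(max(abs(ang[[j]])), 1e-6)
  }
})

test_that("a constructed constant 30-degree hip flexion is recovered exactly", {
  anthro <- default_anthropometrics()
  prof <- gait_profile(n_cycles = 2, hip_fourier = c(30), knee_fourier = c(0),
                       ankle_fourier = c(0), pelvis_sway_amplitude = 0,
                       align_phase = FALSE)
  fk <- forward_kinematics(generate_joint_profiles(prof, 100), anthro, prof)
  cal <- static_calibration(static_pose(anthro)$markers, anthro)
  ang <- compute_joint_angles(fk$markers, cal)
  expect_lt(max(abs(ang$hip_l - 30)), 1e-9)
  expect_lt(max(abs(ang$hip_r - 30)), 1e-9)
  expect_lt(max(abs(ang$knee_l)), 1e-9)
})

test_that("closed loop: noiseless synthetic gait is recovered below 0.5 deg RMSE", {
  nl <- fix_noiseless()
  rec <- compute_joint_angles(nl$fk$markers, nl$cal)
  for (side in c("left", "right")) {
    s <- substr(side, 1, 1)
    for (j in c("hip", "knee", "ankle")) {
      rmse <- sqrt(mean((nl$angles[[side]][[j]] -
                           rec[[paste0(j, "_", s)]])^2))
      expect_lt(rmse, 0.5)
    }
  }
})

test_that("joint angles are invariant to global translation and rotation", {
  nl <- fix_noiseless()
  sub <- nl$fk$markers
  sub$positions <- sub$positions[1:30, , , drop = FALSE]
  sub$gap_mask <- sub$gap_mask[1:30, , drop = FALSE]
  base <- compute_joint_angles(sub, nl$cal)

  shifted <- sub
  shifted$positions <- sweep(sub$positions, 3, c(123, -45, 67), "+")
  tr <- compute_joint_angles(shifted, nl$cal)

  R <- random_rotation(7)
  rot <- rotate_markers(sub, R)
  rr <- compute_joint_angles(rot, nl$cal)
  for (j in c("hip_l", "knee_r", "ankle_l", "ankle_r")) {
    expect_lt(max(abs(base[[j]] - tr[[j]])), 1e-9)
    expect_lt(max(abs(base[[j]] - rr[[j]])), 1e-6)
  }
})

test_that("mirroring across the sagittal plane swaps left and right angles", {
  nl <- fix_noiseless()
  sub <- nl$fk$markers
  sub$positions <- sub$positions[1:30, , , drop = FALSE]
  sub$gap_mask <- sub$gap_mask[1:30, , drop = FALSE]
  base <- compute_joint_angles(sub, nl$cal)
  mir <- sub
  mir$positions[, , 2] <- -mir$positions[, , 2]
  swap <- marker_index(ifelse(startsWith(MARKER_LABELS, "L"),
                              sub("^L", "R", MARKER_LABELS),
                              sub("^R", "L", MARKER_LABELS)))
  mir$positions <- mir$positions[, swap, ]
  dimnames(mir$positions)[[2]] <- MARKER_LABELS
  mm <- compute_joint_angles(mir, nl$cal)
  for (j in c("hip", "knee", "ankle")) {
    expect_lt(max(abs(base[[paste0(j, "_l")]] - mm[[paste0(j, "_r")]])), 1e-9)
    expect_lt(max(abs(base[[paste0(j, "_r")]] - mm[[paste0(j, "_l")]])), 1e-9)
  }
})

test_that("angles from transformed true markers reproduce the raw-marker angles", {
  cs <- fix_cycles()
  c1 <- cs$cycles[[1]]
  cal <- cs$statics[[c1$subject_id]]
  via_targets <- angles_from_predictions(c1$targets, c1$factor, cal)
  raw <- inverse_transform(c1$targets, c1$factor)
  via_raw <- compute_joint_angles(raw, cal)
  for (j in c("hip_l", "knee_l", "ankle_r")) {
    expect_lt(max(abs(via_targets[[j]] - via_raw[[j]])), 1e-9)
  }
  expect_equal(via_targets$n_frames, 101)
})

test_that("an overfit model's predictions produce accurate joint angles", {
  ov <- fix_overfit()
  cal <- static_calibration(ov$dataset$subjects$S01$static_markers,
                            ov$dataset$subjects$S01$anthro)
  pred <- predict(ov$model, ov$train)
  errs <- c()
  for (i in seq_along(ov$train)) {
    at <- angles_from_predictions(ov$train[[i]]$targets,
                                  ov$train[[i]]$factor, cal)
    ap <- angles_from_predictions(pred[i, , , ], ov$train[[i]]$factor, cal)
    for (j in c("hip_l", "knee_l", "ankle_l")) {
      errs <- c(errs, sqrt(mean((at[[j]] - ap[[j]])^2)))
    }
  }
  expect_lt(max(errs), 2)
})

test_that("segment frames are orthonormal at every frame", {
  nl <- fix_noiseless()
  pos <- nl$fk$markers$positions[1:25, , ]
  jc <- nl$fk$joint_centers
  centers <- list(hjc_l = jc$hjc_l[1:25, ], hjc_r = jc$hjc_r[1:25, ],
                  kjc_l = jc$kjc_l[1:25, ], kjc_r = jc$kjc_r[1:25, ],
                  ajc_l = jc$ajc_l[1:25, ], ajc_r = jc$ajc_r[1:25, ])
  fr <- segment_frames(centers, pos)
  for (side in c("l", "r")) for (seg in c("femur", "tibia", "foot")) {
    f <- fr[[side]][[seg]]
    expect_lt(max(abs(rowSums(f$ex * f$ey))), 1e-9)
    expect_lt(max(abs(rowSums(f$ex * f$ez))), 1e-9)
    expect_lt(max(abs(rowSums(f$ex^2) - 1)), 1e-9)
    expect_lt(max(abs(rowSums(f$ez^2) - 1)), 1e-9)
  }
})
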