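# Shared fixtures, built lazily and memoized for the whole test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fix_dataset <- function() {
  memo("dataset", function() {
    generate_dataset(3, profile = gait_profile(n_cycles = 5),
                     noise = noise_model("low"), master_seed = 11)
  })
}

fix_cycles <- function() {
  memo("cycles", function() prepare_cycles(fix_dataset(), events = "truth"))
}

fix_noiseless <- function() {
  memo("noiseless", function() {
    profile <- gait_profile(n_cycles = 4)
    anthro <- default_anthropometrics()
    angles <- generate_joint_profiles(profile, 100)
    fk <- forward_kinematics(angles, anthro, profile)
    list(profile = profile, anthro = anthro, angles = angles, fk = fk,
         cal = static_calibration(static_pose(anthro)$markers, anthro))
  })
}

# a deliberately overfit model on a 10-cycle subset: the capacity probe and
# the baseline for the sensor-swap robustness check
fix_overfit <- function() {
  memo("overfit", function() {
    ds <- generate_dataset(3, profile = gait_profile(n_cycles = 10),
                           noise = noise_model("none"), master_seed = 11)
    cs <- prepare_cycles(ds, events = "truth")
    subj <- vapply(cs$cycles, `[[`, character(1), "subject_id")
    side <- vapply(cs$cycles, `[[`, character(1), "side")
    train <- cs$cycles[subj == "S01" & side == "left"][1:10]
    val <- cs$cycles[subj == "S02" & side == "left"][1:2]
    cfg <- model_config(encoder_lstm_units = 128,
                        decoder_lstm_units = integer(0),
                        attention_heads = 2, attention_key_dim = 8,
                        conv_filters = 128, epochs = 200, batch_size = 1,
                        lr_decay = 0.1, seed = 5)
    model <- build_model(cfg)
    model <- train_model(model, train, val,
                         early_stop_config(min_epochs = 200, patience = 200,
                                           restore_best = FALSE),
                         loss_weights())
    list(model = model, train = train, cycles = cs, dataset = ds)
  })
}

rot_y_deg <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3,
         byrow = TRUE)
}

rotate_markers <- function(set, R) {
  d <- dim(set$positions)
  m <- matrix(set$positions, d[1] * d[2], 3)
  set$positions <- array(m %*% t(R), d, dimnames = dimnames(set$positions))
  set
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# exhaustive enumeration of all monotone, continuous, boundary-complete
# warping paths: the independent oracle for the DTW implementation
dtw_oracle <- function(ref, query) {
  n <- length(ref); m <- length(query)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + (ref[i] - query[j])^2
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n && j < m) recurse(i + 1, j + 1, acc)
    if (i < n) recurse(i + 1, j, acc)
    if (j < m) recurse(i, j + 1, acc)
  }
  recurse(1, 1, 0)
  best
}

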