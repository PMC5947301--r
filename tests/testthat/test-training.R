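# An R-level reimplementation of the babbling loop, built from the exported
# step/update primitives and consuming R's RNG in the documented per-step
# order (d_alpha, d_beta, availability). The compiled trainer must reproduce
# it on the identical stream.
r_reference_train <- function(config) {
  grids <- list(motor = motor_grid(config$command_range, config$n_motor_per_dim),
                visual = visual_grid(config$distance_range, config$azimuth_range,
                                     config$n_visual_per_dim))
  set.seed(config$seed)
  posture <- runif(2, config$joint_range[1], config$joint_range[2])
  params <- init_params(n_motor = nrow(grids$motor$preferred),
                        n_visual = nrow(grids$visual$preferred),
                        n_hidden = config$n_hidden,
                        init_range = config$init_range)
  y_avail <- runif(1) < config$visual_availability
  h <- rep(0.5, config$n_hidden)
  for (t in seq_len(config$n_iterations)) {
    pos0 <- forward_kinematics(posture[1], posture[2], config$segment_length)
    cmd <- sample_babble(1, config$command_range)[1, ]
    avail_next <- runif(1) < config$visual_availability
    posture <- apply_command(posture, cmd, config$joint_range)
    u_code <- encode(cmd, grids$motor)
    y_code <- if (y_avail) encode(c(pos0$r, pos0$theta), grids$visual) else NULL
    fs <- forward_step(params, u_code, y_code, h)
    if (avail_next) {
      pos1 <- forward_kinematics(posture[1], posture[2], config$segment_length)
      teach <- encode(c(pos1$r, pos1$theta), grids$visual)
      params <- update_forward(params, u_code, y_code, h, teach, config$eta)
      # the inverse input state is the pre-step hidden (the Elman context)
      params <- update_inverse(params, teach, h, u_code, config$eta)
    }
    h <- fs$h
    y_avail <- avail_next
  }
  list(params = params, h = h, posture = posture)
}

test_that("the compiled trainer reproduces the R-primitive loop on one RNG stream", {
  cfg <- train_config(n_iterations = 150, seed = 17, checkpoint_every = 150)
  ref <- r_reference_train(cfg)
  mod <- train(cfg)
  for (nm in names(ref$params)) {
    expect_lt(max(abs(mod$params[[nm]] - ref$params[[nm]])), 1e-8)
  }
  expect_lt(max(abs(mod$h - ref$h)), 1e-8)
})

test_that("training is bit-reproducible from (seed, config)", {
  cfg <- train_config(n_iterations = 1000, seed = 3, checkpoint_every = 500)
  a <- train(cfg)
  b <- train(cfg)
  expect_identical(a$params, b$params)
  expect_identical(a$log, b$log)
  expect_identical(a$h, b$h)
  # a different seed gives a different model
  c_ <- train(train_config(n_iterations = 1000, seed = 4,
                           checkpoint_every = 500))
  expect_gt(max(abs(a$params$W_hy - c_$params$W_hy)), 0)
})

test_that("with no visual availability there is never a teacher, so no update", {
  cfg <- train_config(n_iterations = 500, visual_availability = 0, seed = 8,
                      checkpoint_every = 500)
  mod <- train(cfg)
  set.seed(8)
  runif(2)  # the initial-posture draws
  init <- init_params(n_motor = 100, n_visual = 200, n_hidden = cfg$n_hidden,
                      init_range = cfg$init_range)
  expect_identical(unclass(mod$params), unclass(init)[names(mod$params)])
})

test_that("probe evaluation is deterministic and honest about untrained models", {
  mod <- small_model()
  ev1 <- evaluate_probe(mod)
  ev2 <- evaluate_probe(mod)
  expect_identical(ev1, ev2)
  expect_equal(nrow(ev1$probes), 25)
  expect_error(evaluate_probe(mod, commands = matrix(numeric(0), ncol = 2)),
               "empty probe")

  # zero weights: every prediction decodes to the visual lattice centroid
  zero <- mod
  for (nm in names(zero$params)) zero$params[[nm]][] <- 0
  ev0 <- evaluate_probe(zero)
  centroid <- colMeans(zero$grids$visual$preferred)
  cxy <- polar_to_cartesian(centroid[1], centroid[2])
  expect_true(all(abs(ev0$probes$pred_x - cxy[1]) < 1e-9))
  expect_true(all(abs(ev0$probes$pred_y - cxy[2]) < 1e-9))
})

test_that("episodic resets change the walk but keep the run reproducible", {
  cfg <- train_config(n_iterations = 400, seed = 12, checkpoint_every = 400,
                      episode_reset_every = 100)
  a <- train(cfg)
  b <- train(cfg)
  expect_identical(a$params, b$params)
  cont <- train(train_config(n_iterations = 400, seed = 12,
                             checkpoint_every = 400))
  expect_gt(max(abs(a$params$W_hy - cont$params$W_hy)), 0)
})

test_that("invalid training configurations are rejected by field name", {
  expect_error(train_config(eta = -1), "eta")
  expect_error(train_config(visual_availability = 1.2), "visual_availability")
  expect_error(train_config(n_iterations = 0), "n_iterations")
  expect_error(train_config(joint_range = c(10, 5)), "joint_range")
})
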