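#' Training configuration for the motor-babbling learner
#'
#' Collects every tunable of the learning phase with the standard defaults:
#' online backpropagation at learning rate 0.05, 1,200,000 babbling
#' iterations, visual availability 0.8 (vision of the hand is absent in 20%
#' of iterations), motor commands uniform on `[-20, 20]` degrees per joint,
#' joint range of motion `[0, 180]` degrees, unit segment lengths, 10 x 10
#' motor and 10 x 20 visual populations and 400 hidden units per network.
#'
#' @param eta learning rate.
#' @param n_iterations total babbling steps.
#' @param visual_availability probability that vision of the hand is present
#'   on a step; both teachers need the post-movement observation, so a step
#'   without vision performs no weight update.
#' @param command_range half-width of the babbled command range, degrees.
#' @param joint_range admissible joint interval, degrees.
#' @param segment_length length of each limb segment.
#' @param distance_range,azimuth_range visual definition ranges.
#' @param n_motor_per_dim,n_visual_per_dim population grid sizes.
#' @param n_hidden hidden units per network.
#' @param init_range half-width of the uniform weight initialization.
#' @param seed RNG seed; together with the config it fully determines the
#'   trained model.
#' @param checkpoint_every iterations between training-log checkpoints
#'   (default: ten checkpoints over the run).
#' @param episode_reset_every if not `NULL`, every this many iterations the
#'   posture is re-drawn uniformly and the hidden state cleared to 0.5
#'   (episodic babbling). Default: one continuous random walk, no resets.
#' @return a validated list of class `train_config`.
#' @export
train_config <- function(eta = 0.05,
                         n_iterations = 1200000,
                         visual_availability = 0.8,
                         command_range = 20,
                         joint_range = c(0, 180),
                         segment_length = 1,
                         distance_range = c(0, 3),
                         azimuth_range = c(-90, 90),
                         n_motor_per_dim = c(10, 10),
                         n_visual_per_dim = c(10, 20),
                         n_hidden = 400,
                         init_range = 0.1,
                         seed = 1,
                         checkpoint_every = NULL,
                         episode_reset_every = NULL) {
  cfg <- list(eta = eta, n_iterations = as.integer(n_iterations),
              visual_availability = visual_availability,
              command_range = command_range, joint_range = joint_range,
              segment_length = segment_length,
              distance_range = distance_range, azimuth_range = azimuth_range,
              n_motor_per_dim = n_motor_per_dim,
              n_visual_per_dim = n_visual_per_dim,
              n_hidden = as.integer(n_hidden), init_range = init_range,
              seed = as.integer(seed),
              checkpoint_every = if (is.null(checkpoint_every)) {
                max(1L, as.integer(ceiling(n_iterations / 10)))
              } else as.integer(checkpoint_every),
              episode_reset_every = if (is.null(episode_reset_every)) NULL
                                    else as.integer(episode_reset_every))
  validate_train_config(cfg)
  structure(cfg, class = "train_config")
}

validate_train_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  chk(is.numeric(cfg$eta) && length(cfg$eta) == 1 && cfg$eta > 0,
      "eta", "must be a single positive number")
  chk(!is.na(cfg$n_iterations) && cfg$n_iterations >= 1,
      "n_iterations", "must be >= 1")
  chk(is.numeric(cfg$visual_availability) &&
        cfg$visual_availability >= 0 && cfg$visual_availability <= 1,
      "visual_availability", "must lie in [0, 1]")
  chk(cfg$command_range > 0, "command_range", "must be positive")
  chk(length(cfg$joint_range) == 2 && cfg$joint_range[1] < cfg$joint_range[2],
      "joint_range", "must be an increasing interval")
  chk(cfg$segment_length > 0, "segment_length", "must be positive")
  chk(cfg$n_hidden >= 1, "n_hidden", "must be >= 1")
  chk(cfg$init_range > 0, "init_range", "must be positive")
  chk(is.null(cfg$episode_reset_every) || cfg$episode_reset_every >= 1,
      "episode_reset_every", "must be NULL or >= 1")
  invisible(TRUE)
}

#' Train the forward and inverse networks by motor babbling
#'
#' Runs the learning loop: per iteration, (1) a motor command is drawn
#' uniformly, (2) applied to the arm with clipping at the joint limits,
#' (3) the post-movement hand position is observed with probability
#' `visual_availability`, (4) the forward recurrent network takes the
#' encoded command and the encoded pre-movement position (zeros if it was
#' unobserved) and predicts the next visual population, (5) if the
#' post-movement observation is available, both networks take one backprop
#' step — the forward net toward the encoded observation, the inverse net
#' (fed that observation plus the pre-step hidden state, the Elman context
#' that internally represents the situation before the command) toward the
#' encoded command — otherwise no update, (6) the hidden state carries over.
#'
#' The initial posture is drawn uniformly from the joint range, the initial
#' hidden state is 0.5 everywhere, and all randomness comes from `seed`, so
#' the result is bit-reproducible. At every checkpoint the model is scored
#' on a fixed 25-command probe grid ([probe_commands()]) and the metrics
#' appended to the training log.
#'
#' @param config a [train_config()].
#' @return an object of class `reach_model`: the trained `params`, the
#'   motor/visual `grids`, the final hidden state, the training `log`
#'   (data.frame, one row per checkpoint) and metadata.
#' @export
train <- function(config = train_config()) {
  if (!inherits(config, "train_config")) {
    stop("`config` must be a train_config()", call. = FALSE)
  }
  grids <- list(
    motor = motor_grid(config$command_range, config$n_motor_per_dim),
    visual = visual_grid(config$distance_range, config$azimuth_range,
                         config$n_visual_per_dim)
  )

  set.seed(config$seed)
  posture <- stats::runif(2, config$joint_range[1], config$joint_range[2])
  params <- init_params(n_motor = nrow(grids$motor$preferred),
                        n_visual = nrow(grids$visual$preferred),
                        n_hidden = config$n_hidden,
                        init_range = config$init_range)
  y_avail <- stats::runif(1) < config$visual_availability
  h <- rep(0.5, config$n_hidden)

  model <- new_reach_model(params, grids, h, config)
  probes <- probe_commands(config$command_range)
  log <- checkpoint_row(model, 0L, probes)

  done <- 0L
  while (done < config$n_iterations) {
    n_here <- min(config$checkpoint_every, config$n_iterations - done)
    if (!is.null(config$episode_reset_every)) {
      to_reset <- config$episode_reset_every -
        (done %% config$episode_reset_every)
      n_here <- min(n_here, to_reset)
    }
    res <- cpp_train_chunk(
      unclass(params), h, posture[1], posture[2], y_avail,
      grids$motor$preferred, grids$motor$half_width,
      grids$visual$preferred, grids$visual$half_width,
      as.integer(n_here), config$eta, config$visual_availability,
      config$command_range, config$joint_range[1], config$joint_range[2],
      config$segment_length)
    if (res$bad_iter > 0) {
      stop(sprintf("training diverged (non-finite activations) at iteration %d",
                   done + res$bad_iter), call. = FALSE)
    }
    params <- structure(res$weights, class = "reach_params")
    h <- drop(res$h)
    posture <- c(res$alpha, res$beta)
    y_avail <- res$y_avail
    done <- done + n_here

    if (!is.null(config$episode_reset_every) &&
        done %% config$episode_reset_every == 0L) {
      posture <- stats::runif(2, config$joint_range[1], config$joint_range[2])
      h <- rep(0.5, config$n_hidden)
    }

    if (done %% config$checkpoint_every == 0L || done == config$n_iterations) {
      model <- new_reach_model(params, grids, h, config, iterations = done)
      log <- rbind(log, checkpoint_row(model, done, probes))
    }
  }

  model <- new_reach_model(params, grids, h, config,
                           iterations = config$n_iterations)
  model$log <- log
  model
}

new_reach_model <- function(params, grids, h, config, iterations = 0L) {
  structure(
    list(params = params, grids = grids, h = h, config = config,
         iterations = as.integer(iterations), log = NULL),
    class = "reach_model"
  )
}

#' @export
print.reach_model <- function(x, ...) {
  cat("reach_model: forward + inverse place-coded networks\n")
  cat(sprintf("  layers: %d motor, %d visual, %d hidden per network (no biases)\n",
              nrow(x$grids$motor$preferred), nrow(x$grids$visual$preferred),
              x$config$n_hidden))
  cat(sprintf("  trained: %s / %s babbling iterations (eta %g, availability %g, seed %d)\n",
              format(x$iterations, big.mark = ","),
              format(x$config$n_iterations, big.mark = ","),
              x$config$eta, x$config$visual_availability, x$config$seed))
  if (!is.null(x$log) && nrow(x$log) > 0) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  probe at %s iters: forward error %.3f arm-units, inverse direction cosine %.3f\n",
                format(last$iteration, big.mark = ","),
                last$forward_err, last$inverse_dir_cos))
  }
  invisible(x)
}

#' The standard 25-command probe grid
#'
#' All combinations of shoulder and elbow displacements over
#' `{-20, -10, 0, 10, 20}` degrees — the grid used for the one-step forward
#' and inverse transformation tests and for training-log checkpoints.
#'
#' @param command_range half-width of the command range (the grid spans it
#'   in steps of `range/2`).
#' @return a 25 x 2 matrix with columns `d_alpha`, `d_beta`.
#' @export
probe_commands <- function(command_range = 20) {
  v <- seq(-command_range, command_range, length.out = 5)
  as.matrix(expand.grid(d_alpha = v, d_beta = v, KEEP.OUT.ATTRS = FALSE))
}

#' Score a model on a probe set of (posture, command) pairs
#'
#' For each probe the network state is settled on the pre-movement position,
#' then: the forward prediction for the encoded command is decoded and
#' compared with the true post-movement hand position (Euclidean error in
#' Cartesian arm-units); and the inverse postdiction for the encoded true
#' post-movement position is decoded and compared with the true command
#' (mean absolute per-joint error in degrees, plus the direction cosine
#' between the movement the decoded command actually produces and the
#' intended movement).
#'
#' @param model a `reach_model`.
#' @param posture initial `(alpha, beta)` the probes start from.
#' @param commands matrix of probe commands, one per row.
#' @param init_iterations settling iterations before probing.
#' @return a list with the per-probe data.frame (`probes`) and summary
#'   means/quantiles (`forward_err`, `forward_err_q`, `inverse_cmd_err`,
#'   `inverse_dir_cos`).
#' @export
evaluate_probe <- function(model, posture = c(30, 60),
                           commands = probe_commands(), init_iterations = 20) {
  stopifnot(inherits(model, "reach_model"))
  commands <- as.matrix(commands)
  if (nrow(commands) == 0) stop("empty probe set", call. = FALSE)
  L <- model$config$segment_length
  pos0 <- forward_kinematics(posture[1], posture[2], L)
  h0 <- initialize_state(model, c(pos0$r, pos0$theta),
                         n = init_iterations)
  y0_code <- encode(c(pos0$r, pos0$theta), model$grids$visual)

  out <- lapply(seq_len(nrow(commands)), function(i) {
    cmd <- commands[i, ]
    p1 <- apply_command(posture, cmd, model$config$joint_range)
    act <- forward_kinematics(p1[1], p1[2], L)
    fs <- forward_step(model$params, encode(cmd, model$grids$motor),
                       y0_code, h0)
    pred <- decode(fs$y_pred, model$grids$visual)
    pred_xy <- polar_to_cartesian(pred[1], pred[2])
    inv <- inverse_step(model$params,
                        encode(c(act$r, act$theta), model$grids$visual), h0)
    cmd_hat <- decode(inv$u_post, model$grids$motor)
    p1_hat <- apply_command(posture, cmd_hat, model$config$joint_range)
    got <- forward_kinematics(p1_hat[1], p1_hat[2], L)
    want_v <- c(act$x - pos0$x, act$y - pos0$y)
    got_v <- c(got$x - pos0$x, got$y - pos0$y)
    denom <- sqrt(sum(want_v^2)) * sqrt(sum(got_v^2))
    data.frame(
      d_alpha = cmd[1], d_beta = cmd[2],
      actual_x = act$x, actual_y = act$y,
      pred_x = pred_xy[1], pred_y = pred_xy[2],
      forward_err = sqrt((pred_xy[1] - act$x)^2 + (pred_xy[2] - act$y)^2),
      cmd_hat_alpha = unname(cmd_hat[1]), cmd_hat_beta = unname(cmd_hat[2]),
      inverse_cmd_err = mean(abs(cmd_hat - cmd)),
      dir_cos = if (denom > 0) sum(want_v * got_v) / denom else NA_real_
    )
  })
  probes <- do.call(rbind, out)
  list(
    probes = probes,
    forward_err = mean(probes$forward_err),
    forward_err_q = stats::quantile(probes$forward_err, c(0.25, 0.5, 0.75)),
    inverse_cmd_err = mean(probes$inverse_cmd_err),
    inverse_dir_cos = mean(probes$dir_cos, na.rm = TRUE)
  )
}

checkpoint_row <- function(model, iteration, probes) {
  ev <- evaluate_probe(model, commands = probes)
  data.frame(
    iteration = iteration,
    forward_err = ev$forward_err,
    inverse_cmd_err = ev$inverse_cmd_err,
    inverse_dir_cos = ev$inverse_dir_cos,
    w_forward_norm = sqrt(sum(model$params$W_mu^2) + sum(model$params$W_vy^2) +
                          sum(model$params$W_hh^2) + sum(model$params$W_hy^2)),
    w_inverse_norm = sqrt(sum(model$params$V_y^2) + sum(model$params$V_h^2) +
                          sum(model$params$V_u^2))
  )
}
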