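#' Settle the forward hidden state on a visual position
#'
#' Before any test or reach, the recurrent forward network is iterated with
#' the visual input fixed to the given hand position and the motor input
#' fixed to the zero command, so that its hidden layer comes to internally
#' represent that position. No learning takes place.
#'
#' @param model a `reach_model`.
#' @param position `(r, theta)` of the hand, arm-units and degrees.
#' @param n settling iterations (default 20).
#' @return the settled forward hidden state vector.
#' @export
initialize_state <- function(model, position, n = 20) {
  stopifnot(inherits(model, "reach_model"), n >= 1)
  u0 <- encode(c(0, 0), model$grids$motor)
  y0 <- encode(position, model$grids$visual)
  h <- rep(0.5, model$config$n_hidden)
  for (i in seq_len(n)) {
    h <- forward_step(model$params, u0, y0, h)$h
  }
  h
}

#' One-step forward transformation test
#'
#' From a settled initial posture, each probe command is fed (with vision
#' still fixed to the initial hand position) through one forward step; the
#' decoded prediction is paired with the true post-movement hand position
#' computed by the arm kinematics. With the standard grid this reproduces
#' the 25-command prediction table.
#'
#' @param model a `reach_model`.
#' @param initial `(alpha, beta)` initial posture in degrees.
#' @param commands matrix of commands, one per row.
#' @param init_iterations settling iterations.
#' @return data.frame with one row per command: the command, the actual
#'   post-movement position (`actual_*`) and the decoded predicted position
#'   (`pred_*`), in both polar and Cartesian coordinates, plus `err` (the
#'   Cartesian prediction error).
#' @export
test_forward <- function(model, initial = c(30, 60),
                         commands = probe_commands(), init_iterations = 20) {
  stopifnot(inherits(model, "reach_model"))
  commands <- as.matrix(commands)
  L <- model$config$segment_length
  pos0 <- forward_kinematics(initial[1], initial[2], L)
  h0 <- initialize_state(model, c(pos0$r, pos0$theta), n = init_iterations)
  y0_code <- encode(c(pos0$r, pos0$theta), model$grids$visual)
  rows <- lapply(seq_len(nrow(commands)), function(i) {
    cmd <- commands[i, ]
    p1 <- apply_command(initial, cmd, model$config$joint_range)
    act <- forward_kinematics(p1[1], p1[2], L)
    fs <- forward_step(model$params, encode(cmd, model$grids$motor),
                       y0_code, h0)
    pred <- decode(fs$y_pred, model$grids$visual)
    pxy <- polar_to_cartesian(pred[1], pred[2])
    data.frame(d_alpha = unname(cmd[1]), d_beta = unname(cmd[2]),
               actual_r = act$r, actual_theta = act$theta,
               actual_x = act$x, actual_y = act$y,
               pred_r = unname(pred[1]), pred_theta = unname(pred[2]),
               pred_x = pxy[1], pred_y = pxy[2],
               err = sqrt((pxy[1] - act$x)^2 + (pxy[2] - act$y)^2))
  })
  do.call(rbind, rows)
}

#' One-step inverse transformation test
#'
#' The network state is settled on the initial hand position; then each
#' target position — a visual input that is *not* the hand — is encoded and
#' fed through one inverse step, and the output motor population is decoded.
#' The network, never having seen targets, interprets the input as a hand
#' position after a movement and postdicts the command that would achieve
#' it. By default the targets are the 25 positions reached by the standard
#' command grid, reproducing the one-step command table.
#'
#' @param model a `reach_model`.
#' @param initial `(alpha, beta)` initial posture.
#' @param targets data.frame/matrix with columns `(r, theta)`, or `NULL` for
#'   the positions reached from `initial` by [probe_commands()].
#' @param init_iterations settling iterations.
#' @return data.frame with per-target decoded commands (`d_alpha_hat`,
#'   `d_beta_hat`), the hand position the decoded command actually produces,
#'   and the resulting change in distance to the target (`dist_gain` < 0
#'   means the hand moved closer).
#' @export
test_inverse <- function(model, initial = c(30, 60), targets = NULL,
                         init_iterations = 20) {
  stopifnot(inherits(model, "reach_model"))
  L <- model$config$segment_length
  if (is.null(targets)) {
    cmds <- probe_commands(model$config$command_range)
    targets <- do.call(rbind, lapply(seq_len(nrow(cmds)), function(i) {
      p1 <- apply_command(initial, cmds[i, ], model$config$joint_range)
      forward_kinematics(p1[1], p1[2], L)[, c("r", "theta")]
    }))
  }
  targets <- as.data.frame(targets)
  pos0 <- forward_kinematics(initial[1], initial[2], L)
  h0 <- initialize_state(model, c(pos0$r, pos0$theta), n = init_iterations)
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    tg <- c(targets$r[i], targets$theta[i])
    txy <- polar_to_cartesian(tg[1], tg[2])
    inv <- inverse_step(model$params, encode(tg, model$grids$visual), h0)
    cmd_hat <- decode(inv$u_post, model$grids$motor)
    p1 <- apply_command(initial, cmd_hat, model$config$joint_range)
    got <- forward_kinematics(p1[1], p1[2], L)
    d0 <- sqrt((txy[1] - pos0$x)^2 + (txy[2] - pos0$y)^2)
    d1 <- sqrt((txy[1] - got$x)^2 + (txy[2] - got$y)^2)
    data.frame(target_r = tg[1], target_theta = tg[2],
               target_x = txy[1], target_y = txy[2],
               d_alpha_hat = unname(cmd_hat[1]), d_beta_hat = unname(cmd_hat[2]),
               moved_x = got$x, moved_y = got$y,
               dist_gain = d1 - d0)
  })
  do.call(rbind, rows)
}

#' Reaching by the forward-inverse loop, without hand vision
#'
#' Simulates reaching toward a visually presented target, "in the dark" with
#' respect to the hand: after settling on the initial hand position, each
#' loop iteration (1) feeds the encoded target and the current forward
#' hidden state through the inverse network, (2) decodes the output motor
#' population and applies it to the physical arm (with joint clipping), and
#' (3) feeds that same motor population — not a re-encoding of the decoded
#' command — back into the forward network with the visual input zeroed, so
#' the hidden state tracks the predicted, never the seen, hand position.
#' The actual hand position is never encoded during the loop.
#'
#' @param model a `reach_model`.
#' @param target `(r, theta)` of the target; distances beyond 2 segment
#'   lengths are out of reach and were never experienced during babbling.
#' @param initial `(alpha, beta)` initial posture (default `(20, 40)`).
#' @param n_loop loop iterations: 4 is standard for within-reach targets
#'   (distance 2), 7 for out-of-reach targets (distance 3).
#' @param init_iterations settling iterations (default 20).
#' @param reencode_command if `TRUE`, feed the forward network
#'   `encode(decode(u*))` instead of the raw inverse output population
#'   (sensitivity analysis of the double quantization; default `FALSE`).
#' @return a data.frame trajectory, class `reach_trajectory`: row `step = 0`
#'   is the initial state, each later row records the applied decoded
#'   command (`d_alpha`, `d_beta`), the resulting posture and actual hand
#'   position, the model's decoded prediction of the hand position
#'   (`pred_r`, `pred_theta`), and the distance to target (`dist_to_target`).
#' @export
reach <- function(model, target, initial = c(20, 40), n_loop = 4,
                  init_iterations = 20, reencode_command = FALSE) {
  stopifnot(inherits(model, "reach_model"), n_loop >= 0)
  L <- model$config$segment_length
  txy <- polar_to_cartesian(target[1], target[2])
  tgt_code <- encode(target, model$grids$visual)
  posture <- c(initial[1], initial[2])
  pos <- forward_kinematics(posture[1], posture[2], L)
  h <- initialize_state(model, c(pos$r, pos$theta), n = init_iterations)

  row <- function(step, pos, cmd, pred) {
    data.frame(step = step, alpha = posture[1], beta = posture[2],
               x = pos$x, y = pos$y, r = pos$r, theta = pos$theta,
               target_x = txy[1], target_y = txy[2],
               d_alpha = unname(cmd[1]), d_beta = unname(cmd[2]),
               pred_r = unname(pred[1]), pred_theta = unname(pred[2]),
               dist_to_target = sqrt((txy[1] - pos$x)^2 + (txy[2] - pos$y)^2))
  }
  traj <- row(0L, pos, c(NA_real_, NA_real_), c(NA_real_, NA_real_))

  for (k in seq_len(n_loop)) {
    inv <- inverse_step(model$params, tgt_code, h)
    cmd <- decode(inv$u_post, model$grids$motor)
    posture <- apply_command(posture, cmd, model$config$joint_range)
    pos <- forward_kinematics(posture[1], posture[2], L)
    u_pop <- if (reencode_command) encode(cmd, model$grids$motor) else inv$u_post
    fs <- forward_step(model$params, u_pop, y_code = NULL, h)
    h <- fs$h
    pred <- decode(fs$y_pred, model$grids$visual)
    traj <- rbind(traj, row(k, pos, cmd, pred))
  }
  class(traj) <- c("reach_trajectory", "data.frame")
  traj
}

#' Standard target sets for the reaching simulations
#'
#' Seven targets at a common distance, with azimuths evenly spaced over the
#' visual azimuth range: `{-90, -60, -30, 0, 30, 60, 90}` degrees. Positive
#' azimuths are ipsilateral (the side of the modeled right arm), negative
#' contralateral.
#'
#' @param distance target distance in arm-segment units (2 = edge of reach,
#'   3 = out of reach).
#' @param azimuths target azimuths in degrees.
#' @return data.frame with columns `r`, `theta`.
#' @export
reach_targets <- function(distance = 2, azimuths = seq(-90, 90, by = 30)) {
  data.frame(r = distance, theta = azimuths)
}
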