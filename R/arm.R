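#' Forward kinematics of the planar two-joint arm
#'
#' Maps joint angles to the hand position seen from the body center. The
#' shoulder sits at the origin (body width is neglected), `alpha` is the
#' shoulder angle measured counterclockwise from the rightward (+x) axis and
#' `beta` is the interior elbow angle, with 180 degrees meaning a fully
#' extended arm. Under this convention the forearm points along
#' `alpha + 180 - beta`, so `(alpha, beta) = (30, 60)` places the hand at
#' Cartesian `(0, 1)`, i.e. one segment length straight ahead.
#'
#' The returned azimuth `theta` is measured from the straight-ahead (+y) body
#' axis, signed positive toward the arm's (+x, ipsilateral) side, using a
#' full-plane arctangent so positions behind the body yield `|theta| > 90`.
#'
#' @param alpha shoulder angle in degrees, in `[0, 180]`; vectorized.
#' @param beta interior elbow angle in degrees, in `[0, 180]`; vectorized.
#' @param segment_length length of each of the two limb segments (the upper
#'   and lower arm are equally long); all distances are reported in these
#'   units.
#' @return a data.frame with one row per configuration and columns `x`, `y`
#'   (Cartesian hand position), `r` (distance from the body center) and
#'   `theta` (azimuth in degrees).
#' @examples
#' forward_kinematics(30, 60)   # hand at (0, 1): distance 1, straight ahead
#' forward_kinematics(90, 180)  # fully extended: distance 2
#' @export
forward_kinematics <- function(alpha, beta, segment_length = 1) {
  check_posture(alpha, beta)
  if (!is.numeric(segment_length) || length(segment_length) != 1L ||
      !is.finite(segment_length) || segment_length <= 0) {
    stop("`segment_length` must be a single positive number", call. = FALSE)
  }
  a <- alpha * pi / 180
  f <- (alpha + 180 - beta) * pi / 180
  x <- segment_length * (cos(a) + cos(f))
  y <- segment_length * (sin(a) + sin(f))
  r <- sqrt(x^2 + y^2)
  theta <- atan2(x, y) * 180 / pi
  data.frame(x = x, y = y, r = r, theta = theta)
}

#' Apply a motor command to a posture, clipping at the joint limits
#'
#' A motor command is a relative joint displacement `(d_alpha, d_beta)`.
#' Each joint is updated independently and stops at the edge of its range of
#' motion, so commands that would push a joint out of `[0, 180]` are absorbed
#' by the limit rather than raising an error.
#'
#' @param posture numeric of length 2, the current `(alpha, beta)` in degrees.
#' @param command numeric of length 2, the displacement `(d_alpha, d_beta)`
#'   in degrees.
#' @param joint_range numeric of length 2, the admissible joint interval.
#' @return numeric of length 2: the new `(alpha, beta)`.
#' @examples
#' apply_command(c(30, 60), c(10, -20))  # (40, 40)
#' apply_command(c(175, 10), c(20, -20)) # clips to (180, 0)
#' @export
apply_command <- function(posture, command, joint_range = c(0, 180)) {
  check_posture(posture[1], posture[2], joint_range)
  stopifnot(is.numeric(command), length(command) == 2L, all(is.finite(command)))
  unname(pmin(pmax(posture + command, joint_range[1]), joint_range[2]))
}

#' Draw random babbling motor commands
#'
#' During motor babbling each joint displacement is drawn independently and
#' uniformly from `[-range, range]` degrees. Uses R's global random number
#' stream, so `set.seed()` makes the babble reproducible. Draws are laid out
#' so that `sample_babble(n)` yields the same sequence of commands as `n`
#' successive calls to `sample_babble(1)`.
#'
#' @param n number of commands to draw.
#' @param range half-width of the command range in degrees per joint.
#' @return an `n` x 2 matrix with columns `d_alpha`, `d_beta`.
#' @export
sample_babble <- function(n = 1, range = 20) {
  stopifnot(n >= 1, range > 0)
  m <- matrix(stats::runif(2 * n, -range, range), ncol = 2, byrow = TRUE)
  colnames(m) <- c("d_alpha", "d_beta")
  m
}

# shared posture validation; joints outside their range of motion are a
# configuration error everywhere except apply_command's clipped output
check_posture <- function(alpha, beta, joint_range = c(0, 180)) {
  if (!is.numeric(alpha) || !is.numeric(beta) || length(alpha) != length(beta) ||
      !all(is.finite(alpha)) || !all(is.finite(beta))) {
    stop("joint angles must be finite numerics of equal length", call. = FALSE)
  }
  if (any(alpha < joint_range[1] - 1e-9) || any(alpha > joint_range[2] + 1e-9) ||
      any(beta < joint_range[1] - 1e-9) || any(beta > joint_range[2] + 1e-9)) {
    stop(sprintf("joint angles must lie in [%g, %g] degrees",
                 joint_range[1], joint_range[2]), call. = FALSE)
  }
  invisible(TRUE)
}

# polar (r, theta in degrees from +y) -> Cartesian (x, y)
polar_to_cartesian <- function(r, theta) {
  t <- theta * pi / 180
  cbind(x = r * sin(t), y = r * cos(t))
}
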