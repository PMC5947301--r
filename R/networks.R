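#' Logistic activation
#'
#' Componentwise `1 / (1 + exp(-x))`, the squashing nonlinearity of every
#' unit in both networks. Thin wrapper over [stats::plogis()].
#'
#' @param x numeric vector.
#' @return numeric vector in `(0, 1)`.
#' @export
logistic <- function(x) stats::plogis(x)

#' Initialize the connection weights of both networks
#'
#' Allocates every weight matrix of the forward recurrent network
#' (motor-input, visual-input and recurrent connections into the forward
#' hidden layer, and hidden-to-visual-output) and of the inverse network
#' (visual-input and forward-hidden connections into the inverse hidden
#' layer, and hidden-to-motor-output). There are no bias parameters anywhere.
#' Entries are drawn i.i.d. uniform on `[-init_range, init_range]` from R's
#' global random stream, in a fixed matrix order (`W_mu`, `W_vy`, `W_hh`,
#' `W_hy`, `V_y`, `V_h`, `V_u`) so a seed pins the whole initialization.
#'
#' @param n_motor motor-population size (default 100 = 10 x 10 grid).
#' @param n_visual visual-population size (default 200 = 10 x 20 grid).
#' @param n_hidden hidden-layer size of each network (default 400).
#' @param init_range half-width of the uniform initialization interval.
#' @return a list of 7 weight matrices, class `reach_params`.
#' @export
init_params <- function(n_motor = 100, n_visual = 200, n_hidden = 400,
                        init_range = 0.1) {
  stopifnot(n_motor >= 1, n_visual >= 1, n_hidden >= 1, init_range > 0)
  rmat <- function(nr, nc) {
    matrix(stats::runif(nr * nc, -init_range, init_range), nr, nc)
  }
  structure(
    list(
      W_mu = rmat(n_hidden, n_motor),   # motor input -> forward hidden
      W_vy = rmat(n_hidden, n_visual),  # visual input -> forward hidden
      W_hh = rmat(n_hidden, n_hidden),  # forward hidden recurrence
      W_hy = rmat(n_visual, n_hidden),  # forward hidden -> predicted vision
      V_y  = rmat(n_hidden, n_visual),  # visual input -> inverse hidden
      V_h  = rmat(n_hidden, n_hidden),  # forward hidden -> inverse hidden
      V_u  = rmat(n_motor, n_hidden)    # inverse hidden -> motor output
    ),
    class = "reach_params"
  )
}

#' One step of the forward (motor-to-vision) recurrent network
#'
#' The forward hidden layer pools the population-coded motor command, the
#' population-coded visual hand position (zeros when vision is unavailable —
#' the recurrent connection then carries the position estimate), and its own
#' previous activation, Elman-style. The output layer is the predicted
#' visual population for the hand position after the movement.
#'
#' @param params a `reach_params` list.
#' @param u_code motor population activation (length `ncol(W_mu)`).
#' @param y_code visual population activation, or `NULL` for absent vision.
#' @param h previous forward hidden state (length `nrow(W_hh)`); use
#'   `rep(0.5, n_hidden)` for a fresh network (the logistic of zero input).
#' @return list with `h` (new hidden state) and `y_pred` (predicted visual
#'   population), both in `(0, 1)`.
#' @export
forward_step <- function(params, u_code, y_code = NULL, h) {
  check_params_shape(params, u_code, y_code, h)
  net <- params$W_mu %*% u_code + params$W_hh %*% h
  if (!is.null(y_code)) net <- net + params$W_vy %*% y_code
  h_new <- drop(logistic(net))
  y_pred <- drop(logistic(params$W_hy %*% h_new))
  list(h = h_new, y_pred = y_pred)
}

#' One step of the inverse (vision-to-motor) network
#'
#' Given the visual population of a hand position after a movement and the
#' forward hidden state (which internally represents the situation before
#' the movement), outputs the "postdicted" motor population: the command
#' that would have produced that movement. Feeding a position that is *not*
#' the hand's — a target — makes this the command generator for reaching.
#'
#' @param params a `reach_params` list.
#' @param y_code visual population of the (post-movement or target) position.
#' @param h_f forward hidden state for the pre-movement situation.
#' @return list with `h_inv` (inverse hidden state) and `u_post` (motor
#'   output population).
#' @export
inverse_step <- function(params, y_code, h_f) {
  check_params_shape(params, u_code = NULL, y_code = y_code, h = h_f)
  h_inv <- drop(logistic(params$V_y %*% y_code + params$V_h %*% h_f))
  u_post <- drop(logistic(params$V_u %*% h_inv))
  list(h_inv = h_inv, u_post = u_post)
}

#' One online backpropagation update of the forward network
#'
#' A single gradient step on the squared error `0.5 * sum((y_pred - teacher)^2)`
#' between the predicted and the actual (encoded) post-movement visual
#' population, through the logistic derivatives. The recurrent context `h` is
#' treated as a frozen input — no unrolling through time — and the inverse
#' network's weights are untouched.
#'
#' @inheritParams forward_step
#' @param teacher encoded actual post-movement visual population.
#' @param eta learning rate (> 0).
#' @return the updated `reach_params`.
#' @export
update_forward <- function(params, u_code, y_code = NULL, h, teacher,
                           eta = 0.05) {
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0) {
    stop("`eta` must be a single positive number", call. = FALSE)
  }
  stopifnot(length(teacher) == nrow(params$W_hy))
  fs <- forward_step(params, u_code, y_code, h)
  d_out <- (fs$y_pred - teacher) * fs$y_pred * (1 - fs$y_pred)
  d_hid <- drop(crossprod(params$W_hy, d_out)) * fs$h * (1 - fs$h)
  params$W_hy <- params$W_hy - eta * tcrossprod(d_out, fs$h)
  params$W_mu <- params$W_mu - eta * tcrossprod(d_hid, u_code)
  if (!is.null(y_code)) {
    params$W_vy <- params$W_vy - eta * tcrossprod(d_hid, y_code)
  }
  params$W_hh <- params$W_hh - eta * tcrossprod(d_hid, h)
  params
}

#' One online backpropagation update of the inverse network
#'
#' A single gradient step on the squared error between the postdicted motor
#' population and the encoded command that was actually issued. Gradients
#' stop at the forward-hidden boundary: the connection from the forward
#' hidden layer is trained (`V_h`), but nothing propagates back into the
#' forward network's own weights, which stay bit-identical.
#'
#' @inheritParams inverse_step
#' @param teacher encoded actually-issued motor population.
#' @param eta learning rate (> 0).
#' @return the updated `reach_params`.
#' @export
update_inverse <- function(params, y_code, h_f, teacher, eta = 0.05) {
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0) {
    stop("`eta` must be a single positive number", call. = FALSE)
  }
  stopifnot(length(teacher) == nrow(params$V_u))
  is_ <- inverse_step(params, y_code, h_f)
  d_out <- (is_$u_post - teacher) * is_$u_post * (1 - is_$u_post)
  d_hid <- drop(crossprod(params$V_u, d_out)) * is_$h_inv * (1 - is_$h_inv)
  params$V_u <- params$V_u - eta * tcrossprod(d_out, is_$h_inv)
  params$V_y <- params$V_y - eta * tcrossprod(d_hid, y_code)
  params$V_h <- params$V_h - eta * tcrossprod(d_hid, h_f)
  params
}

check_params_shape <- function(params, u_code, y_code, h) {
  if (!is.list(params) || !all(c("W_mu", "W_vy", "W_hh", "W_hy",
                                 "V_y", "V_h", "V_u") %in% names(params))) {
    stop("`params` must hold the 7 weight matrices (see init_params)",
         call. = FALSE)
  }
  if (!is.null(u_code) && length(u_code) != ncol(params$W_mu)) {
    stop("motor population length does not match the model's motor layer",
         call. = FALSE)
  }
  if (!is.null(y_code) && length(y_code) != ncol(params$W_vy)) {
    stop("visual population length does not match the model's visual layer",
         call. = FALSE)
  }
  if (length(h) != ncol(params$W_hh)) {
    stop("hidden state length does not match the model's hidden layer",
         call. = FALSE)
  }
  invisible(TRUE)
}
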