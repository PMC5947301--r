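test_that("logistic squashing and the zero-weight fixed point behave as stated", {
  expect_equal(logistic(0), 0.5)
  expect_equal(logistic(c(-3, 0.7)) + logistic(c(3, -0.7)), c(1, 1))
  expect_true(logistic(30) < 1 && logistic(-30) > 0)
  expect_equal(logistic(30), 1, tolerance = 1e-10)  # asymptote

  zero <- toy_params()
  for (nm in names(zero)) zero[[nm]][] <- 0
  fs <- forward_step(zero, u_code = runif(3), y_code = runif(2), h = runif(4))
  expect_equal(fs$h, rep(0.5, 4))
  expect_equal(fs$y_pred, rep(0.5, 2))
  is_ <- inverse_step(zero, y_code = runif(2), h_f = runif(4))
  expect_equal(is_$u_post, rep(0.5, 3))
  # 0.5 everywhere decodes to the motor-grid centroid: zero displacement
  g <- motor_grid()
  expect_equal(unname(decode(rep(0.5, 100), g)), c(0, 0))
})

test_that("one step of either network matches a matrix-free reimplementation", {
  params <- toy_params()
  inp <- toy_inputs()
  fs <- forward_step(params, inp$u, inp$y, inp$h)
  ref <- naive_forward_step(params, inp$u, inp$y, inp$h)
  expect_equal(fs$h, ref$h, tolerance = 1e-12)
  expect_equal(fs$y_pred, ref$y_pred, tolerance = 1e-12)

  # absent vision = zero visual contribution
  fs0 <- forward_step(params, inp$u, NULL, inp$h)
  ref0 <- naive_forward_step(params, inp$u, NULL, inp$h)
  expect_equal(fs0$h, ref0$h, tolerance = 1e-12)

  is_ <- inverse_step(params, inp$y, inp$h)
  refi <- naive_inverse_step(params, inp$y, inp$h)
  expect_equal(is_$h_inv, refi$h_inv, tolerance = 1e-12)
  expect_equal(is_$u_post, refi$u_post, tolerance = 1e-12)

  expect_error(forward_step(params, runif(5), inp$y, inp$h), "motor population")
  expect_error(inverse_step(params, runif(9), inp$h), "visual population")
})

test_that("backprop gradients match central finite differences on a toy net", {
  params <- toy_params()
  inp <- toy_inputs()
  eta <- 1e-4  # small enough that (W - W')/eta is the gradient at W

  up <- update_forward(params, inp$u, inp$y, inp$h, inp$teacher_y, eta)
  fwd_loss <- function(p) {
    0.5 * sum((forward_step(p, inp$u, inp$y, inp$h)$y_pred - inp$teacher_y)^2)
  }
  for (nm in c("W_hy", "W_mu", "W_vy", "W_hh")) {
    expect_lt(rel_err(update_grad(params, up, nm, eta),
                      numeric_grad(fwd_loss, params, nm)), 1e-5)
  }

  upi <- update_inverse(params, inp$y, inp$h, inp$teacher_u, eta)
  inv_loss <- function(p) {
    0.5 * sum((inverse_step(p, inp$y, inp$h)$u_post - inp$teacher_u)^2)
  }
  for (nm in c("V_u", "V_y", "V_h")) {
    expect_lt(rel_err(update_grad(params, upi, nm, eta),
                      numeric_grad(inv_loss, params, nm)), 1e-5)
  }
})

test_that("updates descend the loss, vanish at the teacher, and stay in their network", {
  params <- toy_params()
  inp <- toy_inputs()

  # teacher equal to the current output: zero gradient, nothing moves
  fs <- forward_step(params, inp$u, inp$y, inp$h)
  same <- update_forward(params, inp$u, inp$y, inp$h, teacher = fs$y_pred,
                         eta = 0.05)
  expect_identical(same, params)
  is_ <- inverse_step(params, inp$y, inp$h)
  same <- update_inverse(params, inp$y, inp$h, teacher = is_$u_post,
                         eta = 0.05)
  expect_identical(same, params)

  # a small step strictly decreases the squared error
  fwd_loss <- function(p) {
    0.5 * sum((forward_step(p, inp$u, inp$y, inp$h)$y_pred - inp$teacher_y)^2)
  }
  up <- update_forward(params, inp$u, inp$y, inp$h, inp$teacher_y, eta = 1e-3)
  expect_lt(fwd_loss(up), fwd_loss(params))
  inv_loss <- function(p) {
    0.5 * sum((inverse_step(p, inp$y, inp$h)$u_post - inp$teacher_u)^2)
  }
  upi <- update_inverse(params, inp$y, inp$h, inp$teacher_u, eta = 1e-3)
  expect_lt(inv_loss(upi), inv_loss(params))

  # weight isolation: each update touches only its own network's matrices
  expect_identical(up[c("V_y", "V_h", "V_u")], params[c("V_y", "V_h", "V_u")])
  expect_identical(upi[c("W_mu", "W_vy", "W_hh", "W_hy")],
                   params[c("W_mu", "W_vy", "W_hh", "W_hy")])

  expect_error(update_forward(params, inp$u, inp$y, inp$h, inp$teacher_y,
                              eta = -1), "eta")
  expect_error(update_inverse(params, inp$y, inp$h, inp$teacher_u, eta = 0),
               "eta")
})

test_that("activations stay strictly inside (0, 1) for finite weights", {
  params <- toy_params(seed = 77, init_range = 3)  # deliberately large weights
  for (k in 1:20) {
    fs <- forward_step(params, runif(3, 0, 1), runif(2, 0, 1), runif(4, 0, 1))
    expect_true(all(fs$h > 0 & fs$h < 1))
    expect_true(all(fs$y_pred > 0 & fs$y_pred < 1))
  }
})
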