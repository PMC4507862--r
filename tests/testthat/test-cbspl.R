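test_that("knot grid arithmetic yields the expected counts and positions", {
  expect_length(cbspl_knot_grid(0.9, 0.02)$knots, 48)
  expect_length(cbspl_knot_grid(1.0, 0.01)$knots, 103)
  expect_length(cbspl_knot_grid(1.32, 0.02)$knots, 69)

  p <- cbspl_knot_grid(1.0, 0.5)
  expect_length(p$knots, 5)
  expect_equal(p$r_knots, c(0, 0.5, 1.0, 1.5, 2.0))

  expect_error(cbspl_knot_grid(1.0, 0.3), "integral")
  expect_error(cbspl_knot_grid(1.0, 0.3), "0.3")
})

test_that("spline evaluation matches the basis-matrix arithmetic", {
  # partition of unity: constant knots give a constant potential
  pc <- knot_potential(rep(2.5, 8), 0.2, 1.0)
  r <- seq(0, 0.999, length.out = 50)
  expect_equal(cbspl_evaluate(pc, r), rep(2.5, 50))

  # segment k = 0, t = 0: u = (c0 + 4 c1 + c2)/6
  expect_equal(cbspl_evaluate(knot_potential(c(0, 6, 0, 0), 1, 1), 0), 4)
  # t -> 1 limit of segment 0: u -> (c1 + 4 c2 + c3)/6
  expect_equal(cbspl_evaluate(knot_potential(c(0, 0, 6, 0), 1, 1), 1 - 1e-10),
               4, tolerance = 1e-8)

  expect_equal(cbspl_evaluate(pc, 1.5), 0)   # beyond cutoff
  expect_error(cbspl_evaluate(pc, -0.1), "non-negative")
})

test_that("basis weights are the parameter derivatives and sum to one", {
  p <- knot_potential(rep(0, 8), 0.2, 1.0)
  w0 <- cbspl_basis_weights(p, 0)
  expect_equal(w0$weights, c(1, 4, 1, 0) / 6)
  wh <- cbspl_basis_weights(p, 0.1)   # t = 0.5
  expect_equal(wh$weights, c(0.125, 2.875, 2.875, 0.125) / 6)

  set.seed(42)
  for (r in runif(200, 0, 0.999)) {
    expect_equal(sum(cbspl_basis_weights(p, r)$weights), 1,
                 tolerance = 1e-12)
  }

  # w_j = du/dc_j: perturbing knot j changes u(r) by exactly w_j * dc
  set.seed(1)
  kn <- rnorm(8)
  r <- 0.731
  w <- cbspl_basis_weights(p, r)
  for (q in 1:4) {
    kn2 <- kn
    kn2[w$idx[q]] <- kn2[w$idx[q]] + 1
    expect_equal(cbspl_evaluate(knot_potential(kn2, 0.2, 1.0), r) -
                   cbspl_evaluate(knot_potential(kn, 0.2, 1.0), r),
                 w$weights[q], tolerance = 1e-12)
  }
})

test_that("evaluation is linear in the knot vector", {
  set.seed(5)
  A <- rnorm(8); B <- rnorm(8)
  r <- runif(20, 0, 0.99)
  a <- 0.7; b <- -1.3
  uAB <- cbspl_evaluate(knot_potential(a * A + b * B, 0.2, 1.0), r)
  uA <- cbspl_evaluate(knot_potential(A, 0.2, 1.0), r)
  uB <- cbspl_evaluate(knot_potential(B, 0.2, 1.0), r)
  expect_equal(uAB, a * uA + b * uB, tolerance = 1e-12)
})

test_that("force is the analytic derivative and is continuous", {
  expect_equal(cbspl_force(knot_potential(rep(3, 8), 0.2, 1.0),
                           seq(0, 0.95, 0.05)), rep(0, 20))
  set.seed(9)
  for (trial in 1:5) {
    p <- knot_potential(rnorm(10), 0.1, 0.7)
    r <- runif(30, 0.05, 0.65)
    h <- 1e-6
    fd <- (cbspl_evaluate(p, r - h) - cbspl_evaluate(p, r + h)) / (2 * h)
    expect_equal(cbspl_force(p, r), fd, tolerance = 1e-6)
    # left/right limits at an interior knot, from the adjacent segment
    # polynomials evaluated exactly at the boundary
    f_left <- -sum(cgforge:::cbspl_dbasis_t(1) * p$knots[3:6]) / p$dr
    f_right <- -sum(cgforge:::cbspl_dbasis_t(0) * p$knots[4:7]) / p$dr
    expect_equal(f_left, f_right, tolerance = 1e-10)
  }
})

test_that("the frozen tail drives potential and force to zero at the cutoff", {
  set.seed(11)
  p <- cbspl_knot_grid(1.0, 0.1)
  kn <- rnorm(length(p$knots))
  kn[p$tail_idx] <- 0
  p <- set_knots(p, kn)
  expect_lt(abs(cbspl_evaluate(p, 1.0 - 1e-9)), 1e-10)
  expect_lt(abs(cbspl_force(p, 1.0 - 1e-9)), 1e-9)
  # four knots frozen given the two-interval overhang
  expect_length(p$tail_idx, 4)
})

test_that("core extrapolation continues the potential smoothly and repulsively", {
  # a repulsive-wall + well shape above r_min
  skel <- cbspl_knot_grid(1.0, 0.1, r_min = 0.35)
  target <- potential_table(seq(0.35, 0.99, 0.01),
                            5 * exp(-8 * (seq(0.35, 0.99, 0.01) - 0.35)) - 0.5)
  pot <- extrapolate_core(fit_cbspl(target, skel))

  rm <- pot$r_min
  h <- 1e-7
  u_left <- cbspl_evaluate(pot, rm - h) - h * cbspl_force(pot, rm - h)
  u_right <- cbspl_evaluate(pot, rm + h) + h * cbspl_force(pot, rm + h)
  expect_equal(u_left, u_right, tolerance = 1e-9)
  h2 <- 1e-9
  expect_equal(cbspl_force(pot, rm - h2), cbspl_force(pot, rm + h2),
               tolerance = 1e-6)
  # energy increases toward the core
  expect_gt(cbspl_evaluate(pot, 0.5 * rm), cbspl_evaluate(pot, rm))
  rr <- seq(0.02, rm, 0.02)
  expect_true(all(diff(cbspl_evaluate(pot, rr)) < 0))

  # non-repulsive anchor falls back to a linear continuation with a warning
  flat <- potential_table(seq(0.35, 0.99, 0.01),
                          rep(-0.2, 65))
  expect_warning(extrapolate_core(fit_cbspl(flat, skel)), "linear")
})
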