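test_that("derivative accumulation scatters basis weights per pair", {
  pot <- cbspl_knot_grid(1.0, 0.1, pair = "A-A")
  # one frame, one pair exactly at a knot position (t = 0 of segment k)
  L <- 10; r0 <- 0.4   # k = 4
  tr <- trajectory(list(rbind(c(0, 0, 0), c(r0, 0, 0))), c("A", "A"), L)
  da <- accumulate_derivatives(tr, list("A-A" = pot))
  expected <- numeric(13)
  expected[5:7] <- c(1, 4, 1) / 6
  expect_equal(da$mean, expected, tolerance = 1e-12)

  # no pair within the cutoff: all averages vanish
  tr0 <- trajectory(list(rbind(c(0, 0, 0), c(4, 0, 0))), c("A", "A"), L)
  expect_equal(accumulate_derivatives(tr0, list("A-A" = pot))$mean,
               numeric(13))

  # duplicating every frame leaves the averages unchanged
  fx <- small_fluid()
  pots <- list("A-A" = cbspl_knot_grid(2.0, 0.2, pair = "A-A"))
  d1 <- accumulate_derivatives(fx$traj, pots)
  dup <- trajectory(rep(fx$traj$frames, 2), fx$traj$species, fx$traj$L,
                    fx$traj$mol, fx$traj$mass)
  d2 <- accumulate_derivatives(dup, pots)
  expect_equal(d2$mean, d1$mean, tolerance = 1e-12)
  expect_equal(d2$second, d1$second, tolerance = 1e-12)

  # pairs inside the frozen core are skipped
  potc <- cbspl_knot_grid(1.0, 0.1, r_min = 0.5, pair = "A-A")
  trc <- trajectory(list(rbind(c(0, 0, 0), c(0.4, 0, 0))), c("A", "A"), L)
  expect_equal(accumulate_derivatives(trc, list("A-A" = potc))$mean,
               numeric(13))

  expect_error(accumulate_derivatives(
    trajectory(list(), c("A", "A"), L, mol = 1:2, mass = c(1, 1)),
    list("A-A" = pot)), "empty")
})

fake_avgs <- function(mean, second = NULL, D = NULL) {
  structure(list(mean = mean,
                 second = if (is.null(second))
                   tcrossprod(mean) else second,
                 n_frames = if (is.null(D)) 1L else nrow(D),
                 per_frame = D), class = "deriv_averages")
}

test_that("the gradient is the beta-weighted ensemble-average difference", {
  aa <- fake_avgs(c(1, 0)); cg <- fake_avgs(c(0, 1))
  expect_equal(srel_gradient(aa, cg, beta = 2), c(2, -2))
  expect_equal(srel_gradient(aa, cg, beta = 4), 2 * srel_gradient(aa, cg, 2))
  expect_equal(srel_gradient(aa, aa, beta = 3), c(0, 0))
  expect_error(srel_gradient(aa, fake_avgs(c(1, 2, 3)), 1), "mismatch")
})

test_that("the Hessian reduces to the CG fluctuation matrix for linear forms", {
  # a single CG frame has zero covariance
  D1 <- matrix(c(1, 2, 3), 1)
  cg1 <- fake_avgs(colMeans(D1), crossprod(D1) / 1, D1)
  expect_equal(srel_hessian(cg1, beta = 1.7), matrix(0, 3, 3))

  # two frames: H = beta^2 outer(d1 - d2, d1 - d2) / 4
  d1 <- c(1, 0.5); d2 <- c(-1, 2)
  D2 <- rbind(d1, d2)
  cg2 <- fake_avgs(colMeans(D2), crossprod(D2) / 2, D2)
  expect_equal(srel_hessian(cg2, beta = 3),
               9 * outer(d1 - d2, d1 - d2) / 4, tolerance = 1e-12)

  # PSD on sampled trajectories
  fx <- small_fluid()
  cg <- accumulate_derivatives(fx$traj,
                               list("A-A" = cbspl_knot_grid(2.0, 0.2)))
  ev <- eigen(srel_hessian(cg, beta = 1), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})

test_that("the Newton update solves H dx = grad with relaxation chi", {
  expect_equal(newton_step(0, -2, matrix(2), chi = 1), 1)
  expect_equal(newton_step(c(3, 4), c(1, 1), diag(2), chi = 0), c(3, 4))
  expect_equal(newton_step(c(0, 0), c(1, 4), diag(c(1, 4)), chi = 0.5),
               c(-0.5, -0.5))
  # singular Hessian takes the ridge path (and logs it)
  expect_message(newton_step(c(0, 0), c(1, 0),
                             matrix(c(1, 0, 0, 0), 2), chi = 1), "ridge")
  # an exactly zero Hessian cannot be rescued
  expect_error(suppressMessages(
    newton_step(0, 1, matrix(0), chi = 1)), "singular")
  # the step cap rescales the displacement
  expect_equal(newton_step(0, -10, matrix(1), chi = 1, step_max = 2), 2)
})

test_that("convergence errors are the printed sums of squares", {
  t0 <- list(potential_table(1:5, rep(0, 5)))
  expect_equal(convergence_errors(c(1, 2), c(1, 2), t0, t0, 1, 1),
               c(eps_lambda = 0, eps_u = 0, eps_tot = 0))
  expect_equal(convergence_errors(c(1, 1), c(0, 0), t0, t0,
                                  w_lambda = 1, w_u = 0)[["eps_tot"]], 2)
  e1 <- convergence_errors(c(1, 1), c(0, 0), t0, t0, 1, 0)[["eps_lambda"]]
  e3 <- convergence_errors(c(3, 3), c(0, 0), t0, t0, 1, 0)[["eps_lambda"]]
  expect_equal(e3, 9 * e1)
  tu <- list(potential_table(1:5, c(1, 0, 0, 0, 2)))
  expect_equal(convergence_errors(c(0), c(0), tu, t0, 0, 1)[["eps_tot"]], 5)
  expect_error(convergence_errors(1, 1, tu,
                                  list(potential_table(1:4, rep(0, 4))), 0, 1),
               "grid")
})

test_that("frozen tail and core knots are untouched by the Newton update", {
  res <- re_recovery()$res
  pots <- res$last_potentials[["A-A"]]
  expect_true(all(pots$knots[pots$tail_idx] == 0))
  # every recorded iterate keeps the tail at exactly zero
  lay <- cgforge:::param_layout(res$last_potentials)
  expect_true(all(res$history[, pots$tail_idx] == 0))
})
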