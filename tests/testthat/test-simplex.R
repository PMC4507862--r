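fixture_state <- function(penalty = c(0, 0.5, 1)) {
  # sorted 2D simplex: best (0,0), middle (1,0), worst (0,1)
  simplex_state(rbind(c(0, 0), c(1, 0), c(0, 1)), penalty)
}

test_that("vertex sorting is ascending and stable", {
  st <- simplex_state(rbind(c(1, 1), c(2, 2), c(3, 3)), c(3, 1, 2))
  so <- sort_vertices(st)
  expect_equal(so$penalty, c(1, 2, 3))
  expect_equal(so$vertices[1, ], c(2, 2))

  expect_identical(sort_vertices(so)$vertices, so$vertices)

  tie <- simplex_state(rbind(c(1, 0), c(2, 0), c(3, 0)), c(1, 1, 1))
  expect_equal(sort_vertices(tie)$vertices[, 1], c(1, 2, 3))

  pend <- simplex_state(rbind(c(1, 0), c(2, 0), c(3, 0)))
  expect_error(sort_vertices(pend), "pending")
})

test_that("reflection, expansion and contraction follow the polytope algebra", {
  st <- fixture_state()
  expect_equal(reflect(st), c(1, -1))
  expect_equal(expand(st), c(1.5, -2))
  expect_equal(contract(st), c(0.75, -0.5))

  # alpha = 0 degenerates to the centroid
  st0 <- simplex_state(st$vertices, st$penalty, alpha = 1e-12)
  expect_equal(reflect(st0), c(0.5, 0), tolerance = 1e-9)

  # reflecting the reflected point recovers the original worst vertex
  st2 <- st
  st2$vertices[3, ] <- reflect(st)
  expect_equal(reflect(st2), c(0, 1))

  # collinearity: p_e - centroid = (gamma/alpha) (p_r - centroid)
  pb <- c(0.5, 0)
  expect_equal(expand(st) - pb, 2 * (reflect(st) - pb))
  # contraction lies between the centroid and the reflection point
  lam <- (contract(st) - pb) / (reflect(st) - pb)
  expect_true(all(lam > 0 & lam < 1))

  expect_error(simplex_state(st$vertices, gamma = 1), "gamma")
  expect_error(simplex_state(st$vertices, rho = 1.2), "rho")
  expect_error(simplex_state(st$vertices, rho = 0), "rho")
})

test_that("reflection with alpha = 1 preserves the simplex volume", {
  set.seed(4)
  for (trial in 1:20) {
    v <- matrix(rnorm(6), 3, 2)
    st <- sort_vertices(simplex_state(v, runif(3)))
    area <- function(m) abs(det(cbind(m[2, ] - m[1, ], m[3, ] - m[1, ]))) / 2
    st2 <- st
    st2$vertices[3, ] <- reflect(st)
    expect_equal(area(st2$vertices), area(st$vertices), tolerance = 1e-12)
  }
})

test_that("reduction shrinks every non-best vertex toward the best", {
  st <- simplex_state(rbind(c(0, 0), c(2, 2), c(4, 0)), c(0, 1, 2))
  rd <- reduce_simplex(st)
  expect_equal(rd$vertices[2, ], c(1, 1))
  expect_equal(rd$vertices[3, ], c(2, 0))
  expect_equal(rd$status[2:3], c("pending", "pending"))
  expect_equal(rd$vertices[1, ], c(0, 0))

  # diameter halves with sigma = 0.5
  expect_equal(max(dist(rd$vertices)), max(dist(st$vertices)) / 2)

  # a vertex equal to the best is a fixed point
  st2 <- simplex_state(rbind(c(1, 1), c(1, 1), c(0, 0)), c(0, 0, 1))
  expect_equal(reduce_simplex(st2)$vertices[2, ], c(1, 1))
})

test_that("the decision flow minimizes a quadratic bowl", {
  f <- function(x) sum(x^2)
  st <- simplex_state(rbind(c(1, 0), c(0, 1), c(1, 1)),
                      c(f(c(1, 0)), f(c(0, 1)), f(c(1, 1))))
  st1 <- simplex_step(st, f)
  expect_lt(max(st1$penalty), f(c(1, 1)))   # worst strictly improves

  run <- simplex_run(simplex_state(rbind(c(1, 0), c(0, 1), c(1, 1))), f,
                     max_steps = 200, tol = 0)
  expect_lt(run$state$penalty[1], 1e-6)
  # elitism: the best penalty never increases along the trace
  expect_true(all(diff(run$trace$best) <= 0))

  # a constant objective never satisfies the strict contraction trigger:
  # the reflected point (equal penalty) replaces the worst vertex
  runc <- simplex_run(simplex_state(rbind(c(1, 0), c(0, 1), c(1, 1))),
                      function(x) 1, max_steps = 3, tol = -1)
  expect_true(all(runc$trace$move[-1] == "reflect"))
  expect_true(all(runc$trace$best == 1))

  # when neither reflection nor contraction improves on the worst vertex,
  # the whole simplex is reduced toward the best one
  wall <- function(v) (if (v[1] < 0) 100 else 0) + sum(v^2)
  stw <- simplex_state(rbind(c(0, 0), c(0.1, 0.1), c(2, 0)))
  runw <- simplex_run(stw, wall, max_steps = 1, tol = -1)
  expect_equal(runw$trace$move[2], "reduce")
  expect_equal(sort(runw$state$vertices[, 1]), c(0, 0.05, 1))

  # evaluator failure scores +Inf instead of aborting
  bad <- function(x) if (x[1] < -5) stop("boom") else sum(x^2)
  expect_warning(
    runb <- simplex_run(simplex_state(rbind(c(-6, 0), c(0, 1), c(1, 1))),
                        bad, max_steps = 2, tol = 0), "Inf")
  expect_true(all(is.finite(runb$state$penalty)))
})

test_that("the RDF + pressure penalty sums deviations as printed", {
  mk_rdf <- function(g) structure(list(r = c(0.1, 0.2, 0.3), g = g,
                                       dr = 0.1, pair = "A-A"),
                                  class = "rdf")
  tg <- mk_rdf(c(1, 2, 1))
  sp0 <- penalty_spec(tg, r_lo = 0, r_hi = 0.3, a = 0)
  expect_equal(penalty_rdf_pressure(mk_rdf(c(1, 2, 1)), sp0), 0)
  # a = 0 ignores any pressure mismatch
  expect_equal(penalty_rdf_pressure(mk_rdf(c(1, 2, 1)), sp0, p_cg = 99), 0)

  sp <- penalty_spec(tg, r_lo = 0, r_hi = 0.3, a = 0.01,
                     target_pressure = 0)
  expect_equal(penalty_rdf_pressure(mk_rdf(c(1.1, 2.2, 1)), sp, p_cg = 10),
               0.1 + 0.2 + 0.01 * 10)

  bad <- structure(list(r = c(0.15, 0.25, 0.35), g = c(1, 2, 1), dr = 0.1),
                   class = "rdf")
  expect_error(penalty_rdf_pressure(bad, sp0), "grids")
  expect_error(penalty_spec(tg, a = 0.1), "target pressure")
})

test_that("state files round trip and drive the evaluate/transform cycle", {
  st <- simplex_state(rbind(c(1, 2), c(3, 4), c(5, 6)) / 7,
                      c(0.25, NA, 1 / 3))
  st$iteration <- 4L
  f <- withr::local_tempfile(fileext = ".state")
  write_simplex_state(st, f)
  back <- read_simplex_state(f)
  expect_equal(back$vertices, st$vertices)
  expect_equal(back$penalty, st$penalty)
  expect_equal(back$status, st$status)
  expect_equal(back$iteration, st$iteration)
  expect_equal(back$alpha, 1); expect_equal(back$gamma, 2)

  expect_equal(simplex_next_action(back), "evaluate")
  back$penalty[2] <- 0.5; back$status[2] <- "done"
  expect_equal(simplex_next_action(back), "transform")

  lines <- readLines(f)
  lines[4] <- "2 done 0.1 oops nan"
  writeLines(lines, f)
  expect_error(read_simplex_state(f), "line 4")
})

test_that("targeted CKDg optimization recovers a self-target reference", {
  fx <- lj_fixture()
  g <- fx$rdfs[["A-A"]]
  truth <- fx$truth[["A-A"]]
  spec <- penalty_spec(g, r_lo = 0, r_hi = 2.0, a = 0)
  start <- get_frame(fx$cg_traj, length(fx$cg_traj$frames))
  set.seed(42)
  v0 <- ckdg_vector(truth)
  verts <- t(vapply(1:7, function(i) v0 * (1 + 0.2 * (runif(6) - 0.5) * 2),
                    numeric(6)))
  res <- simplex_minimize(verts, spec, start, fx$state,
                          sampler = list(n_steps = 5e4, relax_steps = 2000),
                          max_steps = 50, tol = 1e-3, seed = 42)
  # the best vertex beats the reference's own resampling noise
  y_self <- mean(vapply(c(999, 1234, 5678), function(sd) {
    traj <- mc_nvt(start, list("A-A" = truth), fx$state, 5e4,
                   max_disp = 0.15, seed = sd)
    penalty_rdf_pressure(compute_rdf(traj, c("A", "A"),
                                     r_max = max(g$r) + g$dr / 2,
                                     dr = g$dr), spec)
  }, numeric(1)))
  expect_lt(res$best_penalty, y_self)
  # and lands near the generating parameters
  expect_equal(unname(ckdg_vector(res$best)[1:2]), c(1, 1),
               tolerance = 0.1)
  # elitism: the best penalty never increases
  expect_true(all(diff(res$trace$best) <= 1e-12))
})

test_that("identical seeds and config give an identical optimization trace", {
  fx <- lj_fixture()
  g <- fx$rdfs[["A-A"]]
  spec <- penalty_spec(g, r_lo = 0, r_hi = 1.6, a = 0)
  start <- get_frame(fx$cg_traj, 1)
  verts <- t(vapply(1:7, function(i)
    ckdg_vector(fx$truth[["A-A"]]) * (1 + 0.05 * i), numeric(6)))
  smp <- list(n_steps = 5e3, relax_steps = 500)
  r1 <- simplex_minimize(verts, spec, start, fx$state, sampler = smp,
                         max_steps = 3, tol = 0, seed = 9)
  r2 <- simplex_minimize(verts, spec, start, fx$state, sampler = smp,
                         max_steps = 3, tol = 0, seed = 9)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$state$vertices, r2$state$vertices)
})

test_that("the decoupled state-file cycle replays the inline decision flow", {
  f <- function(x) sum((x - c(0.3, -0.2))^2)
  verts <- rbind(c(1, 0), c(0, 1), c(1, 1))
  ref <- simplex_run(simplex_state(verts), f, max_steps = 25, tol = 0)

  st <- simplex_state(verts)
  for (i in which(st$status == "pending")) {
    st$penalty[i] <- f(st$vertices[i, ]); st$status[i] <- "done"
  }
  st <- sort_vertices(st)
  path <- withr::local_tempfile(fileext = ".state")
  while (st$iteration < 25) {
    write_simplex_state(st, path)       # every round trips through disk
    st <- read_simplex_state(path)
    st <- simplex_advance(st)
    if (!is.null(st$trial) && is.na(st$trial$penalty))
      st$trial$penalty <- f(st$trial$point)
    for (i in which(st$status == "pending")) {
      st$penalty[i] <- f(st$vertices[i, ]); st$status[i] <- "done"
    }
  }
  expect_equal(st$penalty, ref$state$penalty, tolerance = 1e-12)
  expect_equal(st$vertices, ref$state$vertices, tolerance = 1e-12)
})
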