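test_that("lattice initialization is deterministic and non-overlapping", {
  fr <- init_lattice(8, 4, "A")
  expect_equal(nrow(fr$pos), 8)
  d <- as.matrix(dist(fr$pos))
  expect_equal(min(d[d > 0]), 2)   # L/2 spacing on the 2x2x2 lattice

  a <- init_lattice(30, 5, c(A = 15, B = 15), seed = 10)
  b <- init_lattice(30, 5, c(A = 15, B = 15), seed = 10)
  expect_identical(a, b)
  expect_equal(sum(a$species == "A"), 15)
})

test_that("total energy enumerates minimum-image pairs", {
  ck <- ckdg_params(1, 1, 0.5)
  tabs <- list("A-A" = ck)
  r0 <- 1.3
  u0 <- ckdg_evaluate(ck, r0)

  fr2 <- frame(rbind(c(0, 0, 0), c(r0, 0, 0)), c("A", "A"), 20)
  expect_equal(total_energy(fr2, tabs), u0, tolerance = 1e-5)

  # 3 collinear particles at spacings r, r, 2r with 2r beyond the cutoff
  fr3 <- frame(rbind(c(0, 0, 0), c(r0, 0, 0), c(2 * r0, 0, 0)),
               rep("A", 3), 20)
  expect_equal(total_energy(fr3, tabs), 2 * u0, tolerance = 1e-5)

  far <- frame(rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0)), rep("A", 3), 20)
  expect_equal(total_energy(far, tabs), 0)

  # minimum image: the pair straddling the boundary interacts
  frb <- frame(rbind(c(0.1, 0, 0), c(19.9, 0, 0)), c("A", "A"), 20)
  expect_equal(total_energy(frb, tabs),
               ckdg_evaluate(ck, 0.2), tolerance = 1e-3)

  expect_error(total_energy(frame(rbind(c(0, 0, 0)), "B", 5), tabs),
               "B-B")
})

test_that("an ideal gas accepts every move and samples a flat RDF", {
  fr <- init_lattice(64, 6, "A")
  st <- thermo_state(1)
  traj <- mc_nvt(fr, list("A-A" = zero_table(2)), st, 3e4,
                 max_disp = 0.8, seed = 42)
  expect_equal(attr(traj, "acceptance"), 1)

  g <- compute_rdf(traj, c("A", "A"), r_max = 2.8, dr = 0.2)
  # Poisson error model per bin: sd(g) ~ 1/sqrt(mean count)
  counts <- g$counts
  se <- 1 / sqrt(pmax(counts, 1))
  dev <- abs(g$g[-1] - 1) / se[-1]
  expect_true(all(dev < 5))
})

test_that("the chain is reproducible and its energy bookkeeping is exact", {
  fr <- init_lattice(40, 4.5, "A")
  st <- thermo_state(1.5)
  pots <- list("A-A" = ckdg_params(1, 1, 0.5))
  t1 <- mc_nvt(fr, pots, st, 2e4, max_disp = 0.25, seed = 77)
  t2 <- mc_nvt(fr, pots, st, 2e4, max_disp = 0.25, seed = 77)
  expect_identical(t1$frames, t2$frames)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_xyz(t1, f1); write_xyz(t2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # incremental dU accounting vs full recomputation every 10^3 moves
  expect_lt(attr(t1, "drift_max"), 1e-8)

  t3 <- mc_nvt(fr, pots, st, 2e4, max_disp = 0.25, seed = 78)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("two-particle sampling matches the Boltzmann marginal (quadrature)", {
  L <- 3
  ck <- ckdg_params(0.9, 1.5, 0.5)
  st <- thermo_state(1)
  fr <- frame(rbind(c(0, 0, 0), c(1, 0, 0)), c("A", "A"), L)
  traj <- mc_nvt(fr, list("A-A" = ck), st, 1.2e6, max_disp = 0.45,
                 seed = 42, equil_fraction = 0.1, stride = 10)
  r_samp <- vapply(traj$frames, function(p) {
    d <- p[1, ] - p[2, ]
    d <- d - L * round(d / L)
    sqrt(sum(d^2))
  }, numeric(1))
  r_samp <- r_samp[r_samp < L / 2]

  # 1D quadrature of the radial Boltzmann weight, conditioned on r < L/2
  rg <- seq(1e-3, L / 2, length.out = 4000)
  u <- ckdg_evaluate(ck, rg)
  w <- 4 * pi * rg^2 * exp(-st$beta * pmin(u, 500))
  cdf <- cumsum(w) / sum(w)
  ks <- max(abs(vapply(rg, function(x) mean(r_samp <= x), numeric(1)) -
                  cdf))
  expect_lt(ks, 0.05)
})

test_that("a two-level separation toy obeys detailed balance", {
  # step potential: u = 0 on the inner band, u = delta on the outer band
  L <- 2.4
  delta <- 1
  rgrid <- seq(0, 1.2, 0.001)
  u <- ifelse(rgrid < 0.6, 0, delta)
  tab <- potential_table(rgrid, u, rep(0, length(rgrid)), pair = "A-A",
                         r_cut = 1.2)
  st <- thermo_state(1)
  fr <- frame(rbind(c(0, 0, 0), c(0.5, 0, 0)), c("A", "A"), L)
  traj <- mc_nvt(fr, list("A-A" = tab), st, 8e5, max_disp = 0.3, seed = 42,
                 equil_fraction = 0.1, stride = 20)
  r_samp <- vapply(traj$frames, function(p) {
    d <- p[1, ] - p[2, ]
    d <- d - L * round(d / L)
    sqrt(sum(d^2))
  }, numeric(1))
  n1 <- sum(r_samp >= 0.3 & r_samp < 0.6)
  n2 <- sum(r_samp >= 0.6 & r_samp < 0.9)
  # expected ratio from the radial geometric weight times Boltzmann factor
  w <- function(lo, hi, uu) integrate(function(r) 4 * pi * r^2 * exp(-uu),
                                      lo, hi)$value
  ratio_exp <- w(0.3, 0.6, 0) / w(0.6, 0.9, delta)
  ratio_obs <- n1 / n2
  se <- ratio_obs * sqrt(1 / n1 + 1 / n2)
  expect_lt(abs(ratio_obs - ratio_exp), 3 * se)
})

test_that("virial pressure reduces to the ideal and single-pair limits", {
  st <- thermo_state(2)
  fr <- init_lattice(27, 4, "A")
  traj <- mc_nvt(fr, list("A-A" = zero_table(1.5)), st, 5e3,
                 max_disp = 0.5, seed = 3)
  expect_equal(virial_pressure(traj, list("A-A" = zero_table(1.5)), st),
               27 / 64 * 2, tolerance = 1e-12)

  # two fixed particles with a known force: P = rho kT + f(r) r / (3V)
  L <- 8
  r0 <- 1.0
  ck <- ckdg_params(1, 1, 0.5)
  tr <- trajectory(list(rbind(c(0, 0, 0), c(r0, 0, 0))), c("A", "A"), L)
  P <- virial_pressure(tr, list("A-A" = ck), st)
  f0 <- ckdg_force(ck, r0)
  expect_equal(P, 2 / L^3 * 2 + f0 * r0 / (3 * L^3), tolerance = 1e-4)

  # a purely repulsive fluid pushes the pressure above rho kT
  wca <- function(r) ifelse(r < 2^(1/6), 4 * ((1/r)^12 - (1/r)^6) + 1, 0)
  tabw <- tabulate_potential(wca, dr = 0.002, r_max = 1.5)
  tabw$pair <- "A-A"
  frd <- init_lattice(60, 4.5, "A")
  trj <- mc_nvt(frd, list("A-A" = tabw), thermo_state(1), 5e4,
                max_disp = 0.2, seed = 5)
  expect_gt(virial_pressure(trj, list("A-A" = tabw), thermo_state(1)),
            60 / 4.5^3)
})

test_that("XYZ trajectories round trip through the dialect", {
  fx <- small_fluid()
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(fx$traj, f)
  back <- read_xyz(f)
  expect_equal(length(back), length(fx$traj))
  expect_equal(back$L, fx$traj$L)
  expect_equal(back$species, fx$traj$species)
  expect_equal(back$frames[[3]], fx$traj$frames[[3]], tolerance = 1e-14)
  expect_equal(back$steps, fx$traj$steps)

  # reader tolerates a missing step stamp
  lines <- readLines(f)
  lines <- sub(" step=[0-9]+", "", lines)
  writeLines(lines, f)
  back2 <- read_xyz(f)
  expect_equal(back2$frames[[1]], fx$traj$frames[[1]])
})
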