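# shared lazy fixtures: expensive runs are computed once per test session
.fx_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, force(expr), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

lj_fixture <- function() {
  cached("lj_fixture", generate_reference_fixture("lj_fluid", seed = 42))
}

# full relative-entropy recovery experiment on the 60-particle fluid;
# used by several property checks
re_recovery <- function() {
  cached("re_recovery", {
    fx <- lj_fixture()
    res <- re_minimize(fx$cg_traj, fx$state, r_cut = 2.4, dr = 0.1,
                       max_iter = 15, seed = 42)
    list(fx = fx, res = res)
  })
}

# a small interacting trajectory for analysis tests
small_fluid <- function() {
  cached("small_fluid", {
    st <- thermo_state(1.5)
    fr <- init_lattice(60, 5, "A")
    pots <- list("A-A" = ckdg_params(1, 1, 0.5))
    traj <- mc_nvt(fr, pots, st, 5e4, max_disp = 0.25, seed = 7)
    list(traj = traj, pots = pots, state = st)
  })
}

random_frame <- function(n, L) {
  frame(matrix(runif(3 * n, 0, L), ncol = 3), rep("A", n), L)
}

zero_table <- function(r_cut = 2, dr = 0.01, pair = "A-A") {
  n <- round(r_cut / dr) + 1
  potential_table(seq(0, r_cut, dr), numeric(n), numeric(n), pair = pair,
                  r_cut = r_cut)
}
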