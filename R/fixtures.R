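#' Mole fractions from per-species counts
#'
#' \eqn{x_i = N_i / \sum_j N_j}.
#' @param counts named or unnamed non-negative counts, total `> 0`.
#' @return numeric vector of fractions (names preserved).
#' @export
mole_fraction <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("all-zero counts")
  counts / total
}

# ground-truth potentials used by the synthetic reference systems (reduced
# units, k_B = 1): a CKD well for the fluids, slightly different wells for
# the two species of the binary mixture
fixture_truth <- function(kind, species) {
  switch(kind,
    lj_fluid = setNames(list(ckdg_params(1, 1, 0.5)), pair_key("A", "A")),
    dimer_fluid = setNames(list(ckdg_params(0.7, 0.8, 0.4)),
                           pair_key("D", "D")),
    trimer_fluid = setNames(list(ckdg_params(0.7, 0.8, 0.4)),
                            pair_key("W", "W")),
    binary_mixture = setNames(
      list(ckdg_params(1, 1, 0.5),
           ckdg_params(1, 0.6, 0.5, h = 0.3, p = 1.6, s = 0.3),
           ckdg_params(0.95, 0.8, 0.5)),
      c(pair_key("A", "A"), pair_key("A", "B"), pair_key("B", "B"))),
    stop(sprintf("unknown fixture kind '%s'", kind)))
}

#' Synthetic reference ensembles for self-target experiments
#'
#' Emulates the role of an external all-atom reference: a toy system with a
#' known ground-truth pair potential is sampled with the built-in NVT
#' Monte-Carlo engine, mapped to center-of-mass beads, and its reference
#' RDFs computed.  The ground truth is returned alongside so optimizers can
#' be tested on potentials they should be able to recover.
#'
#' Kinds: `lj_fluid` (60 single-site particles, the default desk-scale
#' recovery system), `dimer_fluid` (40 two-site rigid molecules),
#' `trimer_fluid` (40 three-site rigid molecules with water-like 16/1/1
#' masses) and `binary_mixture` (two single-site species with three pair
#' interactions, mirroring a two-component solvent).
#'
#' @param kind fixture kind (see above).
#' @param params list overriding the defaults: `n` (molecule count), `rho`
#'   (bead number density), `temperature`, `n_steps`, `max_disp`,
#'   `n_frames`, `rdf_dr`, and for `binary_mixture` the named counts
#'   `n_a` / `n_b`.
#' @param seed integer seed (the whole fixture is reproducible from it).
#' @return list: `traj` (site trajectory), `cg_traj` (mapped bead
#'   trajectory), `rdfs` (named per pair), `truth` (ground-truth
#'   potentials), `state`, `L`, `kind`, `seed`.
#' @export
generate_reference_fixture <- function(kind = c("lj_fluid", "dimer_fluid",
                                                "trimer_fluid",
                                                "binary_mixture"),
                                       params = list(), seed = 42L) {
  kind <- match.arg(kind)
  p <- utils::modifyList(list(n = if (kind == "lj_fluid") 60L else 40L,
                              rho = 0.5, temperature = 1.5,
                              n_steps = 2e5, max_disp = 0.25,
                              n_frames = 200L, rdf_dr = 0.05,
                              n_a = 30L, n_b = 30L), params)
  state <- thermo_state(p$temperature)
  truth <- fixture_truth(kind)

  if (kind == "binary_mixture") {
    n_bead <- p$n_a + p$n_b
    L <- (n_bead / p$rho)^(1 / 3)
    start <- init_lattice(n_bead, L, c(A = p$n_a, B = p$n_b), seed = seed)
  } else if (kind == "lj_fluid") {
    L <- (p$n / p$rho)^(1 / 3)
    start <- init_lattice(p$n, L, "A", seed = seed)
  } else if (kind == "dimer_fluid") {
    ty <- molecule_type("D", c("D", "D"), c(1, 1),
                        geometry = rbind(c(-0.25, 0, 0), c(0.25, 0, 0)))
    L <- (p$n / p$rho)^(1 / 3)
    start <- init_lattice_molecules(p$n, L, ty)
  } else {
    ty <- molecule_type("W", c("W", "W", "W"), c(16, 1, 1),
                        geometry = rbind(c(0, 0, 0), c(0.3, 0, 0),
                                         c(0, 0.3, 0)))
    L <- (p$n / p$rho)^(1 / 3)
    start <- init_lattice_molecules(p$n, L, ty)
  }

  stride <- NULL
  n_equil <- floor(0.25 * p$n_steps)
  stride <- max(1L, floor((p$n_steps - n_equil) / p$n_frames))
  traj <- mc_nvt(start, truth, state, n_steps = p$n_steps,
                 max_disp = p$max_disp, seed = seed, stride = stride)
  cg_traj <- map_com_trajectory(traj)

  sp <- sort(unique(cg_traj$species))
  pairs <- list()
  for (i in seq_along(sp)) for (j in i:length(sp))
    pairs[[pair_key(sp[i], sp[j])]] <- c(sp[i], sp[j])
  r_max <- min(max(vapply(truth, function(t) t$r_c, numeric(1))) * 1.5,
               L / 2)
  r_max <- floor(r_max / p$rdf_dr) * p$rdf_dr
  rdfs <- lapply(pairs, function(ab)
    compute_rdf(cg_traj, ab, r_max = r_max, dr = p$rdf_dr))

  list(traj = traj, cg_traj = cg_traj, rdfs = rdfs, truth = truth,
       state = state, L = L, kind = kind, seed = seed)
}
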