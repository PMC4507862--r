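#' Thermodynamic state
#'
#' Temperature and Boltzmann constant; all internal computations are
#' unit-agnostic, so with the default `k_B = 1` temperatures are in reduced
#' (energy) units.
#' @param temperature temperature, `> 0`.
#' @param k_B Boltzmann constant.
#' @return object of class `thermo_state` with `beta = 1/(k_B T)`.
#' @export
thermo_state <- function(temperature, k_B = 1) {
  stopifnot(temperature > 0, k_B > 0)
  structure(list(temperature = temperature, k_B = k_B,
                 beta = 1 / (k_B * temperature)),
            class = "thermo_state")
}

#' Molecule type definition
#'
#' Sites with masses and species labels plus the coarse-grained bead each
#' site maps to.  Every site belongs to exactly one bead; the builders here
#' only use single-bead (center-of-mass) mappings.
#'
#' @param name molecule/bead label.
#' @param species character vector of site species.
#' @param mass site masses, `> 0`.
#' @param geometry n_sites x 3 matrix of site coordinates in the molecule
#'   frame (single-site molecules may omit it).
#' @return object of class `molecule_type`.
#' @export
molecule_type <- function(name, species, mass, geometry = NULL) {
  stopifnot(length(species) == length(mass), all(mass > 0))
  if (is.null(geometry)) {
    stopifnot(length(species) == 1L)
    geometry <- matrix(0, 1, 3)
  }
  stopifnot(nrow(geometry) == length(species), ncol(geometry) == 3)
  structure(list(name = name, species = species, mass = mass,
                 geometry = geometry, n_sites = length(species)),
            class = "molecule_type")
}

#' A particle configuration in a cubic periodic box
#'
#' @param pos N x 3 matrix of positions, wrapped to `[0, L)`.
#' @param species character vector of site species labels.
#' @param L cubic box side.
#' @param mol molecule id per site (default: each site its own molecule).
#' @param mass site masses (default 1).
#' @param step integer step stamp.
#' @return object of class `frame`.
#' @export
frame <- function(pos, species, L, mol = seq_len(nrow(pos)),
                  mass = rep(1, nrow(pos)), step = 0L) {
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 3, length(species) == nrow(pos),
            length(mol) == nrow(pos), L > 0)
  pos <- pos %% L
  structure(list(pos = pos, species = as.character(species), L = L,
                 mol = as.integer(mol), mass = mass, step = step),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("frame: %d sites, %d molecules, box L = %g (step %d)\n",
              nrow(x$pos), length(unique(x$mol)), x$L, x$step))
  invisible(x)
}

#' A sequence of frames sharing species, molecules and box
#'
#' @param frames list of N x 3 position matrices.
#' @param species,mol,L,mass as in [frame()].
#' @param steps recorded step stamps.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(frames, species, L, mol = NULL, mass = NULL,
                       steps = seq_along(frames)) {
  if (is.null(mol)) mol <- seq_len(nrow(frames[[1]]))
  if (is.null(mass)) mass <- rep(1, nrow(frames[[1]]))
  structure(list(frames = frames, species = as.character(species), L = L,
                 mol = as.integer(mol), mass = mass, steps = steps),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, %d sites, box L = %g\n",
              length(x$frames), nrow(x$frames[[1]]), x$L))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' Extract one frame of a trajectory
#' @param traj `trajectory`.
#' @param i frame index.
#' @return `frame`.
#' @export
get_frame <- function(traj, i) {
  frame(traj$frames[[i]], traj$species, traj$L, traj$mol, traj$mass,
        step = traj$steps[i])
}

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "-")

# Resolve a named list of potentials/tables into C++-ready uniform tables
# plus the species-pair index matrix.  Errors name any missing pair.
resolve_tables <- function(tables, species, dr_table = NULL) {
  sp <- sort(unique(species))
  tabs <- lapply(tables, function(tt) {
    if (inherits(tt, "potential_table")) tt
    else {
      rc <- if (inherits(tt, "knot_potential")) tt$r_cut else tt$r_c
      dr <- if (is.null(dr_table)) rc / 1000 else dr_table
      tabulate_potential(tt, dr = dr)
    }
  })
  n <- length(sp)
  pair_idx <- matrix(NA_integer_, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    key <- pair_key(sp[i], sp[j])
    w <- match(key, names(tabs))
    if (is.na(w))
      stop(sprintf("no potential table for species pair %s", key))
    pair_idx[i, j] <- w
  }
  list(tables = lapply(tabs, as_sampler_table), pair_idx = pair_idx,
       species_levels = sp,
       r_cut_max = max(vapply(tabs, function(t) t$r_cut, numeric(1))))
}

type_codes <- function(species, levels) {
  match(species, levels)
}

#' Place particles on a cubic lattice
#'
#' Deterministic non-overlapping start configuration: `N` single-site
#' particles on the smallest simple cubic lattice that holds them, species
#' assigned by a seeded shuffle of the requested mix.
#'
#' @param N particle count.
#' @param L box side.
#' @param species either a single label or a named vector of counts summing
#'   to `N` (e.g. `c(A = 30, B = 30)`).
#' @param seed integer seed for the species shuffle.
#' @return `frame`.
#' @export
init_lattice <- function(N, L, species = "A", seed = 1L) {
  n_edge <- ceiling(N^(1 / 3) - 1e-9)
  a <- L / n_edge
  if (a < 1e-6)
    stop("density too high: lattice spacing collapses")
  g <- seq(0, by = a, length.out = n_edge)
  grid <- as.matrix(expand.grid(x = g, y = g, z = g))[seq_len(N), , drop = FALSE]
  if (length(species) == 1L && is.null(names(species))) {
    sp <- rep(species, N)
  } else {
    stopifnot(sum(species) == N)
    sp <- rep(names(species), times = species)
    old <- .Random.seed_save()
    set.seed(seed)
    sp <- sample(sp)
    .Random.seed_restore(old)
  }
  frame(grid, sp, L)
}

# keep library RNG use from clobbering the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Place rigid molecules on a cubic lattice
#'
#' One molecule of `type` per lattice point, in its reference orientation.
#' @param n_mol number of molecules.
#' @param L box side.
#' @param type a [molecule_type()].
#' @return `frame` with `mol` grouping the sites of each molecule.
#' @export
init_lattice_molecules <- function(n_mol, L, type) {
  centers <- init_lattice(n_mol, L, species = type$name)$pos
  ns <- type$n_sites
  pos <- matrix(0, n_mol * ns, 3)
  for (m in seq_len(n_mol)) {
    idx <- (m - 1L) * ns + seq_len(ns)
    pos[idx, ] <- sweep(type$geometry, 2, centers[m, ], "+")
  }
  frame(pos, rep(type$species, n_mol), L,
        mol = rep(seq_len(n_mol), each = ns),
        mass = rep(type$mass, n_mol))
}

#' Total pairwise potential energy of a frame
#'
#' \eqn{U = \sum_{i<j} u(r_{ij})} over minimum-image distances; pairs
#' beyond their table's cutoff and intramolecular (same `mol`) pairs
#' contribute zero (bonded degrees of freedom are frozen).
#'
#' @param fr `frame`.
#' @param tables named list of potentials or `potential_table`s keyed by
#'   species pair (`"A-A"`, `"A-B"`, ...).
#' @return total energy.
#' @export
total_energy <- function(fr, tables) {
  rt <- resolve_tables(tables, fr$species)
  cpp_total_energy(fr$pos, type_codes(fr$species, rt$species_levels),
                   fr$mol, fr$L, rt$tables, rt$pair_idx)
}

#' NVT Metropolis Monte-Carlo sampling
#'
#' Single-molecule displacement moves (plus rigid translation/rotation when
#' molecules have more than one site) with Metropolis acceptance at
#' \eqn{\beta = 1/k_B T}.  Frames are recorded every `stride` moves after an
#' equilibration discard; the chain is fully reproducible from `seed`.
#'
#' @param start `frame` to start from.
#' @param tables potentials per species pair (see [total_energy()]).
#' @param state [thermo_state()].
#' @param n_steps number of MC moves.
#' @param max_disp maximum displacement per move.
#' @param seed integer seed.
#' @param equil_fraction fraction of `n_steps` discarded before recording
#'   (default 0.25).
#' @param stride record every `stride` moves (default: 100 frames total).
#' @param max_rot maximum rotation angle (radians) for rigid molecules.
#' @return `trajectory` with attributes `acceptance`, `drift_max` (maximum
#'   discrepancy between incremental and recomputed total energy), `energy`
#'   and `final` (the last configuration as a `frame`).
#' @export
mc_nvt <- function(start, tables, state, n_steps, max_disp = 0.1,
                   seed = 1L, equil_fraction = 0.25, stride = NULL,
                   max_rot = 0.5) {
  stopifnot(inherits(start, "frame"), n_steps > 0)
  rt <- resolve_tables(tables, start$species)
  n_equil <- floor(n_steps * equil_fraction)
  if (is.null(stride)) stride <- max(1L, floor((n_steps - n_equil) / 100))
  old <- .Random.seed_save()
  set.seed(seed)
  res <- cpp_mc_nvt(start$pos, type_codes(start$species, rt$species_levels),
                    start$mol, start$L, rt$tables, rt$pair_idx,
                    state$beta, as.integer(n_steps), max_disp, max_rot,
                    as.integer(n_equil), as.integer(stride))
  .Random.seed_restore(old)
  if (res$acceptance == 0)
    warning("zero acceptance over the whole run: pathological start or max_disp")
  steps <- n_equil + stride * seq_along(res$frames)
  out <- trajectory(res$frames, start$species, start$L, start$mol,
                    start$mass, steps = steps)
  attr(out, "acceptance") <- res$acceptance
  attr(out, "drift_max") <- res$drift_max
  attr(out, "energy") <- res$energy
  attr(out, "final") <- frame(res$final, start$species, start$L, start$mol,
                              start$mass, step = n_steps)
  out
}

#' Virial pressure of a trajectory
#'
#' \eqn{P = \rho k_B T + \langle \sum_{i<j} f(r_{ij}) r_{ij} \rangle / (3V)}
#' averaged over frames, with \eqn{\rho} the molecule number density.  No
#' tail correction is applied: package potentials vanish at their cutoff by
#' construction.
#'
#' @param traj `trajectory`.
#' @param tables potentials per species pair.
#' @param state [thermo_state()].
#' @return pressure (scalar).
#' @export
virial_pressure <- function(traj, tables, state) {
  if (length(traj$frames) == 0L) stop("empty trajectory")
  rt <- resolve_tables(tables, traj$species)
  ty <- type_codes(traj$species, rt$species_levels)
  V <- traj$L^3
  w <- vapply(traj$frames, function(p)
    cpp_virial_frame(p, ty, traj$mol, traj$L, rt$tables, rt$pair_idx),
    numeric(1))
  rho <- length(unique(traj$mol)) / V
  rho * state$k_B * state$temperature + mean(w) / (3 * V)
}

#' Write a trajectory in XYZ dialect
#'
#' Per frame: atom count, a comment line `box=<L> step=<n>`, then
#' `species x y z` rows.
#' @param traj `trajectory`.
#' @param file path.
#' @return the path, invisibly.
#' @export
write_xyz <- function(traj, file) {
  con <- file(file, "w")
  on.exit(close(con))
  N <- nrow(traj$frames[[1]])
  for (i in seq_along(traj$frames)) {
    writeLines(sprintf("%d", N), con)
    writeLines(sprintf("box=%.16e step=%d", traj$L, traj$steps[i]), con)
    p <- traj$frames[[i]]
    writeLines(sprintf("%s %.16e %.16e %.16e",
                       traj$species, p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(file)
}

#' Read an XYZ trajectory
#'
#' Accepts the dialect written by [write_xyz()]; the step stamp in the
#' comment line may be missing.  This is the bring-your-own-trajectory
#' entry point: any ensemble sampled elsewhere can be analyzed or used as
#' reference by writing it in this format.
#'
#' @param file path.
#' @param L box side; required if the comment lines carry no `box=` token.
#' @return `trajectory` (sites as single-site molecules).
#' @export
read_xyz <- function(file, L = NULL) {
  lines <- readLines(file)
  frames <- list(); steps <- integer(0); species <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    N <- as.integer(trimws(lines[i]))
    comment <- lines[i + 1L]
    bx <- regmatches(comment, regexpr("box=[0-9eE.+-]+", comment))
    if (length(bx)) L <- as.numeric(sub("box=", "", bx))
    if (is.null(L)) stop("no box metadata in file and no L supplied")
    st <- regmatches(comment, regexpr("step=[0-9]+", comment))
    steps <- c(steps, if (length(st)) as.integer(sub("step=", "", st))
                      else length(frames) + 1L)
    rows <- strsplit(trimws(lines[i + 1L + seq_len(N)]), "[ \t]+")
    sp <- vapply(rows, `[[`, character(1), 1L)
    xyz <- matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))), ncol = 3,
                  byrow = TRUE)
    if (is.null(species)) species <- sp
    frames[[length(frames) + 1L]] <- xyz %% L
    i <- i + 2L + N
  }
  trajectory(frames, species, L, steps = steps)
}
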