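#' Center-of-mass mapping to coarse-grained beads
#'
#' Maps each molecule of a frame to a single bead at the mass-weighted mean
#' of its sites.  Site coordinates are unwrapped around the molecule's first
#' site before averaging (a mass-weighted mean of wrapped coordinates is
#' wrong across the periodic boundary) and the bead is rewrapped into the
#' box.  Molecules spanning more than half the box after unwrapping are
#' rejected: their periodic image is ambiguous.
#'
#' @param fr `frame` whose `mol` and `mass` fields define the mapping.
#' @param bead_species optional named map from molecule species signature to
#'   bead label; by default a molecule whose sites are all species `"X"`
#'   maps to a bead `"X"`, and mixed molecules map to the first site's
#'   species.
#' @return `frame` of beads, one per molecule.
#' @export
map_com <- function(fr, bead_species = NULL) {
  mols <- unique(fr$mol)
  L <- fr$L
  pos <- matrix(0, length(mols), 3)
  sp <- character(length(mols))
  for (q in seq_along(mols)) {
    idx <- which(fr$mol == mols[q])
    p <- fr$pos[idx, , drop = FALSE]
    m <- fr$mass[idx]
    ref <- p[1, ]
    d <- sweep(p, 2, ref)
    d <- d - L * round(d / L)
    if (nrow(p) > 1L &&
        max(apply(d, 2, function(x) diff(range(x)))) > L / 2 - 1e-12)
      stop(sprintf("molecule %d spans more than half the box: image ambiguous",
                   mols[q]))
    uw <- sweep(d, 2, ref, "+")
    pos[q, ] <- colSums(uw * m) / sum(m)
    sig <- fr$species[idx][1]
    sp[q] <- if (!is.null(bead_species) && sig %in% names(bead_species))
      bead_species[[sig]] else sig
  }
  frame(pos, sp, L, step = fr$step)
}

#' Map every frame of a trajectory to bead coordinates
#' @param traj site `trajectory`.
#' @param bead_species see [map_com()].
#' @return bead `trajectory`.
#' @export
map_com_trajectory <- function(traj, bead_species = NULL) {
  mapped <- lapply(seq_along(traj$frames), function(i)
    map_com(get_frame(traj, i), bead_species))
  trajectory(lapply(mapped, `[[`, "pos"), mapped[[1]]$species, traj$L,
             steps = traj$steps)
}

as_neighbor_pairs <- function(lst) {
  d <- data.frame(i = lst$i, j = lst$j, r = lst$r)
  d <- d[order(d$i, d$j), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("neighbor_pairs", "data.frame")
  d
}

#' Brute-force neighbor search
#'
#' Exhaustive double loop over all pairs with a minimum-image distance test:
#' cost O(N^2), no prerequisites on the box.
#'
#' @param fr `frame`.
#' @param cutoff neighbor cutoff, `> 0`.
#' @return data.frame (`neighbor_pairs`) with columns `i < j` and `r`,
#'   ordered by `(i, j)`.
#' @export
neighbor_simple <- function(fr, cutoff) {
  stopifnot(cutoff > 0)
  as_neighbor_pairs(cpp_neighbor_simple(fr$pos, fr$L, cutoff))
}

#' Cell-list neighbor search
#'
#' Particles are binned once into a grid whose cell edge is at least the
#' cutoff; pairs are then collected from each cell and its 26 periodic
#' neighbor cells, an O(N) procedure at fixed density.  The result is
#' identical to [neighbor_simple()].  Boxes with fewer than 3 cells per
#' edge fall back to the simple search with a message.
#'
#' @inheritParams neighbor_simple
#' @return `neighbor_pairs` data.frame.
#' @export
neighbor_grid <- function(fr, cutoff) {
  stopifnot(cutoff > 0)
  if (floor(fr$L / cutoff) < 3) {
    message("box smaller than 3 cells per edge: falling back to simple search")
    return(neighbor_simple(fr, cutoff))
  }
  as_neighbor_pairs(cpp_neighbor_grid(fr$pos, fr$L, cutoff))
}

#' Frame-parallel analysis with a merge contract
#'
#' Applies a pure per-frame function to every frame of a trajectory and
#' folds the partial results with an associative, commutative merge rule.
#' The result is independent of the worker count: bit-identical for integer
#' histogram accumulators, and equal to the serial fold up to floating-point
#' associativity for float accumulators (chunks are merged in frame order,
#' so the fold order is the serial order).  Workers are forked processes
#' (`parallel::mclapply`) when `n_workers > 1` and the platform supports
#' forks; otherwise chunks run serially with identical semantics.
#'
#' @param traj `trajectory`.
#' @param fn `function(frame) -> partial result`.
#' @param merge `function(a, b) -> merged partial`.
#' @param n_workers worker count (chunks of frames, preserved order).
#' @return the merged result.
#' @export
parallel_map_frames <- function(traj, fn, merge, n_workers = 1L) {
  nf <- length(traj$frames)
  if (nf == 0L) stop("empty trajectory")
  n_workers <- max(1L, min(as.integer(n_workers), nf))
  chunks <- split(seq_len(nf),
                  ceiling(seq_len(nf) / (nf / n_workers)))
  do_chunk <- function(idx) {
    parts <- lapply(idx, function(i) fn(get_frame(traj, i)))
    Reduce(merge, parts)
  }
  partials <- if (n_workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(chunks, do_chunk, mc.cores = n_workers)
  } else {
    lapply(chunks, do_chunk)
  }
  err <- vapply(partials, inherits, logical(1), "try-error")
  if (any(err)) stop("frame analysis failed in a worker chunk")
  Reduce(merge, partials)
}

#' Radial distribution function
#'
#' Histogram of minimum-image pair distances in half-open bins
#' \eqn{[r_k, r_k + \Delta)}, normalized per frame by the ideal-gas shell
#' count \eqn{n_{id} = \rho_{pair} \frac{4\pi}{3}[(r_k+\Delta)^3 - r_k^3]}
#' and averaged over frames.  The pair density convention is
#' \eqn{N(N-1)/2/V} for a same-species pair and \eqn{N_A N_B / V} for a
#' cross pair.  Intramolecular site pairs are excluded.
#'
#' @param traj `trajectory`.
#' @param pair character vector of two species, e.g. `c("A", "A")`.
#' @param r_max histogram extent; must satisfy `r_max <= L/2` (minimum
#'   image is ambiguous beyond).
#' @param dr bin width.
#' @param n_workers frame-parallel worker count (the result does not depend
#'   on it).
#' @return object of class `rdf`: bin centers `r`, values `g`, `edges`,
#'   `pair`, `n_frames`, `dr`.
#' @export
compute_rdf <- function(traj, pair = c("A", "A"), r_max, dr,
                        n_workers = 1L) {
  L <- traj$L
  if (r_max > L / 2 + 1e-12)
    stop(sprintf("r_max = %g exceeds L/2 = %g: image ambiguity", r_max, L / 2))
  sp <- sort(unique(traj$species))
  tA <- match(pair[1], sp); tB <- match(pair[2], sp)
  if (is.na(tA) || is.na(tB)) stop("pair species not present in trajectory")
  nb <- round(r_max / dr)
  counts <- parallel_map_frames(
    traj,
    function(fr) cpp_pair_hist(fr$pos, match(fr$species, sp), fr$mol, L,
                               tA, tB, r_max, dr, TRUE),
    `+`, n_workers = n_workers)
  NA_ <- sum(traj$species == pair[1])
  NB_ <- sum(traj$species == pair[2])
  V <- L^3
  pair_dens <- if (pair[1] == pair[2]) NA_ * (NA_ - 1) / 2 / V
               else NA_ * NB_ / V
  edges <- dr * (0:nb)
  shell <- 4 * pi / 3 * (edges[-1]^3 - edges[-(nb + 1)]^3)
  n_id <- pair_dens * shell
  g <- counts / (length(traj$frames) * n_id)
  structure(list(r = edges[-(nb + 1)] + dr / 2, g = as.numeric(g),
                 edges = edges, counts = as.numeric(counts),
                 pair = pair_key(pair[1], pair[2]),
                 n_frames = length(traj$frames), dr = dr),
            class = "rdf")
}

#' @export
print.rdf <- function(x, ...) {
  cat(sprintf("rdf [%s]: %d bins, dr = %g, %d frames\n",
              x$pair, length(x$g), x$dr, x$n_frames))
  invisible(x)
}

#' Write an RDF table
#'
#' Two columns `r g` with a `#` header carrying the pair label, frame count
#' and bin width; the same format is accepted as a target distribution.
#' @param g `rdf` object.
#' @param file path.
#' @return path, invisibly.
#' @export
write_rdf <- function(g, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pair %s", g$pair),
               sprintf("# frames %d", g$n_frames),
               sprintf("# dr %.16e", g$dr),
               "# r g"), con)
  writeLines(sprintf("%.16e %.16e", g$r, g$g), con)
  invisible(file)
}

#' Read an RDF table written by [write_rdf()] (or any `# r g` text file)
#' @param file path.
#' @return `rdf` object.
#' @export
read_rdf <- function(file) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "#")]
  grab <- function(key, default) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (length(ln)) sub(paste0("^# ", key, " "), "", ln[1]) else default
  }
  dat <- read.table(text = lines[!startsWith(lines, "#")],
                    col.names = c("r", "g"))
  dr <- as.numeric(grab("dr", dat$r[2] - dat$r[1]))
  structure(list(r = dat$r, g = dat$g,
                 edges = c(dat$r - dr / 2, dat$r[length(dat$r)] + dr / 2),
                 counts = NULL, pair = grab("pair", "A-A"),
                 n_frames = as.integer(grab("frames", "1")), dr = dr),
            class = "rdf")
}
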