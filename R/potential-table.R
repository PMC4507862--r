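#' Tabulated pair potential
#'
#' A `potential_table` holds a strictly increasing separation grid with the
#' energy `u(r)` and force `f(r) = -du/dr`, plus a `defined` flag used by
#' Boltzmann inversion to mark bins where the pair distribution was too low
#' to invert.  Tables are the common currency between the potential
#' families, the Monte-Carlo sampler and the state-file workflow.
#'
#' @param r separation grid (strictly increasing).
#' @param u energies.
#' @param f forces; computed by central differences of `u` when missing.
#' @param defined logical mask of usable grid points.
#' @param pair species-pair label.
#' @param r_cut cutoff; `u` is zero at and beyond it.
#' @return object of class `potential_table`.
#' @export
potential_table <- function(r, u, f = NULL, defined = NULL, pair = "A-A",
                            r_cut = max(r)) {
  if (length(r) == 0L) stop("empty separation grid")
  if (any(diff(r) <= 0)) stop("separation grid must be strictly increasing")
  if (is.null(defined)) defined <- rep(TRUE, length(r))
  if (is.null(f)) {
    f <- rep(NA_real_, length(r))
    ok <- which(defined)
    if (length(ok) >= 3L) {
      ru <- r[ok]; uu <- u[ok]
      n <- length(ok)
      f[ok] <- -c((uu[2] - uu[1]) / (ru[2] - ru[1]),
                  (uu[-(1:2)] - uu[seq_len(n - 2)]) /
                    (ru[-(1:2)] - ru[seq_len(n - 2)]),
                  (uu[n] - uu[n - 1]) / (ru[n] - ru[n - 1]))
    }
  }
  structure(list(r = r, u = u, f = f, defined = defined, pair = pair,
                 r_cut = r_cut),
            class = "potential_table")
}

#' @export
print.potential_table <- function(x, ...) {
  cat(sprintf("potential table [%s]: %d points, r in [%g, %g], r_cut = %g\n",
              x$pair, length(x$r), min(x$r), max(x$r), x$r_cut))
  invisible(x)
}

#' Tabulate a potential on a uniform grid
#'
#' Evaluates energy and force of a CBSPL or CKDg potential (or a plain
#' function of `r`) on `r = 0, dr, ..., r_max`.  Values at separations the
#' form cannot support (the diverging LJ core at `r -> 0`) are capped at
#' `u_max` so downstream table interpolation stays finite; capped bins keep
#' a strongly repulsive finite slope, which is all a Metropolis sampler
#' needs of them.
#'
#' @param pot potential object or `function(r)`.
#' @param dr table spacing.
#' @param r_max table extent (defaults to the potential's cutoff).
#' @param u_max finite cap for diverging cores.
#' @return `potential_table` on the uniform grid.
#' @export
tabulate_potential <- function(pot, dr, r_max = NULL, u_max = 1e10) {
  UseMethod("tabulate_potential")
}

#' @export
tabulate_potential.knot_potential <- function(pot, dr, r_max = NULL,
                                              u_max = 1e10) {
  if (is.null(r_max)) r_max <- pot$r_cut
  r <- seq(0, r_max, by = dr)
  u <- pmin(cbspl_evaluate(pot, r), u_max)
  f <- cbspl_force(pot, r)
  potential_table(r, u, f, pair = pot$pair, r_cut = pot$r_cut)
}

#' @export
tabulate_potential.ckdg_params <- function(pot, dr, r_max = NULL,
                                           u_max = 1e10) {
  if (is.null(r_max)) r_max <- pot$r_c
  r <- seq(0, r_max, by = dr)
  rpos <- pmax(r, dr / 2)           # the r = 0 row inherits the core cap
  u <- pmin(ckdg_evaluate(pot, rpos), u_max)
  f <- ckdg_force(pot, rpos)
  f[!is.finite(f) | abs(f) > u_max] <- sign(f[!is.finite(f) | abs(f) > u_max]) * u_max
  potential_table(r, u, f, pair = "A-A", r_cut = r_max)
}

#' @export
tabulate_potential.function <- function(pot, dr, r_max = NULL, u_max = 1e10) {
  if (is.null(r_max)) stop("r_max is required when tabulating a function")
  r <- seq(0, r_max, by = dr)
  rpos <- pmax(r, dr / 2)
  u <- pmin(pot(rpos), u_max)
  h <- dr * 1e-4
  f <- -(pot(rpos + h) - pot(pmax(rpos - h, h))) / (2 * h)
  potential_table(r, u, f, r_cut = r_max)
}

#' Boltzmann inversion of a pair distribution
#'
#' The potential of mean force \eqn{u(r) = -k_B T \ln g(r)}, defined only
#' where \eqn{g(r) > g_{floor}}; bins at or below the floor are marked
#' undefined for downstream extrapolation rather than set to infinity.
#'
#' @param g an [rdf] object or data.frame with columns `r` and `g`.
#' @param temperature temperature.
#' @param k_B Boltzmann constant (default 1: reduced units).
#' @param g_floor positivity floor below which bins are undefined.
#' @return `potential_table` (force by finite differences where defined).
#' @export
boltzmann_invert <- function(g, temperature, k_B = 1, g_floor = 1e-10) {
  r <- g$r
  gv <- g$g
  if (is.null(r) || length(r) == 0L) stop("empty RDF grid")
  if (any(gv < 0)) stop("RDF values must be non-negative")
  defined <- gv > g_floor
  u <- rep(NA_real_, length(r))
  u[defined] <- -k_B * temperature * log(gv[defined])
  pair <- if (!is.null(g$pair)) g$pair else "A-A"
  potential_table(r, u, defined = defined, pair = pair)
}

#' Least-squares fit of a CBSPL potential to a tabulated target
#'
#' Finds the knot values minimizing the sum of squared residuals of
#' [cbspl_evaluate()] against the target over its defined points below the
#' skeleton's cutoff.  Tail knots are held at zero unless
#' `tail_zero = FALSE`.  Knots with no support among the target points
#' (typically the unsampled repulsive core) are left at the skeleton's
#' values; use [extrapolate_core()] to fill them.
#'
#' @param target `potential_table` (or anything with `r`, `u`, `defined`).
#' @param skeleton `knot_potential` defining grid and constraints.
#' @param tail_zero freeze the tail knots at zero.
#' @return fitted `knot_potential`.
#' @export
fit_cbspl <- function(target, skeleton, tail_zero = TRUE) {
  defined <- if (is.null(target$defined)) rep(TRUE, length(target$r))
             else target$defined
  sel <- which(defined & target$r < skeleton$r_cut & target$r >= 0)
  r <- target$r[sel]
  y <- target$u[sel]
  nk <- length(skeleton$knots)
  A <- matrix(0, length(r), nk)
  seg <- cbspl_segment(skeleton, r)
  B <- cbspl_basis_t(seg$t)
  for (q in 1:4) A[cbind(seq_along(r), seg$k + q)] <- B[, q]

  free <- if (tail_zero) setdiff(seq_len(nk), skeleton$tail_idx)
          else seq_len(nk)
  # a knot is only identifiable when several target points fall inside its
  # support; thin-support columns (the unsampled core) stay at the skeleton
  npts <- colSums(abs(A[, free, drop = FALSE]) > 1e-12)
  supported <- free[npts >= pmin(3, length(r))]
  if (length(r) < length(supported)) {
    stop(sprintf("underdetermined fit: %d target points for %d free knots",
                 length(r), length(supported)))
  }
  fit <- qr.coef(qr(A[, supported, drop = FALSE]), y)
  fit[is.na(fit)] <- 0
  knots <- skeleton$knots
  knots[skeleton$tail_idx] <- if (tail_zero) 0 else knots[skeleton$tail_idx]
  knots[supported] <- fit
  set_knots(skeleton, knots)
}

#' Write a potential table file
#'
#' Three whitespace-separated columns `r u f` in 17-significant-digit
#' scientific notation, preceded by `#` header lines naming the species pair
#' and cutoff.  Output is bit-stable for fixed inputs.
#'
#' @param pot a `potential_table`, or any potential accepted by
#'   [tabulate_potential()] together with `dr`/`r_max`.
#' @param file output path.
#' @param dr,r_max grid spec when `pot` is not already a table.
#' @return the path, invisibly.
#' @export
export_table <- function(pot, file, dr = NULL, r_max = NULL) {
  if (!inherits(pot, "potential_table")) {
    if (is.null(dr)) stop("dr is required to tabulate this potential")
    pot <- tabulate_potential(pot, dr = dr, r_max = r_max)
  }
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pair %s", pot$pair),
               sprintf("# r_cut %.16e", pot$r_cut),
               "# r u f"), con)
  u <- pot$u; f <- pot$f
  u[!is.finite(u)] <- 0
  f[!is.finite(f)] <- 0
  writeLines(sprintf("%.16e %.16e %.16e", pot$r, u, f), con)
  invisible(file)
}

#' Read a potential table file written by [export_table()]
#' @param file path.
#' @return `potential_table`.
#' @export
read_table_file <- function(file) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "#")]
  pair <- sub("^# pair ", "", grep("^# pair ", hdr, value = TRUE)[1])
  rcut_line <- grep("^# r_cut ", hdr, value = TRUE)
  dat <- read.table(text = lines[!startsWith(lines, "#")],
                    col.names = c("r", "u", "f"))
  r_cut <- if (length(rcut_line)) as.numeric(sub("^# r_cut ", "", rcut_line[1]))
           else max(dat$r)
  potential_table(dat$r, dat$u, dat$f, pair = if (is.na(pair)) "A-A" else pair,
                  r_cut = r_cut)
}

# internal: shape a uniform-grid table for the C++ kernels
as_sampler_table <- function(tab) {
  stopifnot(inherits(tab, "potential_table"))
  dr <- tab$r[2] - tab$r[1]
  if (abs(tab$r[1]) > 1e-12 || max(abs(diff(tab$r) - dr)) > 1e-8 * dr)
    stop("sampler tables need a uniform grid starting at r = 0")
  u <- tab$u; f <- tab$f
  u[!is.finite(u)] <- 1e10
  f[!is.finite(f)] <- 0
  list(dr = dr, rcut = tab$r_cut, u = u, f = f)
}
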