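#' Uniform cubic B-spline (CBSPL) pair potentials
#'
#' A CBSPL potential is defined by knot values \eqn{c_0, \dots, c_m} on an
#' even grid \eqn{r_i = i\,\Delta r} with \eqn{\Delta r = r_{cut}/(m-2)}: the
#' knot grid extends two intervals beyond the cutoff so that every separation
#' \eqn{r < r_{cut}} has the four supporting knots it needs.  The potential
#' is linear in its knot values, which is what makes the relative-entropy
#' Hessian a covariance matrix (see [srel_hessian()]).
#'
#' Knots whose position lies in the tail region \eqn{r \ge r_{cut} - \Delta r}
#' are frozen at zero, which forces both the potential and the force to reach
#' zero smoothly at the cutoff.  Knots in the poorly sampled core
#' \eqn{r \le r_{min}} are excluded from optimization and filled in by
#' [extrapolate_core()].
#'
#' @param r_cut cutoff distance (length units).
#' @param dr knot spacing; `r_cut / dr` must be integral.
#' @param r_min core radius below which knots are frozen (default 0: none).
#' @param pair species-pair label, e.g. `"A-A"`.
#' @param knots optional initial knot values (default all zero).
#' @return an object of class `knot_potential`.
#' @examples
#' pot <- cbspl_knot_grid(0.9, 0.02)
#' length(pot$knots)  # 48
#' @export
cbspl_knot_grid <- function(r_cut, dr, r_min = 0, pair = "A-A", knots = NULL) {
  stopifnot(r_cut > 0, dr > 0)
  n_int <- r_cut / dr
  if (abs(n_int - round(n_int)) > 1e-8 * max(1, n_int)) {
    stop(sprintf("r_cut/dr must be integral: r_cut = %g, dr = %g (ratio %g)",
                 r_cut, dr, n_int))
  }
  n_int <- round(n_int)
  m <- n_int + 2L                      # dr = r_cut/(m - 2)
  n_knots <- m + 1L                    # c_0 .. c_m
  if (is.null(knots)) knots <- numeric(n_knots)
  knot_potential(knots, dr = dr, r_cut = r_cut, r_min = r_min, pair = pair)
}

#' Construct a CBSPL potential from explicit knot values
#'
#' @param knots numeric vector of knot values \eqn{c_0 \dots c_m}.
#' @inheritParams cbspl_knot_grid
#' @return `knot_potential` object with fields `knots`, `dr`, `r_cut`,
#'   `r_min`, `pair`, `r_knots` (knot positions) and the frozen-index sets
#'   `core_idx` / `tail_idx` (1-based indices into `knots`).
#' @export
knot_potential <- function(knots, dr, r_cut, r_min = 0, pair = "A-A") {
  m <- length(knots) - 1L
  if (abs(dr * (m - 2) - r_cut) > 1e-8 * r_cut) {
    stop(sprintf("knot count %d inconsistent with r_cut = %g, dr = %g",
                 length(knots), r_cut, dr))
  }
  r_knots <- (seq_along(knots) - 1L) * dr
  tail_idx <- which(r_knots >= r_cut - dr - 1e-12)
  core_idx <- if (r_min > 0) which(r_knots <= r_min + 1e-12) else integer(0)
  structure(
    list(knots = knots, dr = dr, r_cut = r_cut, r_min = r_min, pair = pair,
         r_knots = r_knots, core_idx = core_idx, tail_idx = tail_idx),
    class = "knot_potential")
}

#' @export
print.knot_potential <- function(x, ...) {
  cat(sprintf(
    "CBSPL potential [%s]: %d knots, dr = %g, r_cut = %g, r_min = %g\n",
    x$pair, length(x$knots), x$dr, x$r_cut, x$r_min))
  cat(sprintf("  free knots: %d (core %d, tail %d frozen)\n",
              length(free_knot_idx(x)), length(x$core_idx),
              length(x$tail_idx)))
  invisible(x)
}

#' Indices of knots subject to optimization
#'
#' All knots except the frozen core (`r <= r_min`) and the zero tail
#' (`r >= r_cut - dr`).
#' @param pot `knot_potential`.
#' @return integer vector of 1-based indices into `pot$knots`.
#' @export
free_knot_idx <- function(pot) {
  setdiff(seq_along(pot$knots), c(pot$core_idx, pot$tail_idx))
}

# basis polynomials of the uniform cubic B-spline on one segment, t in [0,1)
cbspl_basis_t <- function(t) {
  cbind((1 - 3 * t + 3 * t^2 - t^3) / 6,
        (4 - 6 * t^2 + 3 * t^3) / 6,
        (1 + 3 * t + 3 * t^2 - 3 * t^3) / 6,
        t^3 / 6)
}

cbspl_dbasis_t <- function(t) {
  cbind((-3 + 6 * t - 3 * t^2) / 6,
        (-12 * t + 9 * t^2) / 6,
        (3 + 6 * t - 9 * t^2) / 6,
        3 * t^2 / 6)
}

cbspl_segment <- function(pot, r) {
  if (any(r < 0)) stop("separation r must be non-negative")
  k <- pmin(floor(r / pot$dr), length(pot$knots) - 4L)
  t <- r / pot$dr - k
  list(k = as.integer(k), t = t)
}

#' Evaluate a CBSPL potential
#'
#' On segment \eqn{k} (\eqn{r_k \le r < r_{k+1}}) the value is
#' \eqn{[1\ t\ t^2\ t^3]\,\tfrac16 M\,(c_k, c_{k+1}, c_{k+2}, c_{k+3})^T}
#' with the standard uniform cubic B-spline matrix \eqn{M} and
#' \eqn{t = (r - r_k)/\Delta r}.  Values for `r >= r_cut` are zero.
#'
#' @param pot `knot_potential`.
#' @param r separation(s), each `>= 0`.
#' @return numeric vector of energies.
#' @export
cbspl_evaluate <- function(pot, r) {
  seg <- cbspl_segment(pot, r)
  B <- cbspl_basis_t(seg$t)
  u <- B[, 1] * pot$knots[seg$k + 1L] + B[, 2] * pot$knots[seg$k + 2L] +
    B[, 3] * pot$knots[seg$k + 3L] + B[, 4] * pot$knots[seg$k + 4L]
  u[r >= pot$r_cut] <- 0
  u
}

#' B-spline basis weights of a separation
#'
#' Returns the four non-zero weights \eqn{w_k \dots w_{k+3}} such that
#' \eqn{u(r) = \sum_j w_j c_j}; these are exactly the first parameter
#' derivatives \eqn{\partial u(r)/\partial c_j} used by the relative-entropy
#' gradient and Hessian (second parameter derivatives vanish: the form is
#' linear in its knots).  The weights sum to 1 (partition of unity).
#'
#' @inheritParams cbspl_evaluate
#' @param r a single separation with `0 <= r < r_cut`.
#' @return list with `weights` (length 4), `idx` (1-based knot indices) and
#'   `k` (0-based segment index).
#' @export
cbspl_basis_weights <- function(pot, r) {
  stopifnot(length(r) == 1L)
  if (r >= pot$r_cut) stop("r beyond cutoff has no basis support")
  seg <- cbspl_segment(pot, r)
  list(weights = drop(cbspl_basis_t(seg$t)), idx = seg$k + 1:4, k = seg$k)
}

#' Force of a CBSPL potential
#'
#' \eqn{f = -du/dr}, from the analytic derivative of the segment cubic;
#' continuous across segment boundaries (the spline is C2).
#' @inheritParams cbspl_evaluate
#' @return numeric vector of forces.
#' @export
cbspl_force <- function(pot, r) {
  seg <- cbspl_segment(pot, r)
  D <- cbspl_dbasis_t(seg$t)
  du <- (D[, 1] * pot$knots[seg$k + 1L] + D[, 2] * pot$knots[seg$k + 2L] +
           D[, 3] * pot$knots[seg$k + 3L] + D[, 4] * pot$knots[seg$k + 4L]) /
    pot$dr
  f <- -du
  f[r >= pot$r_cut] <- 0
  f
}

#' Replace the knot vector of a potential
#'
#' @param pot `knot_potential`.
#' @param knots new knot values (same length).
#' @return updated `knot_potential`.
#' @export
set_knots <- function(pot, knots) {
  stopifnot(length(knots) == length(pot$knots))
  pot$knots <- knots
  pot
}

#' Extrapolate the frozen repulsive core of a CBSPL potential
#'
#' The Newton-Raphson update excludes knots at \eqn{r \le r_{min}} (the
#' region is too poorly sampled to constrain them).  This refills those
#' knots by continuing the potential into the core with the repulsive
#' exponential \eqn{A e^{-B r}}.  The continuation is anchored at
#' \eqn{r_a}, the smallest separation whose spline value is determined
#' entirely by non-core knots: \eqn{A} and \eqn{B > 0} are chosen so the
#' exponential matches the spline's value \eqn{u_a} and slope \eqn{s_a}
#' there (\eqn{B = -s_a/u_a}), and the core knot values are then set by an
#' unconstrained least-squares fit of the spline to the exponential on a
#' fine grid over \eqn{(0, r_a]}.  The result is a single C2 spline, so
#' value and slope stay continuous across \eqn{r_{min}}, and the energy
#' rises monotonically toward \eqn{r \to 0}.  If the anchor slope is
#' non-repulsive (\eqn{s_a \ge 0}) or \eqn{u_a \le 0} makes the exponential
#' infeasible, a linear continuation is used instead and a warning logged.
#'
#' @param pot `knot_potential` with at least two free knots above `r_min`.
#' @return `knot_potential` with core knots replaced.
#' @export
extrapolate_core <- function(pot) {
  if (length(pot$core_idx) == 0L) return(pot)
  if (length(free_knot_idx(pot)) < 2L)
    stop("need at least two free knots above r_min to extrapolate the core")
  ci <- pot$core_idx
  nk <- length(pot$knots)
  ra <- length(ci) * pot$dr         # first segment free of core knots
  ua <- cbspl_evaluate(pot, ra)
  sa <- -cbspl_force(pot, ra)       # du/dr at the anchor

  if (sa < 0 && ua > 0) {
    B <- min(-sa / ua, 200 / ra)    # cap keeps exp() finite at r -> 0
    A <- ua * exp(B * ra)
    target <- function(r) A * exp(-B * r)
  } else {
    warning("non-repulsive value/slope at the core anchor; using linear continuation")
    target <- function(r) ua + sa * (r - ra)
  }

  # control points set to the target values at the knot positions: the
  # variation-diminishing property of B-splines then makes the core
  # monotone, with no ringing even for very steep exponentials
  pot$knots[ci] <- target(pot$r_knots[ci])
  pot
}
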