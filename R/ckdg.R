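#' CKDg analytic pair potential
#'
#' A modified Lennard-Jones form with six free parameters: a WCA-like
#' repulsive branch, a cosine-squared smoothed attraction of depth `eps` and
#' width `w_c`, and a shifted Gaussian bump of amplitude `h`, mean `p` and
#' width `s`:
#' \deqn{u(r) = u_{CKD}(r) + h e^{-(r-p)^2/2s^2} - h e^{-(r_c-p)^2/2s^2}}
#' where the Gaussian shift makes the bump vanish continuously at its cutoff
#' \eqn{r_c} (and is clamped to zero beyond it, keeping the potential finite
#' ranged).  The LJ split radius is fixed at \eqn{r_{c,LJ} = 2^{1/6}\sigma}
#' and \eqn{\epsilon} is subtracted from the repulsive branch so the
#' potential is continuous with minimum \eqn{-\epsilon}; set
#' `strict = TRUE` for the raw un-shifted repulsive branch (which jumps by
#' \eqn{\epsilon} at \eqn{r_{c,LJ}}).
#'
#' @param sigma,eps LJ size and well depth (`sigma > 0`; `eps = 0`
#'   degenerates to the pure shifted Gaussian).
#' @param w_c width of the cosine-squared attractive well; `> 0`.
#' @param h,p,s Gaussian amplitude, mean and width (`s > 0`).
#' @param r_c Gaussian cutoff radius; defaults to `2^(1/6)*sigma + w_c`
#'   (the end of the attractive well) and must satisfy
#'   `r_c >= 2^(1/6)*sigma + w_c`.
#' @param strict keep the printed discontinuous repulsive branch.
#' @return object of class `ckdg_params`.
#' @export
ckdg_params <- function(sigma, eps, w_c, h = 0, p = 0, s = 1,
                        r_c = NULL, strict = FALSE) {
  stopifnot(sigma > 0, eps >= 0, w_c > 0, s > 0)
  r_c_lj <- 2^(1 / 6) * sigma
  if (is.null(r_c)) r_c <- r_c_lj + w_c
  if (r_c_lj + w_c > r_c + 1e-12)
    stop("gaussian cutoff r_c must not be smaller than r_c_lj + w_c")
  structure(list(sigma = sigma, eps = eps, w_c = w_c, h = h, p = p, s = s,
                 r_c_lj = r_c_lj, r_c = r_c, strict = strict),
            class = "ckdg_params")
}

#' @export
print.ckdg_params <- function(x, ...) {
  cat(sprintf(
    "CKDg potential: sigma=%g eps=%g w_c=%g h=%g p=%g s=%g (r_c,LJ=%g r_c=%g)\n",
    x$sigma, x$eps, x$w_c, x$h, x$p, x$s, x$r_c_lj, x$r_c))
  invisible(x)
}

#' Number of free parameters of a potential
#'
#' Six for the CKDg form; the count of non-frozen knots for a CBSPL
#' potential.
#' @param pot potential object.
#' @return integer.
#' @export
n_params <- function(pot) UseMethod("n_params")

#' @export
n_params.ckdg_params <- function(pot) 6L

#' @export
n_params.knot_potential <- function(pot) length(free_knot_idx(pot))

#' The 6-vector of free CKDg parameters
#' @param pot `ckdg_params`.
#' @return named numeric vector (sigma, eps, w_c, h, p, s).
#' @export
ckdg_vector <- function(pot) {
  c(sigma = pot$sigma, eps = pot$eps, w_c = pot$w_c,
    h = pot$h, p = pot$p, s = pot$s)
}

#' Rebuild CKDg parameters from a 6-vector
#' @param x numeric vector (sigma, eps, w_c, h, p, s).
#' @param template `ckdg_params` supplying `r_c` policy and `strict` flag.
#' @return `ckdg_params`.
#' @export
ckdg_from_vector <- function(x, template = NULL) {
  strict <- if (is.null(template)) FALSE else template$strict
  ckdg_params(x[[1]], x[[2]], x[[3]], x[[4]], x[[5]], x[[6]], strict = strict)
}

#' Evaluate the CKDg potential
#' @param pot `ckdg_params`.
#' @param r separations, all `> 0`.
#' @return numeric vector of energies.
#' @export
ckdg_evaluate <- function(pot, r) {
  if (any(r <= 0)) stop("separation r must be positive")
  sr6 <- (pot$sigma / r)^6
  shift <- if (pot$strict) 0 else pot$eps
  u <- ifelse(r < pot$r_c_lj,
              4 * pot$eps * (sr6^2 - sr6 + 0.25) - shift,
              ifelse(r < pot$r_c_lj + pot$w_c,
                     -pot$eps *
                       cos(pi * (r - pot$r_c_lj) / (2 * pot$w_c))^2,
                     0))
  g <- ifelse(r <= pot$r_c,
              pot$h * exp(-(r - pot$p)^2 / (2 * pot$s^2)) -
                pot$h * exp(-(pot$r_c - pot$p)^2 / (2 * pot$s^2)),
              0)
  u + g
}

#' Force of the CKDg potential
#' @inheritParams ckdg_evaluate
#' @return numeric vector, \eqn{f = -du/dr}.
#' @export
ckdg_force <- function(pot, r) {
  if (any(r <= 0)) stop("separation r must be positive")
  sr6 <- (pot$sigma / r)^6
  x <- pi * (r - pot$r_c_lj) / (2 * pot$w_c)
  dudr <- ifelse(r < pot$r_c_lj,
                 4 * pot$eps * (-12 * sr6^2 + 6 * sr6) / r,
                 ifelse(r < pot$r_c_lj + pot$w_c,
                        pot$eps * sin(2 * x) * pi / (2 * pot$w_c),
                        0))
  dgdr <- ifelse(r <= pot$r_c,
                 -pot$h * (r - pot$p) / pot$s^2 *
                   exp(-(r - pot$p)^2 / (2 * pot$s^2)),
                 0)
  -(dudr + dgdr)
}
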