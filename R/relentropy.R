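# Concatenated parameter layout over a named list of CBSPL potentials:
# offsets are 0-based (C++ side), free mask collects non-frozen knots.
param_layout <- function(pots) {
  offs <- integer(length(pots))
  o <- 0L
  free <- logical(0)
  for (i in seq_along(pots)) {
    offs[i] <- o
    nk <- length(pots[[i]]$knots)
    mask <- rep(FALSE, nk)
    mask[free_knot_idx(pots[[i]])] <- TRUE
    free <- c(free, mask)
    o <- o + nk
  }
  list(offsets = offs, total = o, free = which(free))
}

lambda_vector <- function(pots) {
  unlist(lapply(pots, `[[`, "knots"), use.names = FALSE)
}

set_lambda <- function(pots, lambda) {
  lay <- param_layout(pots)
  for (i in seq_along(pots)) {
    nk <- length(pots[[i]]$knots)
    pots[[i]]$knots <- lambda[lay$offsets[i] + seq_len(nk)]
  }
  pots
}

#' Ensemble averages of CG energy derivatives
#'
#' For pair potentials linear in their parameters (CBSPL), the derivative
#' of the total CG energy with respect to knot \eqn{c_k} is the sum over all
#' site pairs of the B-spline basis weight of the pair distance.  This
#' accumulates, per frame, those sums for every knot of every pair
#' potential, and returns their ensemble mean, second-moment matrix and the
#' per-frame matrix itself (needed for Monte-Carlo error estimates).
#' Pairs at \eqn{r \le r_{min}} of their potential are skipped (frozen
#' core), as are pairs beyond the cutoff.  Second parameter derivatives are
#' identically zero for the linear CBSPL form.
#'
#' @param traj bead-coordinate `trajectory`.
#' @param pots named list of `knot_potential`s keyed by species pair.
#' @return object of class `deriv_averages`: `mean` (length = total knot
#'   count), `second` (matrix \eqn{\langle d_i d_j \rangle}), `n_frames`,
#'   `per_frame` (frames x knots matrix), `layout`.
#' @export
accumulate_derivatives <- function(traj, pots) {
  if (length(traj$frames) == 0L) stop("empty trajectory")
  lay <- param_layout(pots)
  sp <- sort(unique(traj$species))
  n <- length(sp)
  pair_idx <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    key <- pair_key(sp[i], sp[j])
    w <- match(key, names(pots))
    if (is.na(w)) stop(sprintf("no potential for species pair %s", key))
    pair_idx[i, j] <- w
  }
  meta <- lapply(seq_along(pots), function(i)
    list(dr = pots[[i]]$dr, rcut = pots[[i]]$r_cut, rmin = pots[[i]]$r_min,
         offset = lay$offsets[i]))
  D <- cpp_deriv_frames(traj$frames, match(traj$species, sp), traj$mol,
                        traj$L, meta, pair_idx, lay$total)
  structure(list(mean = colMeans(D), second = crossprod(D) / nrow(D),
                 n_frames = nrow(D), per_frame = D, layout = lay),
            class = "deriv_averages")
}

#' @export
print.deriv_averages <- function(x, ...) {
  cat(sprintf("derivative averages: %d parameters, %d frames\n",
              length(x$mean), x$n_frames))
  invisible(x)
}

#' Relative-entropy gradient
#'
#' \eqn{\nabla_\lambda S_{rel} = \beta\langle\partial U/\partial\lambda
#' \rangle_{AA} - \beta\langle\partial U/\partial\lambda\rangle_{CG}}.
#' Components for frozen knots are excluded when `free` indices are given.
#'
#' @param aa,cg `deriv_averages` from the mapped reference and the CG
#'   ensemble.
#' @param beta inverse temperature.
#' @param free indices of free parameters (default: all).
#' @return gradient vector over the free parameters.
#' @export
srel_gradient <- function(aa, cg, beta, free = NULL) {
  if (length(aa$mean) != length(cg$mean))
    stop("dimension mismatch between AA and CG derivative averages")
  g <- beta * (aa$mean - cg$mean)
  if (!is.null(free)) g <- g[free]
  g
}

#' Monte-Carlo standard error of the relative-entropy gradient
#'
#' Per-component standard error of the AA minus CG derivative-average
#' difference, from block means (block averaging absorbs the MC chain's
#' autocorrelation).
#'
#' @inheritParams srel_gradient
#' @param block frames per block.
#' @return standard-error vector over the free parameters.
#' @export
srel_gradient_se <- function(aa, cg, beta, free = NULL, block = 10L) {
  block_se2 <- function(D) {
    nb <- floor(nrow(D) / block)
    if (nb < 2L) stop("too few frames for block error estimate")
    bm <- vapply(seq_len(nb), function(b)
      colMeans(D[(b - 1L) * block + seq_len(block), , drop = FALSE]),
      numeric(ncol(D)))
    apply(t(bm), 2, var) / nb
  }
  se <- beta * sqrt(block_se2(aa$per_frame) + block_se2(cg$per_frame))
  if (!is.null(free)) se <- se[free]
  se
}

#' Relative-entropy Hessian
#'
#' All four ensemble-average terms: the AA and CG averages of the second
#' parameter derivatives (identically zero for the linear CBSPL form) and
#' the CG-ensemble fluctuation term
#' \eqn{\beta^2(\langle d_i d_j\rangle_{CG} -
#' \langle d_i\rangle_{CG}\langle d_j\rangle_{CG})}, which for CBSPL makes
#' \eqn{H} a positive-semidefinite covariance matrix.
#'
#' @param cg CG-ensemble `deriv_averages`.
#' @param aa AA-ensemble `deriv_averages` (supplies the second-derivative
#'   term; may be `NULL` for linear forms).
#' @param beta inverse temperature.
#' @param free indices of free parameters (default: all).
#' @param d2_aa,d2_cg optional matrices of second-parameter-derivative
#'   averages for nonlinear forms; zero when omitted.
#' @return Hessian matrix over the free parameters.
#' @export
srel_hessian <- function(cg, aa = NULL, beta, free = NULL,
                         d2_aa = NULL, d2_cg = NULL) {
  n <- length(cg$mean)
  if (!is.null(aa) && length(aa$mean) != n)
    stop("dimension mismatch between AA and CG derivative averages")
  H <- beta^2 * (cg$second - tcrossprod(cg$mean))
  if (!is.null(d2_aa)) H <- H + beta * d2_aa
  if (!is.null(d2_cg)) H <- H - beta * d2_cg
  H <- (H + t(H)) / 2
  if (!is.null(free)) H <- H[free, free, drop = FALSE]
  H
}

#' One Newton-Raphson update of the free parameters
#'
#' \eqn{\lambda \leftarrow \lambda - \chi H^{-1}\nabla}, solved by a
#' symmetric (Cholesky) factorization.  A numerically singular Hessian gets
#' a ridge \eqn{\tau I} with \eqn{\tau = 10^{-8}\,\mathrm{tr}(H)/n} (logged
#' via `message`); if the solve still fails the iteration aborts.
#'
#' @param lambda free-parameter vector.
#' @param grad gradient over the free parameters.
#' @param hess Hessian over the free parameters.
#' @param chi relaxation parameter in `(0, 1]` (`chi = 0` returns `lambda`
#'   unchanged).
#' @param step_max optional cap on the largest component of the raw Newton
#'   displacement (energy units); the whole step is rescaled if it is
#'   exceeded.  Poorly sampled knot directions make the sampled-covariance
#'   Hessian nearly flat, and an uncapped step along them can throw the
#'   potential far outside the region the ensembles inform.
#' @return updated parameter vector.
#' @export
newton_step <- function(lambda, grad, hess, chi = 1, step_max = Inf) {
  stopifnot(length(grad) == length(lambda),
            all(dim(hess) == length(lambda)))
  if (chi == 0) return(lambda)
  step <- tryCatch(drop(chol2inv(chol(hess)) %*% grad),
                   error = function(e) NULL)
  if (is.null(step)) {
    tau <- 1e-8 * sum(diag(hess)) / nrow(hess)
    message(sprintf("singular Hessian: applying ridge tau = %g", tau))
    Hr <- hess + tau * diag(nrow(hess))
    step <- tryCatch(drop(chol2inv(chol(Hr)) %*% grad),
                     error = function(e)
                       stop("Hessian singular even after ridge"))
  }
  big <- max(abs(step))
  if (is.finite(step_max) && big > step_max) step <- step * step_max / big
  lambda - chi * step
}

#' Convergence errors of the iteration
#'
#' The parameter error \eqn{\epsilon_\lambda = \sum_i
#' (\lambda_i^k - \lambda_i^{k-1})^2}, the potential error
#' \eqn{\epsilon_u = \sum_{pots}\sum_{grid} (u^k(r_j) - u^{k-1}(r_j))^2}
#' and the weighted total \eqn{\epsilon_{tot} = w_\lambda \epsilon_\lambda +
#' w_u \epsilon_u} -- sums of squares, no square root.
#'
#' @param lambda_k,lambda_prev parameter vectors of two iterates.
#' @param tables_k,tables_prev lists of `potential_table`s on matching
#'   grids.
#' @param w_lambda,w_u error weights.
#' @return named numeric vector `(eps_lambda, eps_u, eps_tot)`.
#' @export
convergence_errors <- function(lambda_k, lambda_prev, tables_k, tables_prev,
                               w_lambda = 0, w_u = 1) {
  if (length(lambda_k) != length(lambda_prev))
    stop("parameter vectors differ in length")
  eps_l <- sum((lambda_k - lambda_prev)^2)
  eps_u <- 0
  for (i in seq_along(tables_k)) {
    if (length(tables_k[[i]]$r) != length(tables_prev[[i]]$r) ||
        max(abs(tables_k[[i]]$r - tables_prev[[i]]$r)) > 1e-10)
      stop("potential-table grids do not match between iterates")
    eps_u <- eps_u + sum((tables_k[[i]]$u - tables_prev[[i]]$u)^2)
  }
  c(eps_lambda = eps_l, eps_u = eps_u,
    eps_tot = w_lambda * eps_l + w_u * eps_u)
}

#' Relative-entropy minimization over CBSPL potentials
#'
#' The outer Newton-Raphson loop: at each iteration a CG ensemble is
#' sampled by [mc_nvt()] with the current potentials, derivative averages
#' are accumulated in both ensembles (the mapped-reference averages are
#' computed once and cached), the gradient and Hessian are assembled over
#' the free knots, the Newton update is applied, the frozen core is
#' refilled by [extrapolate_core()], and the convergence errors are
#' evaluated.  Iterations stop when \eqn{\epsilon_{tot}} falls below `tol`
#' or after `max_iter` iterations; because the CG simulations are
#' stochastic, the reported potentials average the knot vectors of the
#' trailing `window` iterations.  If \eqn{\epsilon_{tot}} grows for 3
#' consecutive iterations the relaxation `chi` is halved and the iterate
#' reset to the best seen; after 3 halvings the run aborts (flagged in the
#' report).
#'
#' @param ref bead-coordinate reference `trajectory` (already mapped).
#' @param state [thermo_state()].
#' @param r_cut,dr CBSPL grid for every pair potential (scalar or named per
#'   pair).
#' @param r_min core radius per pair; `NULL` estimates it per pair as the
#'   smallest reference-RDF bin center with `g > 0`.
#' @param potentials optional initial `knot_potential` list; the default
#'   initial guess fits the CBSPL form to the Boltzmann-inverted reference
#'   RDF of each pair.
#' @param chi Newton relaxation in `(0, 1]`.
#' @param tol convergence tolerance on \eqn{\epsilon_{tot}}.
#' @param max_iter maximum iterations.
#' @param window trailing-average window for the reported potentials.
#' @param w_lambda,w_u convergence-error weights.
#' @param sampler list of [mc_nvt()] settings for the per-iteration CG
#'   runs: `n_steps`, `max_disp`, `equil_fraction`, `stride`, and `start`
#'   (a `frame`; default = last reference frame).
#' @param rdf_dr bin width for reference RDFs (initial guess and `r_min`
#'   estimation).
#' @param step_max Newton step cap passed to [newton_step()]; default one
#'   \eqn{k_B T} per knot.
#' @param seed base seed; iteration `k` samples with `seed + k` (recorded
#'   in the report for exact reruns).
#' @param iter_offset label offset for resumed runs: iteration `k` is
#'   reported and seeded as `iter_offset + k`.
#' @param verbose print per-iteration errors.
#' @return object of class `re_result`: `potentials` (trailing-window
#'   average), `last_potentials`, `converged`, `errors` (data.frame per
#'   iteration), `seeds`, `chi_final`, `history` (knot matrix), `aborted`.
#' @export
re_minimize <- function(ref, state, r_cut, dr, r_min = NULL,
                        potentials = NULL, chi = 1, tol = 1e-4,
                        max_iter = 20L, window = 5L, w_lambda = 0, w_u = 1,
                        sampler = list(), rdf_dr = NULL, seed = 42L,
                        step_max = NULL, iter_offset = 0L, verbose = FALSE) {
  if (is.null(step_max)) step_max <- state$k_B * state$temperature
  sp <- sort(unique(ref$species))
  pairs <- character(0)
  for (i in seq_along(sp)) for (j in i:length(sp))
    pairs <- c(pairs, pair_key(sp[i], sp[j]))
  get_par <- function(x, key) if (length(x) > 1L || !is.null(names(x)))
    x[[key]] else x
  if (is.null(rdf_dr)) rdf_dr <- min(unlist(dr)) / 2

  # reference RDFs: r_min estimation and initial PMF guess
  ref_rdfs <- lapply(pairs, function(key) {
    ab <- strsplit(key, "-")[[1]]
    compute_rdf(ref, ab, r_max = min(max(unlist(r_cut)), ref$L / 2),
                dr = rdf_dr)
  })
  names(ref_rdfs) <- pairs

  if (is.null(potentials)) {
    potentials <- lapply(pairs, function(key) {
      g <- ref_rdfs[[key]]
      rmin_k <- if (!is.null(r_min)) get_par(r_min, key)
                else g$r[min(which(g$g > 0))]
      skel <- cbspl_knot_grid(get_par(r_cut, key), get_par(dr, key),
                              r_min = rmin_k, pair = key)
      pmf <- boltzmann_invert(g, state$temperature, state$k_B)
      extrapolate_core(fit_cbspl(pmf, skel))
    })
    names(potentials) <- pairs
  }

  lay <- param_layout(potentials)
  free <- lay$free
  aa <- accumulate_derivatives(ref, potentials)

  smp <- utils::modifyList(
    list(n_steps = 4e5, max_disp = 0.15, equil_fraction = 0.25,
         stride = NULL, n_frames = 400L, start = NULL), sampler)
  if (is.null(smp$stride))
    smp$stride <- max(1L, floor(smp$n_steps * (1 - smp$equil_fraction) /
                                  smp$n_frames))
  start <- if (is.null(smp$start)) get_frame(ref, length(ref$frames))
           else smp$start

  # convergence tables cover the optimized region (r_min, r_cut]: the
  # extrapolated core is excluded so its large absolute values cannot
  # dominate the potential error
  tab_dr <- min(vapply(potentials, `[[`, numeric(1), "dr")) / 4
  tab_of <- function(pots) lapply(pots, function(p) {
    r <- seq(ceiling(p$r_min / tab_dr) * tab_dr + tab_dr, p$r_cut,
             by = tab_dr)
    potential_table(r, cbspl_evaluate(p, r), cbspl_force(p, r),
                    pair = p$pair, r_cut = p$r_cut)
  })

  lambda <- lambda_vector(potentials)
  errors <- data.frame(iteration = integer(0), eps_lambda = numeric(0),
                       eps_u = numeric(0), eps_tot = numeric(0),
                       acceptance = numeric(0), hess_min_eig = numeric(0),
                       seed = integer(0))
  history <- list()
  grow <- 0L; halvings <- 0L; aborted <- FALSE
  best <- list(eps = Inf, lambda = lambda)
  prev_tabs <- tab_of(potentials)
  converged <- FALSE

  for (k in seq_len(max_iter)) {
    it <- iter_offset + k
    it_seed <- seed + it
    cg_traj <- mc_nvt(start, potentials, state, n_steps = smp$n_steps,
                      max_disp = smp$max_disp, seed = it_seed,
                      equil_fraction = smp$equil_fraction,
                      stride = smp$stride)
    start <- attr(cg_traj, "final")
    cg <- accumulate_derivatives(cg_traj, potentials)

    g <- srel_gradient(aa, cg, state$beta, free = free)
    H <- srel_hessian(cg, aa, state$beta, free = free)
    h_min <- min(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
    lambda_new <- lambda
    lambda_new[free] <- newton_step(lambda[free], g, H, chi = chi,
                                    step_max = step_max)
    potentials <- set_lambda(potentials, lambda_new)
    potentials <- lapply(potentials, extrapolate_core)
    lambda_new <- lambda_vector(potentials)

    tabs <- tab_of(potentials)
    eps <- convergence_errors(lambda_new[free], lambda[free], tabs,
                              prev_tabs, w_lambda, w_u)
    errors <- rbind(errors, data.frame(
      iteration = it, eps_lambda = eps[["eps_lambda"]],
      eps_u = eps[["eps_u"]], eps_tot = eps[["eps_tot"]],
      acceptance = attr(cg_traj, "acceptance"), hess_min_eig = h_min,
      seed = it_seed))
    if (verbose)
      cat(sprintf("iter %3d  eps_tot %.3e  acc %.2f\n", it,
                  eps[["eps_tot"]], attr(cg_traj, "acceptance")))

    lambda <- lambda_new
    prev_tabs <- tabs
    history[[k]] <- lambda

    if (eps[["eps_tot"]] < best$eps)
      best <- list(eps = eps[["eps_tot"]], lambda = lambda)
    n_err <- nrow(errors)
    grew <- n_err >= 2L && errors$eps_tot[n_err] > errors$eps_tot[n_err - 1L]
    if (!grew) {
      grow <- 0L
    } else {
      grow <- grow + 1L
      if (grow >= 3L) {
        halvings <- halvings + 1L
        if (halvings > 3L) { aborted <- TRUE; break }
        chi <- chi / 2
        lambda <- best$lambda
        potentials <- set_lambda(potentials, lambda)
        prev_tabs <- tab_of(potentials)
        grow <- 0L
        if (verbose) cat(sprintf("divergence guard: chi halved to %g\n", chi))
      }
    }
    if (eps[["eps_tot"]] < tol) { converged <- TRUE; break }
  }

  win <- utils::tail(history, window)
  lambda_avg <- Reduce(`+`, win) / length(win)
  final <- lapply(set_lambda(potentials, lambda_avg), extrapolate_core)

  structure(list(potentials = final,
                 last_potentials = set_lambda(potentials, lambda),
                 converged = converged, aborted = aborted,
                 errors = errors, seeds = errors$seed,
                 chi_final = chi, window = length(win),
                 ref_rdfs = ref_rdfs, final_frame = start,
                 history = do.call(rbind, history)),
            class = "re_result")
}

#' @export
print.re_result <- function(x, ...) {
  cat(sprintf("relative-entropy minimization: %d iterations, %s\n",
              nrow(x$errors),
              if (x$aborted) "ABORTED (divergence guard)"
              else if (x$converged) "converged"
              else "max iterations reached"))
  if (nrow(x$errors))
    cat(sprintf("  final eps_tot = %.3e (chi = %g)\n",
                x$errors$eps_tot[nrow(x$errors)], x$chi_final))
  invisible(x)
}
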