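#' Downhill-simplex optimizer state
#'
#' `n + 1` parameter vertices with their penalty values and the four
#' transformation coefficients: reflection `alpha`, expansion `gamma`,
#' contraction `rho` and reduction `sigma` (defaults 1, 2, 0.5, 0.5).
#' Vertices whose penalty has not been evaluated yet are `pending`.
#'
#' @param vertices `(n+1) x n` matrix (rows = vertices) or list of vectors.
#' @param penalty numeric vector of penalties (`NA` = pending).
#' @param alpha reflection coefficient, `> 0`.
#' @param gamma expansion coefficient, `> 1`.
#' @param rho contraction coefficient in `(0, 1)`.
#' @param sigma reduction coefficient.
#' @return object of class `simplex_state`.
#' @export
simplex_state <- function(vertices, penalty = NULL, alpha = 1, gamma = 2,
                          rho = 0.5, sigma = 0.5) {
  if (is.list(vertices)) vertices <- do.call(rbind, vertices)
  n <- ncol(vertices)
  if (nrow(vertices) != n + 1L)
    stop(sprintf("need n+1 = %d vertices of dimension n = %d, got %d",
                 n + 1L, n, nrow(vertices)))
  if (alpha <= 0) stop("reflection coefficient alpha must be > 0")
  if (gamma <= 1) stop("expansion coefficient gamma must be > 1")
  if (rho <= 0 || rho >= 1) stop("contraction coefficient rho must lie in (0, 1)")
  if (is.null(penalty)) penalty <- rep(NA_real_, n + 1L)
  stopifnot(length(penalty) == n + 1L)
  structure(list(vertices = vertices, penalty = penalty,
                 status = ifelse(is.na(penalty), "pending", "done"),
                 alpha = alpha, gamma = gamma, rho = rho, sigma = sigma,
                 iteration = 0L),
            class = "simplex_state")
}

#' @export
print.simplex_state <- function(x, ...) {
  cat(sprintf(
    "simplex state: n = %d, iteration %d, %d pending (alpha=%g gamma=%g rho=%g sigma=%g)\n",
    ncol(x$vertices), x$iteration, sum(x$status == "pending"),
    x$alpha, x$gamma, x$rho, x$sigma))
  if (all(x$status == "done"))
    cat(sprintf("  penalties: best %.6g, worst %.6g\n",
                min(x$penalty), max(x$penalty)))
  invisible(x)
}

#' Sort simplex vertices by penalty
#'
#' Ascending, stable (ties keep their original relative order).  Every
#' vertex must have been evaluated.
#' @param state `simplex_state`.
#' @return sorted `simplex_state`.
#' @export
sort_vertices <- function(state) {
  if (any(state$status == "pending"))
    stop("cannot sort: pending vertices must be evaluated first")
  ord <- order(state$penalty)          # radix order is stable
  state$vertices <- state$vertices[ord, , drop = FALSE]
  state$penalty <- state$penalty[ord]
  state$status <- state$status[ord]
  state
}

simplex_centroid <- function(state) {
  n <- ncol(state$vertices)
  colMeans(state$vertices[seq_len(n), , drop = FALSE])
}

#' Reflection of the worst vertex through the centroid of the rest
#'
#' \eqn{p_r = \bar p + \alpha(\bar p - p_{n+1})}; with \eqn{\alpha = 1}
#' this preserves the simplex volume.
#' @param state sorted `simplex_state`.
#' @return candidate parameter vector.
#' @export
reflect <- function(state) {
  pb <- simplex_centroid(state)
  pb + state$alpha * (pb - state$vertices[nrow(state$vertices), ])
}

#' Expansion along the reflection direction
#'
#' \eqn{p_e = \bar p + \gamma(\bar p - p_{n+1})}, \eqn{\gamma > 1}.
#' @inheritParams reflect
#' @return candidate parameter vector.
#' @export
expand <- function(state) {
  pb <- simplex_centroid(state)
  pb + state$gamma * (pb - state$vertices[nrow(state$vertices), ])
}

#' Contraction toward the centroid
#'
#' \eqn{p_c = \bar p + \rho(\bar p - p_{n+1})}, \eqn{\rho \in (0, 1)}.
#' @inheritParams reflect
#' @return candidate parameter vector.
#' @export
contract <- function(state) {
  pb <- simplex_centroid(state)
  pb + state$rho * (pb - state$vertices[nrow(state$vertices), ])
}

#' Reduction of the whole simplex around the best vertex
#'
#' Every vertex but the best is replaced by \eqn{\sigma(p_i + p_1)} and
#' marked pending.  With \eqn{\sigma = 0.5} this is the midpoint toward the
#' best vertex (identical to the conventional
#' \eqn{p_1 + \sigma(p_i - p_1)}); for other \eqn{\sigma} the summed form
#' is used as printed and a message notes it.
#' @inheritParams reflect
#' @return `simplex_state` with replaced, pending vertices.
#' @export
reduce_simplex <- function(state) {
  if (state$sigma != 0.5)
    message("reduction with sigma != 0.5 uses the summed form sigma*(p_i + p_1)")
  p1 <- state$vertices[1, ]
  for (i in 2:nrow(state$vertices)) {
    state$vertices[i, ] <- state$sigma * (state$vertices[i, ] + p1)
    state$penalty[i] <- NA_real_
    state$status[i] <- "pending"
  }
  state
}

eval_penalty <- function(evaluator, x) {
  y <- tryCatch(evaluator(x), error = function(e) {
    warning(sprintf("penalty evaluation failed (%s): vertex marked +Inf",
                    conditionMessage(e)))
    Inf
  })
  if (!is.finite(y) && !is.infinite(y)) Inf else y
}

#' One polytope transformation step
#'
#' The decision flow: reflect; if the reflected penalty beats the best
#' vertex, try an expansion and keep the better of the two; if it is worse
#' than the worst vertex, contract, and if even the contraction does not
#' improve on the worst vertex, reduce the whole simplex (re-evaluating the
#' shrunken vertices) and resume with a reflection on the next call.
#' Otherwise the reflected point simply replaces the worst vertex.  The
#' state is resorted before returning.
#'
#' @param state fully evaluated `simplex_state`.
#' @param evaluator `function(params) -> penalty`; failures score `+Inf`.
#' @return updated `simplex_state` (field `last_move` records the move:
#'   reflect / expand / contract / reduce).
#' @export
simplex_step <- function(state, evaluator) {
  state <- sort_vertices(state)
  worst <- nrow(state$vertices)
  y1 <- state$penalty[1]
  yw <- state$penalty[worst]

  pr <- reflect(state)
  yr <- eval_penalty(evaluator, pr)
  if (yr < y1) {
    pe <- expand(state)
    ye <- eval_penalty(evaluator, pe)
    if (ye < yr) { cand <- pe; yc <- ye; move <- "expand" }
    else         { cand <- pr; yc <- yr; move <- "reflect" }
  } else if (yr > yw) {
    pc <- contract(state)
    yc2 <- eval_penalty(evaluator, pc)
    if (yc2 <= yw) { cand <- pc; yc <- yc2; move <- "contract" }
    else {
      state <- reduce_simplex(state)
      for (i in which(state$status == "pending")) {
        state$penalty[i] <- eval_penalty(evaluator, state$vertices[i, ])
        state$status[i] <- "done"
      }
      state <- sort_vertices(state)
      state$iteration <- state$iteration + 1L
      state$last_move <- "reduce"
      return(state)
    }
  } else {
    cand <- pr; yc <- yr; move <- "reflect"
  }
  state$vertices[worst, ] <- cand
  state$penalty[worst] <- yc
  state <- sort_vertices(state)
  state$iteration <- state$iteration + 1L
  state$last_move <- move
  state
}

#' Run the simplex to convergence on an arbitrary objective
#'
#' Evaluates any pending vertices, then applies [simplex_step()] until the
#' penalty spread `y_{n+1} - y_1` falls below `tol` or `max_steps` is
#' reached.
#'
#' @param state `simplex_state` (pending vertices allowed).
#' @param evaluator `function(params) -> penalty`.
#' @param max_steps maximum polytope steps.
#' @param tol penalty-spread tolerance.
#' @return list `state` (final), `trace` (data.frame of per-step best /
#'   worst penalties and moves), `converged`.
#' @export
simplex_run <- function(state, evaluator, max_steps = 200L, tol = 0) {
  for (i in which(state$status == "pending")) {
    state$penalty[i] <- eval_penalty(evaluator, state$vertices[i, ])
    state$status[i] <- "done"
  }
  state <- sort_vertices(state)
  trace <- data.frame(step = 0L, best = state$penalty[1],
                      worst = max(state$penalty), move = "init",
                      stringsAsFactors = FALSE)
  converged <- FALSE
  for (s in seq_len(max_steps)) {
    state <- simplex_step(state, evaluator)
    trace <- rbind(trace, data.frame(
      step = s, best = state$penalty[1], worst = max(state$penalty),
      move = state$last_move, stringsAsFactors = FALSE))
    if (max(state$penalty) - state$penalty[1] < tol) {
      converged <- TRUE
      break
    }
  }
  list(state = state, trace = trace, converged = converged)
}

#' RDF + pressure penalty for targeted coarse-graining
#'
#' \eqn{y = \sum_{r_i \in [r_{lo}, r_{hi}]} |g_{CG}(r_i) - g_{AA}(r_i)| +
#' a\,|p_{CG} - p_{AA}|}; with `a = 0` the penalty is RDF-only.
#'
#' @param g_cg CG-ensemble [rdf] (same bin grid as the target over the
#'   comparison range).
#' @param spec [penalty_spec()].
#' @param p_cg CG pressure (ignored when `a = 0`).
#' @return penalty value.
#' @export
penalty_rdf_pressure <- function(g_cg, spec, p_cg = NA_real_) {
  tg <- spec$target_rdf
  sel_t <- which(tg$r >= spec$r_lo - 1e-12 & tg$r <= spec$r_hi + 1e-12)
  sel_c <- which(g_cg$r >= spec$r_lo - 1e-12 & g_cg$r <= spec$r_hi + 1e-12)
  if (length(sel_t) != length(sel_c) ||
      max(abs(tg$r[sel_t] - g_cg$r[sel_c])) > 1e-9)
    stop("RDF bin grids do not match over the comparison range")
  y <- sum(abs(g_cg$g[sel_c] - tg$g[sel_t]))
  if (spec$a > 0) y <- y + spec$a * abs(p_cg - spec$target_pressure)
  y
}

#' Penalty specification for [penalty_rdf_pressure()]
#'
#' @param target_rdf reference [rdf].
#' @param r_lo,r_hi RDF comparison range (bin centers inside the target
#'   grid).
#' @param a pressure weight (inverse-pressure units); `a = 0` switches the
#'   pressure term off.
#' @param target_pressure reference pressure (required when `a > 0`).
#' @return object of class `penalty_spec`.
#' @export
penalty_spec <- function(target_rdf, r_lo = 0, r_hi = max(target_rdf$r),
                         a = 0, target_pressure = NA_real_) {
  stopifnot(r_lo < r_hi, a >= 0)
  if (a > 0 && is.na(target_pressure))
    stop("a > 0 requires a target pressure")
  structure(list(target_rdf = target_rdf, r_lo = r_lo, r_hi = r_hi, a = a,
                 target_pressure = target_pressure),
            class = "penalty_spec")
}

#' Advance the state-file optimization cycle by one communication round
#'
#' The decoupled counterpart of [simplex_step()] for workflows where the
#' penalty of each parameter set is evaluated externally (a separate
#' sampling run) and communicated back through the state file.  The state
#' carries at most one pending *trial* point:
#'
#' * no trial stored: a reflection trial is proposed -- evaluate it next;
#' * an evaluated reflection: either accepted, or an expansion/contraction
#'   trial is proposed per the decision flow;
#' * an evaluated expansion: the better of expansion and reflection
#'   replaces the worst vertex;
#' * an evaluated contraction: accepted if it improves on the worst
#'   vertex, otherwise the simplex is reduced and its shrunken vertices
#'   marked pending.
#'
#' Driving this function to completion visits exactly the same simplex
#' states as [simplex_step()] with an inline evaluator.
#'
#' @param state evaluated `simplex_state`, possibly carrying a `trial`.
#' @return updated `simplex_state`; inspect [simplex_next_action()] and
#'   `state$trial` to see what must be evaluated next.
#' @export
simplex_advance <- function(state) {
  if (any(state$status == "pending"))
    stop("pending vertices must be evaluated before advancing")
  worst <- nrow(state$vertices)
  if (is.null(state$trial)) {
    state <- sort_vertices(state)
    state$trial <- list(stage = "reflect", point = reflect(state),
                        penalty = NA_real_, y_reflect = NA_real_,
                        p_reflect = NULL)
    return(state)
  }
  tr <- state$trial
  if (is.na(tr$penalty))
    stop("the trial point must be evaluated before advancing")
  y1 <- state$penalty[1]
  yw <- state$penalty[worst]
  accept <- function(state, point, y) {
    state$vertices[worst, ] <- point
    state$penalty[worst] <- y
    state <- sort_vertices(state)
    state$iteration <- state$iteration + 1L
    state$trial <- NULL
    state
  }
  if (tr$stage == "reflect") {
    if (tr$penalty < y1) {
      state$trial <- list(stage = "expand", point = expand(state),
                          penalty = NA_real_, y_reflect = tr$penalty,
                          p_reflect = tr$point)
      state
    } else if (tr$penalty > yw) {
      state$trial <- list(stage = "contract", point = contract(state),
                          penalty = NA_real_, y_reflect = tr$penalty,
                          p_reflect = tr$point)
      state
    } else {
      accept(state, tr$point, tr$penalty)
    }
  } else if (tr$stage == "expand") {
    if (tr$penalty < tr$y_reflect) accept(state, tr$point, tr$penalty)
    else accept(state, tr$p_reflect, tr$y_reflect)
  } else if (tr$stage == "contract") {
    if (tr$penalty <= yw) {
      accept(state, tr$point, tr$penalty)
    } else {
      state <- reduce_simplex(state)
      state$iteration <- state$iteration + 1L
      state$trial <- NULL
      state
    }
  } else stop(sprintf("unknown trial stage '%s'", tr$stage))
}

#' Write a simplex state file
#'
#' Line-based text format used to communicate parameters between the
#' optimizer and the sampling stage: a header with the dimension, the four
#' coefficients and the iteration counter, then one record per vertex
#' `id status p_1 ... p_n penalty` (penalty `nan` while pending).
#'
#' @param state `simplex_state`.
#' @param path file path.
#' @return path, invisibly.
#' @export
write_simplex_state <- function(state, path) {
  n <- ncol(state$vertices)
  hdr <- c("# simplex state",
           sprintf("n %d alpha %.17g gamma %.17g rho %.17g sigma %.17g iteration %d",
                   n, state$alpha, state$gamma, state$rho, state$sigma,
                   state$iteration))
  rows <- vapply(seq_len(nrow(state$vertices)), function(i) {
    pen <- if (is.na(state$penalty[i])) "nan"
           else sprintf("%.17g", state$penalty[i])
    paste(i, state$status[i],
          paste(sprintf("%.17g", state$vertices[i, ]), collapse = " "), pen)
  }, character(1))
  if (!is.null(state$trial)) {
    tr <- state$trial
    fmt <- function(x) if (is.na(x)) "nan" else sprintf("%.17g", x)
    rows <- c(rows, paste("trial", tr$stage,
                          paste(sprintf("%.17g", tr$point), collapse = " "),
                          fmt(tr$penalty), fmt(tr$y_reflect),
                          if (is.null(tr$p_reflect)) ""
                          else paste(sprintf("%.17g", tr$p_reflect),
                                     collapse = " ")))
  }
  writeLines(c(hdr, trimws(rows)), path)
  invisible(path)
}

#' Read a simplex state file
#' @param path file path written by [write_simplex_state()].
#' @return `simplex_state`.
#' @export
read_simplex_state <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  hdr <- strsplit(trimws(body[1]), "[ \t]+")[[1]]
  kv <- setNames(hdr[seq(2, length(hdr), 2)], hdr[seq(1, length(hdr), 2)])
  n <- as.integer(kv[["n"]])
  trial_line <- body[startsWith(trimws(body), "trial ")]
  body <- body[!startsWith(trimws(body), "trial ")]
  verts <- matrix(0, n + 1L, n)
  pen <- rep(NA_real_, n + 1L)
  status <- character(n + 1L)
  for (q in seq_len(n + 1L)) {
    ln <- body[1L + q]
    toks <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(toks) != n + 3L)
      stop(sprintf("malformed state-file line %d: expected %d fields, got %d",
                   which(lines == ln)[1], n + 3L, length(toks)))
    vals <- suppressWarnings(as.numeric(toks[3:(n + 3L)]))
    if (any(is.na(vals) & tolower(toks[3:(n + 3L)]) != "nan"))
      stop(sprintf("malformed numeric field on state-file line %d",
                   which(lines == ln)[1]))
    verts[q, ] <- vals[seq_len(n)]
    pen[q] <- vals[n + 1L]
    status[q] <- toks[2]
  }
  st <- simplex_state(verts, pen, alpha = as.numeric(kv[["alpha"]]),
                      gamma = as.numeric(kv[["gamma"]]),
                      rho = as.numeric(kv[["rho"]]),
                      sigma = as.numeric(kv[["sigma"]]))
  st$iteration <- as.integer(kv[["iteration"]])
  st$status <- ifelse(is.na(pen), "pending", "done")
  if (length(trial_line)) {
    toks <- strsplit(trimws(trial_line[1]), "[ \t]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks[-(1:2)]))
    st$trial <- list(stage = toks[2], point = vals[seq_len(n)],
                     penalty = vals[n + 1L], y_reflect = vals[n + 2L],
                     p_reflect = if (length(vals) >= 2L * n + 2L)
                       vals[n + 2L + seq_len(n)] else NULL)
  }
  st
}

#' The next workflow action for a state file
#'
#' `"evaluate"` while any vertex is pending, `"transform"` otherwise --
#' the evaluate/communicate cycle of the state-file workflow.
#' @param state `simplex_state`.
#' @return `"evaluate"` or `"transform"`.
#' @export
simplex_next_action <- function(state) {
  if (any(state$status == "pending")) "evaluate" else "transform"
}

#' Targeted coarse-graining of the CKDg form by downhill simplex
#'
#' For each pending vertex: rebuild the CKDg potential from the vertex
#' parameters, relax the shared start configuration by a greedy
#' zero-temperature Monte-Carlo descent (the stand-in for an energy
#' minimization: expansion moves can place vertices far from any stable
#' structure), sample an NVT ensemble, compute the RDF (and pressure when
#' the penalty weights it) and score with [penalty_rdf_pressure()].  All
#' vertices within one polytope step share the same sampler seed (common
#' random numbers reduce noise-induced misordering).  Parameters
#' `sigma, eps, w_c, s` are constrained positive by rejection (`+Inf`
#' penalty).
#'
#' @param vertices `(7 x 6)` matrix or list of 6-vectors
#'   `(sigma, eps, w_c, h, p, s)`.
#' @param spec [penalty_spec()].
#' @param start `frame` shared by every evaluation.
#' @param state [thermo_state()].
#' @param sampler list: `n_steps`, `max_disp`, `equil_fraction`, `stride`,
#'   `relax_steps` (greedy-descent budget), `table_dr`.
#' @param max_steps maximum polytope steps.
#' @param tol penalty-spread stopping tolerance.
#' @param seed base seed; polytope step `k` uses `seed + k`.
#' @param coeff list overriding `alpha`, `gamma`, `rho`, `sigma`.
#' @param init_state resume from an existing evaluated `simplex_state`
#'   (vertices/spec arguments are then ignored).
#' @param step_offset polytope steps already completed when resuming (keeps
#'   the per-step seeds of an uninterrupted run).
#' @param callback optional `function(state, step)` invoked after every
#'   polytope step (used for on-disk checkpointing).
#' @return list of class `simplex_result`: `best` (`ckdg_params`),
#'   `best_penalty`, `trace`, `state`, `converged`.
#' @export
simplex_minimize <- function(vertices, spec, start, state,
                             sampler = list(), max_steps = 50L, tol = 1e-3,
                             seed = 42L, coeff = list(), init_state = NULL,
                             step_offset = 0L, callback = NULL) {
  co <- utils::modifyList(list(alpha = 1, gamma = 2, rho = 0.5, sigma = 0.5),
                          coeff)
  smp <- utils::modifyList(
    list(n_steps = 2e4, max_disp = 0.15, equil_fraction = 0.25,
         stride = NULL, relax_steps = 2000L, table_dr = NULL), sampler)
  sstate <- if (is.null(init_state))
    simplex_state(vertices, alpha = co$alpha, gamma = co$gamma,
                  rho = co$rho, sigma = co$sigma)
  else init_state
  step_seed <- seed + step_offset       # shared within each polytope step

  evaluator <- function(x) {
    if (x[1] <= 0 || x[2] <= 0 || x[3] <= 0 || x[6] <= 0) return(Inf)
    pot <- ckdg_from_vector(x)
    dr_tab <- if (is.null(smp$table_dr)) pot$r_c / 1000 else smp$table_dr
    tabs <- setNames(list(tabulate_potential(pot, dr = dr_tab)),
                     pair_key(start$species[1], start$species[1]))
    relaxed <- mc_nvt(start, tabs, thermo_state(1e-12, state$k_B),
                      n_steps = smp$relax_steps, max_disp = smp$max_disp,
                      seed = step_seed, equil_fraction = 1, stride = 0)
    traj <- mc_nvt(attr(relaxed, "final"), tabs, state,
                   n_steps = smp$n_steps, max_disp = smp$max_disp,
                   seed = step_seed, equil_fraction = smp$equil_fraction,
                   stride = smp$stride)
    g <- compute_rdf(traj, rep(start$species[1], 2),
                     r_max = max(spec$target_rdf$r) + spec$target_rdf$dr / 2,
                     dr = spec$target_rdf$dr)
    p <- if (spec$a > 0) virial_pressure(traj, tabs, state) else NA_real_
    penalty_rdf_pressure(g, spec, p)
  }

  # initial vertex evaluations share the base seed
  for (i in which(sstate$status == "pending")) {
    sstate$penalty[i] <- eval_penalty(evaluator, sstate$vertices[i, ])
    sstate$status[i] <- "done"
  }
  sstate <- sort_vertices(sstate)
  trace <- data.frame(step = 0L, best = sstate$penalty[1],
                      worst = max(sstate$penalty), move = "init",
                      stringsAsFactors = FALSE)
  converged <- FALSE
  for (s in step_offset + seq_len(max_steps)) {
    step_seed <- seed + s
    sstate <- simplex_step(sstate, evaluator)
    trace <- rbind(trace, data.frame(
      step = s, best = sstate$penalty[1], worst = max(sstate$penalty),
      move = sstate$last_move, stringsAsFactors = FALSE))
    if (!is.null(callback)) callback(sstate, s)
    if (max(sstate$penalty) - sstate$penalty[1] < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(best = ckdg_from_vector(sstate$vertices[1, ]),
                 best_penalty = sstate$penalty[1], trace = trace,
                 state = sstate, converged = converged),
            class = "simplex_result")
}

#' @export
print.simplex_result <- function(x, ...) {
  cat(sprintf("simplex targeted coarse-graining: %d steps, best penalty %.6g%s\n",
              max(x$trace$step), x$best_penalty,
              if (x$converged) " (spread below tolerance)" else ""))
  invisible(x)
}
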