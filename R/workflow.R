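#' Run configuration for the iterative coarse-graining drivers
#'
#' Bundles the synthetic reference system, the sampler settings and the
#' optimizer settings into one validated object that [run_workflow()]
#' executes and echoes into the results directory.
#'
#' @param method `"re"` (relative-entropy over CBSPL) or `"simplex"`
#'   (targeted CKDg optimization).
#' @param fixture list: `kind`, `params`, passed to
#'   [generate_reference_fixture()].
#' @param sampler per-iteration CG sampler settings (see [re_minimize()] /
#'   [simplex_minimize()]).
#' @param method_opts optimizer settings: for `"re"` the `r_cut`, `dr`,
#'   `r_min`, `chi`, `tol`, `max_iter`, `window`, `w_lambda`, `w_u`; for
#'   `"simplex"` the `vertices` (or `spread` to auto-build them around the
#'   fixture truth), `r_lo`, `r_hi`, `a`, `max_steps`, `tol`.
#' @param seed base seed recorded in all outputs.
#' @return object of class `run_config`.
#' @export
run_config <- function(method = c("re", "simplex"), fixture = list(),
                       sampler = list(), method_opts = list(), seed = 42L) {
  method <- match.arg(method)
  fixture <- utils::modifyList(list(kind = "lj_fluid", params = list()),
                               fixture)
  structure(list(method = method, fixture = fixture, sampler = sampler,
                 method_opts = method_opts, seed = as.integer(seed)),
            class = "run_config")
}

log_line <- function(log_file, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 sprintf(...))
  cat(msg, "\n", sep = "", file = log_file, append = TRUE)
}

step_dir <- function(out_dir, k) file.path(out_dir, sprintf("step_%03d", k))

write_knots <- function(pots, dir) {
  for (key in names(pots)) {
    p <- pots[[key]]
    writeLines(c(sprintf("# pair %s r_cut %.17g dr %.17g r_min %.17g",
                         key, p$r_cut, p$dr, p$r_min),
                 sprintf("%.17g", p$knots)),
               file.path(dir, sprintf("knots_%s.txt", key)))
  }
}

read_knots <- function(dir) {
  files <- list.files(dir, pattern = "^knots_.*\\.txt$", full.names = TRUE)
  pots <- list()
  for (f in files) {
    lines <- readLines(f)
    hdr <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
    kv <- setNames(hdr[seq(2, length(hdr), 2)], hdr[seq(1, length(hdr), 2)])
    pots[[kv[["pair"]]]] <- knot_potential(
      as.numeric(lines[-1]), dr = as.numeric(kv[["dr"]]),
      r_cut = as.numeric(kv[["r_cut"]]), r_min = as.numeric(kv[["r_min"]]),
      pair = kv[["pair"]])
  }
  pots
}

#' Execute an iterative coarse-graining run
#'
#' Drives the full loop for the configured method against a synthetic
#' reference fixture, writing a deterministic directory layout: the echoed
#' config, one `step_XXX/` subdirectory per optimizer iteration (potential
#' knots and tables for the relative-entropy method; the simplex state file
#' per polytope step), final potential tables under `final/`, a timestamped
#' log and a machine-readable `report.json`.  Rerunning with the same
#' config and seed reproduces all numeric artifacts; a partial previous run
#' resumes from the last completed iteration unless `fresh = TRUE`.
#'
#' @param config [run_config()].
#' @param out_dir results directory (created if missing).
#' @param fresh discard any partial state on disk and restart.
#' @return the final report (list), invisibly; also written as JSON.
#' @export
run_workflow <- function(config, out_dir, fresh = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (fresh && dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "log.txt")
  report_file <- file.path(out_dir, "report.json")
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  if (file.exists(report_file) && !fresh) {
    log_line(log_file, "complete run found: returning stored report")
    return(invisible(jsonlite::read_json(report_file, simplifyVector = TRUE)))
  }

  t0 <- proc.time()[["elapsed"]]
  log_line(log_file, "fixture %s (seed %d)", config$fixture$kind, config$seed)
  fx <- generate_reference_fixture(config$fixture$kind,
                                   config$fixture$params, seed = config$seed)
  log_line(log_file, "fixture sampled in %.1f s: %d beads, L = %.3f",
           proc.time()[["elapsed"]] - t0, nrow(fx$cg_traj$frames[[1]]), fx$L)
  for (key in names(fx$rdfs))
    write_rdf(fx$rdfs[[key]], file.path(out_dir, sprintf("ref_rdf_%s.txt", key)))

  report <- if (config$method == "re") {
    run_re(config, fx, out_dir, log_file)
  } else {
    run_simplex(config, fx, out_dir, log_file)
  }
  report$seed <- config$seed
  report$method <- config$method
  report$fixture <- config$fixture$kind
  jsonlite::write_json(report, report_file, auto_unbox = TRUE, digits = NA)
  log_line(log_file, "done: report written")
  invisible(report)
}

run_re <- function(config, fx, out_dir, log_file) {
  mo <- utils::modifyList(
    list(r_cut = 2.4, dr = 0.1, r_min = NULL, chi = 1, tol = 0.1,
         max_iter = 15L, window = 5L, w_lambda = 0, w_u = 1), config$method_opts)
  done <- sort(list.files(out_dir, pattern = "^step_[0-9]+$"))
  k0 <- length(done)
  pots <- NULL
  start <- NULL
  errors <- NULL
  chi <- mo$chi
  if (k0 > 0) {
    last <- file.path(out_dir, done[k0])
    pots <- read_knots(last)
    st <- read_xyz(file.path(last, "start_next.xyz"))
    start <- get_frame(st, 1)
    start$mol <- fx$cg_traj$mol
    errors <- utils::read.csv(file.path(out_dir, "errors.csv"))
    chi <- utils::tail(errors$chi, 1)
    log_line(log_file, "resuming after %d completed iterations", k0)
  }

  history <- list()
  if (k0 > 0)
    history <- lapply(done, function(d)
      lambda_vector(read_knots(file.path(out_dir, d))))
  converged <- FALSE
  k <- k0
  while (k < mo$max_iter && !converged) {
    k <- k + 1L
    res <- re_minimize(fx$cg_traj, fx$state, r_cut = mo$r_cut, dr = mo$dr,
                       r_min = mo$r_min, potentials = pots, chi = chi,
                       tol = 0, max_iter = 1L, window = 1L,
                       w_lambda = mo$w_lambda, w_u = mo$w_u,
                       sampler = utils::modifyList(config$sampler,
                                                   list(start = start)),
                       seed = config$seed, iter_offset = k - 1L)
    pots <- res$last_potentials
    start <- res$final_frame
    sd <- step_dir(out_dir, k - 1L)
    dir.create(sd, showWarnings = FALSE)
    write_knots(pots, sd)
    for (key in names(pots))
      export_table(pots[[key]], file.path(sd, sprintf("pot_%s.table", key)),
                   dr = pots[[key]]$dr / 4)
    write_xyz(trajectory(list(start$pos), start$species, start$L,
                         start$mol, start$mass),
              file.path(sd, "start_next.xyz"))
    row <- cbind(res$errors, chi = res$chi_final)
    errors <- rbind(errors, row)
    utils::write.csv(errors, file.path(out_dir, "errors.csv"),
                     row.names = FALSE)
    history[[k]] <- lambda_vector(pots)
    log_line(log_file, "iteration %d: eps_tot %.3e (seed %d)", k,
             row$eps_tot, row$seed)
    converged <- row$eps_tot < mo$tol
    chi <- res$chi_final
  }

  win <- utils::tail(history, mo$window)
  lambda_avg <- Reduce(`+`, win) / length(win)
  final <- lapply(set_lambda(pots, lambda_avg), extrapolate_core)
  fd <- file.path(out_dir, "final")
  dir.create(fd, showWarnings = FALSE)
  write_knots(final, fd)
  for (key in names(final))
    export_table(final[[key]], file.path(fd, sprintf("pot_%s.table", key)),
                 dr = final[[key]]$dr / 4)
  list(converged = converged, iterations = k,
       eps_tot = errors$eps_tot, seeds = errors$seed,
       window = length(win))
}

run_simplex <- function(config, fx, out_dir, log_file) {
  sp <- fx$cg_traj$species[1]
  truth <- fx$truth[[pair_key(sp, sp)]]
  mo <- utils::modifyList(
    list(vertices = NULL, spread = 0.2, r_lo = 0, r_hi = NULL, a = 0,
         max_steps = 30L, tol = 1e-3), config$method_opts)
  g <- fx$rdfs[[pair_key(sp, sp)]]
  if (is.null(mo$r_hi)) mo$r_hi <- max(g$r)
  p_ref <- if (mo$a > 0)
    virial_pressure(fx$cg_traj, fx$truth, fx$state) else NA_real_
  spec <- penalty_spec(g, r_lo = mo$r_lo, r_hi = mo$r_hi, a = mo$a,
                       target_pressure = p_ref)
  if (is.null(mo$vertices)) {
    v0 <- ckdg_vector(truth)
    old <- .Random.seed_save()
    set.seed(config$seed)
    verts <- t(vapply(seq_len(7), function(i)
      v0 * (1 + mo$spread * (runif(6) - 0.5) * 2), numeric(6)))
    .Random.seed_restore(old)
    mo$vertices <- verts
  }
  start <- get_frame(fx$cg_traj, length(fx$cg_traj$frames))

  state_file <- file.path(out_dir, "simplex_state.txt")
  init_state <- NULL
  step_offset <- 0L
  if (file.exists(state_file)) {
    init_state <- read_simplex_state(state_file)
    step_offset <- init_state$iteration
    log_line(log_file, "resuming simplex at polytope step %d", step_offset)
  }
  res <- simplex_minimize(mo$vertices, spec, start, fx$state,
                          sampler = config$sampler,
                          max_steps = mo$max_steps - step_offset,
                          tol = mo$tol, seed = config$seed,
                          init_state = init_state, step_offset = step_offset,
                          callback = function(st, s) {
                            sd <- step_dir(out_dir, s - 1L)
                            dir.create(sd, showWarnings = FALSE)
                            write_simplex_state(st, file.path(sd, "state.txt"))
                            write_simplex_state(st, state_file)
                          })
  utils::write.csv(res$trace, file.path(out_dir, "trace.csv"),
                   row.names = FALSE)
  fd <- file.path(out_dir, "final")
  dir.create(fd, showWarnings = FALSE)
  export_table(res$best, file.path(fd, sprintf("pot_%s-%s.table", sp, sp)),
               dr = res$best$r_c / 1000)
  log_line(log_file, "simplex finished: best penalty %.4g", res$best_penalty)
  list(converged = res$converged, iterations = max(res$trace$step),
       best_penalty = res$best_penalty,
       best_params = as.list(ckdg_vector(res$best)))
}
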