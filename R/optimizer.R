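#' Bundle stored condensate conformations for rescoring
#'
#' @param system_id Label.
#' @param topology The shared `cg_topology` of all conformations.
#' @param conformations List of N x 3 coordinate matrices (snapshots).
#' @param box Box edges (nm) the snapshots were generated in.
#' @param csat_exp Experimental saturation concentration (mM), > 0.
#' @param is_idp Marks systems without folded domains (used by the scan
#'   stage, which trains on disordered systems only).
#' @return A `rescore_set` object.
#' @export
rescore_set <- function(system_id, topology, conformations, box,
                        csat_exp = NA_real_,
                        is_idp = !any(topology$beads$is_folded)) {
  stopifnot(length(conformations) >= 1,
            all(vapply(conformations, nrow, 1L) == nrow(topology$beads)))
  if (!is.na(csat_exp) && csat_exp <= 0) stop("csat_exp must be > 0")
  structure(list(system_id = system_id, topology = topology,
                 conformations = conformations, box = box,
                 csat_exp = csat_exp, is_idp = is_idp,
                 n_residues = nrow(topology$beads)),
            class = "rescore_set")
}

#' Rescore stored conformations under candidate parameters
#'
#' Mean per-residue potential energy over the stored snapshots, evaluated
#' under `candidate` without any new simulation. Surface-exposure scales
#' xi are re-thresholded from the stored surface ratios when the
#' candidate's lambda differs from the topology's.
#'
#' @param rset A [rescore_set()].
#' @param candidate A `cg_params` object.
#' @return Mean potential energy per residue (kJ/mol).
#' @export
rescore <- function(rset, candidate) {
  topo <- rset$topology
  if (!identical(candidate$lambda_surface, topo$lambda))
    topo <- update_xi(topo, candidate$lambda_surface)
  # marshal the engine arguments once; only coordinates change per snapshot
  st <- system_state(topo, rset$conformations[[1]], rset$box, candidate)
  a <- .engine_args(st)
  a$use_neighbour_list <- FALSE
  u <- vapply(rset$conformations, function(xyz) {
    a$coords <- as.matrix(xyz)
    do.call(cpp_energy_forces, a)$total
  }, numeric(1))
  mean(u) / rset$n_residues
}

#' Robust linear fit of log10 csat against potential energy
#'
#' RANSAC (random sample consensus): repeatedly fit a line through a
#' minimal sample of points, score it by its inlier consensus under a
#' median-absolute-deviation-scaled residual threshold, and refit by
#' ordinary least squares on the best inlier set. With clean collinear
#' data this reduces exactly to OLS.
#'
#' @param U Per-residue potential energies (kJ/mol).
#' @param csat Saturation concentrations (mM), > 0. Alternatively a
#'   two-column data.frame/matrix of (U, csat) as first argument.
#' @param n_trials Sampling iterations.
#' @param min_samples Minimal sample size per trial.
#' @param residual_threshold Absolute residual (in log10 csat) separating
#'   inliers; default: MAD of log10 csat about its median.
#' @param seed RNG seed for the sampling.
#' @return A `fit_model`: slope `a`, intercept `b`, logical `inliers`,
#'   `r2` on inliers.
#' @export
fit_energy_csat <- function(U, csat = NULL, n_trials = 1000L,
                            min_samples = 2L, residual_threshold = NULL,
                            seed = 1L) {
  if (is.null(csat)) {
    csat <- U[[2]]; U <- U[[1]]
  }
  stopifnot(length(U) == length(csat), all(csat > 0))
  if (length(U) < max(3L, min_samples)) stop("need at least 3 points")
  if (max(U) - min(U) < 1e-12) stop("degenerate design: all U identical")
  y <- log10(csat)
  if (is.null(residual_threshold)) {
    residual_threshold <- stats::mad(y, constant = 1)
    if (residual_threshold == 0) residual_threshold <- 1e-9
  }
  n <- length(U)
  best <- NULL
  with_local_seed(seed, {
    for (t in seq_len(n_trials)) {
      s <- sample.int(n, min_samples)
      if (max(U[s]) - min(U[s]) < 1e-12) next
      cf <- stats::coef(stats::lm.fit(cbind(1, U[s]), y[s]))
      res <- abs(y - (cf[1] + cf[2] * U))
      inl <- res <= residual_threshold
      score <- sum(inl)
      if (is.null(best) || score > best$score ||
          (score == best$score && sum(res[inl]) < best$loss)) {
        best <- list(score = score, loss = sum(res[inl]), inliers = inl)
      }
    }
  })
  inl <- best$inliers
  if (sum(inl) < 2 || max(U[inl]) - min(U[inl]) < 1e-12) inl <- rep(TRUE, n)
  X <- cbind(1, U[inl])
  cf <- stats::coef(stats::lm.fit(X, y[inl]))
  res <- y[inl] - drop(X %*% cf)
  ss_tot <- sum((y[inl] - mean(y[inl]))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(res^2) / ss_tot
  structure(list(a = unname(cf[2]),
                 b = unname(cf[1]),
                 inliers = inl, r2 = r2,
                 residual_threshold = residual_threshold),
            class = "fit_model")
}

#' @export
print.fit_model <- function(x, ...) {
  cat(sprintf("<fit_model> log10 csat = %.4g * U + %.4g (inliers %d/%d, R2 %.4f)\n",
              x$a, x$b, sum(x$inliers), length(x$inliers), x$r2))
  invisible(x)
}

#' Predict csat from a fitted energy relationship
#'
#' @param model A `fit_model`.
#' @param U Per-residue potential energy (kJ/mol), vectorized.
#' @return Predicted csat in mM: 10^(a U + b).
#' @export
predict_csat <- function(model, U) 10^(model$a * U + model$b)

#' Define a parameter-optimization problem
#'
#' @param systems List of lists, each with a `rescore_set` (`rset`) and its
#'   `fit_model` (`fit`).
#' @param free Names of free parameters, a subset of
#'   c("eps_polar", "eps_hydrophobic", "A0_polar", "A0_hydrophobic",
#'   "lambda_surface").
#' @param lower,upper Named bounds; lambda_surface is capped at 0.7.
#' @param start A `cg_params` giving fixed fields and starting values.
#' @return An `optimization_problem`.
#' @export
optimization_problem <- function(systems, free = c("eps_polar",
                                   "eps_hydrophobic", "A0_polar",
                                   "A0_hydrophobic", "lambda_surface"),
                                 lower = NULL, upper = NULL,
                                 start = cg_params()) {
  allowed <- c("eps_polar", "eps_hydrophobic", "A0_polar", "A0_hydrophobic",
               "lambda_surface")
  stopifnot(all(free %in% allowed))
  lo <- c(eps_polar = 0.01, eps_hydrophobic = 0.01, A0_polar = 0,
          A0_hydrophobic = 0, lambda_surface = 0.05)
  hi <- c(eps_polar = 2, eps_hydrophobic = 2, A0_polar = 1,
          A0_hydrophobic = 1, lambda_surface = 0.7)
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)
  hi["lambda_surface"] <- min(hi["lambda_surface"], 0.7)
  structure(list(systems = systems, free = free, lower = lo[free],
                 upper = hi[free], start = start),
            class = "optimization_problem")
}

.apply_free <- function(params, free, values) {
  for (k in seq_along(free)) params[[free[k]]] <- unname(values[k])
  validate_cg_params(params)
}

# sum of squared log10-csat deviations over the given systems
.objective <- function(values, free, params, systems) {
  cand <- .apply_free(params, free, values)
  dev <- vapply(systems, function(s) {
    u <- rescore(s$rset, cand)
    pred <- s$fit$a * u + s$fit$b
    pred - log10(s$rset$csat_exp)
  }, numeric(1))
  sum(dev^2)
}

#' Staged force-field optimization against experimental csat
#'
#' Three stages mirroring the parameterization protocol:
#' \describe{
#'   \item{scan}{coarse grid over the free parameters (lambda excluded,
#'     since surface scaling has no effect on disordered chains) on the
#'     disordered (IDP) systems only; returns the best grid point.}
#'   \item{refine}{bounded L-BFGS-B from the current start, still on the
#'     IDP systems, lambda excluded.}
#'   \item{joint}{bounded L-BFGS-B over all systems with lambda included,
#'     capped at 0.7.}
#' }
#' The objective is the sum over systems of squared deviations between
#' predicted (via each system's energy-csat fit) and experimental
#' log10 csat.
#'
#' @param problem An [optimization_problem()].
#' @param stage `"scan"`, `"refine"` or `"joint"`.
#' @param grid_points Grid resolution per free parameter (scan stage).
#' @param maxit L-BFGS-B iteration budget.
#' @return List: `params` (optimized `cg_params`), `objective`, `trace`
#'   (data.frame of accepted objective values), `convergence`,
#'   `active_bounds` (free parameters sitting on a bound).
#' @export
optimize_parameters <- function(problem, stage = c("joint", "scan", "refine"),
                                grid_points = 5L, maxit = 200L) {
  stage <- match.arg(stage)
  params <- problem$start
  if (stage %in% c("scan", "refine")) {
    systems <- Filter(function(s) isTRUE(s$rset$is_idp), problem$systems)
    free <- setdiff(problem$free, "lambda_surface")
  } else {
    systems <- problem$systems
    free <- problem$free
  }
  if (!length(systems)) stop("no systems available for stage ", stage)
  lo <- problem$lower[free]; hi <- problem$upper[free]
  start_vals <- pmin(pmax(unlist(params[free]), lo), hi)
  trace <- list()
  if (stage == "scan") {
    # geometric spacing for strictly positive parameters (well depths span
    # orders of magnitude), square-root spacing towards zero otherwise
    axes <- lapply(seq_along(free), function(k) {
      if (lo[k] > 0) exp(seq(log(lo[k]), log(hi[k]),
                             length.out = grid_points))
      else seq(sqrt(lo[k]), sqrt(hi[k]), length.out = grid_points)^2
    })
    grid <- as.matrix(expand.grid(axes))
    vals <- apply(grid, 1, .objective, free = free, params = params,
                  systems = systems)
    best <- which.min(vals)
    trace <- data.frame(eval = seq_along(vals), objective = cummin(vals))
    out_par <- .apply_free(params, free, grid[best, ])
    top <- order(vals)[seq_len(min(5L, nrow(grid)))]
    return(list(params = out_par, objective = vals[best], trace = trace,
                convergence = 0L, active_bounds = character(0),
                top_starts = lapply(top, function(i)
                  .apply_free(params, free, grid[i, ]))))
  }
  evals <- new.env(); evals$v <- numeric(0)
  fn <- function(p) {
    o <- .objective(p, free, params, systems)
    evals$v <- c(evals$v, o)
    o
  }
  opt <- stats::optim(start_vals, fn, method = "L-BFGS-B",
                      lower = lo, upper = hi,
                      control = list(maxit = maxit, factr = 1e4,
                                     parscale = pmax(abs(start_vals), 0.05)))
  out_par <- .apply_free(params, free, opt$par)
  act <- free[opt$par <= lo + 1e-10 | opt$par >= hi - 1e-10]
  list(params = out_par, objective = opt$value,
       trace = data.frame(eval = seq_along(evals$v),
                          objective = cummin(evals$v)),
       convergence = opt$convergence, active_bounds = act)
}

#' Run the full scan / refine / joint protocol with multi-start refinement
#'
#' The scan objective is multi-modal in the well depths and solvation
#' amplitudes, so refinement is started from the best few scan points and
#' the lowest refined objective is carried into the joint stage.
#'
#' @param problem An [optimization_problem()].
#' @param grid_points Scan resolution per free parameter.
#' @param n_starts How many top scan points to refine.
#' @param maxit L-BFGS-B iteration budget per stage.
#' @return The joint-stage result of [optimize_parameters()], plus
#'   `stage_objectives` (scan / refine / joint).
#' @export
optimize_staged <- function(problem, grid_points = 5L, n_starts = 3L,
                            maxit = 200L) {
  sc <- optimize_parameters(problem, "scan", grid_points = grid_points,
                            maxit = maxit)
  starts <- sc$top_starts[seq_len(min(n_starts, length(sc$top_starts)))]
  refined <- lapply(starts, function(s) {
    pr <- problem; pr$start <- s
    optimize_parameters(pr, "refine", maxit = maxit)
  })
  refined <- refined[order(vapply(refined, `[[`, numeric(1), "objective"))]
  # distinct refined candidates only: the disordered-only stage can be
  # underdetermined, and different basins must all be offered to the
  # joint stage
  keyfun <- function(r) paste(signif(unlist(r$params[problem$free]), 4),
                              collapse = "|")
  refined <- refined[!duplicated(vapply(refined, keyfun, character(1)))]
  joint <- lapply(refined[seq_len(min(n_starts, length(refined)))],
                  function(r) {
    pr <- problem; pr$start <- r$params
    optimize_parameters(pr, "joint", maxit = maxit)
  })
  out <- joint[[which.min(vapply(joint, `[[`, numeric(1), "objective"))]]
  out$stage_objectives <- c(scan = sc$objective,
                            refine = refined[[1]]$objective,
                            joint = out$objective)
  out
}
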