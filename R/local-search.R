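# L-BFGS local minimization of the stage-1 energy over all ligand Cartesian
# coordinates (3 * N_L variables); the receptor never moves.

#' Optimizer configuration
#'
#' Convergence is declared on the projected-gradient infinity norm falling
#' below `grad_tol`; the default is tight enough that duplicate-minimum RMSDs
#' are dominated by the pool uniqueness threshold, not optimizer noise.
#'
#' @param grad_tol Gradient tolerance, kcal/mol/Angstrom. Default 1e-3.
#' @param max_iter Iteration cap. Default 2000.
#' @param history_size L-BFGS history length. Default 10.
#' @param saddle_kick Amplitude (Angstrom) of the deterministic displacement
#'   used to test a converged point for saddle character: quasi-Newton
#'   iterations are attracted to any stationary point, so every converged
#'   result is re-optimized from a slightly kicked pose and the kicked
#'   result is adopted only when it is strictly lower. Set 0 to disable.
#' @export
optimizer_config <- function(grad_tol = 1e-3, max_iter = 2000L,
                             history_size = 10L, saddle_kick = 0.02) {
  if (grad_tol <= 0) abort("grad_tol must be > 0")
  if (max_iter < 1) abort("max_iter must be >= 1")
  structure(
    list(grad_tol = grad_tol, max_iter = as.integer(max_iter),
         history_size = as.integer(history_size),
         saddle_kick = saddle_kick),
    class = "qd_optimizer_config"
  )
}

#' Locally optimize a pose in the receptor field
#'
#' Minimizes `model$evaluate` with L-BFGS-B over all ligand Cartesian
#' coordinates from the start pose. The returned energy never exceeds the
#' start energy. A non-finite energy encountered during the line search
#' aborts the optimization; the caller receives the failure reason in the
#' `error` field and normally discards the pose.
#'
#' @param model A `qd_energy_model`.
#' @param receptor A `qd_receptor`.
#' @param ligand A `qd_ligand`.
#' @param start Start pose matrix.
#' @param config An `qd_optimizer_config`.
#' @return List with `pose`, `energy`, `converged` (max gradient component
#'   at the solution <= `grad_tol`), `iterations`, and `error` (`NULL` on
#'   success).
#' @export
optimize_pose <- function(model, receptor, ligand, start,
                          config = optimizer_config()) {
  start <- qd_pose(start, ligand)
  n <- nrow(start)
  e0 <- model$evaluate(receptor, ligand, start)
  if (!is.finite(e0)) abort("energy not finite at the start pose")

  fn <- function(x) {
    e <- model$evaluate(receptor, ligand, matrix(x, n, 3))
    if (!is.finite(e)) stop("non-finite energy during line search")
    e
  }
  gr <- function(x) {
    as.numeric(model_gradient(model, receptor, ligand, matrix(x, n, 3)))
  }

  run_lbfgs <- function(x0) {
    optim(x0, fn, gr, method = "L-BFGS-B",
          control = list(maxit = config$max_iter, pgtol = config$grad_tol,
                         factr = 10, lmm = config$history_size))
  }
  res <- tryCatch(run_lbfgs(as.numeric(start)), error = function(e) e)
  if (inherits(res, "error")) {
    return(list(pose = start, energy = e0, converged = FALSE,
                iterations = 0L, error = conditionMessage(res)))
  }
  pose <- matrix(res$par, n, 3)
  energy <- res$value
  iters <- res$counts[["function"]]
  # Saddle escape: re-optimize from a deterministically kicked copy; adopt
  # only a strictly lower result (a true minimum shrugs the kick off).
  if (config$saddle_kick > 0) {
    kick <- config$saddle_kick * matrix(sin(1.7 * seq_len(3 * n)), n, 3)
    res2 <- tryCatch(run_lbfgs(as.numeric(pose + kick)),
                     error = function(e) NULL)
    if (!is.null(res2) && res2$value < energy - 1e-9) {
      pose <- matrix(res2$par, n, 3)
      energy <- res2$value
      iters <- iters + res2$counts[["function"]]
    }
  }
  if (energy > e0) {  # monotone-improvement guarantee
    pose <- start
    energy <- e0
  }
  gmax <- max(abs(model_gradient(model, receptor, ligand, pose)))
  list(pose = pose, energy = energy, converged = gmax <= config$grad_tol,
       iterations = iters, error = NULL)
}

#' Locally optimize an unbound ligand conformation
#'
#' Identical to [optimize_pose()] with an empty receptor; used by the
#' unbound-ligand leg of the binding-enthalpy protocol.
#'
#' @inheritParams optimize_pose
#' @export
optimize_ligand_alone <- function(model, ligand, start,
                                  config = optimizer_config()) {
  if (nrow(ligand$atoms) == 0) abort("ligand has no atoms")
  optimize_pose(model, empty_receptor(), ligand, start, config)
}
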