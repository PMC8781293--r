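# Stage 2 of quasi-docking: recompute every pool minimum's energy with a
# second model as a single-point calculation (coordinates never move), then
# rank by ascending rescored energy. Two backends: a MOPAC-dialect file
# interface for external semiempirical programs, and a bundled surrogate
# model for fully self-contained runs.

QM_METHODS <- c("PM7", "PM6-D3H4X")

#' Rescoring job description
#'
#' `single_point = TRUE` is the 1SCF contract: rescoring never modifies
#' coordinates (and this implementation offers nothing else for pool
#' rescoring; geometry relaxation appears only in the enthalpy protocol).
#'
#' @param method `"PM7"`, `"PM6-D3H4X"`, or `"surrogate"`.
#' @param solvent `"none"` or `"cosmo"`.
#' @param eps COSMO dielectric constant; default 78.4 (water at room
#'   temperature).
#' @param surrogate_model For `method = "surrogate"`: the `qd_energy_model`
#'   to evaluate.
#' @export
rescore_job <- function(method = c("surrogate", "PM7", "PM6-D3H4X"),
                        solvent = c("cosmo", "none"), eps = 78.4,
                        surrogate_model = NULL) {
  method <- match.arg(method)
  solvent <- match.arg(solvent)
  if (method == "surrogate" && is.null(surrogate_model)) {
    abort("surrogate jobs need surrogate_model")
  }
  structure(
    list(method = method, solvent = solvent, eps = eps,
         single_point = TRUE, surrogate_model = surrogate_model),
    class = "qd_rescore_job"
  )
}

#' Write a MOPAC-dialect single-point input
#'
#' Keyword line: the method token, `1SCF` (single point), `MOZYME`
#' (localized orbitals for large systems), the total charge, and
#' `EPS=<dielectric>` when the COSMO solvent is requested. Geometry follows
#' as one `element x 1 y 1 z 1` line per atom, receptor atoms first then
#' ligand atoms, in fixed order.
#'
#' @param receptor A `qd_receptor`.
#' @param ligand A `qd_ligand`.
#' @param pose Ligand pose matrix.
#' @param job A `qd_rescore_job` with an external method.
#' @return The input file text (single string).
#' @export
write_qm_input <- function(receptor, ligand, pose, job) {
  if (!job$method %in% QM_METHODS) {
    abort(sprintf("method '%s' has no external input format", job$method))
  }
  pose <- qd_pose(pose, ligand)
  if (nrow(receptor$coords) > 0 && !all(is.finite(receptor$coords))) {
    abort("receptor coordinates must be finite")
  }
  keywords <- c(job$method, "1SCF", "MOZYME",
                sprintf("CHARGE=%d", ligand$formal_charge))
  if (job$solvent == "cosmo") {
    keywords <- c(keywords, sprintf("EPS=%.1f", job$eps))
  }
  coords <- rbind(receptor$coords, pose)
  elements <- c(receptor$atoms$element, ligand$atoms$element)
  lines <- c(
    paste(keywords, collapse = " "),
    "protein-ligand complex single point",
    "",
    sprintf("%-2s %12.6f 1 %12.6f 1 %12.6f 1",
            elements, coords[, 1], coords[, 2], coords[, 3])
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse the final heat of formation from external program output
#'
#' Returns the last `FINAL HEAT OF FORMATION` value, in kcal/mol (reruns
#' append; the final one stands). Errors if the marker is absent or a
#' run-failure marker is present, carrying the tail of the file for
#' diagnosis.
#'
#' @param text Output file text (single string or character vector of lines).
#' @return Energy in kcal/mol.
#' @export
parse_qm_energy <- function(text) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  failure <- grepl("CALCULATION ABANDONED|GEOMETRY IS FAULTY|JOB ENDED ABNORMALLY",
                   lines)
  hits <- regmatches(
    lines,
    regexpr("FINAL HEAT OF FORMATION\\s*=\\s*(-?[0-9]+\\.?[0-9]*)", lines)
  )
  hits <- hits[nzchar(hits)]
  if (any(failure) || length(hits) == 0) {
    tail_txt <- paste(tail(lines, 5), collapse = "\n")
    abort(paste0(
      if (any(failure)) "external program reported a failed run"
      else "no FINAL HEAT OF FORMATION found in output",
      "; file tail:\n", tail_txt
    ))
  }
  as.numeric(sub(".*=\\s*", "", tail(hits, 1)))
}

#' Rescore every pool record and assign ranks
#'
#' Computes a single-point stage-2 energy for every stored minimum (poses are
#' untouched -- the 1SCF contract) and ranks records 1..N by ascending
#' stage-2 energy; ties break by ascending stage-1 energy, then insertion
#' order. The rank-1 record is the declared global minimum (GM) of the
#' complex under the stage-2 model. Failed evaluations flag the record and
#' exclude it from ranking; more than 10 percent failures aborts the run.
#'
#' @param pool A `qd_pool` (modified in place).
#' @param receptor A `qd_receptor`.
#' @param job A `qd_rescore_job`.
#' @param runner For external methods: `function(input_text) -> output_text`
#'   executing one job (at most `max_parallel` in flight; results must not
#'   depend on completion order). Ignored for surrogate jobs.
#' @param max_parallel Advisory parallelism bound for the runner contract.
#' @return The pool, invisibly; its `e_stage2` and `rank` fields are filled.
#' @export
rescore_pool <- function(pool, receptor, job, runner = NULL,
                         max_parallel = 1L) {
  n <- pool_size(pool)
  if (n == 0) abort("pool is empty")
  eval_one <- if (job$method == "surrogate") {
    function(pose) job$surrogate_model$evaluate(receptor, pool$ligand, pose)
  } else {
    if (is.null(runner)) abort("external methods need a runner")
    function(pose) {
      parse_qm_energy(runner(write_qm_input(receptor, pool$ligand, pose, job)))
    }
  }
  e2 <- rep(NA_real_, n)
  failed <- logical(n)
  for (k in seq_len(n)) {
    res <- tryCatch(eval_one(pool$poses[[k]]), error = function(e) e)
    if (inherits(res, "error") || !is.finite(res)) {
      failed[k] <- TRUE
    } else {
      e2[k] <- res
    }
  }
  if (mean(failed) > 0.10) {
    abort(sprintf("stage-2 rescoring failed for %d of %d records (> 10%%)",
                  sum(failed), n))
  }
  pool$e_stage2 <- e2
  ranked <- which(!failed)
  ord <- ranked[order(e2[ranked], pool$e_stage1[ranked], pool$seq[ranked])]
  pool$rank <- rep(NA_integer_, n)
  pool$rank[ord] <- seq_along(ord)
  invisible(pool)
}
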