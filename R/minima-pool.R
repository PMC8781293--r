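# Fixed-capacity pool of unique low-energy minima. Uniqueness is decided by
# heavy-atom RMSD (identity atom mapping, common receptor frame) against every
# stored record; the pool keeps the lower-energy representative of each basin
# and, at capacity, evicts the highest-energy record when something better
# arrives.

#' Pool configuration
#'
#' @param capacity Maximum number of stored minima. Default 8192 (it may be
#'   raised freely; hard cases need far more minima retained).
#' @param uniqueness_rmsd Heavy-atom RMSD below which two minima are the same
#'   basin, Angstrom. Default 0.5 -- well under the 2 Angstrom near-native
#'   criterion, while not splitting optimizer jitter into fake basins.
#' @param energy_merge_tol Energy tolerance used by diagnostics when
#'   comparing basin energy multisets, kcal/mol.
#' @export
pool_config <- function(capacity = 8192L, uniqueness_rmsd = 0.5,
                        energy_merge_tol = 1e-6) {
  if (capacity < 1) abort("capacity must be >= 1")
  if (uniqueness_rmsd <= 0) abort("uniqueness_rmsd must be > 0")
  structure(
    list(capacity = as.integer(capacity), uniqueness_rmsd = uniqueness_rmsd,
         energy_merge_tol = energy_merge_tol),
    class = "qd_pool_config"
  )
}

#' Create an empty minima pool
#'
#' The pool is a mutable reference object: [try_insert()] updates it in
#' place. Records are exposed in ascending stage-1 energy order (ties by
#' insertion order) via [as_tibble()][tibble::as_tibble] / [tidy()].
#'
#' @param ligand The `qd_ligand` whose poses the pool stores.
#' @param config A `qd_pool_config`.
#' @return An object of class `qd_pool`.
#' @export
minima_pool <- function(ligand, config = pool_config()) {
  e <- new.env(parent = emptyenv())
  e$ligand <- ligand
  e$config <- config
  e$heavy <- heavy_atoms(ligand)
  e$poses <- list()
  e$e_stage1 <- numeric(0)
  e$e_stage2 <- numeric(0)
  e$rank <- integer(0)
  e$converged <- logical(0)
  e$start_index <- integer(0)
  e$seq <- integer(0)          # insertion sequence number per stored record
  e$hmat <- NULL               # n_records x (3 * n_heavy) heavy-coord matrix
  e$n_seen <- 0L
  e$n_inserted <- 0L
  e$n_rejected_duplicate <- 0L
  e$n_above_cutoff <- 0L
  e$n_evicted <- 0L
  e$improvement_log <- logical(0)  # per candidate: extended/deepened spectrum?
  class(e) <- "qd_pool"
  e
}

#' @method print qd_pool
#' @export
print.qd_pool <- function(x, ...) {
  cat(sprintf(
    "<qd_pool> %d/%d records, %d candidates seen (%d duplicates, %d above cutoff)\n",
    pool_size(x), x$config$capacity, x$n_seen, x$n_rejected_duplicate,
    x$n_above_cutoff
  ))
  invisible(x)
}

#' Number of records currently stored
#' @param pool A `qd_pool`.
#' @export
pool_size <- function(pool) length(pool$e_stage1)

heavy_row <- function(pool, pose) {
  as.numeric(t(pose[pool$heavy, , drop = FALSE]))
}

# Heavy-atom RMSD from a candidate to every stored record, vectorized.
rmsd_to_all <- function(pool, pose) {
  if (pool_size(pool) == 0) return(numeric(0))
  v <- heavy_row(pool, pose)
  d2 <- rowSums((pool$hmat - matrix(v, nrow(pool$hmat), length(v),
                                    byrow = TRUE))^2)
  sqrt(d2 / length(pool$heavy))
}

#' Offer a candidate minimum to the pool
#'
#' Outcomes:
#' * `"duplicate"` -- heavy-atom RMSD to some stored record is below the
#'   uniqueness threshold. If the candidate's energy is lower, it replaces
#'   that basin's stored representative (same basin, better-converged point).
#' * `"inserted"` -- stored as a new unique minimum; at capacity, the
#'   highest-energy record is evicted to make room.
#' * `"above_cutoff"` -- pool full and the candidate is no better than the
#'   worst stored record.
#'
#' @param pool A `qd_pool` (modified in place).
#' @param pose Optimized pose matrix.
#' @param e_stage1 Stage-1 (search field) energy, kcal/mol.
#' @param converged Optimizer convergence flag.
#' @param start_index Index of the originating start (bookkeeping).
#' @return The outcome string, invisibly carrying the pool.
#' @export
try_insert <- function(pool, pose, e_stage1, converged = TRUE,
                       start_index = NA_integer_) {
  if (!is.finite(e_stage1)) abort("candidate stage-1 energy must be finite")
  pose <- qd_pose(pose, pool$ligand)
  pool$n_seen <- pool$n_seen + 1L
  prev_max <- if (pool_size(pool) > 0) max(pool$e_stage1) else Inf
  at_capacity <- pool_size(pool) >= pool$config$capacity

  r <- rmsd_to_all(pool, pose)
  if (length(r) > 0 && min(r) < pool$config$uniqueness_rmsd) {
    k <- which.min(r)
    if (e_stage1 < pool$e_stage1[k]) {
      pool$poses[[k]] <- pose
      pool$e_stage1[k] <- e_stage1
      pool$converged[k] <- converged
      pool$hmat[k, ] <- heavy_row(pool, pose)
    }
    pool$n_rejected_duplicate <- pool$n_rejected_duplicate + 1L
    pool$improvement_log <- c(pool$improvement_log, FALSE)
    return(invisible("duplicate"))
  }

  if (at_capacity && e_stage1 >= prev_max) {
    pool$n_above_cutoff <- pool$n_above_cutoff + 1L
    pool$improvement_log <- c(pool$improvement_log, FALSE)
    return(invisible("above_cutoff"))
  }

  if (at_capacity) {
    # evict the highest-energy record (latest-inserted among exact ties)
    worst <- which(pool$e_stage1 == prev_max)
    worst <- worst[which.max(pool$seq[worst])]
    pool$poses[[worst]] <- NULL
    pool$e_stage1 <- pool$e_stage1[-worst]
    pool$e_stage2 <- pool$e_stage2[-worst]
    pool$rank <- pool$rank[-worst]
    pool$converged <- pool$converged[-worst]
    pool$start_index <- pool$start_index[-worst]
    pool$seq <- pool$seq[-worst]
    pool$hmat <- pool$hmat[-worst, , drop = FALSE]
    pool$n_evicted <- pool$n_evicted + 1L
  }

  pool$poses[[pool_size(pool) + 1L]] <- pose
  pool$e_stage1 <- c(pool$e_stage1, e_stage1)
  pool$e_stage2 <- c(pool$e_stage2, NA_real_)
  pool$rank <- c(pool$rank, NA_integer_)
  pool$converged <- c(pool$converged, converged)
  pool$start_index <- c(pool$start_index, as.integer(start_index))
  pool$seq <- c(pool$seq, pool$n_seen)
  row <- heavy_row(pool, pose)
  pool$hmat <- rbind(pool$hmat, row)
  pool$n_inserted <- pool$n_inserted + 1L
  # The spectrum improved: either it grew below capacity or it deepened.
  pool$improvement_log <- c(pool$improvement_log,
                            !at_capacity || e_stage1 < prev_max)
  invisible("inserted")
}

# Order of stored records: ascending stage-1 energy, ties by insertion order.
pool_order <- function(pool) order(pool$e_stage1, pool$seq)

#' Saturation diagnostic
#'
#' The search is saturated when, over the last `window` candidates, no
#' insertion extended or deepened the stored spectrum: continued sampling is
#' not revealing any minimum below the stored ones.
#'
#' @param pool A `qd_pool`.
#' @param window Number of trailing candidates to inspect.
#' @return List with `new_low_minima_in_window` and `saturated`.
#' @export
saturation_report <- function(pool, window) {
  window <- as.integer(window)
  if (window < 1 || window > pool$n_seen) {
    abort(sprintf("window (%d) must be in 1..candidates processed (%d)",
                  window, pool$n_seen))
  }
  recent <- tail(pool$improvement_log, window)
  n_new <- sum(recent)
  list(new_low_minima_in_window = n_new, saturated = n_new == 0L)
}

#' @method as_tibble qd_pool
#' @export
as_tibble.qd_pool <- function(x, ...) {
  ord <- pool_order(x)
  tibble(
    pool_index = ord,
    start_index = x$start_index[ord],
    e_stage1 = x$e_stage1[ord],
    e_stage2 = x$e_stage2[ord],
    rank = x$rank[ord],
    converged = x$converged[ord]
  )
}

#' Tidy a minima pool into one row per stored minimum
#' @param x A `qd_pool`.
#' @param ... Unused.
#' @method tidy qd_pool
#' @export
tidy.qd_pool <- function(x, ...) as_tibble.qd_pool(x)

#' One-row pool summary (counters and saturation state)
#' @param x A `qd_pool`.
#' @param window Saturation window; defaults to half the candidates seen.
#' @param ... Unused.
#' @method glance qd_pool
#' @export
glance.qd_pool <- function(x, window = NULL, ...) {
  sat <- if (x$n_seen > 0) {
    saturation_report(x, if (is.null(window)) max(1L, x$n_seen %/% 2L) else window)
  } else {
    list(new_low_minima_in_window = NA_integer_, saturated = NA)
  }
  tibble(
    n_records = pool_size(x),
    capacity = x$config$capacity,
    n_seen = x$n_seen,
    n_inserted = x$n_inserted,
    n_rejected_duplicate = x$n_rejected_duplicate,
    n_above_cutoff = x$n_above_cutoff,
    n_evicted = x$n_evicted,
    e_min = if (pool_size(x) > 0) min(x$e_stage1) else NA_real_,
    saturated = sat$saturated
  )
}

#' Retrieve a stored pose by its position in the stage-1 energy ordering
#' @param pool A `qd_pool`.
#' @param i Position (1 = lowest stage-1 energy), or if `by_rank = TRUE` the
#'   stage-2 rank.
#' @param by_rank Look up by stage-2 rank instead.
#' @export
pool_pose <- function(pool, i, by_rank = FALSE) {
  if (by_rank) {
    k <- which(pool$rank == i)
    if (length(k) != 1) abort(sprintf("no record with rank %d", i))
    pool$poses[[k]]
  } else {
    pool$poses[[pool_order(pool)[i]]]
  }
}
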