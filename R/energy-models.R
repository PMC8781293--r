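# Bundled smooth energy models. The search stage of quasi-docking only
# requires something satisfying the energy-model contract; the models here
# are smooth pairwise/field potentials with analytic gradients, used for the
# desk-scale synthetic complexes and as the stage-2 surrogate. External
# force-field or semiempirical backends plug into the same contract.

COULOMB_K <- 332.0636  # kcal/mol * Angstrom / e^2

#' Quadratic toy energy with a single known minimum
#'
#' `E = k * sum |r - r0|^2`, minimized exactly at the target pose. Convex, so
#' every local optimization must recover the target; used to validate the
#' optimizer and gradient plumbing.
#'
#' @param target Numeric n x 3 target pose.
#' @param k Force constant, kcal/mol/Angstrom^2.
#' @return A `qd_energy_model` with analytic gradient.
#' @export
quadratic_model <- function(target, k = 1) {
  target <- as_coord_matrix(target)
  energy_model(
    name = "quadratic-toy",
    evaluate = function(receptor, ligand, pose) {
      k * sum((pose - target)^2)
    },
    gradient = function(receptor, ligand, pose) {
      2 * k * (pose - target)
    }
  )
}

#' General smooth terms model
#'
#' Composes, with analytic gradients:
#' * harmonic distance springs between ligand atom pairs
#'   (`springs`: columns `i`, `j`, `l0`, `k`) -- the ligand's internal
#'   stiffness;
#' * quartic double-well terms on a ligand atom pair
#'   (`pair_wells`: columns `i`, `j`, `d1`, `d2`, `h`, `tilt`), giving a
#'   controllable two-well torsional profile through the 1-4 distance;
#' * full-pose attraction wells (`field_wells`: list of
#'   `list(target = pose, depth, lambda)`), each contributing
#'   `-depth / (1 + D^2/lambda^2)` where `D^2` is the summed squared deviation
#'   of the pose from the well's target pose. The slowly decaying tail makes
#'   every start point downhill from some well, so the minima set is exactly
#'   the (enumerable) well set. Field wells represent the receptor's field
#'   and are skipped when the receptor has no atoms (unbound ligand);
#' * soft Lennard-Jones plus distance-damped Coulomb interactions between all
#'   ligand and receptor atoms (`pair_params`: list with per-atom vectors
#'   `q_lig`, `q_rec`, `eps`, `sigma`, and damping `delta`).
#'
#' @param name Model name.
#' @param springs,pair_wells Data frames as described (or `NULL`).
#' @param field_wells List of wells (or `NULL`).
#' @param pair_params Receptor-interaction parameters (or `NULL`).
#' @return A `qd_energy_model`.
#' @export
terms_model <- function(name, springs = NULL, pair_wells = NULL,
                        field_wells = NULL, pair_params = NULL) {
  if (!is.null(springs)) springs <- as.data.frame(springs)
  if (!is.null(pair_wells)) pair_wells <- as.data.frame(pair_wells)
  well_targets <- lapply(field_wells, function(w) as_coord_matrix(w$target))
  well_depth <- vapply(field_wells, function(w) w$depth, numeric(1))
  well_lambda <- vapply(field_wells, function(w) w$lambda, numeric(1))

  eval_terms <- function(receptor, ligand, pose, want_grad = FALSE) {
    e <- 0
    g <- if (want_grad) matrix(0, nrow(pose), 3) else NULL
    if (!is.null(springs) && nrow(springs) > 0) {
      dvec <- pose[springs$i, , drop = FALSE] - pose[springs$j, , drop = FALSE]
      d <- sqrt(rowSums(dvec^2))
      e <- e + sum(springs$k * (d - springs$l0)^2)
      if (want_grad) {
        coef <- 2 * springs$k * (d - springs$l0) / pmax(d, 1e-12)
        gv <- dvec * coef
        for (r in seq_len(nrow(springs))) {
          g[springs$i[r], ] <- g[springs$i[r], ] + gv[r, ]
          g[springs$j[r], ] <- g[springs$j[r], ] - gv[r, ]
        }
      }
    }
    if (!is.null(pair_wells) && nrow(pair_wells) > 0) {
      for (r in seq_len(nrow(pair_wells))) {
        i <- pair_wells$i[r]; j <- pair_wells$j[r]
        dvec <- pose[i, ] - pose[j, ]
        d <- sqrt(sum(dvec^2))
        a <- d - pair_wells$d1[r]; b <- d - pair_wells$d2[r]
        e <- e + pair_wells$h[r] * (a * b)^2 + pair_wells$tilt[r] * a
        if (want_grad) {
          dw <- 2 * pair_wells$h[r] * (a * b) * (a + b) + pair_wells$tilt[r]
          gv <- dw * dvec / max(d, 1e-12)
          g[i, ] <- g[i, ] + gv
          g[j, ] <- g[j, ] - gv
        }
      }
    }
    if (length(well_targets) > 0 && nrow(receptor$atoms) > 0) {
      for (w in seq_along(well_targets)) {
        dev <- pose - well_targets[[w]]
        s <- sum(dev^2) / well_lambda[w]^2
        e <- e - well_depth[w] / (1 + s)
        if (want_grad) {
          g <- g + (2 * well_depth[w] / (well_lambda[w]^2 * (1 + s)^2)) * dev
        }
      }
    }
    if (!is.null(pair_params) && nrow(receptor$atoms) > 0) {
      pp <- pair_params
      rc <- receptor$coords
      for (jl in seq_len(nrow(pose))) {
        dvec <- sweep(rc, 2, pose[jl, ], "-")      # receptor - ligand atom
        d2 <- rowSums(dvec^2)
        q <- d2 + pp$delta
        u <- pp$sigma^2 / q
        elj <- pp$eps * (u^4 - 2 * u^2)
        qc <- d2 + pp$delta
        ec <- COULOMB_K * pp$q_lig[jl] * pp$q_rec / sqrt(qc)
        e <- e + sum(elj) + sum(ec)
        if (want_grad) {
          dlj_dq <- -(4 * pp$eps * pp$sigma^2 / q^2) * u * (u^2 - 1)
          dc_dq <- -0.5 * COULOMB_K * pp$q_lig[jl] * pp$q_rec * qc^(-1.5)
          coef <- 2 * (dlj_dq + dc_dq)               # d/d(d2) * chain to coords
          # gradient wrt ligand atom: dvec points receptor - ligand
          g[jl, ] <- g[jl, ] - colSums(dvec * coef)
        }
      }
    }
    list(e = e, g = g)
  }

  energy_model(
    name = name,
    evaluate = function(receptor, ligand, pose) {
      eval_terms(receptor, ligand, pose, want_grad = FALSE)$e
    },
    gradient = function(receptor, ligand, pose) {
      eval_terms(receptor, ligand, pose, want_grad = TRUE)$g
    }
  )
}

# Full pairwise rest-length springs at the given reference geometry, keeping
# a toy ligand effectively rigid; pairs listed in `skip` (e.g. the 1-4 pair
# spanned by a torsion) are left out.
rigid_springs <- function(ref_pose, k = 400, skip = NULL) {
  n <- nrow(ref_pose)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- rep(TRUE, nrow(pairs))
  if (!is.null(skip)) {
    for (s in skip) {
      keep[pairs[, 1] == min(s) & pairs[, 2] == max(s)] <- FALSE
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  d0 <- sqrt(rowSums((ref_pose[pairs[, 1], , drop = FALSE] -
                        ref_pose[pairs[, 2], , drop = FALSE])^2))
  data.frame(i = pairs[, 1], j = pairs[, 2], l0 = d0, k = k)
}
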