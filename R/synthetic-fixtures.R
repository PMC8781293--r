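# Desk-scale synthetic complexes with known, enumerable minima landscapes,
# plus loaders for the packaged benchmark tables. The toy stage-1 landscape
# is a sum of slowly decaying full-pose attraction wells: every start point
# is downhill from some well, so the complete minima list is enumerable by a
# dense grid plus local refinement, in seconds.

#' Toy complex specification
#'
#' @param k Number of designed attraction wells (2-20); each contributes one
#'   stage-1 minimum (for symmetric ligands, one per ligand automorphism).
#' @param ligand `"triad"` (3 heavy atoms, rigid, asymmetric),
#'   `"square"` (4-atom symmetric ring), or `"chain5"` (5 atoms, 2 torsions).
#' @param native_well Which well provides the designated native pose.
#' @param hotspot_well Which well the stage-2 surrogate favors (an oppositely
#'   charged receptor pseudo-atom sits above it).
#' @param well_radius Radius of the circle the well centroids sit on,
#'   Angstrom.
#' @param depth0,depth_step Well depths: well `k` gets
#'   `depth0 + depth_step * (K - k + 1)` kcal/mol, so well 1 is the stage-1
#'   global minimum.
#' @param lambda Well width, Angstrom.
#' @param site_radius Binding-site sphere radius, Angstrom.
#' @export
toy_complex_spec <- function(k = 2L, ligand = c("triad", "square", "chain5"),
                             native_well = 1L, hotspot_well = 2L,
                             well_radius = 3.5, depth0 = 8, depth_step = 1.5,
                             lambda = 2.0, site_radius = 6) {
  ligand <- match.arg(ligand)
  if (k < 1 || k > 20) abort("k must be in 1..20")
  structure(
    list(k = as.integer(k), ligand = ligand,
         native_well = as.integer(native_well),
         hotspot_well = as.integer(hotspot_well),
         well_radius = well_radius, depth0 = depth0,
         depth_step = depth_step, lambda = lambda,
         site_radius = site_radius),
    class = "qd_toy_spec"
  )
}

toy_triad_ligand <- function() {
  coords <- rbind(c(0, 0, 0), c(1.45, 0, 0), c(2.15, 1.15, 0.35))
  qd_ligand(
    qd_atoms(c("C", "N", "O"), coords),
    bonds = data.frame(i = c(1, 2), j = c(2, 3), order = 1L)
  )
}

toy_square_ligand <- function(side = 2.2) {
  h <- side / 2
  coords <- rbind(c(-h, -h, 0), c(h, -h, 0), c(h, h, 0), c(-h, h, 0))
  qd_ligand(
    qd_atoms(rep("C", 4), coords),
    bonds = data.frame(i = c(1, 2, 3, 4), j = c(2, 3, 4, 1), order = 1L)
  )
}

#' Toy n-carbon chain ligand (butane- and pentane-like)
#'
#' Built in the all-anti conformation with 1.53 Angstrom bonds and 112 degree
#' angles; interior bonds are rotatable torsions.
#'
#' @param n Number of carbon atoms (>= 2).
#' @export
toy_chain_ligand <- function(n = 4L) {
  bond <- 1.53; angle <- 112 * pi / 180
  # bond directions alternate +/- half the supplement about x: planar zigzag
  # with the exact bond angle at every interior atom (all-anti chain)
  half <- (pi - angle) / 2
  coords <- matrix(0, n, 3)
  for (i in seq_len(n)[-1]) {
    s <- if (i %% 2 == 0) 1 else -1
    coords[i, ] <- coords[i - 1, ] + bond * c(cos(half), s * sin(half), 0)
  }
  qd_ligand(
    qd_atoms(rep("C", n), coords),
    bonds = data.frame(i = seq_len(n - 1), j = 2:n, order = 1L)
  )
}

#' Double-well torsional toy (butane-like)
#'
#' A 4-carbon chain with one rotatable torsion and a smooth intramolecular
#' model: stiff pairwise springs fix bonds and angles while a quartic
#' double-well in the 1-4 distance carves a gauche well and an anti well of
#' different depths. The two well energies are enumerable from a torsion
#' grid.
#'
#' @param h Double-well stiffness, kcal/mol/Angstrom^4.
#' @param tilt Linear tilt making the two wells inequivalent, kcal/mol/Angstrom.
#' @param spring_k Spring constant for the rigid part, kcal/mol/Angstrom^2.
#' @return List with `ligand` and `model` (a `qd_energy_model`).
#' @export
toy_butane <- function(h = 8, tilt = 0.3, spring_k = 500) {
  ligand <- toy_chain_ligand(4L)
  ref <- ligand_pose(ligand)
  gauche <- set_torsion(ref, ligand, 1L, 65)
  d_g <- sqrt(sum((gauche[1, ] - gauche[4, ])^2))
  d_a <- sqrt(sum((ref[1, ] - ref[4, ])^2))
  model <- terms_model(
    name = "butane-toy",
    springs = rigid_springs(ref, k = spring_k, skip = list(c(1, 4))),
    pair_wells = data.frame(i = 1, j = 4, d1 = d_g, d2 = d_a,
                            h = h, tilt = tilt)
  )
  list(ligand = ligand, model = model, d_gauche = d_g, d_anti = d_a)
}

#' Build a toy complex with an enumerable minima landscape
#'
#' The receptor is a ring of carbon pseudo-atoms around a concave site, plus
#' one oxygen "hotspot" above the `hotspot_well` centroid that only the
#' stage-2 surrogate feels. The stage-1 model is a sum of `k` full-pose
#' attraction wells of distinct depths centered on a circle inside the site;
#' the stage-2 surrogate is a soft Lennard-Jones plus damped-Coulomb pairwise
#' model whose charges make the hotspot well its global minimum, so
#' re-ranking genuinely permutes the stage-1 order.
#'
#' The complete oracle minima list is computed by brute-force enumeration: a
#' dense translation grid crossed with a fixed orientation set, each start
#' refined by L-BFGS, deduplicated by heavy-atom RMSD.
#'
#' @param spec A `qd_toy_spec`.
#' @param oracle Also enumerate the oracle minima list (default `TRUE`).
#' @return List with `receptor`, `ligand`, `stage1_model`, `surrogate_model`,
#'   `native_pose`, `well_targets`, and `oracle` (tibble with `energy` and a
#'   `pose` list-column, ascending energy).
#' @export
build_toy_complex <- function(spec = toy_complex_spec(), oracle = TRUE) {
  ligand <- switch(spec$ligand,
    triad = toy_triad_ligand(),
    square = toy_square_ligand(),
    chain5 = toy_chain_ligand(5L)
  )
  ref <- ligand_pose(ligand)
  ref_centered <- sweep(ref, 2, colMeans(ref), "-")

  if (spec$k <= 6) {
    # circle in the site plane; adjacent wells stay well separated
    ang <- 2 * pi * (seq_len(spec$k) - 1) / max(spec$k, 2)
    centroids <- cbind(spec$well_radius * cos(ang),
                       spec$well_radius * sin(ang), 0)
  } else {
    # Fibonacci sphere: larger well counts keep pairwise separations that a
    # circle of feasible radius cannot
    r3 <- spec$well_radius + 0.7
    i <- seq_len(spec$k)
    z <- 1 - 2 * (i - 0.5) / spec$k
    th <- pi * (1 + sqrt(5)) * i
    centroids <- r3 * cbind(sqrt(1 - z^2) * cos(th),
                            sqrt(1 - z^2) * sin(th), z)
  }
  base_targets <- lapply(seq_len(spec$k), function(w) {
    sweep(ref_centered, 2, centroids[w, ], "+")
  })
  depths <- spec$depth0 + spec$depth_step * (spec$k - seq_len(spec$k) + 1)

  # A symmetric ligand's wells are expanded over its graph automorphisms so
  # the landscape is invariant under relabeling of equivalent atoms; the
  # oracle minima then come in symmetry-equivalent groups of equal energy.
  targets <- list(); target_depths <- numeric(0)
  autos <- ligand_automorphisms(ligand)
  for (w in seq_len(spec$k)) {
    seen <- list()
    for (m in autos) {
      tgt <- base_targets[[w]][order(m), , drop = FALSE]
      dup <- any(vapply(seen, function(s) max(abs(s - tgt)) < 1e-9, logical(1)))
      if (!dup) seen[[length(seen) + 1L]] <- tgt
    }
    targets <- c(targets, seen)
    target_depths <- c(target_depths, rep(depths[w], length(seen)))
  }

  wells <- lapply(seq_along(targets), function(i) {
    list(target = targets[[i]], depth = target_depths[i], lambda = spec$lambda)
  })
  springs <- rigid_springs(ref, k = 400)
  stage1 <- terms_model("toy-field", springs = springs, field_wells = wells)

  ring_n <- 8
  ring_ang <- 2 * pi * (seq_len(ring_n) - 1) / ring_n
  ring <- cbind(7.5 * cos(ring_ang), 7.5 * sin(ring_ang), 0)
  hc <- centroids[min(spec$hotspot_well, spec$k), ]
  hotspot <- if (abs(hc[3]) < 1e-9) c(hc[1:2], 3.0) else
    hc * (1 + 3.0 / sqrt(sum(hc^2)))  # radially outward, 3 Angstrom clear
  rec_coords <- rbind(ring, hotspot)
  receptor <- qd_receptor(
    qd_atoms(c(rep("C", ring_n), "O"), rec_coords),
    site_center = c(0, 0, 0), site_radius = spec$site_radius
  )

  lig_charge <- c(C = 0.15, N = 0.35, O = -0.20)[ligand$atoms$element]
  rec_charge <- c(rep(0.08, ring_n), -0.90)
  surrogate <- terms_model(
    "toy-surrogate",
    springs = springs,
    pair_params = list(q_lig = unname(lig_charge), q_rec = rec_charge,
                       eps = 0.08, sigma = 3.2, delta = 0.5)
  )

  oracle_tbl <- NULL
  native_pose <- base_targets[[min(spec$native_well, spec$k)]]
  if (oracle) {
    oracle_tbl <- enumerate_toy_minima(stage1, receptor, ligand, spec)
    if (nrow(oracle_tbl) < length(targets)) {
      abort(sprintf(
        "oracle enumeration found %d basins, fewer than the %d designed wells",
        nrow(oracle_tbl), length(targets)
      ))
    }
    # native = the oracle minimum nearest the designated well's target
    nat_idx <- which.min(vapply(oracle_tbl$pose, function(p) {
      heavy_rmsd(p, native_pose, ligand)
    }, numeric(1)))
    native_pose <- oracle_tbl$pose[[nat_idx]]
  }

  list(receptor = receptor, ligand = ligand, stage1_model = stage1,
       surrogate_model = surrogate, native_pose = native_pose,
       well_targets = targets, well_depths = target_depths,
       spec = spec, oracle = oracle_tbl)
}

# Fixed orientation set for the oracle grid: identity plus skew rotations.
# Deliberately non-symmetric (irrational-looking axes and angles): starts on
# an exact symmetry axis of a well would sit on the invariant manifold of an
# orientation saddle and "converge" onto it instead of sliding off.
oracle_orientations <- function(n = 9L) {
  # deterministic low-discrepancy-ish axis/angle sequence
  rots <- list(diag(3))
  phi <- (1 + sqrt(5)) / 2
  i <- 1L
  while (length(rots) < n) {
    z <- 1 - 2 * ((i * phi) %% 1)
    th <- 2 * pi * ((i * phi^2) %% 1)
    ax <- c(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
    ang <- 0.4 + 5.5 * ((i * sqrt(2)) %% 1)
    rots[[length(rots) + 1L]] <- axis_angle_matrix(ax, ang)
    i <- i + 1L
  }
  rots
}

#' Enumerate all stage-1 minima of a toy complex by brute force
#'
#' Dense deterministic translation grid (step `grid_step`) over the site
#' ball, crossed with a fixed orientation set; every grid pose is refined by
#' L-BFGS and the refined minima are deduplicated by heavy-atom RMSD.
#' Independent of the stochastic search path: no random numbers involved.
#'
#' @param model Stage-1 `qd_energy_model`.
#' @param receptor,ligand Toy complex members.
#' @param spec The `qd_toy_spec`.
#' @param grid_step Translation grid spacing, Angstrom.
#' @param dedup_rmsd RMSD below which two refined minima are one basin.
#' @return Tibble with `energy` (ascending) and `pose` list-column.
#' @export
enumerate_toy_minima <- function(model, receptor, ligand, spec,
                                 grid_step = 2.0, dedup_rmsd = 0.5,
                                 n_orient = NULL) {
  ref <- ligand_pose(ligand)
  ref_centered <- sweep(ref, 2, colMeans(ref), "-")
  ax <- seq(-spec$site_radius, spec$site_radius, by = grid_step)
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  grid <- grid[rowSums(grid^2) <= spec$site_radius^2, , drop = FALSE]
  if (is.null(n_orient)) {
    # symmetric ligands have one basin per label assignment: cover
    # orientation space more densely for them
    n_orient <- if (length(ligand_automorphisms(ligand)) > 1) 30L else 9L
  }
  rots <- oracle_orientations(n_orient)
  cfg <- optimizer_config(grad_tol = 1e-4, max_iter = 4000L)

  energies <- numeric(0)
  poses <- list()
  for (r in rots) {
    oriented <- ref_centered %*% t(r)
    for (gidx in seq_len(nrow(grid))) {
      start <- sweep(oriented, 2, grid[gidx, ], "+")
      res <- optimize_pose(model, receptor, ligand, start, cfg)
      if (!is.null(res$error) || !res$converged) next
      dup <- FALSE
      for (i in seq_along(poses)) {
        if (heavy_rmsd(res$pose, poses[[i]], ligand) < dedup_rmsd) {
          dup <- TRUE
          if (res$energy < energies[i]) {
            energies[i] <- res$energy
            poses[[i]] <- res$pose
          }
          break
        }
      }
      if (!dup) {
        energies <- c(energies, res$energy)
        poses[[length(poses) + 1L]] <- res$pose
      }
    }
  }
  # Saddle rejection: a true minimum survives small deterministic kicks; a
  # flat saddle reached along an invariant direction does not. Re-optimize
  # from perturbed copies and drop candidates that escape their basin.
  keep <- vapply(seq_along(poses), function(i) {
    n <- nrow(poses[[i]])
    for (s in 1:2) {
      kick <- 0.05 * matrix(sin(s * seq_len(3 * n) + i), n, 3)
      res <- optimize_pose(model, receptor, ligand, poses[[i]] + kick, cfg)
      if (is.null(res$error) &&
          heavy_rmsd(res$pose, poses[[i]], ligand) >= dedup_rmsd) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  energies <- energies[keep]
  poses <- poses[keep]
  ord <- order(energies)
  tibble(energy = energies[ord], pose = poses[ord])
}

#' Serialize a toy complex's energy-model parameters to YAML
#'
#' Writes the stage-1 well field (targets, depths, width) and the stage-2
#' surrogate parameters, so a command-line run can rebuild both models from
#' plain-text artifacts.
#'
#' @param toy A toy complex from [build_toy_complex()].
#' @param path Output YAML path.
#' @export
toy_model_to_yaml <- function(toy, path) {
  obj <- list(
    lambda = toy$spec$lambda,
    spring_k = 400,
    depths = as.numeric(toy$well_depths),
    targets = lapply(toy$well_targets, function(t) {
      lapply(seq_len(nrow(t)), function(i) as.numeric(t[i, ]))
    }),
    surrogate = list(
      q_lig = as.numeric(c(C = 0.15, N = 0.35,
                           O = -0.20)[toy$ligand$atoms$element]),
      q_rec = c(rep(0.08, nrow(toy$receptor$atoms) - 1), -0.90),
      eps = 0.08, sigma = 3.2, delta = 0.5
    )
  )
  writeLines(yaml::as.yaml(obj), path)
  invisible(path)
}

#' Rebuild toy stage-1 and surrogate models from a YAML parameter file
#'
#' @param path YAML written by [toy_model_to_yaml()].
#' @param ligand The matching `qd_ligand`.
#' @return List with `stage1_model` and `surrogate_model`.
#' @export
toy_model_from_yaml <- function(path, ligand) {
  if (!file.exists(path)) abort(sprintf("no such model file: %s", path))
  obj <- yaml::read_yaml(path)
  springs <- rigid_springs(ligand_pose(ligand), k = obj$spring_k)
  wells <- lapply(seq_along(obj$targets), function(i) {
    list(target = do.call(rbind, obj$targets[[i]]),
         depth = obj$depths[i], lambda = obj$lambda)
  })
  list(
    stage1_model = terms_model("toy-field", springs = springs,
                               field_wells = wells),
    surrogate_model = terms_model(
      "toy-surrogate", springs = springs,
      pair_params = list(q_lig = obj$surrogate$q_lig,
                         q_rec = obj$surrogate$q_rec,
                         eps = obj$surrogate$eps,
                         sigma = obj$surrogate$sigma,
                         delta = obj$surrogate$delta)
    )
  )
}

# ---- packaged benchmark tables ---------------------------------------------

paper_table_checksums <- c(
  table1_complexes.tsv = "77ad6a36d2b665bf5d00bc637f3543c9",
  table2_positioning.tsv = "800a2c449c8b4579011b29de5625e182",
  table3_enthalpy.tsv = "891ee28d838e378e71cba95da0554198",
  table3_exclusions.tsv = "c1a5fca4d0e0435b7d48c7a8542a7828"
)

#' Load the packaged benchmark tables
#'
#' Returns the packaged 25-complex benchmark: per-complex characteristics
#' (atom and torsion counts), the positioning results (N_min, INN, and
#' global-minimum RMSD under both stage-2 methods), the binding-enthalpy
#' table (12 complexes with measured and calculated values; two calculated
#' values are missing for one method), and the exclusion metadata naming the
#' complexes left out of the enthalpy correlation and why.
#'
#' @return List of tibbles: `table1`, `table2`, `table3`, `exclusions`.
#' @export
load_paper_tables <- function() {
  dir <- system.file("extdata", package = "quasidock")
  paths <- file.path(dir, names(paper_table_checksums))
  missing <- !file.exists(paths)
  if (any(missing)) {
    abort(paste("packaged table files missing:",
                paste(names(paper_table_checksums)[missing], collapse = ", ")))
  }
  sums <- tools::md5sum(paths)
  ok <- unname(sums) == unname(paper_table_checksums)
  if (!all(ok)) {
    abort(paste("checksum mismatch for:",
                paste(names(paper_table_checksums)[!ok], collapse = ", ")))
  }
  rd <- function(f) as_tibble(read.delim(file.path(dir, f), sep = "\t",
                                         check.names = FALSE))
  list(
    table1 = rd("table1_complexes.tsv"),
    table2 = rd("table2_positioning.tsv"),
    table3 = rd("table3_enthalpy.tsv"),
    exclusions = rd("table3_exclusions.tsv")
  )
}
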