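# Positioning metrics (heavy-atom RMSD, symmetry-corrected RMSD, INN),
# docking-paradigm verdicts, the binding-enthalpy protocol, and benchmark
# summary statistics.

#' Heavy-atom RMSD between two poses of the same ligand
#'
#' Docking convention: both poses live in the common receptor frame and no
#' superposition is applied. Only heavy (non-hydrogen) atoms enter. An atom
#' `mapping` may re-index the heavy atoms of `pose_b` (it must be a
#' permutation of the heavy-atom indices, normally a bond-graph
#' automorphism); by default the identity mapping fixed at load time is used.
#'
#' @param pose_a,pose_b Pose matrices sharing the ligand's atom order.
#' @param ligand The `qd_ligand`.
#' @param mapping Optional integer vector over all atoms: atom `i` of
#'   `pose_a` is compared with atom `mapping[i]` of `pose_b`.
#' @return RMSD in Angstrom.
#' @export
heavy_rmsd <- function(pose_a, pose_b, ligand, mapping = NULL) {
  pose_a <- qd_pose(pose_a, ligand)
  pose_b <- qd_pose(pose_b, ligand)
  hv <- heavy_atoms(ligand)
  if (is.null(mapping)) {
    mapping <- seq_len(nrow(pose_a))
  }
  mh <- mapping[hv]
  if (length(unique(mh)) != length(hv) || !all(mh %in% hv)) {
    abort("mapping is not a bijection on the heavy atoms")
  }
  sqrt(mean(rowSums((pose_a[hv, , drop = FALSE] -
                       pose_b[mh, , drop = FALSE])^2)))
}

#' Element- and bond-preserving automorphisms of the heavy-atom graph
#'
#' Enumerated with the VF2 matcher on the heavy-atom bond graph, with
#' element symbols as vertex colors and bond orders as edge colors. Each
#' automorphism is returned as a full-atom mapping vector (hydrogens map to
#' themselves).
#'
#' @param ligand A `qd_ligand`.
#' @param cap Error if more than this many automorphisms exist (supply an
#'   explicit mapping instead). Default 10000.
#' @return List of integer mapping vectors; the identity is always first.
#' @export
ligand_automorphisms <- function(ligand, cap = 10000L) {
  hv <- heavy_atoms(ligand)
  n <- nrow(ligand$atoms)
  hb <- ligand$bonds[ligand$bonds$i %in% hv & ligand$bonds$j %in% hv, ,
                     drop = FALSE]
  idx <- match(seq_len(n), hv)  # full index -> heavy index
  g <- igraph::make_empty_graph(n = length(hv), directed = FALSE)
  if (nrow(hb) > 0) {
    g <- igraph::add_edges(g, rbind(idx[hb$i], idx[hb$j]))
  }
  vcol <- as.integer(factor(ligand$atoms$element[hv]))
  ecol <- if (nrow(hb) > 0) as.integer(hb$order) else integer(0)
  maps <- igraph::graph.get.isomorphisms.vf2(
    g, g, vertex.color1 = vcol, vertex.color2 = vcol,
    edge.color1 = ecol, edge.color2 = ecol
  )
  if (length(maps) > cap) {
    abort(sprintf(
      "%d automorphisms exceed the cap (%d); supply an explicit mapping",
      length(maps), cap
    ))
  }
  out <- lapply(maps, function(m) {
    full <- seq_len(n)
    full[hv] <- hv[as.integer(m)]
    full
  })
  is_id <- vapply(out, function(m) all(m == seq_len(n)), logical(1))
  c(out[is_id], out[!is_id])
}

#' Symmetry-corrected heavy-atom RMSD
#'
#' Minimum of [heavy_rmsd()] over all element- and bond-preserving
#' automorphisms of the ligand's heavy-atom graph, so chemically equivalent
#' binding modes (e.g. a two-fold symmetric ring flipped 180 degrees) are
#' not penalized.
#'
#' @inheritParams heavy_rmsd
#' @param cap Automorphism cap, as in [ligand_automorphisms()].
#' @return List with `rmsd` (Angstrom) and `mapping` (the minimizer).
#' @export
symmetry_corrected_rmsd <- function(pose_a, pose_b, ligand, cap = 10000L) {
  maps <- ligand_automorphisms(ligand, cap = cap)
  vals <- vapply(maps, function(m) heavy_rmsd(pose_a, pose_b, ligand, m),
                 numeric(1))
  best <- which.min(vals)
  list(rmsd = vals[best], mapping = maps[[best]])
}

#' Index Near Native (INN) and global-minimum RMSD
#'
#' Minima are ranked in ascending stage-2 energy (rank 1 = global minimum).
#' INN is the smallest rank whose heavy-atom RMSD to the native pose is below
#' `cutoff` (strictly; a boundary value is a failure); `NA` when no ranked
#' minimum is near-native. `rmsd_gm` is the RMSD of the rank-1 pose. RMSD is
#' symmetry-corrected by default; with several equivalent native references
#' (e.g. two symmetric sites of a homodimer receptor) the minimum over
#' references is taken.
#'
#' @param pool A rescored, ranked `qd_pool`.
#' @param native Native pose matrix (crystallographic reference).
#' @param cutoff Near-native RMSD cutoff, Angstrom. Default 2.
#' @param symmetry Apply symmetry correction (default `TRUE`).
#' @param alt_native Optional list of additional native reference poses.
#' @return List with `inn` (integer or `NA`) and `rmsd_gm` (Angstrom).
#' @export
compute_inn <- function(pool, native, cutoff = 2.0, symmetry = TRUE,
                        alt_native = NULL) {
  if (all(is.na(pool$rank))) abort("pool is not ranked; rescore it first")
  native_refs <- c(list(qd_pose(native, pool$ligand)), alt_native)
  n_ranked <- sum(!is.na(pool$rank))
  rmsd_of <- function(pose) {
    min(vapply(native_refs, function(ref) {
      if (symmetry) {
        symmetry_corrected_rmsd(pose, ref, pool$ligand)$rmsd
      } else {
        heavy_rmsd(pose, ref, pool$ligand)
      }
    }, numeric(1)))
  }
  inn <- NA_integer_
  rmsd_gm <- NA_real_
  for (r in seq_len(n_ranked)) {
    v <- rmsd_of(pool_pose(pool, r, by_rank = TRUE))
    if (r == 1L) rmsd_gm <- v
    if (v < cutoff) {
      inn <- r
      break
    }
  }
  list(inn = inn, rmsd_gm = rmsd_gm)
}

#' Docking-paradigm verdict for one evaluated complex
#'
#' The paradigm -- the bound pose sits at the global energy minimum -- is
#' satisfied iff INN equals 1. A missing INN (no near-native minimum at all)
#' is a failure.
#'
#' @param inn INN value (integer or `NA`), or a list/row with an `inn` field.
#' @return `TRUE` iff `inn == 1`.
#' @export
paradigm_verdict <- function(inn) {
  if (is.list(inn)) inn <- inn$inn
  !is.na(inn) && inn == 1L
}

#' Count docking-paradigm failures over a set of complexes
#'
#' @param inn Integer vector of INN values (`NA` = no near-native minimum,
#'   counted as failure), or a data frame with an `inn` column.
#' @return Number of complexes with INN != 1.
#' @export
count_paradigm_failures <- function(inn) {
  if (is.data.frame(inn)) inn <- inn$inn
  if (length(inn) == 0) abort("no evaluation rows")
  sum(is.na(inn) | inn != 1L)
}

#' Protein-ligand binding enthalpy from global-minimum energies
#'
#' `dH_bind = E1(PL) - E1(P) - E1(L)`, all in kcal/mol and all from the same
#' stage-2 method/solvent combination. Components may carry a `method`
#' attribute; mixing methods is an error.
#'
#' @param e1_pl,e1_p,e1_l Global-minimum energies of the complex, the
#'   unbound protein, and the unbound ligand, kcal/mol.
#' @return dH_bind in kcal/mol.
#' @export
binding_enthalpy <- function(e1_pl, e1_p, e1_l) {
  methods <- c(attr(e1_pl, "method"), attr(e1_p, "method"),
               attr(e1_l, "method"))
  if (length(unique(methods)) > 1) {
    abort(sprintf("mixed-method components: %s",
                  paste(methods, collapse = ", ")))
  }
  as.numeric(e1_pl) - as.numeric(e1_p) - as.numeric(e1_l)
}

#' Binding-enthalpy protocol
#'
#' Computes the three components entering the enthalpy estimate:
#' * `e1_pl`: the complex is relaxed from the global-minimum pose by varying
#'   all ligand Cartesians under the vacuum stage-2 model, then the solvent
#'   stage-2 model is evaluated single-point at the relaxed geometry;
#' * `e1_p`: solvent-model energy of the receptor in its fixed docking
#'   conformation (no relaxation);
#' * `e1_l`: each unbound-ligand conformer in `ligand_pool` is relaxed under
#'   the vacuum model, the solvent model is evaluated single-point at each
#'   relaxed conformer, and the minimum is taken.
#'
#' @param gm_pose Rank-1 (global minimum) pose of the complex.
#' @param receptor A `qd_receptor`.
#' @param ligand A `qd_ligand`.
#' @param vacuum_model,solvent_model Stage-2 `qd_energy_model`s without and
#'   with solvent. Pass the same model for both if the backend has no
#'   solvent split.
#' @param ligand_pool List of unbound-ligand conformer poses.
#' @param config Optimizer configuration for the relaxations.
#' @return List with `e1_pl`, `e1_p`, `e1_l`, `dh_bind` (kcal/mol).
#' @export
enthalpy_protocol <- function(gm_pose, receptor, ligand, vacuum_model,
                              solvent_model, ligand_pool,
                              config = optimizer_config()) {
  if (length(ligand_pool) == 0) abort("ligand_pool must hold >= 1 conformer")
  relaxed <- optimize_pose(vacuum_model, receptor, ligand, gm_pose, config)
  if (!is.null(relaxed$error)) {
    abort(paste("complex relaxation failed:", relaxed$error))
  }
  e1_pl <- solvent_model$evaluate(receptor, ligand, relaxed$pose)
  e1_p <- solvent_model$receptor_energy(receptor)
  e1_l <- min(vapply(ligand_pool, function(conf) {
    r <- optimize_ligand_alone(vacuum_model, ligand, conf, config)
    if (!is.null(r$error)) abort(paste("ligand relaxation failed:", r$error))
    solvent_model$evaluate(empty_receptor(), ligand, r$pose)
  }, numeric(1)))
  list(e1_pl = e1_pl, e1_p = e1_p, e1_l = e1_l,
       dh_bind = binding_enthalpy(e1_pl, e1_p, e1_l))
}

#' Pearson correlation over complete pairs
#'
#' Pairs with either value missing are dropped first. Errors below 3 complete
#' pairs or at zero variance.
#'
#' @param x,y Numeric vectors of equal length (kcal/mol in the enthalpy use).
#' @return The sample Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("zero variance")
  cor(x, y)
}

#' Positioning summary over evaluation rows
#'
#' @param rows Tibble with columns `complex_id`, `inn`, `rmsd_gm` (and
#'   optionally `n_min`).
#' @return One-row tibble with totals, failures, and the success count.
#' @export
positioning_summary <- function(rows) {
  failures <- count_paradigm_failures(rows)
  tibble(
    n_complexes = nrow(rows),
    paradigm_failures = failures,
    paradigm_successes = nrow(rows) - failures
  )
}
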