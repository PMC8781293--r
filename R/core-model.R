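# Domain types shared by all stages: atoms, ligand topology, rigid receptor,
# poses, and the two-stage energy-model contract.

#' Build an atom table
#'
#' Atoms are kept as a tibble with one row per atom. Heavy-atom status is
#' derived from the element symbol (everything except hydrogen counts as
#' heavy); RMSD-based metrics in this package operate on heavy atoms only.
#'
#' @param element Character vector of element symbols (e.g. `"C"`, `"N"`).
#' @param coords Numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param name Optional atom names (opaque labels).
#' @param residue Optional residue tags (opaque labels).
#' @return A tibble with columns `element`, `x`, `y`, `z`, `name`, `residue`,
#'   `is_heavy`.
#' @export
qd_atoms <- function(element, coords, name = NULL, residue = NULL) {
  coords <- as_coord_matrix(coords, length(element))
  if (!all(is.finite(coords))) {
    abort("atom coordinates must be finite numbers")
  }
  element <- as.character(element)
  tibble(
    element = element,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    name = if (is.null(name)) element else as.character(name),
    residue = if (is.null(residue)) "" else as.character(residue),
    is_heavy = toupper(element) != "H"
  )
}

as_coord_matrix <- function(coords, n_expected = NULL) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3) {
    abort("coordinates must be an n x 3 matrix")
  }
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (!is.null(n_expected) && nrow(coords) != n_expected) {
    abort(sprintf(
      "coordinate rows (%d) do not match atom count (%d)",
      nrow(coords), n_expected
    ))
  }
  coords
}

#' Ligand topology: atoms, bonds, rotatable torsions, formal charge
#'
#' The bond graph must be connected. Rotatable torsions are internal rotations
#' about ordinary (single-order, acyclic) bonds; each is stored as a 4-atom
#' index tuple `(a, b, c, d)` where `b-c` is the rotated bond. If `torsions`
#' is `NULL` they are enumerated automatically from the bond table.
#'
#' @param atoms Atom tibble from [qd_atoms()].
#' @param bonds Data frame with integer columns `i`, `j` and `order`.
#' @param torsions Optional list of integer 4-vectors, or `NULL` to enumerate.
#' @param formal_charge Integer net charge of the ligand, in units of e.
#' @return An object of class `qd_ligand`.
#' @export
qd_ligand <- function(atoms, bonds, torsions = NULL, formal_charge = 0L) {
  stopifnot(is_tibble(atoms) || is.data.frame(atoms))
  n <- nrow(atoms)
  if (n < 1) abort("ligand must contain at least one atom")
  bonds <- as.data.frame(bonds)
  if (!all(c("i", "j") %in% names(bonds))) {
    abort("bonds need columns i and j")
  }
  if (is.null(bonds$order)) bonds$order <- rep(1L, nrow(bonds))
  if (nrow(bonds) > 0 &&
      (any(bonds$i < 1 | bonds$i > n) || any(bonds$j < 1 | bonds$j > n))) {
    abort("bond indices out of range of the atom list")
  }
  g <- bond_graph(n, bonds)
  if (n > 1 && igraph::components(g)$no != 1) {
    abort("ligand bond graph is not connected")
  }
  ring_edge <- bonds_in_rings(g, bonds)
  if (is.null(torsions)) {
    torsions <- enumerate_torsions(atoms, bonds, g, ring_edge)
  } else {
    torsions <- lapply(torsions, function(t) {
      t <- as.integer(t)
      if (length(t) != 4) abort("each torsion is a 4-atom index tuple")
      validate_torsion_bond(t, bonds, ring_edge)
      t
    })
  }
  graph_dist <- igraph::distances(g)
  structure(
    list(
      atoms = as_tibble(atoms),
      bonds = tibble(
        i = as.integer(bonds$i), j = as.integer(bonds$j),
        order = as.integer(bonds$order), in_ring = ring_edge
      ),
      torsions = torsions,
      formal_charge = as.integer(formal_charge),
      graph = g,
      graph_dist = graph_dist
    ),
    class = "qd_ligand"
  )
}

bond_graph <- function(n, bonds) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds) > 0) {
    g <- igraph::add_edges(g, rbind(as.integer(bonds$i),
                                    as.integer(bonds$j)))
  }
  g
}

# An edge lies in a ring iff its endpoints stay connected after removal.
bonds_in_rings <- function(g, bonds) {
  if (nrow(bonds) == 0) return(logical(0))
  vapply(seq_len(nrow(bonds)), function(k) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(bonds$i[k], bonds$j[k])))
    igraph::distances(g2, v = bonds$i[k], to = bonds$j[k])[1, 1] < Inf
  }, logical(1))
}

validate_torsion_bond <- function(t, bonds, ring_edge) {
  hit <- which((bonds$i == t[2] & bonds$j == t[3]) |
                 (bonds$i == t[3] & bonds$j == t[2]))
  if (length(hit) == 0) abort("torsion central pair is not a bond")
  if (bonds$order[hit[1]] != 1L) {
    abort("torsion central bond must be a single (ordinary) bond")
  }
  if (ring_edge[hit[1]]) {
    abort("torsion central bond must not be part of a ring")
  }
  invisible(t)
}

# Rotatable torsions: single-order acyclic bonds with non-terminal endpoints.
# Reference atoms a and d are the lowest-index neighbours off the bond.
enumerate_torsions <- function(atoms, bonds, g, ring_edge) {
  out <- list()
  if (nrow(bonds) == 0) return(out)
  adj <- igraph::as_adj_list(g)
  for (k in seq_len(nrow(bonds))) {
    if (bonds$order[k] != 1L || ring_edge[k]) next
    b <- as.integer(bonds$i[k]); c <- as.integer(bonds$j[k])
    nb <- setdiff(as.integer(adj[[b]]), c)
    nc <- setdiff(as.integer(adj[[c]]), b)
    if (length(nb) == 0 || length(nc) == 0) next  # terminal bond
    out[[length(out) + 1L]] <- c(min(nb), b, c, min(nc))
  }
  out
}

#' Extract ligand coordinates as a pose matrix
#' @param ligand A `qd_ligand`.
#' @return Numeric n x 3 matrix (Angstrom).
#' @export
ligand_pose <- function(ligand) {
  as_coord_matrix(cbind(ligand$atoms$x, ligand$atoms$y, ligand$atoms$z))
}

#' Indices of heavy (non-hydrogen) ligand atoms
#' @param ligand A `qd_ligand`.
#' @export
heavy_atoms <- function(ligand) which(ligand$atoms$is_heavy)

#' Rigid receptor with a binding-site sphere
#'
#' Receptor coordinates never change during a run. The only positional
#' restriction the search applies is that the ligand's geometric center stays
#' within `site_radius` of `site_center`.
#'
#' @param atoms Atom tibble from [qd_atoms()] (may have zero rows).
#' @param site_center Numeric 3-vector, Angstrom.
#' @param site_radius Positive sphere radius, Angstrom. Default 8.
#' @return An object of class `qd_receptor`.
#' @export
qd_receptor <- function(atoms, site_center, site_radius = 8) {
  if (length(site_center) != 3 || !all(is.finite(site_center))) {
    abort("site_center must be a finite 3-vector")
  }
  if (!is.numeric(site_radius) || site_radius <= 0) {
    abort("site_radius must be > 0")
  }
  structure(
    list(
      atoms = as_tibble(atoms),
      coords = if (nrow(atoms) > 0)
        as_coord_matrix(cbind(atoms$x, atoms$y, atoms$z)) else
        matrix(numeric(0), 0, 3),
      site_center = as.numeric(site_center),
      site_radius = as.numeric(site_radius)
    ),
    class = "qd_receptor"
  )
}

#' An empty receptor (used for unbound-ligand protocols)
#' @param site_radius Sphere radius for sampling, Angstrom.
#' @export
empty_receptor <- function(site_radius = 8) {
  qd_receptor(qd_atoms(character(0), matrix(numeric(0), 0, 3)),
              site_center = c(0, 0, 0), site_radius = site_radius)
}

#' Validate a pose against a ligand
#' @param pose Numeric n x 3 matrix.
#' @param ligand A `qd_ligand`.
#' @return The pose as a plain double matrix.
#' @export
qd_pose <- function(pose, ligand) {
  as_coord_matrix(pose, nrow(ligand$atoms))
}

#' Energy-model contract
#'
#' Both stages of quasi-docking plug into the same contract: `evaluate` maps
#' (receptor, ligand, pose) to an energy in kcal/mol and must be deterministic
#' for identical inputs. `gradient` is optional; single-point-only backends
#' (external quantum-chemistry programs) omit it and a central
#' finite-difference fallback is used where a gradient is needed.
#' `receptor_energy` returns the energy of the unbound receptor in its fixed
#' conformation (the E1(P) term of the binding-enthalpy protocol); models
#' whose receptor contribution is an additive constant may leave it at 0.
#'
#' @param name Model name.
#' @param evaluate `function(receptor, ligand, pose) -> kcal/mol`.
#' @param gradient Optional `function(receptor, ligand, pose) -> n x 3 matrix`
#'   in kcal/mol/Angstrom.
#' @param receptor_energy Optional `function(receptor) -> kcal/mol`.
#' @return An object of class `qd_energy_model`.
#' @export
energy_model <- function(name, evaluate, gradient = NULL,
                         receptor_energy = function(receptor) 0) {
  stopifnot(is.function(evaluate))
  structure(
    list(name = name, evaluate = evaluate, gradient = gradient,
         receptor_energy = receptor_energy),
    class = "qd_energy_model"
  )
}

#' Gradient of an energy model, using the analytic form when available
#' @inheritParams finite_difference_gradient
#' @export
model_gradient <- function(model, receptor, ligand, pose, h = 1e-4) {
  if (!is.null(model$gradient)) {
    model$gradient(receptor, ligand, pose)
  } else {
    finite_difference_gradient(model, receptor, ligand, pose, h = h)
  }
}

#' Central finite-difference gradient of an energy model
#'
#' Used whenever a model supplies no analytic gradient.
#'
#' @param model A `qd_energy_model`.
#' @param receptor A `qd_receptor`.
#' @param ligand A `qd_ligand`.
#' @param pose Numeric n x 3 pose matrix.
#' @param h Displacement step, Angstrom (> 0).
#' @return n x 3 matrix of kcal/mol/Angstrom.
#' @export
finite_difference_gradient <- function(model, receptor, ligand, pose,
                                       h = 1e-4) {
  if (!is.numeric(h) || h <= 0) abort("h must be > 0")
  pose <- qd_pose(pose, ligand)
  g <- matrix(0, nrow(pose), 3)
  for (a in seq_len(nrow(pose))) {
    for (d in 1:3) {
      p1 <- pose; p1[a, d] <- p1[a, d] + h
      p2 <- pose; p2[a, d] <- p2[a, d] - h
      e1 <- model$evaluate(receptor, ligand, p1)
      e2 <- model$evaluate(receptor, ligand, p2)
      if (!is.finite(e1) || !is.finite(e2)) {
        abort(sprintf(
          "non-finite energy while differencing atom %d (component %d)", a, d
        ))
      }
      g[a, d] <- (e1 - e2) / (2 * h)
    }
  }
  g
}
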