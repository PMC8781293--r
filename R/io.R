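# Structure and pool I/O. Receptors arrive as PDB (read with bio3d), ligands
# as SDF/MOL V2000 (read with ChemmineR; carries the bond table) or as PDB
# with a distance-based bond-perception fallback. Pools serialize to one
# multi-record SDF (poses, with stage energies as SD tags) plus a TSV index;
# both are re-loadable losslessly at the printed precision.

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    abort(sprintf("package '%s' is required for this reader", pkg))
  }
}

#' Read a rigid receptor from a PDB file
#'
#' @param path PDB file path.
#' @param site_center Numeric 3-vector; when `NULL`, the geometric center of
#'   all receptor atoms is used (normally you pass the native ligand's
#'   center).
#' @param site_radius Binding-site sphere radius, Angstrom.
#' @return A `qd_receptor`.
#' @export
read_receptor_pdb <- function(path, site_center = NULL, site_radius = 8) {
  need_pkg("bio3d")
  if (!file.exists(path)) abort(sprintf("no such PDB file: %s", path))
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) {
                    abort(sprintf("failed to parse PDB %s: %s", path,
                                  conditionMessage(e)))
                  })
  at <- pdb$atom
  element <- trimws(at$elesy)
  blank <- is.na(element) | element == ""
  element[blank] <- substr(trimws(at$elety[blank]), 1, 1)
  coords <- cbind(at$x, at$y, at$z)
  atoms <- qd_atoms(element, coords, name = trimws(at$elety),
                    residue = paste0(at$resid, at$resno))
  if (is.null(site_center)) site_center <- colMeans(coords)
  qd_receptor(atoms, site_center, site_radius)
}

#' Read a ligand (with bond table) from an SDF/MOL file
#'
#' The first molecule of the file is used. Formal charge is taken from the
#' `M  CHG` block sum unless overridden.
#'
#' @param path SDF or MOL file path.
#' @param formal_charge Integer override, or `NULL` to use the file value.
#' @return A `qd_ligand` whose atom order fixes the identity RMSD mapping.
#' @export
read_ligand_sdf <- function(path, formal_charge = NULL) {
  need_pkg("ChemmineR")
  if (!file.exists(path)) abort(sprintf("no such SDF file: %s", path))
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  if (length(sdfset) < 1) abort(sprintf("no molecules in %s", path))
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  if (is.null(formal_charge)) {
    chg <- tryCatch(sum(ab[, "charge"]), error = function(e) 0)
    # MOL charge column codes: 0 none, 1..7 map to +3..-3 (4 = radical)
    code_to_charge <- c(3, 2, 1, 0, -1, -2, -3)
    formal_charge <- sum(ifelse(ab[, ncol(ab)] %in% 1:7 & ab[, ncol(ab)] != 4,
                                code_to_charge[ab[, ncol(ab)]], 0))
  }
  qd_ligand(qd_atoms(element, coords), bonds,
            formal_charge = as.integer(formal_charge))
}

#' Read a ligand from PDB with distance-based bond perception
#'
#' Fallback for ligands without a bond table: two atoms are bonded when
#' their distance is below 1.25 times the sum of their covalent radii. All
#' perceived bonds are treated as single bonds.
#'
#' @param path PDB file path.
#' @param formal_charge Integer net charge (PDB carries none reliably).
#' @return A `qd_ligand`.
#' @export
read_ligand_pdb <- function(path, formal_charge = 0L) {
  need_pkg("bio3d")
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  element <- trimws(at$elesy)
  blank <- is.na(element) | element == ""
  element[blank] <- substr(trimws(at$elety[blank]), 1, 1)
  coords <- cbind(at$x, at$y, at$z)
  bonds <- perceive_bonds(element, coords)
  qd_ligand(qd_atoms(element, coords, name = trimws(at$elety)), bonds,
            formal_charge = as.integer(formal_charge))
}

COVALENT_RADII <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07, S = 1.05,
  CL = 1.02, BR = 1.20, I = 1.39, B = 0.84, SI = 1.11, SE = 1.20
)

perceive_bonds <- function(element, coords, scale = 1.25) {
  r <- COVALENT_RADII[toupper(element)]
  if (any(is.na(r))) {
    abort(sprintf("no covalent radius for element(s): %s",
                  paste(unique(element[is.na(r)]), collapse = ", ")))
  }
  n <- length(element)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d < scale * (r[i] + r[j])) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(0), j = integer(0), order = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2], order = 1L)
}

# ---- writers ----------------------------------------------------------------

#' Write a receptor as a PDB file
#' @param receptor A `qd_receptor`.
#' @param path Output path.
#' @export
write_receptor_pdb <- function(receptor, path) {
  at <- receptor$atoms
  lines <- sprintf(
    "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(at)), substr(at$name, 1, 4), "TOY", seq_len(nrow(at)),
    at$x, at$y, at$z, at$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

sdf_record <- function(ligand, pose, title = "ligand", tags = NULL) {
  n <- nrow(pose)
  nb <- nrow(ligand$bonds)
  lines <- c(
    title, "  quasidock", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            pose[, 1], pose[, 2], pose[, 3], ligand$atoms$element),
    if (nb > 0) sprintf("%3d%3d%3d  0  0  0  0",
                        ligand$bonds$i, ligand$bonds$j, ligand$bonds$order),
    if (ligand$formal_charge != 0)
      sprintf("M  CHG  1 %3d %3d", 1L, ligand$formal_charge),
    "M  END"
  )
  if (!is.null(tags)) {
    for (nm in names(tags)) {
      lines <- c(lines, sprintf("> <%s>", nm), as.character(tags[[nm]]), "")
    }
  }
  c(lines, "$$$$")
}

#' Write a ligand pose (or several) as an SDF file
#' @param ligand A `qd_ligand`.
#' @param poses A pose matrix or list of pose matrices.
#' @param path Output path.
#' @export
write_ligand_sdf <- function(ligand, poses, path) {
  if (is.matrix(poses)) poses <- list(poses)
  lines <- unlist(lapply(seq_along(poses), function(i) {
    sdf_record(ligand, qd_pose(poses[[i]], ligand),
               title = sprintf("pose_%d", i))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a minima pool to SDF (poses + energies as SD tags)
#'
#' Records are written in ascending stage-1 energy order with SD tags
#' `e_stage1`, `e_stage2`, `rank`, `start_index`, `converged`.
#'
#' @param pool A `qd_pool`.
#' @param path Output path.
#' @export
write_pool_sdf <- function(pool, path) {
  ord <- pool_order(pool)
  lines <- unlist(lapply(seq_along(ord), function(i) {
    k <- ord[i]
    sdf_record(
      pool$ligand, pool$poses[[k]], title = sprintf("minimum_%d", i),
      tags = list(
        e_stage1 = sprintf("%.8f", pool$e_stage1[k]),
        e_stage2 = ifelse(is.na(pool$e_stage2[k]), "NA",
                          sprintf("%.8f", pool$e_stage2[k])),
        rank = ifelse(is.na(pool$rank[k]), "NA", pool$rank[k]),
        start_index = pool$start_index[k],
        converged = pool$converged[k]
      )
    )
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a serialized pool back
#'
#' @param path SDF written by [write_pool_sdf()].
#' @param ligand The matching `qd_ligand`.
#' @param config Pool configuration.
#' @return A `qd_pool` with poses, energies, and ranks restored.
#' @export
read_pool_sdf <- function(path, ligand, config = pool_config()) {
  need_pkg("ChemmineR")
  if (!file.exists(path)) abort(sprintf("no such pool file: %s", path))
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  pool <- minima_pool(ligand, config)
  e2 <- numeric(0); rk <- integer(0)
  for (i in seq_along(sdfset)) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    pose <- unname(ab[, 1:3, drop = FALSE])
    tags <- ChemmineR::datablock(sdf)
    try_insert(pool, pose, as.numeric(tags[["e_stage1"]]),
               converged = as.logical(tags[["converged"]]),
               start_index = as.integer(tags[["start_index"]]))
    e2 <- c(e2, suppressWarnings(as.numeric(tags[["e_stage2"]])))
    rk <- c(rk, suppressWarnings(as.integer(tags[["rank"]])))
  }
  # records arrive in stage-1 order, so stored order = file order
  ord <- pool_order(pool)
  pool$e_stage2[ord] <- e2
  pool$rank[ord] <- rk
  # counters reflect reloading, not the original run
  pool$n_seen <- length(sdfset)
  pool
}

#' Write the pool index TSV
#'
#' Fixed-precision text (8 decimals) so identical pools are byte-identical
#' on disk. Columns: `rank`, `pool_index`, `start_index`, `e_stage1`,
#' `e_stage2`, `converged`, and `rmsd_to_native` when a native pose is given.
#'
#' @param pool A `qd_pool`.
#' @param path Output path.
#' @param native Optional native pose for the RMSD column.
#' @export
write_pool_tsv <- function(pool, path, native = NULL) {
  tb <- as_tibble(pool)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.8f", x))
  out <- data.frame(
    rank = ifelse(is.na(tb$rank), "NA", tb$rank),
    pool_index = seq_len(nrow(tb)),
    start_index = tb$start_index,
    e_stage1 = fmt(tb$e_stage1),
    e_stage2 = fmt(tb$e_stage2),
    converged = tb$converged
  )
  if (!is.null(native)) {
    ord <- pool_order(pool)
    out$rmsd_to_native <- fmt(vapply(ord, function(k) {
      heavy_rmsd(pool$poses[[k]], native, pool$ligand)
    }, numeric(1)))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pool index TSV
#' @param path TSV written by [write_pool_tsv()].
#' @return A tibble.
#' @export
read_pool_tsv <- function(path) {
  as_tibble(read.delim(path, sep = "\t", na.strings = "NA"))
}
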