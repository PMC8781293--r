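# Random start-pose generation: uniform rigid-body placement inside the
# binding-site sphere, uniform torsion randomization, and clash rejection.

# Bondi van der Waals radii, Angstrom.
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  CL = 1.75, BR = 1.85, I = 1.98, B = 1.92, SI = 2.10, SE = 1.90
)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  if (any(is.na(r))) {
    abort(sprintf(
      "no van der Waals radius for element(s): %s",
      paste(unique(element[is.na(r)]), collapse = ", ")
    ))
  }
  unname(r)
}

#' Sampler configuration
#'
#' @param site_radius Sphere radius for the ligand's geometric center,
#'   Angstrom. Default 8.
#' @param clash_scale Fraction of the summed van der Waals radii below which
#'   an interatomic distance counts as a clash. Default 0.5 (permissive
#'   enough that soft overlaps are left for the local optimizer to resolve).
#' @param max_attempts_per_start Retry budget per accepted pose.
#' @return A list of class `qd_sampler_config`.
#' @export
sampler_config <- function(site_radius = 8, clash_scale = 0.5,
                           max_attempts_per_start = 200L) {
  if (clash_scale <= 0 || clash_scale >= 1) abort("0 < clash_scale < 1 required")
  if (site_radius <= 0) abort("site_radius must be > 0")
  structure(
    list(site_radius = site_radius, clash_scale = clash_scale,
         max_attempts_per_start = as.integer(max_attempts_per_start)),
    class = "qd_sampler_config"
  )
}

#' Uniform random rotation matrix (quaternion method)
#'
#' Draws a rotation uniformly over SO(3) via Shoemake's uniform unit
#' quaternion construction, consuming three uniforms from the current RNG
#' stream.
#'
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation_matrix <- function() {
  u <- runif(3)
  q <- c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )
  quaternion_to_matrix(q)
}

quaternion_to_matrix <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Uniform random point in a ball
#' @param center Numeric 3-vector.
#' @param radius Ball radius.
#' @export
sample_in_ball <- function(center, radius) {
  repeat {
    v <- runif(3, -1, 1)
    if (sum(v^2) <= 1) break
  }
  center + radius * v
}

#' Random torsion angles, uniform on [0, 360) degrees
#' @param ligand A `qd_ligand`.
#' @return Numeric vector, one angle per rotatable torsion (possibly empty).
#' @export
random_torsion_set <- function(ligand) {
  n <- length(ligand$torsions)
  if (n == 0) return(numeric(0))
  runif(n, 0, 360)
}

dihedral_angle <- function(pose, t) {
  b1 <- pose[t[2], ] - pose[t[1], ]
  b2 <- pose[t[3], ] - pose[t[2], ]
  b3 <- pose[t[4], ] - pose[t[3], ]
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Atoms on the side of bond b-c that moves under a torsion: the smaller of
# the two components after cutting the bond; tie broken toward the side
# containing the lower minimum atom index. The returned set is the moving
# set, rotated about the b->c axis.
torsion_moving_side <- function(ligand, b, c) {
  g2 <- igraph::delete_edges(ligand$graph, igraph::get_edge_ids(ligand$graph, c(b, c)))
  comp <- igraph::components(g2)$membership
  side_b <- which(comp == comp[b])
  side_c <- which(comp == comp[c])
  if (length(side_c) < length(side_b)) {
    side_c
  } else if (length(side_b) < length(side_c)) {
    side_b
  } else if (min(side_b) < min(side_c)) side_b else side_c
}

#' Set a torsion to an absolute dihedral angle
#'
#' Rotates the moving side of the torsion's central bond about the bond axis
#' so that the dihedral defined by the 4-atom tuple equals `angle`. Internal
#' bond lengths and angles are untouched (pure internal rotation).
#'
#' @param pose n x 3 pose matrix.
#' @param ligand A `qd_ligand`.
#' @param torsion_index Index into `ligand$torsions`.
#' @param angle Target dihedral, degrees.
#' @export
set_torsion <- function(pose, ligand, torsion_index, angle) {
  t <- ligand$torsions[[torsion_index]]
  current <- dihedral_angle(pose, t)
  moving <- torsion_moving_side(ligand, t[2], t[3])
  # With the dihedral convention used here, rotating the a-b side by +delta
  # about the b->c axis increases the dihedral; the c-d side by -delta.
  delta <- (angle - current) * pi / 180
  if (t[3] %in% moving) delta <- -delta
  axis_origin <- pose[t[2], ]
  axis <- pose[t[3], ] - pose[t[2], ]
  axis <- axis / sqrt(sum(axis^2))
  rot <- axis_angle_matrix(axis, delta)
  pose[moving, ] <- sweep(
    sweep(pose[moving, , drop = FALSE], 2, axis_origin, "-") %*% t(rot),
    2, axis_origin, "+"
  )
  pose
}

axis_angle_matrix <- function(axis, theta) {
  ct <- cos(theta); st <- sin(theta)
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(
    ct + x^2 * (1 - ct), x * y * (1 - ct) - z * st, x * z * (1 - ct) + y * st,
    y * x * (1 - ct) + z * st, ct + y^2 * (1 - ct), y * z * (1 - ct) - x * st,
    z * x * (1 - ct) - y * st, z * y * (1 - ct) + x * st, ct + z^2 * (1 - ct)
  ), 3, 3, byrow = TRUE)
}

#' Clash test between a posed ligand and the receptor, and within the ligand
#'
#' A pose clashes when any ligand-receptor pair, or any ligand-ligand pair
#' separated by at least three bonds (1-4 and beyond), is closer than
#' `clash_scale` times the sum of the two van der Waals radii. 1-2 and 1-3
#' pairs are excluded: bonded geometry is legitimately short.
#'
#' @param receptor A `qd_receptor`.
#' @param ligand A `qd_ligand`.
#' @param pose n x 3 pose matrix.
#' @param config A `qd_sampler_config`.
#' @export
has_clash <- function(receptor, ligand, pose, config = sampler_config()) {
  rl <- vdw_radius(ligand$atoms$element)
  if (nrow(receptor$atoms) > 0) {
    rr <- vdw_radius(receptor$atoms$element)
    for (j in seq_len(nrow(pose))) {
      d2 <- rowSums(sweep(receptor$coords, 2, pose[j, ], "-")^2)
      thr <- (config$clash_scale * (rr + rl[j]))^2
      if (any(d2 < thr)) return(TRUE)
    }
  }
  n <- nrow(pose)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (ligand$graph_dist[i, j] < 3) next
        thr <- config$clash_scale * (rl[i] + rl[j])
        if (sum((pose[i, ] - pose[j, ])^2) < thr^2) return(TRUE)
      }
    }
  }
  FALSE
}

#' Generate one clash-free random start pose
#'
#' Torsions are randomized first, then the (possibly reshaped) ligand is
#' placed as a rigid body: a uniform rotation about its geometric center
#' followed by a translation taking the center to a point drawn uniformly
#' from the binding-site ball. Poses that clash are rejected and redrawn, up
#' to `max_attempts_per_start` times.
#'
#' @inheritParams has_clash
#' @return A clash-free pose matrix.
#' @export
generate_start_pose <- function(receptor, ligand, config = sampler_config()) {
  base <- ligand_pose(ligand)
  for (attempt in seq_len(config$max_attempts_per_start)) {
    pose <- base
    angles <- random_torsion_set(ligand)
    for (k in seq_along(angles)) {
      pose <- set_torsion(pose, ligand, k, angles[k])
    }
    center <- colMeans(pose)
    rot <- random_rotation_matrix()
    target <- sample_in_ball(receptor$site_center, config$site_radius)
    pose <- sweep(sweep(pose, 2, center, "-") %*% t(rot), 2, target, "+")
    if (!has_clash(receptor, ligand, pose, config)) return(pose)
  }
  abort(sprintf(
    "no clash-free pose in %d attempts (site overfilled or clash_scale too strict)",
    config$max_attempts_per_start
  ))
}
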