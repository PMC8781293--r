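test_that("sampled ligand centers are uniform over the site ball", {
  set.seed(7)
  R <- 8
  centers <- t(replicate(10000, sample_in_ball(c(1, -2, 0.5), R)))
  d <- sqrt(rowSums(sweep(centers, 2, c(1, -2, 0.5))^2))
  expect_true(all(d <= R + 1e-12))
  # uniform-ball radial moment: E[d] = 3R/4, sd = R * sqrt(3/80)
  se <- R * sqrt(3 / 80) / sqrt(length(d))
  expect_lt(abs(mean(d) - 3 * R / 4), 3 * se)
})

test_that("random rotations are uniform over SO(3)", {
  set.seed(8)
  angles <- replicate(10000, {
    r <- random_rotation_matrix()
    # orthonormality with unit determinant
    expect_lt(max(abs(crossprod(r) - diag(3))), 1e-12)
    acos(pmin(1, pmax(-1, (sum(diag(r)) - 1) / 2)))
  })
  # uniform SO(3): p(theta) = (1 - cos theta)/pi, mean = pi/2 + 2/pi
  expected <- pi / 2 + 2 / pi
  se <- sd(angles) / sqrt(length(angles))
  expect_lt(abs(mean(angles) - expected), 3 * se)
})

test_that("torsion randomization is uniform and preserves internal geometry", {
  lig <- toy_chain_ligand(5)
  set.seed(9)
  draws <- t(replicate(5000, random_torsion_set(lig)))
  expect_equal(ncol(draws), 2)
  for (j in 1:2) {
    ks <- suppressWarnings(stats::ks.test(draws[, j] / 360, "punif"))
    expect_gt(ks$p.value, 0.01)
  }
  # rigid ligand: empty angle set
  expect_length(random_torsion_set(quasidock:::toy_triad_ligand()), 0)
  # internal rotation leaves bond lengths and angles untouched
  pose <- ligand_pose(lig)
  d_before <- dist(pose)
  rotated <- set_torsion(pose, lig, 1, 180)
  expect_lt(max(abs(dist(rotated[1:4, ]) - dist(pose[1:4, ]))), 1e-10)
  anti <- set_torsion(pose, lig, 1, 180)
  expect_equal(quasidock:::dihedral_angle(anti, lig$torsions[[1]]), 180,
               tolerance = 1e-9)
})

test_that("clash detection agrees with a brute-force pairwise check", {
  toy <- cached_toy(2)
  cfg <- sampler_config(site_radius = 6)
  # far-away ligand never clashes; two heavy atoms at 0.5 A always do
  far <- ligand_pose(toy$ligand) + 50
  expect_false(has_clash(toy$receptor, toy$ligand, far, cfg))
  bonded2 <- qd_ligand(
    qd_atoms(c("C", "C", "C", "C"),
             rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0), c(4.5, 0, 0))),
    data.frame(i = 1:3, j = 2:4, order = 1L)
  )
  squeezed <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0), c(0.5, 0, 0))
  expect_true(has_clash(empty_receptor(), bonded2, squeezed, cfg))
  # brute force over every pair with Bondi radii, 1-2/1-3 pairs exempt
  bondi <- c(C = 1.70, N = 1.55, O = 1.52)
  brute <- function(receptor, ligand, pose) {
    rl <- bondi[ligand$atoms$element]
    rr <- bondi[receptor$atoms$element]
    for (i in seq_len(nrow(pose))) {
      for (j in seq_len(nrow(receptor$coords))) {
        if (sqrt(sum((pose[i, ] - receptor$coords[j, ])^2)) <
            0.5 * (rl[i] + rr[j])) return(TRUE)
      }
    }
    for (i in seq_len(nrow(pose) - 1)) {
      for (j in (i + 1):nrow(pose)) {
        if (ligand$graph_dist[i, j] < 3) next
        if (sqrt(sum((pose[i, ] - pose[j, ])^2)) < 0.5 * (rl[i] + rl[j])) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  set.seed(10)
  base <- ligand_pose(toy$ligand)
  agree <- vapply(1:1000, function(i) {
    pose <- sweep(base, 2, colMeans(base), "-") %*%
      t(random_rotation_matrix())
    pose <- sweep(pose, 2, sample_in_ball(c(0, 0, 0), 8), "+")
    has_clash(toy$receptor, toy$ligand, pose, cfg) ==
      brute(toy$receptor, toy$ligand, pose)
  }, logical(1))
  expect_true(all(agree))
  expect_error(
    has_clash(toy$receptor,
              qd_ligand(qd_atoms("Xx", matrix(0, 1, 3)),
                        data.frame(i = integer(0), j = integer(0))),
              matrix(0, 1, 3), cfg),
    "Xx"
  )
})

test_that("start-pose generation is clash-free, in-site, and seed-reproducible", {
  toy <- cached_toy(2)
  cfg <- sampler_config(site_radius = 6)
  set.seed(42)
  poses <- replicate(50, generate_start_pose(toy$receptor, toy$ligand, cfg),
                     simplify = FALSE)
  for (p in poses) {
    expect_false(has_clash(toy$receptor, toy$ligand, p, cfg))
    expect_lte(sqrt(sum(colMeans(p)^2)), 6)
  }
  set.seed(42)
  again <- generate_start_pose(toy$receptor, toy$ligand, cfg)
  expect_identical(again, poses[[1]])
  set.seed(43)
  other <- generate_start_pose(toy$receptor, toy$ligand, cfg)
  expect_gt(max(abs(other - poses[[1]])), 1e-6)
  # empty receptor: first attempt accepted
  set.seed(1)
  expect_silent(generate_start_pose(empty_receptor(6), toy$ligand, cfg))
  # fully occupied site: sampling exhausts
  grid <- as.matrix(expand.grid(x = -3:3, y = -3:3, z = -3:3)) * 1.0
  packed <- qd_receptor(qd_atoms(rep("C", nrow(grid)), grid),
                        c(0, 0, 0), site_radius = 2)
  set.seed(2)
  expect_error(
    generate_start_pose(packed, toy$ligand,
                        sampler_config(site_radius = 2,
                                       max_attempts_per_start = 25)),
    "clash-free"
  )
})
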