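triad <- quasidock:::toy_triad_ligand()

test_that("heavy-atom RMSD has its closed forms and rejects bad mappings", {
  pose <- ligand_pose(triad)
  expect_identical(heavy_rmsd(pose, pose, triad), 0)
  # uniform (3,4,0) shift: exactly 5
  expect_equal(heavy_rmsd(pose, sweep(pose, 2, c(3, 4, 0), "+"), triad), 5)
  # two heavy atoms, displacements 0 and 2: sqrt(2)
  two <- qd_ligand(qd_atoms(c("C", "C"), rbind(c(0, 0, 0), c(5, 0, 0))),
                   data.frame(i = 1, j = 2, order = 1L))
  a <- ligand_pose(two)
  b <- a; b[2, 3] <- b[2, 3] + 2
  expect_equal(heavy_rmsd(a, b, two), sqrt(2))
  # hydrogens are excluded
  withH <- qd_ligand(
    qd_atoms(c("C", "H"), rbind(c(0, 0, 0), c(1.1, 0, 0))),
    data.frame(i = 1, j = 2, order = 1L)
  )
  ph <- ligand_pose(withH)
  moved <- ph; moved[2, ] <- moved[2, ] + 10
  expect_identical(heavy_rmsd(ph, moved, withH), 0)
  expect_error(heavy_rmsd(pose, pose, triad, mapping = c(1, 1, 2)),
               "bijection")
})

test_that("symmetry correction minimizes over graph automorphisms", {
  # asymmetric ligand: identity only
  sym <- symmetry_corrected_rmsd(ligand_pose(triad),
                                 sweep(ligand_pose(triad), 2, c(1, 0, 0), "+"),
                                 triad)
  expect_equal(sym$mapping, 1:3)
  expect_equal(sym$rmsd, 1)
  # symmetric 4-ring rotated 90 degrees in-plane: corrected RMSD 0
  square <- quasidock:::toy_square_ligand()
  expect_length(ligand_automorphisms(square), 8)
  p <- ligand_pose(square)
  rot <- p %*% t(quasidock:::axis_angle_matrix(c(0, 0, 1), pi / 2))
  expect_gt(heavy_rmsd(p, rot, square), 1)
  expect_lt(symmetry_corrected_rmsd(p, rot, square)$rmsd, 1e-8)
  expect_error(ligand_automorphisms(square, cap = 4), "cap")
  # property: corrected <= identity on random pairs, and equals the
  # brute-force minimum over independently enumerated automorphisms
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 4), ]
  adjacent <- function(i, j) (abs(i - j) %in% c(1, 3))
  valid <- apply(perms, 1, function(m) {
    all(vapply(1:4, function(i) {
      adjacent(m[i], m[(i %% 4) + 1])
    }, logical(1)))
  })
  perms <- perms[valid, , drop = FALSE]
  set.seed(14)
  for (i in 1:100) {
    a <- p + matrix(runif(12, -2, 2), 4, 3)
    b <- p + matrix(runif(12, -2, 2), 4, 3)
    plain <- heavy_rmsd(a, b, square)
    corrected <- symmetry_corrected_rmsd(a, b, square)$rmsd
    expect_lte(corrected, plain + 1e-12)
    brute <- min(apply(perms, 1, function(m) {
      sqrt(mean(rowSums((a - b[m, ])^2)))
    }))
    expect_equal(corrected, brute, tolerance = 1e-12)
  }
})

test_that("INN finds the lowest-ranked near-native minimum", {
  base <- ligand_pose(triad)
  native <- base
  # four basins at controlled RMSDs; stage-2 energies rank them so the
  # RMSD-by-rank sequence is 2.5, 2.1, 1.0, 0.5
  shifts <- list(c(2.5, 0, 0), c(0, 2.1, 0), c(1, 0, 0), c(0, 0, 0.5))
  pool <- minima_pool(triad, pool_config(capacity = 10))
  for (s in shifts) try_insert(pool, sweep(base, 2, s, "+"), 0)
  bydist <- energy_model("neg-shift", function(receptor, ligand, pose) {
    -sqrt(mean(rowSums((pose - native)^2)))
  })
  expect_error(compute_inn(pool, native), "not ranked")
  rescore_pool(pool, empty_receptor(),
               rescore_job("surrogate", surrogate_model = bydist))
  res <- compute_inn(pool, native)
  expect_equal(res$inn, 3L)
  expect_equal(res$rmsd_gm, 2.5)
  # boundary: a minimum at exactly the cutoff does not count
  expect_equal(compute_inn(pool, native, cutoff = 1.0)$inn, 4L)
  # no near-native minimum at all
  expect_true(is.na(compute_inn(pool, native, cutoff = 0.1)$inn))
  # rank-1 within the cutoff: paradigm fulfilled
  res1 <- compute_inn(pool, sweep(base, 2, c(2.5, 0, 0), "+"))
  expect_equal(res1$inn, 1L)
  expect_true(paradigm_verdict(res1))
  expect_false(paradigm_verdict(res))
  expect_false(paradigm_verdict(NA_integer_))
})

test_that("paradigm failures are counted over the packaged positioning table", {
  t2 <- load_paper_tables()$table2
  expect_equal(count_paradigm_failures(t2$inn_pm6), 11L)
  expect_equal(count_paradigm_failures(t2$inn_pm7), 6L)
  expect_equal(count_paradigm_failures(rep(1L, 10)), 0L)
  expect_equal(count_paradigm_failures(c(1L, 2L, NA)), 2L)
  expect_error(count_paradigm_failures(integer(0)), "no evaluation rows")
  summary <- positioning_summary(
    tibble::tibble(complex_id = t2$pdb_id, inn = t2$inn_pm7)
  )
  expect_equal(summary$paradigm_successes, 19L)
})

test_that("binding enthalpy is exact arithmetic with method guarding", {
  expect_identical(binding_enthalpy(-100, -60, -10), -30)
  expect_identical(binding_enthalpy(-70, -60, -10), 0)
  a <- structure(-100, method = "PM7")
  b <- structure(-60, method = "PM6-D3H4X")
  expect_error(binding_enthalpy(a, b, -10), "mixed-method")
  expect_equal(binding_enthalpy(a, structure(-60, method = "PM7"),
                                structure(-10, method = "PM7")), -30)
})

test_that("the enthalpy protocol is self-consistent against direct evaluation", {
  toy <- cached_toy(2)
  res <- run_search(toy$receptor, toy$ligand, toy$stage1_model,
                    run_config(n_starts = 60, seed = 3))
  rescore_pool(res$pool, toy$receptor,
               rescore_job("surrogate", surrogate_model = toy$stage1_model))
  gm <- pool_pose(res$pool, 1, by_rank = TRUE)
  # stage-2 = stage-1 model, single relaxed conformer
  comp <- enthalpy_protocol(gm, toy$receptor, toy$ligand,
                            vacuum_model = toy$stage1_model,
                            solvent_model = toy$stage1_model,
                            ligand_pool = list(ligand_pose(toy$ligand)))
  expect_identical(comp$dh_bind,
                   binding_enthalpy(comp$e1_pl, comp$e1_p, comp$e1_l))
  # direct recomposition: relaxed complex energy minus relaxed ligand energy
  relaxed <- optimize_pose(toy$stage1_model, toy$receptor, toy$ligand, gm)
  lig_relaxed <- optimize_ligand_alone(toy$stage1_model, toy$ligand,
                                       ligand_pose(toy$ligand))
  direct <- relaxed$energy - 0 - lig_relaxed$energy
  expect_lt(abs(comp$dh_bind - direct), 1e-8)
  # determinism: bit-identical components run-to-run
  comp2 <- enthalpy_protocol(gm, toy$receptor, toy$ligand,
                             vacuum_model = toy$stage1_model,
                             solvent_model = toy$stage1_model,
                             ligand_pool = list(ligand_pose(toy$ligand)))
  expect_identical(comp, comp2)
})

test_that("Pearson correlation reproduces the packaged benchmark values", {
  t3 <- load_paper_tables()$table3
  expect_equal(round(pearson_r(t3$dh_exp, t3$dh_pm7), 2), 0.74)
  expect_equal(round(pearson_r(t3$dh_exp, t3$dh_pm6), 1), 0.4)
  expect_equal(sum(!is.na(t3$dh_pm6)), 10)
  x <- c(1, 2, 3, 4.5)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_error(pearson_r(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson_r(c(1, 2, NA, 3), c(1, NA, 2, 3)), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  # every calculated enthalpy in the packaged table is negative
  expect_true(all(c(t3$dh_pm6, t3$dh_pm7) < 0, na.rm = TRUE))
})
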