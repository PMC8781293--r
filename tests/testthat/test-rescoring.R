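test_that("external single-point inputs carry the contracted keyword line", {
  toy <- cached_toy(2)
  job <- rescore_job("PM7", "cosmo")
  lig_charged <- qd_ligand(toy$ligand$atoms, toy$ligand$bonds,
                           formal_charge = 1L)
  txt <- write_qm_input(toy$receptor, lig_charged, toy$native_pose, job)
  kw <- strsplit(txt, "\n")[[1]][1]
  for (token in c("PM7", "1SCF", "MOZYME", "CHARGE=1", "EPS=78.4")) {
    expect_match(kw, token, fixed = TRUE)
  }
  # no solvent: no EPS keyword; PM6-D3H4X token verbatim
  kw2 <- strsplit(write_qm_input(toy$receptor, lig_charged, toy$native_pose,
                                 rescore_job("PM6-D3H4X", "none")),
                  "\n")[[1]][1]
  expect_match(kw2, "PM6-D3H4X", fixed = TRUE)
  expect_no_match(kw2, "EPS")
  # surrogate jobs never write files
  sj <- rescore_job("surrogate", surrogate_model = toy$surrogate_model)
  expect_error(write_qm_input(toy$receptor, toy$ligand, toy$native_pose, sj),
               "no external input format")
  # 2-atom toy complex: exactly two coordinate lines after the header
  lig2 <- qd_ligand(qd_atoms(c("C", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0))),
                    data.frame(i = 1, j = 2, order = 1L))
  txt2 <- write_qm_input(empty_receptor(), lig2, ligand_pose(lig2),
                         rescore_job("PM7"))
  lines2 <- strsplit(txt2, "\n")[[1]]
  expect_length(lines2, 3 + 2)
})

test_that("heat-of-formation parsing takes the final value and flags failures", {
  one <- "  header\n FINAL HEAT OF FORMATION = -1234.56789 KCAL/MOL\n done\n"
  expect_equal(parse_qm_energy(one), -1234.56789)
  # rerun convention: the last printed value stands
  two <- paste0(" FINAL HEAT OF FORMATION = -1.0 KCAL/MOL\n",
                " FINAL HEAT OF FORMATION = -2.5 KCAL/MOL\n")
  expect_equal(parse_qm_energy(two), -2.5)
  expect_error(parse_qm_energy(" SCF cycle 3\n energy so far -12.0\n"),
               "no FINAL HEAT OF FORMATION")
  expect_error(
    parse_qm_energy(paste0(" FINAL HEAT OF FORMATION = -1.0 KCAL/MOL\n",
                           " CALCULATION ABANDONED\n")),
    "failed run"
  )
})

test_that("canned output fixtures round-trip through the parser", {
  fix <- test_path("fixtures", "mopac_pm7_cosmo_synthetic.out")
  expect_equal(parse_qm_energy(readLines(fix)), -4523.91854)
  expect_error(
    parse_qm_energy(readLines(test_path("fixtures",
                                        "mopac_truncated_synthetic.out"))),
    "no FINAL HEAT OF FORMATION"
  )
})

test_that("rescoring ranks by stage-2 energy and never moves coordinates", {
  toy <- cached_toy(5)
  res <- run_search(toy$receptor, toy$ligand, toy$stage1_model,
                    run_config(n_starts = 250, seed = 11))
  pool <- res$pool
  poses_before <- lapply(quasidock:::pool_order(pool),
                         function(k) pool$poses[[k]])
  # identity rescoring: stage-2 = stage-1 model, ranks equal stage-1 order
  rescore_pool(pool, toy$receptor,
               rescore_job("surrogate", surrogate_model = toy$stage1_model))
  tb <- as_tibble(pool)
  expect_equal(tb$rank, seq_len(nrow(tb)))
  expect_equal(tb$e_stage2, tb$e_stage1)
  # surrogate rescoring: ranks are a permutation; poses byte-identical (1SCF)
  rescore_pool(pool, toy$receptor,
               rescore_job("surrogate", surrogate_model = toy$surrogate_model))
  tb <- as_tibble(pool)
  expect_setequal(tb$rank, seq_len(nrow(tb)))
  expect_false(all(tb$rank == seq_len(nrow(tb))))  # ranking truly changes
  poses_after <- lapply(quasidock:::pool_order(pool),
                        function(k) pool$poses[[k]])
  expect_identical(poses_before, poses_after)
  # the declared GM minimizes the surrogate over all records (brute force)
  direct <- vapply(pool$poses, function(p) {
    toy$surrogate_model$evaluate(toy$receptor, toy$ligand, p)
  }, numeric(1))
  expect_equal(min(pool$e_stage2), min(direct))
  expect_equal(pool_pose(pool, 1, by_rank = TRUE),
               pool$poses[[which.min(direct)]])
})

test_that("explicit stage-2 energies give the expected ranks", {
  triad <- quasidock:::toy_triad_ligand()
  pool <- minima_pool(triad, pool_config(capacity = 10))
  base <- ligand_pose(triad)
  for (i in 1:3) try_insert(pool, sweep(base, 2, c(3 * i, 0, 0), "+"), -i)
  fake <- setNames(c(-10, -30, -20), 1:3)
  model <- energy_model("lookup", function(receptor, ligand, pose) {
    unname(fake[as.character(round(pose[1, 1] / 3))])
  })
  rescore_pool(pool, empty_receptor(),
               rescore_job("surrogate", surrogate_model = model))
  ord <- quasidock:::pool_order(pool)
  byins <- order(pool$seq[ord])
  expect_equal(pool$rank[ord][byins], c(3L, 1L, 2L))
})

test_that("failed stage-2 evaluations follow the error policy", {
  triad <- quasidock:::toy_triad_ligand()
  base <- ligand_pose(triad)
  pool <- minima_pool(triad, pool_config(capacity = 50))
  for (i in 1:20) try_insert(pool, sweep(base, 2, c(3 * i, 0, 0), "+"), -i)
  # one failure out of 20 (5%): flagged, excluded from ranking, run continues
  flaky <- energy_model("flaky", function(receptor, ligand, pose) {
    if (abs(pose[1, 1] - 3) < 1e-6) stop("boom") else -pose[1, 1]
  })
  rescore_pool(pool, empty_receptor(),
               rescore_job("surrogate", surrogate_model = flaky))
  expect_equal(sum(is.na(pool$e_stage2)), 1L)
  expect_setequal(pool$rank[!is.na(pool$e_stage2)], 1:19)
  # > 10% failures abort the run
  dead <- energy_model("dead", function(receptor, ligand, pose) {
    if (pose[1, 1] < 20) stop("boom") else -pose[1, 1]
  })
  expect_error(
    rescore_pool(pool, empty_receptor(),
                 rescore_job("surrogate", surrogate_model = dead)),
    "> 10%"
  )
})
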