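# Shared toy complexes, built lazily and cached for the whole test session
# (the oracle enumeration is the expensive part).

.toy_cache <- new.env(parent = emptyenv())

cached_toy <- function(k = 2L, ligand = "triad", ...) {
  key <- paste(k, ligand, ...)
  if (is.null(.toy_cache[[key]])) {
    .toy_cache[[key]] <- build_toy_complex(
      toy_complex_spec(k = k, ligand = ligand, ...)
    )
  }
  .toy_cache[[key]]
}

# Independent brute-force pool oracle: dedup a full candidate stream by
# heavy-atom RMSD (keeping each basin's lowest energy and first-seen order),
# then sort by energy and truncate to capacity. Plain double loops on
# purpose.
brute_force_pool <- function(stream, ligand, capacity, uniq_rmsd) {
  hv <- which(toupper(ligand$atoms$element) != "H")
  rmsd <- function(a, b) sqrt(mean(rowSums((a[hv, , drop = FALSE] -
                                              b[hv, , drop = FALSE])^2)))
  energies <- numeric(0); poses <- list(); first_seen <- integer(0)
  for (s in seq_along(stream)) {
    cand <- stream[[s]]
    hit <- 0L
    for (i in seq_along(poses)) {
      if (rmsd(cand$pose, poses[[i]]) < uniq_rmsd) { hit <- i; break }
    }
    if (hit > 0L) {
      if (cand$energy < energies[hit]) {
        energies[hit] <- cand$energy
        poses[[hit]] <- cand$pose
      }
    } else {
      energies <- c(energies, cand$energy)
      poses[[length(poses) + 1L]] <- cand$pose
      first_seen <- c(first_seen, s)
    }
  }
  ord <- order(energies, first_seen)
  keep <- ord[seq_len(min(capacity, length(ord)))]
  list(energies = energies[keep], poses = poses[keep],
       first_seen = first_seen[keep])
}

# Synthetic minima stream: `n` candidates drawn from `n_basins` basins with
# distinct energies, optimizer-jitter-sized noise on poses and energies.
make_minima_stream <- function(n, n_basins, ligand, seed) {
  set.seed(seed)
  base <- ligand_pose(ligand)
  basin_pose <- lapply(seq_len(n_basins), function(i) {
    base + matrix(runif(length(base), -4, 4), nrow(base), 3)
  })
  # keep basins at least 1 Angstrom apart pairwise
  for (i in seq_len(n_basins)) {
    repeat {
      ok <- TRUE
      for (j in seq_len(i - 1)) {
        if (sqrt(mean(rowSums((basin_pose[[i]] - basin_pose[[j]])^2))) < 1) {
          basin_pose[[i]] <- base + matrix(runif(length(base), -4, 4),
                                           nrow(base), 3)
          ok <- FALSE
          break
        }
      }
      if (ok) break
    }
  }
  basin_energy <- sort(runif(n_basins, -40, -5))
  picks <- sample.int(n_basins, n, replace = TRUE)
  lapply(seq_len(n), function(s) {
    b <- picks[s]
    list(
      pose = basin_pose[[b]] + matrix(runif(length(base), -0.02, 0.02),
                                      nrow(base), 3),
      energy = basin_energy[b] + runif(1, 0, 1e-8)
    )
  })
}
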