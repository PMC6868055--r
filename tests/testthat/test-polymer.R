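test_that("the default genome build has 2803 beads with 361 rDNA beads", {
  p <- polymer_params()
  st <- init_chain(p, seed = 1)
  expect_equal(nrow(st$pos), 2803L)
  expect_length(st$rdna_idx, 361L)
  expect_equal(st$rdna_idx, seq(st$rdna_idx[1], length.out = 361))
  # all beads inside the confinement sphere
  expect_true(all(rowSums(st$pos^2) <= p$confinement_radius^2 + 1e-6))
  # centromere bead at the tether site
  expect_equal(st$pos[1, ], p$tether_site, tolerance = 1e-6)
  expect_identical(init_chain(p, seed = 5)$pos, init_chain(p, seed = 5)$pos)
})

test_that("parameter invariants are enforced", {
  expect_error(polymer_params(n_rdna_beads = 10, n_beads = 5), "<=")
  expect_error(polymer_params(mu = 0), "mu")
  expect_error(polymer_params(dt = -1), "dt")
  expect_error(polymer_params(rest_length = 5000,
                              confinement_radius = 1000), "rest_length")
})

test_that("a straight chain at rest length is a zero-force fixed point", {
  p <- polymer_params(n_beads = 5, n_rdna_beads = 1, kT = 0, k_on = 0,
                      ev_strength = 0, tether_beads = integer(0),
                      confinement_radius = 1e6)
  st <- init_chain(p, seed = 1)
  st$pos <- cbind(seq(0, by = p$rest_length, length.out = 5), 0, 0)
  st2 <- step_dynamics(st)
  expect_equal(st2$pos, st$pos, tolerance = 1e-9)

  # stretched bond relaxes
  st$pos[5, 1] <- st$pos[4, 1] + 2 * p$rest_length
  d0 <- st$pos[5, 1] - st$pos[4, 1]
  st3 <- step_dynamics(st)
  expect_lt(st3$pos[5, 1] - st3$pos[4, 1], d0)
})

test_that("a free bead diffuses at the Einstein rate", {
  p <- polymer_params(n_beads = 1, n_rdna_beads = 1, k_on = 0,
                      ev_strength = 0, tether_beads = integer(0),
                      confinement_radius = 1e7)
  st <- init_chain(p, seed = 2)
  withr::with_seed(3, {
    msd <- 0
    prev <- st$pos
    n_steps <- 1e5
    for (i in seq_len(n_steps)) {
      st <- step_dynamics(st)
      msd <- msd + sum((st$pos - prev)^2)
      prev <- st$pos
    }
  })
  expect_equal(msd / (n_steps * p$dt), 6 * p$kT / p$drag, tolerance = 0.1)
})

test_that("no crosslinks form without attempts or capture range", {
  p0 <- rdna_only_params(n_rdna_beads = 30, k_on = 0,
                         confinement_radius = 200)
  tr0 <- run_trajectory(p0, total_steps = 200, sample_every = 200,
                        seed = 4, burn_in = 0)
  expect_equal(tr0$n_active_links, 0L)
  expect_length(tr0$completed_lifetimes, 0L)

  pc <- rdna_only_params(n_rdna_beads = 30, capture_radius = 0,
                         confinement_radius = 200)
  trc <- run_trajectory(pc, total_steps = 200, sample_every = 200,
                        seed = 4, burn_in = 0)
  expect_equal(trc$n_active_links, 0L)
})

test_that("crosslink lifetimes follow the exponential law", {
  p <- rdna_only_params(n_rdna_beads = 160, mu = 0.19, k_on = 60,
                        confinement_radius = 300, form_every = 1L)
  tr <- run_trajectory(p, total_steps = 6000, sample_every = 6000,
                       seed = 6, burn_in = 1000)
  # drop links created near the end of the run: their completion is
  # censored by the finite simulation and would bias the sample short
  t_end <- max(tr$times)
  keep <- tr$completed_created < t_end - 8 * p$mu
  lt <- tr$completed_lifetimes[keep]
  expect_gt(length(lt), 1e4)
  se <- p$mu / sqrt(length(lt))
  expect_lt(abs(mean(lt) - p$mu), 3 * se)
  # exponential: variance equals the squared mean
  expect_equal(var(lt) / mean(lt)^2, 1, tolerance = 0.05)
})

test_that("crosslink bookkeeping keeps pairs unique and expiry prompt", {
  p <- rdna_only_params(n_rdna_beads = 40, mu = 0.4, k_on = 30,
                        confinement_radius = 150, form_every = 1L)
  st <- init_chain(p, seed = 7)
  kf <- asNamespace("kinetoforge")
  thermal <- kf$rng_stream(1)
  kinetics <- kf$rng_stream(2)
  for (i in 1:400) {
    st <- update_crosslinks(st, kinetics)
    if (nrow(st$links)) {
      key <- st$links[, 1] * 1000 + st$links[, 2]
      expect_equal(anyDuplicated(key), 0L)
      expect_true(all(st$links[, 1] < st$links[, 2]))
      expect_true(all(st$links[, 4] > st$time))
      occupancy <- tabulate(c(st$links[, 1], st$links[, 2]), 40)
      expect_true(all(occupancy <= p$max_links_per_bead))
    }
    st <- step_dynamics(st, thermal)
  }
  expect_gt(nrow(st$links), 0L)
})

test_that("trajectories sample on schedule and reproduce bit-for-bit", {
  p <- rdna_only_params(n_rdna_beads = 40, confinement_radius = 300)
  tr <- run_trajectory(p, total_steps = 1000, sample_every = 100,
                       seed = 8, burn_in = 50)
  expect_length(tr$snapshots, 10L)
  expect_equal(tr$times, tr$times[1] + (0:9) * 100 * p$dt)
  # confinement and chain integrity across all snapshots
  for (s in tr$snapshots) {
    expect_true(all(is.finite(s)))
    expect_true(all(rowSums(s^2) <= p$confinement_radius^2 + 1e-6))
    bond <- sqrt(rowSums((s[-1, ] - s[-nrow(s), ])^2))
    expect_true(all(is.finite(bond)))
    expect_lt(mean(bond), 5 * p$rest_length)
  }
  tr2 <- run_trajectory(p, total_steps = 1000, sample_every = 100,
                        seed = 8, burn_in = 50)
  expect_identical(tr$snapshots, tr2$snapshots)
})

test_that("longer crosslink lifetimes compact the rDNA cloud", {
  rg <- vapply(c(0.09, 0.19, 1.6), function(mu) {
    tr <- run_trajectory(rdna_only_params(mu = mu), total_steps = 500,
                         sample_every = 250, seed = 9, burn_in = 3500)
    mean(rdna_rg(tr))
  }, numeric(1))
  expect_true(all(diff(rg) < 0))
})

test_that("trajectory export writes snapshots and a manifest", {
  p <- rdna_only_params(n_rdna_beads = 20, confinement_radius = 200)
  tr <- run_trajectory(p, total_steps = 200, sample_every = 100,
                       seed = 10, burn_in = 10)
  dir <- file.path(tempdir(), "traj")
  write_trajectory(tr, dir)
  files <- list.files(dir)
  expect_setequal(files, c("snapshot_0001.csv", "snapshot_0002.csv",
                           "manifest.json"))
  snap <- read.csv(file.path(dir, "snapshot_0001.csv"))
  expect_equal(names(snap), c("bead_index", "x_nm", "y_nm", "z_nm",
                              "is_rdna"))
  expect_equal(nrow(snap), 20L)
  expect_true(all(snap$is_rdna == 1))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 10L)
  expect_equal(man$params$mu, 0.19)
  # snapshots convert to red-channel fluorophores
  fl <- fluorophores_from_snapshot(tr, 1)
  expect_equal(nrow(fl), 20L)
  expect_true(all(fl$channel == "red"))
  expect_equal(colMeans(as.matrix(as.data.frame(fl)[, 1:3])), rep(0, 3),
               tolerance = 1e-9, ignore_attr = TRUE)
})
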