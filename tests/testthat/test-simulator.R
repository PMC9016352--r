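# Chain growth, slab extension, Langevin dynamics: determinism, thermostat
# calibration, Boltzmann sampling, NVE drift, topology conservation.

test_that("compact initialization: bonds at r0, no clashes, bounded failure", {
  ff <- test_ff()
  seq5 <- protein_sequence("GSGSG")
  cfg <- initialize_compact(1, seq5, ff, c(90, 90, 90), seed = 2)
  for (k in 1:4) {
    d <- cfg$positions[k, ] - cfg$positions[k + 1, ]
    d <- d - cfg$box * round(d / cfg$box)
    expect_equal(sqrt(sum(d^2)), ff$bond_r0, tolerance = 1e-6)
  }
  lcd <- tdp43_lcd()
  cfg10 <- initialize_compact(10, lcd, ff, c(110, 110, 160), seed = 1)
  expect_equal(nrow(cfg10$positions), 1540)
  # pairwise clash scan against the growth contract
  dmin <- 0.8 * min(ff$beads$sigma[match(unique(lcd$residues),
                                         ff$beads$code)])
  pr <- hpslab:::cpp_contact_pairs(cfg10$positions, cfg10$box, dmin,
                                   numeric(0))
  bonded <- abs(pr[, 1] - pr[, 2]) == 1 &
    ((pr[, 1] - 1) %/% 154 == (pr[, 2] - 1) %/% 154)
  expect_equal(sum(!bonded), 0)
  # impossible density: error, not a hang
  expect_error(initialize_compact(5, lcd, ff, c(20, 20, 20), seed = 1,
                                  max_restarts = 3), "too dense")
})

test_that("n_steps = 0 returns exactly the initial frame", {
  ff <- test_ff()
  cfg <- random_config(30, c(80, 80, 80), seed = 1)
  sch <- simulation_schedule(phases = list(list(label = "production",
                                                n_steps = 0L, box_z = NULL)))
  tr <- run_langevin(cfg, ff, sch)
  expect_equal(n_frames(tr), 1)
  expect_equal(tr$frames[, , 1], cfg$positions %% 80, tolerance = 1e-12)
})

test_that("identical seed and inputs give bit-identical trajectories", {
  ff <- test_ff()
  cfg <- initialize_compact(3, protein_sequence("GSGSNQGSGSNQGSGSNQGS"), ff,
                            c(80, 80, 80), seed = 3)
  sch <- simulation_schedule(seed = 42, stride = 50L,
                             phases = list(list(label = "production",
                                                n_steps = 500L,
                                                box_z = NULL)))
  t1 <- run_langevin(cfg, ff, sch)
  t2 <- run_langevin(cfg, ff, sch)
  expect_identical(t1$frames, t2$frames)
  sch2 <- sch; sch2$seed <- 43L
  t3 <- run_langevin(cfg, ff, sch2)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("free bead samples Maxwell-Boltzmann kinetic energy at 310 K", {
  ff <- test_ff()
  cfg <- system_configuration(matrix(c(50, 50, 50), 1, 3), c(100, 100, 100),
                              cbind(start = 1, end = 1), "G")
  for (seed in 1:3) {
    # stride 400 steps = 4 ps = 2 velocity relaxation times at friction
    # 0.5/ps, so saved samples are effectively independent
    sch <- simulation_schedule(temperature = 310, friction = 0.5, seed = seed,
                               stride = 400L,
                               phases = list(list(label = "production",
                                                  n_steps = 4e5L,
                                                  box_z = NULL)))
    tr <- run_langevin(cfg, ff, sch)
    temps <- tr$provenance$temperatures
    se <- stats::sd(temps) / sqrt(length(temps))
    expect_lt(abs(mean(temps) - 310), 3 * se)
  }
})

test_that("bonded dimer samples the harmonic-bond Boltzmann distribution", {
  ff <- test_ff()
  cfg <- system_configuration(rbind(c(50, 50, 50), c(50, 50, 53.8)),
                              c(100, 100, 100), cbind(start = 1, end = 2),
                              c("G", "G"))
  kT <- 8.314462618e-3 * 310
  rg <- seq(0.5, 8, length.out = 4000)
  cdf <- cumsum(rg^2 * exp(-0.5 * ff$bond_k * (rg - ff$bond_r0)^2 / kT))
  cdf <- cdf / max(cdf)
  pvals <- vapply(1:3, function(seed) {
    # stride 500 steps = 5 ps decorrelates successive bond-length samples
    sch <- simulation_schedule(temperature = 310, friction = 0.5,
                               seed = 10 + seed, stride = 500L,
                               phases = list(list(label = "production",
                                                  n_steps = 1e6L,
                                                  box_z = NULL)))
    tr <- run_langevin(cfg, ff, sch)
    bl <- apply(tr$frames, 3, function(p) {
      d <- p[1, ] - p[2, ]
      d <- d - 100 * round(d / 100)
      sqrt(sum(d^2))
    })
    suppressWarnings(stats::ks.test(
      bl, function(q) stats::approx(rg, cdf, xout = q, rule = 2)$y)$p.value)
  }, 0)
  expect_true(all(pvals > 0.01))
})

test_that("near-zero friction conserves energy (NVE check mode)", {
  ff <- test_ff()
  # a 6-bead chain never spans the vdw cutoff, so the truncated potential
  # is smooth along the whole trajectory
  cfg <- initialize_compact(1, protein_sequence("GSGSGS"), ff,
                            c(80, 80, 80), seed = 6)
  cfg <- minimize_energy(cfg, ff, max_iter = 500, max_step = 0.05)
  sch <- simulation_schedule(timestep = 5, friction = 0, seed = 1,
                             stride = 1000L,
                             phases = list(list(label = "production",
                                                n_steps = 1e5L,
                                                box_z = NULL)))
  tr <- run_langevin(cfg, ff, sch)
  epot <- vapply(seq_len(n_frames(tr)), function(i)
    total_energy(get_frame(tr, i), ff)$total, 0)
  ekin <- 1.5 * 6 * 8.314462618e-3 * tr$provenance$temperatures
  etot <- epot + ekin
  drift <- abs(etot[length(etot)] - etot[1])
  expect_lt(drift / max(abs(mean(epot)), 1), 0.001)
})

test_that("bond topology is conserved and bonds never exceed 2 r0", {
  ff <- test_ff()
  lcd <- extract_region(tdp43_sequence(), 370, 414)  # 45 residues
  cfg <- initialize_compact(3, lcd, ff, c(90, 90, 90), seed = 4)
  cfg <- minimize_energy(cfg, ff)
  sch <- simulation_schedule(seed = 5, stride = 200L,
                             phases = list(list(label = "production",
                                                n_steps = 4000L,
                                                box_z = NULL)))
  tr <- run_langevin(cfg, ff, sch)
  expect_equal(dim(tr$frames)[1], 135)
  for (f in seq_len(n_frames(tr))) {
    p <- tr$frames[, , f]
    for (k in seq_len(nrow(tr$chains))) {
      idx <- tr$chains[k, 1]:tr$chains[k, 2]
      d <- diff(p[idx, , drop = FALSE])
      d <- d - sweep(round(sweep(d, 2, tr$box[f, ], "/")), 2, tr$box[f, ], "*")
      expect_lt(max(sqrt(rowSums(d^2))), 2 * ff$bond_r0)
    }
  }
})

test_that("slab extension recenters without distorting the cluster", {
  ff <- test_ff()
  lcd <- extract_region(tdp43_sequence(), 370, 414)
  # grow a cluster that does not span the z boundary, then embed it in a
  # taller box: every pairwise minimum-image distance must be preserved
  cfg <- initialize_compact(4, lcd, ff, c(90, 90, 70), seed = 7)
  cfg$box[3] <- 150
  cfg$positions[, 3] <- cfg$positions[, 3] + 40
  ext <- extend_to_slab(cfg, 900)
  expect_equal(ext$box, c(90, 90, 900))
  # pairwise distances preserved (old-box minimum image vs new geometry)
  pick <- cbind(sample(180, 60), sample(180, 60))
  d_old <- vapply(seq_len(60), function(k) {
    d <- cfg$positions[pick[k, 1], ] - cfg$positions[pick[k, 2], ]
    d <- d - cfg$box * round(d / cfg$box)
    sqrt(sum(d^2))
  }, 0)
  d_new <- vapply(seq_len(60), function(k) {
    d <- ext$positions[pick[k, 1], ] - ext$positions[pick[k, 2], ]
    d <- d - ext$box * round(d / ext$box)
    sqrt(sum(d^2))
  }, 0)
  expect_equal(d_new, d_old, tolerance = 1e-9)
  # idempotent
  ext2 <- extend_to_slab(ext, 900)
  expect_equal(ext2$positions, ext$positions, tolerance = 1e-9)
  expect_error(extend_to_slab(ext, 100), "smaller")
  # condensate centered at the box midpoint
  expect_lt(abs(mean(ext$positions[, 3]) - 450), 30)
})
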