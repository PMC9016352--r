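# Density profiles, coexistence concentrations, transfer free energy,
# condensate detection, ranking.

test_that("delta_g_trans: exact formula, antisymmetry, errors", {
  expect_equal(delta_g_trans(5, 5, 310), 0)
  expect_equal(delta_g_trans(exp(1), 1, 310), -8.314462618e-3 * 310,
               tolerance = 1e-12)
  expect_equal(delta_g_trans(exp(1), 1, 310), -2.577, tolerance = 1e-3)
  for (pair in list(c(300, 1), c(7, 2), c(1.5, 0.3)))
    expect_equal(delta_g_trans(pair[1], pair[2], 310),
                 -delta_g_trans(pair[2], pair[1], 310))
  expect_error(delta_g_trans(0, 1, 310), "positive")
  expect_error(delta_g_trans(10, -1, 310), "positive")
})

test_that("uniform configurations give flat profiles and no condensate", {
  traj <- make_tanh_slab(c_dense = 50, c_dilute = 50, box = c(80, 80, 800),
                         n_beads = 20000, n_frames = 5, seed = 3)
  ffu <- uniform_mass_forcefield(110)
  prof <- density_profile(traj, ffu, n_bins = 40, discard_fraction = 0,
                          centering = "none")
  expect_lt(max(prof$concentration) / min(prof$concentration), 2)
  pc <- phase_concentrations(prof, 50, 250)
  expect_equal(pc$c_dense, pc$c_dilute, tolerance = 0.1)
  expect_false(detect_condensate(prof, 10, 250))
  # degenerate threshold 1: any nonuniform profile counts as condensed
  expect_true(detect_condensate(prof, 1.0, 250))
})

test_that("profile mass conservation: sum(c * V_bin) = total bead mass", {
  traj <- make_tanh_slab(c_dense = 300, c_dilute = 3, box = c(80, 80, 800),
                         n_beads = 2000, n_frames = 3, seed = 8)
  ffu <- uniform_mass_forcefield(110)
  prof <- density_profile(traj, ffu, n_bins = 60, discard_fraction = 0)
  total_Da <- sum(prof$concentration) * attr(prof, "bin_volume") / 1660.53907
  expect_equal(total_Da, 2000 * 110, tolerance = 1e-6 * 2000 * 110)
})

test_that("tanh slab fixtures are recovered within tolerance", {
  ffu <- uniform_mass_forcefield(110)
  traj <- make_tanh_slab(c_dense = 300, c_dilute = 1, interface_width = 12,
                         box = c(100, 100, 1200), n_beads = 6000,
                         n_frames = 40, seed = 1)
  prof <- density_profile(traj, ffu, n_bins = 120, discard_fraction = 0)
  pc <- phase_concentrations(prof, 50, 250)
  expect_lt(abs(pc$c_dense - 300) / 300, 0.05)
  expect_lt(abs(pc$c_dilute - 1) / 1, 0.05)
  expect_true(detect_condensate(prof, 10, 250))
  # profile RMS error against the planted analytic curve, dense region
  h <- attr(traj, "manifest")$ground_truth$slab_halfwidth
  zmid <- 600
  planted <- 1 + (300 - 1) * 0.5 *
    (tanh((h - abs(prof$z - zmid)) / 12) + 1)
  rms <- sqrt(mean((prof$concentration - planted)^2))
  expect_lt(rms, 0.05 * 300)
})

test_that("profile centering makes the analysis translation invariant", {
  ffu <- uniform_mass_forcefield(110)
  traj <- make_tanh_slab(c_dense = 250, c_dilute = 2, box = c(80, 80, 900),
                         n_beads = 2500, n_frames = 4, seed = 5)
  shifted <- traj
  for (f in 1:4)
    shifted$frames[, 3, f] <- (traj$frames[, 3, f] + 330) %% 900
  p1 <- density_profile(traj, ffu, n_bins = 90, discard_fraction = 0)
  p2 <- density_profile(shifted, ffu, n_bins = 90, discard_fraction = 0)
  expect_equal(p2$concentration, p1$concentration,
               tolerance = 0.02 * max(p1$concentration))
})

test_that("window logic errors", {
  traj <- make_tanh_slab(300, 1, box = c(80, 80, 900), n_beads = 2000,
                         seed = 2)
  prof <- density_profile(traj, uniform_mass_forcefield(110), n_bins = 40,
                          discard_fraction = 0)
  expect_error(phase_concentrations(prof, 300, 250), "overlaps")
  expect_error(phase_concentrations(prof, 50, 2000), "margin too large")
  expect_error(density_profile(traj, uniform_mass_forcefield(110), n_bins = 5),
               ">= 10")
})

test_that("transfer free energy recovery across planted ratios", {
  ffu <- uniform_mass_forcefield(110)
  set.seed(42)
  ratios <- 10^runif(20, 1, 4)
  for (k in seq_along(ratios)) {
    cdil <- 400 / ratios[k]
    # bead budget sized so the dense slab half-width is ~90 A (the +-50 A
    # dense window then sits on the plateau); frames sized beforehand so
    # the dilute window collects >= ~1200 samples (~38 per frame per mg/mL)
    # >= ~3000 dilute samples keep the counting noise on delta-G (RT/sqrt(N))
    # near 0.05 kJ/mol, four times below the 0.2 kJ/mol recovery tolerance
    nb <- ceiling(65.7 * (0.85 * cdil + 60))
    nf <- max(2, min(2000, ceiling(3000 / (38.3 * cdil))))
    traj <- make_tanh_slab(c_dense = 400, c_dilute = cdil,
                           interface_width = 12, box = c(100, 100, 1200),
                           n_beads = nb, n_frames = nf, seed = 100 + k)
    prof <- density_profile(traj, ffu, n_bins = 120, discard_fraction = 0)
    pc <- phase_concentrations(prof, 50, 250)
    dg <- delta_g_trans(pc$c_dense, pc$c_dilute, 310)
    expect_lt(abs(dg - delta_g_trans(400, cdil, 310)), 0.2)
  }
})

test_that("rank_variants sorts by c_dilute with dissolved last and ties", {
  metrics <- list(
    A = list(c_dilute = 1, has_condensate = TRUE),
    B = list(c_dilute = 5, has_condensate = TRUE),
    C = list(c_dilute = 0.2, has_condensate = FALSE))
  rk <- rank_variants(metrics)
  expect_equal(rk$name, c("A", "B", "C"))
  expect_false(rk$has_condensate[3])
  # ties within tolerance share a rank
  m2 <- list(X = list(c_dilute = 1.0, has_condensate = TRUE),
             Y = list(c_dilute = 1.1, has_condensate = TRUE),
             Z = list(c_dilute = 9, has_condensate = TRUE))
  rk2 <- rank_variants(m2, tol = 0.25)
  expect_equal(rk2$rank, c(1L, 1L, 3L))
  expect_error(rank_variants(m2[1]), "at least two")
  names(m2)[2] <- "X"
  expect_error(rank_variants(m2), "duplicate")
})
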