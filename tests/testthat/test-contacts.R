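# Contact maps, type-resolved contact profiles and solvation histograms on
# planted-geometry fixtures.

test_that("planted inter-chain contact gives probability exactly 1", {
  pairs <- data.frame(chain_i = 1, res_i = 3, chain_j = 2, res_j = 7)
  traj <- make_planted_contact_traj(pairs, distances = 4.4, n_frames = 4)
  cm <- contact_map(traj, contact_rule("fixed_cutoff", 4.5), exclusion = 2,
                    chain_mode = "inter")
  expect_equal(cm[3, 7], 1)
  expect_equal(cm[7, 3], 1)
  expect_equal(sum(cm > 0, na.rm = TRUE), 2)
  # empty pair list: all-zero map
  traj0 <- make_planted_contact_traj(pairs[0, ], numeric(0), n_frames = 2)
  cm0 <- contact_map(traj0, contact_rule("fixed_cutoff", 4.5),
                     chain_mode = "inter")
  expect_equal(sum(cm0, na.rm = TRUE), 0)
})

test_that("contacts at the cutoff are excluded (strict inequality)", {
  pairs <- data.frame(chain_i = 1, res_i = 2, chain_j = 2, res_j = 2)
  at <- make_planted_contact_traj(pairs, distances = 4.5, n_frames = 1)
  cm <- contact_map(at, contact_rule("fixed_cutoff", 4.5), chain_mode = "inter")
  expect_equal(cm[2, 2], 0)
  below <- make_planted_contact_traj(pairs, distances = 4.4999, n_frames = 1)
  cmb <- contact_map(below, contact_rule("fixed_cutoff", 4.5),
                     chain_mode = "inter")
  expect_equal(cmb[2, 2], 1)
})

test_that("near-diagonal intra-chain contacts are excluded and flagged absent", {
  # same-chain residues 4 and 6 placed 3 A apart via a bent geometry
  traj <- make_planted_contact_traj(
    data.frame(chain_i = 1, res_i = 4, chain_j = 1, res_j = 6),
    distances = 3, n_frames = 2, n_chains = 1)
  cm <- contact_map(traj, contact_rule("fixed_cutoff", 4.5), exclusion = 2,
                    chain_mode = "both")
  expect_true(is.na(cm[4, 6]))  # |i-j| = 2 <= exclusion: absent, not zero
  expect_true(all(is.na(diag(cm))))
  # with exclusion 1 the same geometry counts
  cm1 <- contact_map(traj, contact_rule("fixed_cutoff", 4.5), exclusion = 1,
                     chain_mode = "intra")
  expect_equal(cm1[4, 6], 1)
})

test_that("sigma rule threshold sits at 2^(1/6) sigma_ij", {
  ff <- test_ff()
  # plant G-G pairs around the 2^(1/6) * 4.5 = 5.05 A threshold
  thr <- 2^(1/6) * ff$beads$sigma[ff$beads$code == "G"]
  for (d in c(thr - 0.05, thr + 0.05)) {
    traj <- make_planted_contact_traj(
      data.frame(chain_i = 1, res_i = 2, chain_j = 2, res_j = 5),
      distances = d, n_frames = 1)
    cm <- contact_map(traj, contact_rule("sigma_cutoff"), ff = ff,
                      chain_mode = "inter")
    expect_equal(cm[2, 5], as.numeric(d < thr))
  }
  expect_error(contact_map(
    make_planted_contact_traj(
      data.frame(chain_i = 1, res_i = 1, chain_j = 2, res_j = 1), 4),
    contact_rule("sigma_cutoff")), "force field")
})

test_that("maps are symmetric, frame-duplication invariant and translation invariant", {
  pairs <- data.frame(chain_i = c(1, 1), res_i = c(2, 8),
                      chain_j = c(2, 2), res_j = c(5, 9))
  traj <- make_planted_contact_traj(pairs, distances = c(4.0, 4.2),
                                    n_frames = 2)
  strip <- function(x) {
    x <- unclass(x)
    attributes(x) <- attributes(x)[c("dim", "dimnames")]
    x
  }
  cm <- contact_map(traj, contact_rule("fixed_cutoff", 4.5))
  m <- strip(cm)
  expect_identical(m, t(m))
  traj4 <- make_planted_contact_traj(pairs, distances = c(4.0, 4.2),
                                     n_frames = 6)
  cm4 <- contact_map(traj4, contact_rule("fixed_cutoff", 4.5))
  expect_equal(strip(cm4), m)
  # rigid translation with periodic wrap
  trajT <- traj
  for (f in 1:2) {
    trajT$frames[, , f] <- sweep(traj$frames[, , f], 2, c(111, 222, 333), "+")
    trajT$frames[, , f] <- trajT$frames[, , f] %% rep(traj$box[f, ], each = dim(traj$frames)[1])
  }
  cmT <- contact_map(trajT, contact_rule("fixed_cutoff", 4.5))
  expect_equal(strip(cmT), m)
})

test_that("difference maps are exact and antisymmetric", {
  mk <- function(d, nf) contact_map(
    make_planted_contact_traj(
      data.frame(chain_i = 1, res_i = 3, chain_j = 2, res_j = 7), d, nf),
    contact_rule("fixed_cutoff", 4.5), chain_mode = "inter")
  A <- mk(4.0, 3)  # P = 1 at (3,7)
  B <- mk(9.0, 3)  # P = 0
  dAB <- contact_difference(A, B)
  expect_equal(dAB[3, 7], 1)
  expect_equal(contact_difference(A, A)[3, 7], 0)
  expect_equal(unclass(contact_difference(B, A)), -unclass(dAB))
  B2 <- contact_map(
    make_planted_contact_traj(
      data.frame(chain_i = 1, res_i = 3, chain_j = 2, res_j = 7), 4, 3),
    contact_rule("fixed_cutoff", 5.0), chain_mode = "inter")
  expect_error(contact_difference(A, B2), "different rules")
})

test_that("type-resolved contacts put all mass on the planted partner type", {
  # chain 2 is all arginine; the only source with any contact is the
  # serine at position 5 of chain 1, touching an arginine at position 7
  traj <- make_planted_contact_traj(
    data.frame(chain_i = 1, res_i = 5, chain_j = 2, res_j = 7),
    distances = 4.0, n_frames = 3, chain_length = 10)
  codes <- traj$bead_codes
  codes[1:10] <- "S"; codes[11:20] <- "R"
  traj$bead_codes <- codes
  prof <- type_resolved_contacts(traj, source_sites = 5,
                                 rule = contact_rule("fixed_cutoff", 4.5))
  expect_equal(unname(prof["R"]), 1)
  expect_equal(sum(prof), 1, tolerance = 1e-9)
  # no contacts anywhere: explicitly flagged empty profile
  far <- make_planted_contact_traj(
    data.frame(chain_i = 1, res_i = 5, chain_j = 2, res_j = 7), 50, 1)
  p0 <- type_resolved_contacts(far, 5)
  expect_true(attr(p0, "no_contacts"))
  expect_equal(sum(p0), 0)
  expect_error(type_resolved_contacts(traj, integer(0)), "empty")
})

test_that("solvation histograms recover planted water counts exactly", {
  cfg <- make_solvated_frame(water_counts = c(7, 0, 3), cutoff = 5, seed = 2)
  h <- solvation_histogram(cfg, selection = 1:3, cutoff = 5)
  expect_equal(sum(h$frequency), 1)
  expect_equal(h$frequency[h$count == 7], 1/3)
  expect_equal(h$frequency[h$count == 0], 1/3)
  expect_equal(h$frequency[h$count == 3], 1/3)
  # selection restricted to the first residue
  h1 <- solvation_histogram(cfg, selection = 1, cutoff = 5)
  expect_equal(h1$frequency[h1$count == 7], 1)
  # cutoff -> 0: all counts zero
  h0 <- solvation_histogram(cfg, selection = 1:3, cutoff = 1e-9)
  expect_equal(h0$frequency[h0$count == 0], 1)
  expect_error(make_solvated_frame(c(-1, 2)), "non-negative")
})
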