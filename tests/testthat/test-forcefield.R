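# Energy model: pair potentials, Debye screening, neighbor-list vs
# brute-force totals, analytic vs numerical forces.

test_that("force field validates its parameter table", {
  ff <- test_ff()
  expect_equal(nrow(ff$beads), 21)
  tab <- ff$beads
  f <- tempfile(fileext = ".csv")
  write.csv(tab[tab$code != "s", ], f, row.names = FALSE)
  expect_error(hps_forcefield(param_table = f), "missing residue type.*s")
  expect_error(hps_forcefield(ionic_strength = 0), "positive")
})

test_that("Debye length follows the screening formula", {
  # closed-form hand value at 100 mM, 310 K, D = 80
  eps0 <- 8.8541878128e-12; e <- 1.602176634e-19
  kB <- 1.380649e-23; NAv <- 6.02214076e23
  hand <- sqrt(eps0 * 80 * kB * 310 / (2 * NAv * e^2 * 100)) * 1e10
  expect_equal(debye_length(310, 0.1, 80), hand, tolerance = 1e-12)
  expect_lt(abs(debye_length(310, 0.1, 80) - hand) / hand, 0.05)
  # kappa^-1 ~ I^(-1/2): quadrupling I halves the length
  expect_equal(debye_length(310, 0.4, 80), debye_length(310, 0.1, 80) / 2,
               tolerance = 1e-12)
})

test_that("Ashbaugh-Hatch potential: continuity, limits, zero crossing", {
  ff <- test_ff()
  sig <- (ff$beads$sigma[ff$beads$code == "S"] +
          ff$beads$sigma[ff$beads$code == "F"]) / 2
  lam <- (ff$beads$lambda[ff$beads$code == "S"] +
          ff$beads$lambda[ff$beads$code == "F"]) / 2
  rsw <- 2^(1/6) * sig
  # both branches meet at -lambda_ij * epsilon
  expect_equal(vdw_pair_energy(rsw - 1e-9, "S", "F", ff), -lam * ff$epsilon,
               tolerance = 1e-6)
  expect_equal(vdw_pair_energy(rsw + 1e-9, "S", "F", ff), -lam * ff$epsilon,
               tolerance = 1e-6)
  # at r = sigma_ij the LJ term vanishes: only the (1 - lambda) eps shift
  expect_equal(vdw_pair_energy(sig, "S", "F", ff), (1 - lam) * ff$epsilon,
               tolerance = 1e-12)
  # lambda = 1 beads (F, P): plain Lennard-Jones on both branches
  r <- seq(5, 20, by = 0.25)
  srf <- ff$beads$sigma[ff$beads$code == "F"]
  lj <- 4 * ff$epsilon * ((srf / r)^12 - (srf / r)^6)
  expect_equal(vdw_pair_energy(r, "F", "F", ff), lj, tolerance = 1e-12)
  # symmetry in (i, j)
  expect_equal(vdw_pair_energy(7.3, "D", "R", ff),
               vdw_pair_energy(7.3, "R", "D", ff))
  expect_error(vdw_pair_energy(-1, "S", "S", ff), "positive")
  expect_error(vdw_pair_energy(5, "Z", "S", ff), "unknown")
})

test_that("Debye-Hueckel pair energy matches the scalar formula", {
  ff <- test_ff()
  expect_equal(elec_pair_energy(8, "G", "D", ff), 0)  # neutral partner
  # screening definition: at r = kappa^-1 the Coulomb value drops by 1/e
  kap <- ff$debye_length
  coul <- 1389.35458 / (80 * kap)
  expect_equal(elec_pair_energy(kap, "D", "D", ff), coul * exp(-1),
               tolerance = 1e-6)
  # hand evaluation: two aspartates at 10 A
  hand <- 1389.35458 * 1 * exp(-10 / kap) / (80 * 10)
  expect_equal(elec_pair_energy(10, "D", "D", ff), hand, tolerance = 1e-9)
  expect_gt(hand, 0)  # like charges repel
  expect_lt(elec_pair_energy(10, "D", "R", ff), 0)
  expect_equal(elec_pair_energy(10, "D", "K", ff),
               elec_pair_energy(10, "K", "D", ff))
})

test_that("neighbor-list energy equals the brute-force oracle", {
  ff <- test_ff()
  for (seed in 1:20) {
    cfg <- random_config(200, box = c(80, 80, 80), seed = seed)
    e_nl <- total_energy(cfg, ff, use_neighbor_list = TRUE)
    e_ap <- total_energy(cfg, ff, use_neighbor_list = FALSE)
    expect_lt(abs(e_nl$total - e_ap$total) /
                max(abs(e_ap$total), 1e-10), 1e-8)
  }
  # and both equal the independent R double-loop oracle on a few cases
  for (seed in c(2, 11)) {
    cfg <- random_config(120, box = c(80, 80, 80), seed = seed)
    eo <- brute_energy(cfg, ff)
    ec <- total_energy(cfg, ff)
    expect_equal(ec$bond, unname(eo["bond"]), tolerance = 1e-10)
    expect_equal(ec$vdw, unname(eo["vdw"]), tolerance = 1e-10)
    expect_equal(ec$elec, unname(eo["elec"]), tolerance = 1e-10)
  }
})

test_that("trivial energy cases", {
  ff <- test_ff()
  # two bonded beads at r0: zero bond energy
  cfg <- system_configuration(rbind(c(40, 40, 40), c(40, 40, 40 + ff$bond_r0)),
                              c(90, 90, 90), cbind(start = 1, end = 2),
                              c("G", "G"))
  expect_equal(total_energy(cfg, ff)$bond, 0)
  # lambda = 0 beads (R) beyond the switch distance: vdw exactly zero
  d <- 2^(1/6) * ff$beads$sigma[ff$beads$code == "R"] + 0.5
  sq <- rbind(c(40, 40, 40), c(40 + d, 40, 40),
              c(40, 40 + d, 40), c(40 + d, 40 + d, 40))
  cfg <- system_configuration(sq, c(90, 90, 90),
                              cbind(start = 1:4, end = 1:4), rep("R", 4))
  e <- total_energy(cfg, ff)
  expect_equal(e$vdw, 0)
  expect_error(total_energy(
    system_configuration(sq, c(60, 90, 90), cbind(start = 1:4, end = 1:4),
                         rep("R", 4)), ff), "twice the largest cutoff")
})

test_that("energy is invariant under rigid translation (periodic image)", {
  ff <- test_ff()
  cfg <- random_config(150, box = c(80, 80, 80), seed = 5)
  e0 <- total_energy(cfg, ff)$total
  for (shift in list(c(13, -27, 41), c(80, 0, 0), c(1.5, 1.5, 200.5))) {
    cfg2 <- cfg
    cfg2$positions <- sweep(cfg$positions, 2, shift, "+") %% 80
    expect_equal(total_energy(cfg2, ff)$total, e0, tolerance = 1e-8)
  }
})

test_that("swapping a serine for phosphoserine changes only local terms", {
  ff <- test_ff()
  cfg <- random_config(60, box = c(80, 80, 80), seed = 9,
                       codes = rep(c("S", "G", "R"), each = 20))
  e0 <- total_energy(cfg, ff)
  cfg2 <- cfg
  cfg2$bead_codes[1] <- "s"
  e1 <- total_energy(cfg2, ff)
  # bond terms have no type dependence; vdw/elec may change
  expect_equal(e1$bond, e0$bond)
  # removing bead 1 from both systems gives identical energies
  drop1 <- function(cfg) {
    ch <- cfg$chains
    ch[1, 1] <- 2L          # bead 1 leaves chain 1 ...
    ch <- ch - 1L           # ... and every index shifts down by one
    system_configuration(cfg$positions[-1, ], cfg$box, ch,
                         cfg$bead_codes[-1])
  }
  expect_equal(total_energy(drop1(cfg), ff)$total,
               total_energy(drop1(cfg2), ff)$total)
})

test_that("analytic forces match central differences and sum to zero", {
  ff <- test_ff()
  cfg <- random_config(50, box = c(80, 80, 80), seed = 4)
  f <- forces(cfg, ff)
  expect_lt(max(abs(colSums(f))), 1e-6)
  h <- 1e-5
  set.seed(1)
  for (i in sample(50, 8)) for (d in 1:3) {
    cp <- cfg; cp$positions[i, d] <- cp$positions[i, d] + h
    cm <- cfg; cm$positions[i, d] <- cm$positions[i, d] - h
    fd <- -(total_energy(cp, ff)$total - total_energy(cm, ff)$total) / (2 * h)
    expect_equal(f[i, d], fd, tolerance = 1e-4)
  }
})

test_that("isolated bead and stretched dimer forces", {
  ff <- test_ff()
  cfg <- system_configuration(matrix(c(40, 40, 40), 1, 3), c(90, 90, 90),
                              cbind(start = 1, end = 1), "G")
  expect_equal(max(abs(forces(cfg, ff))), 0)
  # bonded dimer stretched by delta: |F| = k * delta (far beyond vdw range? no,
  # bonded pairs are excluded from nonbonded terms, so force is purely Hookean)
  delta <- 0.7
  cfg <- system_configuration(rbind(c(40, 40, 40),
                                    c(40, 40, 40 + ff$bond_r0 + delta)),
                              c(90, 90, 90), cbind(start = 1, end = 2),
                              c("G", "G"))
  f <- forces(cfg, ff)
  expect_equal(f[1, 3], ff$bond_k * delta, tolerance = 1e-9)
  expect_equal(f[2, 3], -ff$bond_k * delta, tolerance = 1e-9)
})
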