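# Independent oracles and small builders shared across tests.  The energy
# oracle is a literal O(N^2) double loop written against the model formulas,
# kept free of any package internals beyond the exported pair energies.

# All-pairs potential energy from scalar formulas (R double loop).
brute_energy <- function(cfg, ff) {
  n <- nrow(cfg$positions)
  bonded <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(cfg$chains))) {
    s <- cfg$chains[k, 1]; e <- cfg$chains[k, 2]
    if (e > s) for (i in s:(e - 1)) bonded[i, i + 1] <- bonded[i + 1, i] <- TRUE
  }
  E <- c(bond = 0, vdw = 0, elec = 0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- cfg$positions[i, ] - cfg$positions[j, ]
    d <- d - cfg$box * round(d / cfg$box)
    r <- sqrt(sum(d^2))
    if (bonded[i, j]) {
      E["bond"] <- E["bond"] + 0.5 * ff$bond_k * (r - ff$bond_r0)^2
    } else {
      E["vdw"] <- E["vdw"] +
        vdw_pair_energy(r, cfg$bead_codes[i], cfg$bead_codes[j], ff)
      E["elec"] <- E["elec"] +
        elec_pair_energy(r, cfg$bead_codes[i], cfg$bead_codes[j], ff)
    }
  }
  E
}

# Random non-pathological configuration: beads at least min_sep apart.
random_config <- function(n, box, codes = NULL, min_sep = 3.5, seed = 1,
                          chain_len = 10) {
  set.seed(seed)
  pool <- c("G", "S", "N", "Q", "A", "F", "R", "D", "K", "E")
  if (is.null(codes)) codes <- sample(pool, n, replace = TRUE)
  pos <- matrix(NA_real_, n, 3)
  placed <- 0L
  while (placed < n) {
    p <- runif(3) * box
    ok <- TRUE
    if (placed > 0) {
      d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, p)
      d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
      ok <- all(rowSums(d^2) >= min_sep^2)
    }
    if (ok) { placed <- placed + 1L; pos[placed, ] <- p }
  }
  nch <- ceiling(n / chain_len)
  starts <- (seq_len(nch) - 1L) * chain_len + 1L
  ends <- pmin(seq_len(nch) * chain_len, n)
  system_configuration(pos, box, cbind(start = starts, end = ends), codes)
}

# Shared force field (construction is cheap but avoid repeating I/O).
test_ff <- local({
  ff <- NULL
  function() {
    if (is.null(ff)) ff <<- hps_forcefield()
    ff
  }
})

tdp43_lcd <- function() extract_region(tdp43_sequence(), 261, 414)
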