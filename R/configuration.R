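# Bead configurations in periodic orthorhombic boxes, and energy/force
# evaluation through the compiled engine.

#' Bead configuration in a periodic box
#'
#' @param positions N x 3 matrix of bead coordinates (A).
#' @param box lengths `c(Lx, Ly, Lz)` of the orthorhombic periodic box (A).
#' @param chains two-column matrix or data.frame of 1-based `(start, end)`
#'   bead index ranges, one row per chain; chains must be disjoint and cover
#'   all beads.
#' @param bead_codes character vector of residue codes, one per bead.
#' @return an object of class `system_configuration`.
#' @export
system_configuration <- function(positions, box, chains, bead_codes) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths")
  chains <- as.matrix(as.data.frame(chains)[, 1:2])
  storage.mode(chains) <- "integer"
  colnames(chains) <- c("start", "end")
  n <- nrow(positions)
  covered <- unlist(lapply(seq_len(nrow(chains)),
                           function(k) chains[k, 1]:chains[k, 2]))
  if (anyDuplicated(covered) || length(covered) != n ||
      !setequal(covered, seq_len(n)))
    stop("chains must be disjoint and cover all beads")
  if (length(bead_codes) != n) stop("one bead code per bead required")
  structure(list(positions = positions, box = box, chains = chains,
                 bead_codes = as.character(bead_codes)),
            class = "system_configuration")
}

#' @export
print.system_configuration <- function(x, ...) {
  cat(sprintf("system_configuration: %d beads in %d chain(s), box %.0f x %.0f x %.0f A\n",
              nrow(x$positions), nrow(x$chains), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Build a configuration from protein chains
#'
#' Convenience constructor: `n_chains` copies of `seq` with the given
#' per-chain coordinate list.
#' @param coords list of L x 3 matrices, one per chain.
#' @param seq a [protein_sequence()] shared by all chains.
#' @param box periodic box lengths.
#' @return a [system_configuration()].
#' @keywords internal
config_from_chains <- function(coords, seq, box) {
  L <- length(seq$residues)
  n_chains <- length(coords)
  chains <- cbind(start = (seq_len(n_chains) - 1L) * L + 1L,
                  end = seq_len(n_chains) * L)
  system_configuration(do.call(rbind, coords), box, chains,
                       rep(seq$residues, n_chains))
}

# Bond list (0-based, for the engine): consecutive beads within each chain.
config_bonds0 <- function(config) {
  out <- lapply(seq_len(nrow(config$chains)), function(k) {
    s <- config$chains[k, 1]; e <- config$chains[k, 2]
    if (e > s) cbind(s:(e - 1L), (s + 1L):e) else NULL
  })
  b <- do.call(rbind, out)
  if (is.null(b)) b <- matrix(integer(0), 0, 2)
  storage.mode(b) <- "integer"
  b - 1L
}

# Pack force-field parameters for the engine, with bead types indexed
# 0-based in the order of ff$beads.
ff_pack <- function(config, ff) {
  type0 <- ff_index(ff, config$bead_codes) - 1L
  list(type0 = as.integer(type0),
       params = list(sigma = ff$beads$sigma, lambda = ff$beads$lambda,
                     charge = as.numeric(ff$beads$charge),
                     mass = ff$beads$mass,
                     epsilon = ff$epsilon, bond_k = ff$bond_k,
                     bond_r0 = ff$bond_r0, debye_length = ff$debye_length,
                     kq = COULOMB_K / ff$dielectric,
                     cutoff_vdw = ff$cutoff_vdw,
                     cutoff_elec = ff$cutoff_elec))
}

check_box_cutoffs <- function(config, ff) {
  if (any(config$box < 2 * max(ff$cutoff_vdw, ff$cutoff_elec)))
    stop("box smaller than twice the largest cutoff")
}

#' Total potential energy with per-term breakdown
#'
#' Sums harmonic bond, Ashbaugh-Hatch and Debye-Hueckel terms over all bonds
#' and nonbonded pairs under the periodic minimum image.  With
#' `use_neighbor_list = TRUE` a cell-binned neighbor list restricted to the
#' interaction cutoffs is used; the result is identical (to floating-point
#' noise) to the all-pairs evaluation.
#'
#' @param config a [system_configuration()].
#' @param ff an [hps_forcefield()].
#' @param use_neighbor_list use the cell/Verlet pair list (default) or an
#'   explicit all-pairs double loop.
#' @return list with components `bond`, `vdw`, `elec`, `total` (kJ/mol).
#' @export
total_energy <- function(config, ff, use_neighbor_list = TRUE) {
  check_box_cutoffs(config, ff)
  p <- ff_pack(config, ff)
  cpp_energy(config$positions, config$box, p$type0, config_bonds0(config),
             p$params, use_neighbor_list)
}

#' Relax steric overlaps by clamped steepest descent
#'
#' Moves beads along the force direction with a bounded per-iteration
#' displacement until the largest force drops below ~10 kJ/mol/A or
#' `max_iter` is reached.  Used to relax grown configurations before
#' dynamics; deterministic.
#'
#' @inheritParams total_energy
#' @param max_iter iteration cap.
#' @param max_step largest per-bead displacement per iteration, A.
#' @return the relaxed [system_configuration()].
#' @export
minimize_energy <- function(config, ff, max_iter = 300, max_step = 0.2) {
  check_box_cutoffs(config, ff)
  p <- ff_pack(config, ff)
  out <- config
  out$positions <- cpp_minimize(config$positions, config$box, p$type0,
                                config_bonds0(config), p$params,
                                as.integer(max_iter), max_step)
  out
}

#' Analytic forces on every bead
#'
#' Gradient of [total_energy()]; matches central finite differences of the
#' energy and sums to zero over all beads under the minimum image.
#'
#' @inheritParams total_energy
#' @return N x 3 matrix of forces (kJ/mol/A).
#' @export
forces <- function(config, ff) {
  check_box_cutoffs(config, ff)
  p <- ff_pack(config, ff)
  cpp_forces(config$positions, config$box, p$type0, config_bonds0(config),
             p$params)
}
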