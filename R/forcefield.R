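# HPS force field: per-residue bead parameters, Ashbaugh-Hatch short-range
# potential and Debye-Hueckel electrostatics.  Units throughout: length in
# Angstrom, energy in kJ/mol, mass in g/mol (Da), charge in elementary
# charges, time in ps.

KCAL_TO_KJ <- 4.184
# e^2 N_A / (4 pi eps0), in kJ A / mol: Coulomb energy prefactor in vacuum
COULOMB_K <- 1389.35458
KB_KJ <- 8.314462618e-3   # gas constant, kJ/(mol K)

#' Debye screening length
#'
#' \eqn{\kappa^{-1} = \sqrt{\epsilon_0 D k_B T / (2 N_A e^2 I)}} for a
#' monovalent salt of ionic strength `ionic_strength`.
#'
#' @param temperature K.
#' @param ionic_strength mol/L; must be positive.
#' @param dielectric relative solvent dielectric constant.
#' @return screening length in Angstrom.
#' @examples
#' debye_length(310, 0.1, 80)  # ~9.9 A
#' @export
debye_length <- function(temperature, ionic_strength, dielectric = 80) {
  if (ionic_strength <= 0) stop("ionic strength must be positive")
  eps0 <- 8.8541878128e-12; e <- 1.602176634e-19
  kB <- 1.380649e-23; NA_ <- 6.02214076e23
  lm <- sqrt(eps0 * dielectric * kB * temperature /
             (2 * NA_ * e^2 * ionic_strength * 1000))
  lm * 1e10
}

#' Build an HPS force field
#'
#' Loads the per-residue bead parameters (mass, integer charge, diameter
#' sigma, hydrophobicity lambda) and combines them with the global model
#' constants.  The pair potential is the Ashbaugh-Hatch form
#' \deqn{\Phi(r) = LJ(r) + (1-\lambda_{ij})\epsilon \quad (r \le 2^{1/6}\sigma_{ij}),
#'       \qquad \lambda_{ij} LJ(r) \quad (r > 2^{1/6}\sigma_{ij})}
#' with arithmetic mixing \eqn{\sigma_{ij} = (\sigma_i+\sigma_j)/2},
#' \eqn{\lambda_{ij} = (\lambda_i+\lambda_j)/2}, plus Debye-Hueckel screened
#' electrostatics and harmonic bonds between consecutive beads.  Nonbonded
#' terms are truncated at their cutoffs; directly bonded pairs are excluded
#' from the nonbonded sums.
#'
#' @param param_table CSV of bead parameters; defaults to the bundled table
#'   covering the 20 canonical residues plus phosphoserine.
#' @param temperature K (used for the Debye length).
#' @param ionic_strength mol/L.
#' @param epsilon Ashbaugh-Hatch energy scale, kJ/mol (default 0.2 kcal/mol).
#' @param bond_k harmonic bond constant, kJ/(mol A^2); the bond energy is
#'   \eqn{k(r-r_0)^2/2}.
#' @param bond_r0 equilibrium bond length, A.
#' @param dielectric relative dielectric constant.
#' @param cutoff_vdw,cutoff_elec truncation distances, A.
#' @return an object of class `hps_forcefield`.
#' @export
hps_forcefield <- function(param_table = NULL, temperature = 310,
                           ionic_strength = 0.1,
                           epsilon = 0.2 * KCAL_TO_KJ,
                           bond_k = 10, bond_r0 = 3.8, dielectric = 80,
                           cutoff_vdw = 25, cutoff_elec = 35) {
  if (is.null(param_table))
    param_table <- system.file("extdata", "hps_params.csv", package = "hpslab")
  beads <- utils::read.csv(param_table, comment.char = "#",
                           stringsAsFactors = FALSE)
  names(beads) <- c("code", "mass", "charge", "sigma", "lambda")
  missing <- setdiff(c(AA_CODES, SEP_CODE), beads$code)
  if (length(missing))
    stop("parameter table missing residue type(s): ",
         paste(missing, collapse = ", "))
  if (any(beads$mass <= 0) || any(beads$sigma <= 0))
    stop("bead masses and diameters must be positive")
  if (any(beads$lambda < 0 | beads$lambda > 1.1))
    stop("lambda outside [0, 1.1]")
  if (epsilon <= 0) stop("epsilon must be positive")
  rmin_max <- 2^(1/6) * max(beads$sigma)
  if (cutoff_vdw <= rmin_max || cutoff_elec <= rmin_max)
    stop("cutoffs must exceed 2^(1/6) * max sigma")
  ff <- structure(list(
    beads = beads, epsilon = epsilon, bond_k = bond_k, bond_r0 = bond_r0,
    dielectric = dielectric, temperature = temperature,
    ionic_strength = ionic_strength,
    debye_length = debye_length(temperature, ionic_strength, dielectric),
    cutoff_vdw = cutoff_vdw, cutoff_elec = cutoff_elec),
    class = "hps_forcefield")
  ff
}

#' @export
print.hps_forcefield <- function(x, ...) {
  cat(sprintf(paste0(
    "HPS force field: %d bead types; epsilon %.4f kJ/mol; bond k %.1f, ",
    "r0 %.1f A\n  T %.0f K, I %.3f M, D %.0f, Debye length %.2f A, ",
    "cutoffs vdw %.0f / elec %.0f A\n"),
    nrow(x$beads), x$epsilon, x$bond_k, x$bond_r0, x$temperature,
    x$ionic_strength, x$dielectric, x$debye_length,
    x$cutoff_vdw, x$cutoff_elec))
  invisible(x)
}

ff_index <- function(ff, codes) {
  idx <- match(codes, ff$beads$code)
  if (anyNA(idx))
    stop("unknown residue code(s): ",
         paste(unique(codes[is.na(idx)]), collapse = ", "))
  idx
}

#' Ashbaugh-Hatch pair energy
#'
#' Vectorized over `r`.  Continuous at the switch point
#' \eqn{r = 2^{1/6}\sigma_{ij}}, where both branches evaluate to
#' \eqn{-\lambda_{ij}\epsilon}; truncated to zero beyond `cutoff_vdw`.
#'
#' @param r distance(s), A.
#' @param code_i,code_j residue codes.
#' @param ff an [hps_forcefield()].
#' @return energy in kJ/mol.
#' @export
vdw_pair_energy <- function(r, code_i, code_j, ff) {
  if (any(r <= 0)) stop("r must be positive")
  i <- ff_index(ff, code_i); j <- ff_index(ff, code_j)
  sig <- (ff$beads$sigma[i] + ff$beads$sigma[j]) / 2
  lam <- (ff$beads$lambda[i] + ff$beads$lambda[j]) / 2
  eps <- ff$epsilon
  sr6 <- (sig / r)^6
  lj <- 4 * eps * (sr6^2 - sr6)
  u <- ifelse(r <= 2^(1/6) * sig, lj + (1 - lam) * eps, lam * lj)
  ifelse(r < ff$cutoff_vdw, u, 0)
}

#' Debye-Hueckel pair energy
#'
#' \eqn{\Phi(r) = q_i q_j e^2 \exp(-r/\kappa^{-1}) / (4\pi\epsilon_0 D r)},
#' truncated to zero beyond `cutoff_elec`.  Zero whenever either bead is
#' uncharged.
#'
#' @inheritParams vdw_pair_energy
#' @return energy in kJ/mol.
#' @export
elec_pair_energy <- function(r, code_i, code_j, ff) {
  if (any(r <= 0)) stop("r must be positive")
  i <- ff_index(ff, code_i); j <- ff_index(ff, code_j)
  qq <- ff$beads$charge[i] * ff$beads$charge[j]
  u <- COULOMB_K * qq * exp(-r / ff$debye_length) / (ff$dielectric * r)
  ifelse(r < ff$cutoff_elec, u, 0)
}
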