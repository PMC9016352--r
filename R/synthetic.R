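# Seeded generators for every fixture the analysis operators need: slab
# configurations with a prescribed tanh density profile, trajectories with
# planted contacts, frames with planted water coordination, exponential
# FRAP recoveries and label images of ellipses.  Every generator is a pure
# function of (parameters, seed) and serializes its ground truth alongside
# the fixture (attribute "manifest").

fixture_manifest <- function(generator, params, seed, ground_truth) {
  list(generator = generator, params = params, seed = seed,
       ground_truth = ground_truth)
}

#' Write a fixture manifest as JSON
#' @param x an object with a `"manifest"` attribute.
#' @param path output path.
#' @export
write_manifest <- function(x, path) {
  m <- attr(x, "manifest")
  if (is.null(m)) stop("object carries no fixture manifest")
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Slab fixture with a prescribed tanh density profile
#'
#' Places single-bead "chains" by rejection sampling from the planted profile
#' \deqn{c(z) = c_{dil} + (c_{dense}-c_{dil})\,
#'   \tfrac12\left[\tanh\!\left(\frac{h - |z - L_z/2|}{w}\right) + 1\right]}
#' where the slab half-width `h` follows from the bead budget by mass
#' conservation.  Frames are independent draws, so averaging reduces
#' counting noise exactly as for an ideal uncorrelated trajectory.
#'
#' @param c_dense,c_dilute planted coexistence concentrations, mg/mL.
#' @param interface_width tanh width `w`, A.
#' @param box box lengths, A.
#' @param n_beads beads per frame.
#' @param n_frames number of independent frames.
#' @param bead_mass mass per bead, Da.
#' @param seed integer seed.
#' @return a [trajectory()] with the analytic profile and planted values in
#'   its `"manifest"` attribute.
#' @export
make_tanh_slab <- function(c_dense, c_dilute, interface_width = 15,
                           box = c(100, 100, 1200), n_beads = 20000,
                           n_frames = 1, bead_mass = 110, seed = 1L) {
  if (c_dense < c_dilute) stop("c_dense must be >= c_dilute")
  if (c_dilute < 0) stop("concentrations must be non-negative")
  Lz <- box[3]
  total_conc <- n_beads * bead_mass / prod(box) * DA_PER_A3_TO_MG_ML
  # mass conservation: c_dil*Lz + (c_dense - c_dil)*2h = total_conc*Lz
  if (c_dense > c_dilute) {
    h <- (total_conc - c_dilute) * Lz / (c_dense - c_dilute) / 2
    if (h <= 2 * interface_width)
      stop("bead budget too small for the requested dense slab")
    if (h >= Lz / 2 - 2 * interface_width)
      stop("bead budget too large: slab fills the box")
  } else h <- 0
  prof <- function(z) {
    if (c_dense == c_dilute) return(rep(c_dense, length(z)))
    c_dilute + (c_dense - c_dilute) *
      0.5 * (tanh((h - abs(z - Lz / 2)) / interface_width) + 1)
  }
  set.seed(seed)
  cmax <- c_dense * 1.0000001
  draw_z <- function(n) {
    out <- numeric(0)
    guard <- 0L
    while (length(out) < n) {
      guard <- guard + 1L
      if (guard > 10000L) stop("rejection sampling failed to converge")
      m <- max(1000L, ceiling((n - length(out)) * 1.2 * cmax /
                                max(mean(prof(seq(0, Lz, length.out = 256))),
                                    1e-12)))
      m <- min(m, 5e6)
      z <- stats::runif(m, 0, Lz)
      acc <- stats::runif(m) < prof(z) / cmax
      out <- c(out, z[acc])
    }
    out[seq_len(n)]
  }
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    z <- draw_z(n_beads)
    frames[[f]] <- cbind(stats::runif(n_beads, 0, box[1]),
                         stats::runif(n_beads, 0, box[2]), z)
  }
  chains <- cbind(start = seq_len(n_beads), end = seq_len(n_beads))
  traj <- trajectory(frames, times = seq_len(n_frames), box = box,
                     chains = chains, bead_codes = rep("G", n_beads))
  attr(traj, "bead_mass") <- bead_mass
  attr(traj, "manifest") <- fixture_manifest(
    "make_tanh_slab",
    list(c_dense = c_dense, c_dilute = c_dilute,
         interface_width = interface_width, box = box, n_beads = n_beads,
         n_frames = n_frames, bead_mass = bead_mass),
    seed,
    list(c_dense = c_dense, c_dilute = c_dilute, slab_halfwidth = h))
  traj
}

#' Uniform-mass force field for density fixtures
#'
#' A minimal force field whose beads all share `bead_mass`; lets the density
#' operators run on fixtures whose beads are not real residues.
#' @param bead_mass Da.
#' @return an [hps_forcefield()]-compatible object.
#' @export
uniform_mass_forcefield <- function(bead_mass = 110) {
  ff <- hps_forcefield()
  ff$beads$mass <- rep(bead_mass, nrow(ff$beads))
  ff
}

#' Trajectory with planted residue contacts
#'
#' Builds `n_chains` straight chains whose beads are spaced far beyond any
#' contact cutoff, then pins the listed bead pairs at the listed distances
#' in every frame.  All other inter-residue distances exceed
#' `2 * max(cutoffs)`.
#'
#' @param pairs data.frame with columns `chain_i`, `res_i`, `chain_j`,
#'   `res_j` (1-based chain and residue indices).
#' @param distances planted distances, A (recycled to `nrow(pairs)`).
#' @param n_frames frames to generate (identical geometry each frame).
#' @param n_chains,chain_length topology.
#' @param spacing intra-chain bead spacing, A (default 20).
#' @param box optional box lengths; default sized to hold the chain grid.
#' @return a [trajectory()] with the planted pairs in its manifest.
#' @export
make_planted_contact_traj <- function(pairs, distances, n_frames = 3,
                                      n_chains = 2, chain_length = 10,
                                      spacing = 20, box = NULL) {
  pairs <- as.data.frame(pairs)
  distances <- rep_len(distances, nrow(pairs))
  gap <- chain_length * spacing + 100
  if (is.null(box))
    box <- c(gap * n_chains + 200, 400, chain_length * spacing + 200)
  pos <- matrix(0, n_chains * chain_length, 3)
  for (c in seq_len(n_chains)) {
    idx <- (c - 1) * chain_length + seq_len(chain_length)
    pos[idx, 1] <- 100 + (c - 1) * gap
    pos[idx, 2] <- 100
    pos[idx, 3] <- 50 + spacing * (seq_len(chain_length) - 1)
  }
  bead <- function(ch, re) (ch - 1) * chain_length + re
  for (k in seq_len(nrow(pairs))) {
    bi <- bead(pairs$chain_i[k], pairs$res_i[k])
    bj <- bead(pairs$chain_j[k], pairs$res_j[k])
    # move bead j next to bead i, offset along y to stay clear of others
    pos[bj, ] <- pos[bi, ] + c(0, distances[k], 0)
  }
  chains <- cbind(start = (seq_len(n_chains) - 1) * chain_length + 1,
                  end = seq_len(n_chains) * chain_length)
  traj <- trajectory(replicate(n_frames, pos, simplify = FALSE),
                     times = seq_len(n_frames), box = box, chains = chains,
                     bead_codes = rep("G", n_chains * chain_length))
  attr(traj, "manifest") <- fixture_manifest(
    "make_planted_contact_traj",
    list(n_frames = n_frames, n_chains = n_chains,
         chain_length = chain_length, spacing = spacing),
    NA, list(pairs = pairs, distances = distances))
  traj
}

#' Frame with planted water coordination
#'
#' Residue beads are spread far apart; for each, exactly the requested
#' number of solvent particles is placed within `cutoff` of it (and beyond
#' `cutoff` of every other residue).  Distractor solvent is placed beyond
#' `2 * cutoff` of all residues.
#'
#' @param water_counts non-negative integer per residue.
#' @param cutoff coordination shell radius, A.
#' @param n_distractors solvent particles planted outside every shell.
#' @param spacing distance between residue beads, A.
#' @param seed integer seed.
#' @return a [system_configuration()] with a `"solvent"` attribute and the
#'   planted counts in its manifest.
#' @export
make_solvated_frame <- function(water_counts, cutoff = 5, n_distractors = 50,
                                spacing = 60, seed = 1L) {
  if (any(water_counts < 0)) stop("water counts must be non-negative")
  n <- length(water_counts)
  box <- c(spacing * (n + 1) + 100, 200, 200)
  set.seed(seed)
  respos <- cbind(spacing * seq_len(n) + 50, box[2] / 2, box[3] / 2)
  sol <- NULL
  for (i in seq_len(n)) {
    k <- water_counts[i]
    if (k > 0) {
      u <- matrix(stats::rnorm(3 * k), k, 3)
      u <- u / sqrt(rowSums(u^2))
      r <- cutoff * 0.9 * stats::runif(k)^(1 / 3)
      sol <- rbind(sol, sweep(u * r, 2, respos[i, ], "+"))
    }
  }
  if (n_distractors > 0) {
    far <- cbind(stats::runif(n_distractors, 0, box[1]),
                 stats::runif(n_distractors, box[2] / 2 + 2.5 * cutoff, box[2]),
                 stats::runif(n_distractors, 0, box[3]))
    sol <- rbind(sol, far)
  }
  cfg <- system_configuration(respos, box,
                              cbind(start = seq_len(n), end = seq_len(n)),
                              rep("S", n))
  attr(cfg, "solvent") <- sol
  attr(cfg, "manifest") <- fixture_manifest(
    "make_solvated_frame",
    list(cutoff = cutoff, n_distractors = n_distractors, spacing = spacing),
    seed, list(water_counts = water_counts))
  cfg
}

#' Synthetic FRAP trace with exponential recovery
#'
#' ROI series constructed so the normalized recovery is
#' `plateau * (1 - exp(-rate * t))` after the bleach (plus optional noise on
#' the bleached ROI), with prebleach frames at full intensity.
#'
#' @param plateau mobile fraction (recovery plateau).
#' @param rate recovery rate, 1/s.
#' @param noise_sd Gaussian noise SD on the normalized scale.
#' @param n_frames total frames.
#' @param n_prebleach prebleach frames.
#' @param dt frame interval, s.
#' @param seed integer seed.
#' @return a [frap_trace()] with ground truth in its manifest.
#' @export
make_frap_trace <- function(plateau = 0.6, rate = 0.1, noise_sd = 0,
                            n_frames = 100, n_prebleach = 5, dt = 1,
                            seed = 1L) {
  set.seed(seed)
  times <- (seq_len(n_frames) - 1) * dt
  tpost <- times - times[n_prebleach + 1]
  f <- ifelse(seq_len(n_frames) <= n_prebleach, 1,
              plateau * (1 - exp(-rate * tpost)))
  roi3 <- rep(10, n_frames)
  roi2 <- rep(110, n_frames)
  roi1 <- roi3 + (roi2 - roi3) * (f + stats::rnorm(n_frames, 0, noise_sd) *
                                    (seq_len(n_frames) > n_prebleach))
  tr <- frap_trace(times, roi1, roi2, roi3, bleach_index = n_prebleach + 1L)
  attr(tr, "manifest") <- fixture_manifest(
    "make_frap_trace",
    list(plateau = plateau, rate = rate, noise_sd = noise_sd,
         n_frames = n_frames, n_prebleach = n_prebleach, dt = dt),
    seed, list(plateau = plateau, rate = rate))
  tr
}

#' Synthetic droplet image of anti-aliased ellipses
#'
#' Renders filled ellipses with a smooth (half-pixel) edge on a constant
#' background, with optional Gaussian noise.  Ground truth includes each
#' ellipse's axes and expected roundness (minor/major).
#'
#' @param ellipses data.frame with columns `cx`, `cy`, `a` (semi-major, px),
#'   `b` (semi-minor, px), `angle` (radians).
#' @param dim image dimensions `c(nx, ny)`.
#' @param intensity,background foreground/background gray values.
#' @param noise_sd Gaussian noise SD.
#' @param seed integer seed.
#' @return numeric matrix with ground truth in its manifest.
#' @export
make_droplet_image <- function(ellipses, dim = c(256, 256), intensity = 1,
                               background = 0.05, noise_sd = 0, seed = 1L) {
  set.seed(seed)
  ellipses <- as.data.frame(ellipses)
  if (!"angle" %in% names(ellipses)) ellipses$angle <- 0
  img <- matrix(background, dim[1], dim[2])
  xs <- matrix(seq_len(dim[1]), dim[1], dim[2])
  ys <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  for (k in seq_len(nrow(ellipses))) {
    e <- ellipses[k, ]
    dx <- xs - e$cx; dy <- ys - e$cy
    xr <- dx * cos(e$angle) + dy * sin(e$angle)
    yr <- -dx * sin(e$angle) + dy * cos(e$angle)
    d <- sqrt((xr / e$a)^2 + (yr / e$b)^2)
    # smooth edge ~half a pixel wide at the ellipse boundary
    edge <- 0.5 / min(e$a, e$b)
    cov <- pmin(1, pmax(0, (1 + edge - d) / (2 * edge)))
    img <- pmax(img, background + (intensity - background) * cov)
  }
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(prod(dim), 0, noise_sd),
                                        dim[1], dim[2])
  gt <- data.frame(cx = ellipses$cx, cy = ellipses$cy, a = ellipses$a,
                   b = ellipses$b, area = pi * ellipses$a * ellipses$b,
                   roundness = ellipses$b / ellipses$a)
  attr(img, "manifest") <- fixture_manifest(
    "make_droplet_image",
    list(dim = dim, intensity = intensity, background = background,
         noise_sd = noise_sd),
    seed, list(ellipses = gt))
  img
}

#' Random low-complexity-like sequence
#'
#' Draws a sequence from a residue composition, either multinomially or with
#' exact counts (`exact = TRUE` permutes a vector with the rounded target
#' counts).
#'
#' @param length sequence length.
#' @param composition named numeric vector of residue weights (codes from
#'   the package alphabet); default mimics a G/S/N/Q-rich LCD.
#' @param seed integer seed.
#' @param exact enforce exact rounded counts.
#' @return a [protein_sequence()].
#' @export
make_random_lcd <- function(length = 154,
                            composition = c(G = 0.3, S = 0.2, N = 0.15,
                                            Q = 0.15, A = 0.1, F = 0.05,
                                            R = 0.05),
                            seed = 1L, exact = FALSE) {
  if (is.null(names(composition)) ||
      !all(names(composition) %in% c(AA_CODES, SEP_CODE)))
    stop("composition must be named with valid residue codes")
  set.seed(seed)
  p <- composition / sum(composition)
  res <- if (exact) {
    counts <- floor(p * length)
    rem <- length - sum(counts)
    if (rem > 0) {
      extra <- order(p * length - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    sample(rep(names(p), counts))
  } else {
    sample(names(p), length, replace = TRUE, prob = p)
  }
  ps <- protein_sequence(res, id = sprintf("random_lcd_seed%d", seed))
  attr(ps, "manifest") <- fixture_manifest(
    "make_random_lcd", list(length = length, composition = as.list(p),
                            exact = exact),
    seed, list(counts = as.list(table(res))))
  ps
}
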