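# Langevin dynamics driver and the slab coexistence protocol: compact
# equilibration in a small sub-volume, box extension along z, production.

#' Grow chains in a compact sub-volume
#'
#' Chains are grown as self-avoiding random walks with all bonds at the
#' equilibrium length `bond_r0`.  No two non-bonded beads come closer than
#' `0.8 * min(sigma)` (periodic minimum image in the sub-box).  Growth is
#' retried a bounded number of times; an impossible density request errors
#' rather than hanging.
#'
#' @param n_chains number of chains.
#' @param seq a [protein_sequence()]; all chains share it.
#' @param ff an [hps_forcefield()] (supplies bond length and bead sizes).
#' @param sub_box lengths of the compact periodic box, A.
#' @param seed integer seed.
#' @param max_restarts growth restarts allowed per chain.
#' @return a [system_configuration()] with `box = sub_box`.
#' @export
initialize_compact <- function(n_chains, seq, ff, sub_box, seed = 1L,
                               max_restarts = 60L) {
  stopifnot(inherits(seq, "protein_sequence"), inherits(ff, "hps_forcefield"))
  sub_box <- as.numeric(sub_box)
  L <- length(seq$residues)
  r0 <- ff$bond_r0
  dmin <- 0.8 * min(ff$beads$sigma[ff_index(ff, unique(seq$residues))])
  dmin2 <- dmin^2
  set.seed(seed)
  placed <- matrix(NA_real_, n_chains * L, 3)
  nplaced <- 0L
  clash <- function(p, skip_last = FALSE) {
    upto <- nplaced - if (skip_last) 1L else 0L
    if (upto == 0L) return(FALSE)
    d <- sweep(placed[seq_len(upto), , drop = FALSE], 2, p)
    d <- d - sweep(round(sweep(d, 2, sub_box, "/")), 2, sub_box, "*")
    any(rowSums(d^2) < dmin2)
  }
  for (ch in seq_len(n_chains)) {
    done <- FALSE
    for (restart in seq_len(max_restarts)) {
      base <- nplaced
      p <- stats::runif(3) * sub_box
      if (clash(p)) next
      nplaced <- nplaced + 1L; placed[nplaced, ] <- p
      ok <- TRUE
      for (k in seq_len(L - 1L)) {
        hit <- FALSE
        for (try in 1:60) {
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          q <- (placed[nplaced, ] + r0 * u) %% sub_box
          if (!clash(q, skip_last = TRUE)) { hit <- TRUE; break }
        }
        if (!hit) { ok <- FALSE; break }
        nplaced <- nplaced + 1L; placed[nplaced, ] <- q
      }
      if (ok) { done <- TRUE; break }
      nplaced <- base  # discard partial chain, retry
    }
    if (!done)
      stop(sprintf("failed to place chain %d after %d restarts: sub-box too dense",
                   ch, max_restarts))
  }
  config_from_chains(
    lapply(seq_len(n_chains), function(k) placed[((k - 1) * L + 1):(k * L), ]),
    seq, sub_box)
}

#' Simulation schedule
#'
#' @param timestep integration step, fs.
#' @param temperature target temperature, K.
#' @param friction Langevin friction, 1/ps.  The default 0.01/ps is weakly
#'   coupled, which accelerates configurational sampling in implicit solvent.
#' @param seed integer seed; recorded in the trajectory provenance, and used
#'   (with a per-phase stream offset) for all stochastic forces.
#' @param phases list of phases, each `list(label, n_steps, box_z = NULL)`;
#'   a non-NULL `box_z` extends the box along z (slab extension) before the
#'   phase runs.
#' @param stride save every `stride` steps.
#' @return an object of class `simulation_schedule`.
#' @export
simulation_schedule <- function(timestep = 10, temperature = 310,
                                friction = 0.01, seed = 1L,
                                phases = list(list(label = "production",
                                                   n_steps = 10000L,
                                                   box_z = NULL)),
                                stride = 1000L) {
  if (timestep <= 0) stop("timestep must be positive")
  for (p in phases) if (p$n_steps < 0) stop("n_steps must be >= 0")
  structure(list(timestep = timestep, temperature = temperature,
                 friction = friction, seed = as.integer(seed),
                 phases = phases, stride = as.integer(stride)),
            class = "simulation_schedule")
}

#' Slab protocol presets
#'
#' `"full"` is the full-scale protocol (100 chains, 212 x 212 x 2800 A, at
#' least 5.8 us production) and is cluster-scale; `"desk"` is a reduced single-
#' workstation protocol (50 chains, 160 x 160 x 1200 A, 2e6 production
#' steps); `"mini"` is a minutes-scale smoke protocol used by the package's
#' own test suite (10 chains, 110 x 110 x 700 A, with shortened runs).
#'
#' @param name one of `"mini"`, `"desk"`, `"full"`.
#' @param seed integer seed.
#' @return list with components `n_chains`, `sub_box`, `box_z`, `schedule`.
#' @export
schedule_preset <- function(name = c("mini", "desk", "full"), seed = 1L) {
  name <- match.arg(name)
  par <- switch(name,
    mini = list(n_chains = 10L, sub_box = c(110, 110, 160), box_z = 700,
                equil = 10000L, prod = 150000L, stride = 2500L),
    desk = list(n_chains = 50L, sub_box = c(160, 160, 300), box_z = 1200,
                equil = 500000L, prod = 2000000L, stride = 10000L),
    full = list(n_chains = 100L, sub_box = c(212, 212, 400), box_z = 2800,
                equil = 500000L, prod = 580000000L, stride = 100000L))
  list(n_chains = par$n_chains, sub_box = par$sub_box, box_z = par$box_z,
       preset = name,
       schedule = simulation_schedule(
         seed = seed, stride = par$stride,
         phases = list(
           list(label = "equilibration", n_steps = par$equil, box_z = NULL),
           list(label = "production", n_steps = par$prod, box_z = par$box_z))))
}

#' Run Langevin dynamics under a schedule
#'
#' BAOAB-split Langevin integration at constant volume.  Phases run
#' sequentially, carrying positions and velocities over; a phase with a
#' `box_z` entry first applies [extend_to_slab()].  Identical inputs and
#' seed give bit-identical trajectories on the same platform.
#'
#' @param config a [system_configuration()].
#' @param ff an [hps_forcefield()].
#' @param schedule a [simulation_schedule()].
#' @return a [trajectory()]; per-frame instantaneous temperatures are stored
#'   in `provenance$temperatures` and phase labels in `$phase`.
#' @export
run_langevin <- function(config, ff, schedule) {
  stopifnot(inherits(schedule, "simulation_schedule"))
  check_box_cutoffs(config, ff)
  p <- ff_pack(config, ff)
  bonds0 <- config_bonds0(config)
  dt_ps <- schedule$timestep / 1000
  frames <- list(); times <- numeric(0); temps <- numeric(0)
  boxes <- NULL; phase_lab <- character(0)
  vel <- NULL
  t0 <- 0
  cfg <- config
  for (iph in seq_along(schedule$phases)) {
    ph <- schedule$phases[[iph]]
    if (!is.null(ph$box_z)) cfg <- extend_to_slab(cfg, ph$box_z)
    if (ph$n_steps == 0L) next
    res <- cpp_langevin(cfg$positions, cfg$box, p$type0, bonds0, p$params,
                        as.integer(ph$n_steps), dt_ps,
                        schedule$temperature, schedule$friction,
                        schedule$stride,
                        seed = schedule$seed * 1000 + iph, vel0 = vel)
    vel <- res$velocities
    cfg$positions <- res$positions
    nf <- length(res$times)
    if (nf > 0) {
      for (k in seq_len(nf))
        frames[[length(frames) + 1L]] <- matrix(res$frames[, , k], ncol = 3)
      times <- c(times, t0 + res$times)
      temps <- c(temps, res$temperatures)
      boxes <- rbind(boxes, matrix(cfg$box, nf, 3, byrow = TRUE))
      phase_lab <- c(phase_lab, rep(ph$label, nf))
    }
    t0 <- t0 + ph$n_steps * dt_ps
  }
  if (!length(frames)) { # n_steps = 0 everywhere: keep the initial frame
    frames <- list(cfg$positions); times <- 0; temps <- NA_real_
    boxes <- matrix(cfg$box, 1, 3); phase_lab <- "initial"
  }
  trajectory(frames, times, boxes, cfg$chains, cfg$bead_codes,
             phase = phase_lab,
             provenance = list(schedule = unclass(schedule),
                               temperatures = temps,
                               forcefield_hash = ff_hash(ff)))
}

#' Extend the box along z for slab coexistence
#'
#' The condensate is recentered: coordinates are unwrapped relative to the
#' periodic (circular-mean) center of mass along z, shifted so the center
#' sits at `new_Lz / 2`, and the box z-length is replaced.  Relative
#' positions are unchanged.  Applying the operation twice with the same
#' target is idempotent.
#'
#' @param config a [system_configuration()].
#' @param new_Lz new z box length, A; must exceed the current one.
#' @return the extended [system_configuration()].
#' @export
extend_to_slab <- function(config, new_Lz) {
  Lz <- config$box[3]
  if (new_Lz < Lz) stop("new_Lz smaller than current box z-length")
  z <- config$positions[, 3] %% Lz
  # unwrap each chain contiguously along z so no bond spans the boundary
  for (k in seq_len(nrow(config$chains))) {
    idx <- config$chains[k, 1]:config$chains[k, 2]
    if (length(idx) > 1) {
      dz <- diff(z[idx])
      dz <- dz - Lz * round(dz / Lz)
      z[idx] <- z[idx[1]] + c(0, cumsum(dz))
    }
  }
  # periodic center of the condensate: circular mean, refined by one
  # arithmetic pass so a non-spanning cluster centers on its exact mean
  # (making the operation idempotent)
  theta <- 2 * pi * (z %% Lz) / Lz
  center <- (atan2(mean(sin(theta)), mean(cos(theta))) / (2 * pi) * Lz) %% Lz
  zc <- ((z - center + Lz / 2) %% Lz) - Lz / 2
  center <- center + mean(zc)
  # move whole chains by box periods so their centers lie around `center`
  for (k in seq_len(nrow(config$chains))) {
    idx <- config$chains[k, 1]:config$chains[k, 2]
    com <- mean(z[idx])
    z[idx] <- z[idx] - Lz * round((com - center) / Lz)
  }
  out <- config
  out$positions[, 3] <- new_Lz / 2 + (z - center)
  out$box[3] <- new_Lz
  out
}

# Content hash of the force field (temp-file md5; used in run manifests).
ff_hash <- function(ff) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(lapply(unclass(ff), function(x) if (is.numeric(x)) signif(x, 12) else x),
       file = f)
  unname(tools::md5sum(f))
}
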