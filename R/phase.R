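# Slab coexistence analysis: z density profiles, dense/dilute phase
# concentrations, transfer free energy, condensate detection and variant
# ranking.

DA_PER_A3_TO_MG_ML <- 1660.53907  # (Da / A^3) -> mg/mL

#' z-density profile of a slab trajectory
#'
#' Per frame, bead masses are binned along z; each frame's profile is
#' recentered so that the densest sliding window (periodic wrap) sits at the
#' box midpoint, then frames are averaged.  Concentrations are in mg/mL, so
#' the profile integrates to the total protein mass per frame.
#'
#' @param traj a [trajectory()].
#' @param ff an [hps_forcefield()] supplying bead masses.
#' @param n_bins number of z bins (>= 10).
#' @param discard_fraction fraction of initial frames discarded as
#'   equilibration (applied after any phase filter).
#' @param centering `"window"` recenters on the densest 100-A sliding
#'   window; `"none"` averages raw profiles.
#' @param window_width sliding window width, A.
#' @param phases optional phase labels to keep (e.g. `"production"`).
#' @return object of class `density_profile`: data.frame with `z` (bin
#'   centers, A) and `concentration` (mg/mL), with the box, bin volume and
#'   frame count as attributes.
#' @export
density_profile <- function(traj, ff, n_bins = 120, discard_fraction = 0.5,
                            centering = c("window", "none"),
                            window_width = 100, phases = NULL) {
  centering <- match.arg(centering)
  if (n_bins < 10) stop("n_bins must be >= 10")
  keep <- seq_len(n_frames(traj))
  if (!is.null(phases) && !is.null(traj$phase))
    keep <- keep[traj$phase %in% phases]
  if (discard_fraction > 0) {
    ndrop <- floor(length(keep) * discard_fraction)
    keep <- if (ndrop < length(keep)) keep[(ndrop + 1):length(keep)] else integer(0)
  }
  if (!length(keep)) stop("no frames left after discard")
  Lz <- traj$box[keep[1], 3]
  if (any(abs(traj$box[keep, 3] - Lz) > 1e-9))
    stop("frames mix different box z-lengths; filter by phase first")
  area <- traj$box[keep[1], 1] * traj$box[keep[1], 2]
  masses <- ff$beads$mass[ff_index(ff, traj$bead_codes)]
  edges <- seq(0, Lz, length.out = n_bins + 1)
  binw <- Lz / n_bins
  wbins <- max(1L, round(window_width / binw))
  acc <- numeric(n_bins)
  for (i in keep) {
    z <- traj$frames[, 3, i] %% Lz
    idx <- pmin(n_bins, floor(z / binw) + 1L)
    m <- numeric(n_bins)
    rs <- rowsum(masses, idx)
    m[as.integer(rownames(rs))] <- rs
    if (centering == "window") {
      # coarse: densest sliding window (argmax ties resolve arbitrarily on
      # a flat-topped slab, so refine afterwards)
      csum <- cumsum(c(m, m))
      wsum <- csum[(wbins):(wbins + n_bins - 1)] -
              c(0, csum[seq_len(n_bins - 1)])
      cen <- (which.max(wsum) + (wbins - 1) / 2 - 1) %% n_bins
      shift <- round(n_bins / 2 - cen)
      m <- m[((seq_len(n_bins) - 1 - shift) %% n_bins) + 1]
      # refine: mass-weighted mean offset from the midpoint (the uniform
      # dilute background averages out; the slab pulls the center onto its
      # true midline)
      if (sum(m) > 0) {
        rel <- seq_len(n_bins) - (n_bins / 2 + 0.5)
        shift2 <- round(sum(m * rel) / sum(m))
        if (shift2 != 0) m <- m[((seq_len(n_bins) - 1 + shift2) %% n_bins) + 1]
      }
    }
    acc <- acc + m
  }
  conc <- acc / length(keep) / (area * binw) * DA_PER_A3_TO_MG_ML
  out <- data.frame(z = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                    concentration = conc)
  structure(out, class = c("density_profile", "data.frame"),
            box = traj$box[keep[1], ], n_frames = length(keep),
            bin_volume = area * binw, centering = centering,
            total_mass = sum(masses))
}

#' @export
plot.density_profile <- function(x, ...) {
  graphics::plot(x$z, x$concentration, type = "l", xlab = "z (Å)",
                 ylab = "concentration (mg/mL)", ...)
  invisible(x)
}

#' Coexisting dense and dilute concentrations
#'
#' On a centered profile, `c_dense` is the mean concentration within
#' `dense_halfwidth` of the slab center and `c_dilute` the mean at least
#' `dilute_margin` away from it.
#'
#' @param profile a [density_profile()].
#' @param dense_halfwidth half-width of the dense window, A.
#' @param dilute_margin minimum distance from the slab center for the dilute
#'   window, A; must exceed `dense_halfwidth`.
#' @return list with `c_dense` and `c_dilute` (mg/mL).
#' @export
phase_concentrations <- function(profile, dense_halfwidth = 50,
                                 dilute_margin = 250) {
  if (dense_halfwidth >= dilute_margin)
    stop("dense window overlaps dilute window (dense_halfwidth >= dilute_margin)")
  zmid <- attr(profile, "box")[3] / 2
  dz <- abs(profile$z - zmid)
  dense <- dz <= dense_halfwidth
  dilute <- dz >= dilute_margin
  if (!any(dense)) stop("dense window contains no bins")
  if (!any(dilute)) stop("dilute window contains no bins (margin too large)")
  list(c_dense = mean(profile$concentration[dense]),
       c_dilute = mean(profile$concentration[dilute]))
}

#' Excess free energy of transfer between coexisting phases
#'
#' \eqn{\Delta G_{trans} = -RT \ln(c_{dense}/c_{dilute})}: the free energy
#' of moving one chain from the dilute solution at saturation into the dense
#' condensed phase.  Negative when the dense phase is favored.
#'
#' @param c_dense,c_dilute coexisting concentrations (any common unit); both
#'   must be positive.
#' @param temperature K.
#' @return kJ/mol.
#' @examples
#' delta_g_trans(exp(1), 1, 310)  # -RT = -2.577 kJ/mol
#' @export
delta_g_trans <- function(c_dense, c_dilute, temperature = 310) {
  if (c_dense <= 0 || c_dilute <= 0)
    stop("concentrations must be positive for a defined transfer free energy")
  -KB_KJ * temperature * log(c_dense / c_dilute)
}

#' Is there a condensate?
#'
#' A profile is flagged as containing a condensate when its maximum bin
#' concentration is at least `peak_ratio_threshold` times the dilute-region
#' mean.  A profile with an empty dilute region but nonzero peak counts as
#' condensed.
#'
#' @param profile a [density_profile()].
#' @param peak_ratio_threshold peak-to-dilute ratio defining a "clear peak".
#' @param dilute_margin distance from the center defining the dilute region.
#' @return logical flag.
#' @export
detect_condensate <- function(profile, peak_ratio_threshold = 10,
                              dilute_margin = 250) {
  zmid <- attr(profile, "box")[3] / 2
  dilute <- abs(profile$z - zmid) >= dilute_margin
  peak <- max(profile$concentration)
  dil <- mean(profile$concentration[dilute])
  if (!is.finite(dil) || dil <= 0) return(peak > 0)
  peak >= peak_ratio_threshold * dil
}

#' Rank variants by saturation concentration
#'
#' Orders variants by ascending dilute-phase concentration (stronger
#' condensation first); variants without a condensate are ranked last.
#' Variants whose `c_dilute` differ by at most `tol` (relative) are reported
#' as tied.
#'
#' @param metrics named list: for each variant a list with at least
#'   `c_dilute` and `has_condensate`.
#' @param tol relative tie tolerance on `c_dilute`.
#' @return data.frame with columns `name`, `c_dilute`, `has_condensate`,
#'   `rank` (ties share a rank).
#' @export
rank_variants <- function(metrics, tol = 0.25) {
  if (length(metrics) < 2) stop("need at least two variants to rank")
  nms <- names(metrics)
  if (anyDuplicated(nms)) stop("duplicate variant names")
  cd <- vapply(metrics, function(m) as.numeric(m$c_dilute), 0)
  hc <- vapply(metrics, function(m) isTRUE(m$has_condensate), TRUE)
  key <- ifelse(hc, cd, Inf)
  ord <- order(key)  # stable
  out <- data.frame(name = nms[ord], c_dilute = cd[ord],
                    has_condensate = hc[ord])
  rank <- integer(nrow(out))
  r <- 1L
  for (i in seq_len(nrow(out))) {
    if (i > 1) {
      a <- out$c_dilute[i - 1]; b <- out$c_dilute[i]
      tied <- out$has_condensate[i] == out$has_condensate[i - 1] &&
        (!out$has_condensate[i] ||
           abs(b - a) <= tol * max(abs(a), abs(b), .Machine$double.eps))
      if (!tied) r <- i
    }
    rank[i] <- r
  }
  out$rank <- rank
  rownames(out) <- NULL
  out
}
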