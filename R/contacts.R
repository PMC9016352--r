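# Residue contact maps, difference maps, amino-acid-type-resolved contact
# profiles and solvation histograms.

#' Contact rule
#'
#' Two residues are in contact when their beads are closer than a fixed
#' cutoff (`fixed_cutoff`, default 4.5 A, the Martini-style rule) or than
#' \eqn{2^{1/6}\sigma_{ij}} (`sigma_cutoff`, the HPS analysis rule; needs a
#' force field for the bead diameters).  Comparisons are strict (`<`).
#'
#' @param rule `"fixed_cutoff"` or `"sigma_cutoff"`.
#' @param cutoff distance, A (fixed rule only).
#' @return list describing the rule.
#' @export
contact_rule <- function(rule = c("fixed_cutoff", "sigma_cutoff"),
                         cutoff = 4.5) {
  rule <- match.arg(rule)
  list(rule = rule, cutoff = cutoff)
}

# Bead-level contact pairs of one frame under a rule (1-based indices).
frame_contacts <- function(pos, box, rule, sigma = NULL) {
  if (rule$rule == "sigma_cutoff") {
    if (is.null(sigma)) stop("sigma_cutoff rule requires a force field")
    cpp_contact_pairs(pos, box, 0, sigma)
  } else {
    cpp_contact_pairs(pos, box, rule$cutoff, numeric(0))
  }
}

#' Residue contact probability map
#'
#' All chains must share one sequence of length L.  For each frame, an
#' inter-chain contact event for residue pair (i, j) is recorded for an
#' unordered chain pair when residue i of one chain and residue j of the
#' other are within the rule's distance; the probability is the event count
#' divided by frames x chain pairs.  Intra-chain events (same convention,
#' denominator frames x chains) are tallied separately; pairs with sequence
#' separation `|i - j| <= exclusion` are excluded from the intra-chain tally
#' and flagged absent (NA) on the near-diagonal of the combined map.
#'
#' @param traj a [trajectory()].
#' @param rule a [contact_rule()].
#' @param exclusion intra-chain sequence-separation exclusion (default 2,
#'   i.e. residues i+-1, i+-2 never count).
#' @param chain_mode `"inter"`, `"intra"` or `"both"` (opportunity-weighted
#'   combination).
#' @param ff force field (required for the sigma rule).
#' @param offset full-length number of the first residue, for labelling.
#' @return object of class `contact_map`: an L x L symmetric matrix of
#'   probabilities with near-diagonal NA entries, with the rule, exclusion
#'   and counts as attributes.
#' @export
contact_map <- function(traj, rule = contact_rule(), exclusion = 2L,
                        chain_mode = c("both", "inter", "intra"), ff = NULL,
                        offset = 1L) {
  chain_mode <- match.arg(chain_mode)
  exclusion <- as.integer(exclusion)
  if (exclusion < 0) stop("exclusion must be >= 0")
  lens <- traj$chains[, 2] - traj$chains[, 1] + 1L
  L <- lens[1]
  if (any(lens != L)) stop("heterogeneous chain lengths")
  C <- nrow(traj$chains)
  sigma <- if (!is.null(ff))
    ff$beads$sigma[ff_index(ff, traj$bead_codes)] else NULL
  chain_of <- rep(seq_len(C), each = L)
  res_of <- rep(seq_len(L), C)
  nf <- n_frames(traj)
  inter <- matrix(0, L, L)
  intra <- matrix(0, L, L)
  for (f in seq_len(nf)) {
    pr <- frame_contacts(traj$frames[, , f], traj$box[f, ], rule, sigma)
    if (!nrow(pr)) next
    ci <- chain_of[pr[, 1]]; cj <- chain_of[pr[, 2]]
    ri <- res_of[pr[, 1]]; rj <- res_of[pr[, 2]]
    same <- ci == cj
    if (any(!same)) {
      # one event per unordered chain pair per residue pair per frame
      key <- paste(pmin(ci, cj)[!same], pmax(ci, cj)[!same],
                   pmin(ri, rj)[!same], pmax(ri, rj)[!same])
      uq <- !duplicated(key)
      a <- pmin(ri, rj)[!same][uq]; b <- pmax(ri, rj)[!same][uq]
      for (k in seq_along(a)) {
        inter[a[k], b[k]] <- inter[a[k], b[k]] + 1
        if (a[k] != b[k]) inter[b[k], a[k]] <- inter[b[k], a[k]] + 1
      }
    }
    if (any(same)) {
      sep <- abs(ri - rj)[same]
      keep <- sep > exclusion
      a <- pmin(ri, rj)[same][keep]; b <- pmax(ri, rj)[same][keep]
      for (k in seq_along(a)) {
        intra[a[k], b[k]] <- intra[a[k], b[k]] + 1
        if (a[k] != b[k]) intra[b[k], a[k]] <- intra[b[k], a[k]] + 1
      }
    }
  }
  n_inter_opp <- nf * C * (C - 1) / 2
  n_intra_opp <- nf * C
  P <- switch(chain_mode,
    inter = if (n_inter_opp > 0) inter / n_inter_opp else inter * 0,
    intra = intra / n_intra_opp,
    both = (inter + intra) / max(1, n_inter_opp + n_intra_opp))
  mask <- abs(row(P) - col(P)) <= exclusion
  if (chain_mode != "inter") P[mask] <- NA_real_
  dimnames(P) <- list(seq_len(L) + offset - 1L, seq_len(L) + offset - 1L)
  structure(P, class = c("contact_map", "matrix"),
            rule = rule, exclusion = exclusion, chain_mode = chain_mode,
            n_frames = nf, n_chains = C)
}

#' Difference of two contact maps
#'
#' Entrywise `map_a - map_b` (e.g. Wt minus a phosphomimetic variant);
#' absent (NA) entries stay absent.  Maps must share shape, rule and
#' exclusion.
#'
#' @param map_a,map_b [contact_map()] objects.
#' @return a `contact_map`-shaped matrix of probability differences.
#' @export
contact_difference <- function(map_a, map_b) {
  if (!identical(dim(map_a), dim(map_b)))
    stop("contact maps have different shapes")
  ra <- attr(map_a, "rule"); rb <- attr(map_b, "rule")
  if (!identical(ra, rb) ||
      !identical(attr(map_a, "exclusion"), attr(map_b, "exclusion")))
    stop("contact maps were computed under different rules")
  d <- unclass(map_a) - unclass(map_b)
  structure(d, class = c("contact_map", "matrix"), rule = ra,
            exclusion = attr(map_a, "exclusion"), difference = TRUE)
}

#' Write a contact map as CSV with a header recording the rule
#' @param map a [contact_map()].
#' @param path output path.
#' @export
write_contact_map <- function(map, path) {
  r <- attr(map, "rule")
  hdr <- sprintf("# contact map: rule=%s cutoff=%s exclusion=%d",
                 r$rule, format(r$cutoff), attr(map, "exclusion"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(unclass(map)), con, row.names = TRUE)
  invisible(path)
}

#' Contacts of selected residues resolved by partner amino-acid type
#'
#' Counts contact events from the selected source residues (full-length
#' numbering) to partner residues across all chains, tallied by the
#' partner's amino-acid type and normalized to sum to one.  Intra-chain
#' partners within the exclusion separation are ignored.
#'
#' @param traj a [trajectory()].
#' @param source_sites full-length residue numbers of the source selection.
#' @param rule a [contact_rule()].
#' @param ff force field (sigma rule only).
#' @param exclusion intra-chain sequence-separation exclusion.
#' @param offset full-length number of the first residue in each chain.
#' @return object of class `type_contact_profile`: named numeric vector of
#'   probabilities summing to 1 (or all zero, with attribute
#'   `no_contacts = TRUE`, when no contact exists).
#' @export
type_resolved_contacts <- function(traj, source_sites, rule = contact_rule(),
                                   ff = NULL, exclusion = 2L, offset = 1L) {
  if (!length(source_sites)) stop("empty source selection")
  lens <- traj$chains[, 2] - traj$chains[, 1] + 1L
  L <- lens[1]
  if (any(lens != L)) stop("heterogeneous chain lengths")
  C <- nrow(traj$chains)
  local <- source_sites - offset + 1L
  if (any(local < 1 | local > L)) stop("source site(s) outside the sequence")
  sigma <- if (!is.null(ff))
    ff$beads$sigma[ff_index(ff, traj$bead_codes)] else NULL
  chain_of <- rep(seq_len(C), each = L)
  res_of <- rep(seq_len(L), C)
  is_src <- res_of %in% local
  counts <- stats::setNames(numeric(length(AA_CODES) + 1),
                            c(AA_CODES, SEP_CODE))
  for (f in seq_len(n_frames(traj))) {
    pr <- frame_contacts(traj$frames[, , f], traj$box[f, ], rule, sigma)
    if (!nrow(pr)) next
    for (col in 1:2) {
      src <- pr[, col]; prt <- pr[, 3 - col]
      keep <- is_src[src] &
        !(chain_of[src] == chain_of[prt] &
            abs(res_of[src] - res_of[prt]) <= exclusion)
      if (any(keep)) {
        tab <- table(traj$bead_codes[prt[keep]])
        counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
      }
    }
  }
  tot <- sum(counts)
  out <- if (tot > 0) counts / tot else counts
  structure(out, class = "type_contact_profile", n_events = tot,
            no_contacts = tot == 0)
}

#' Histogram of solvent particles near a residue selection
#'
#' For every selected residue in every frame, counts the solvent particles
#' within `cutoff` (periodic minimum image) and histograms the counts.
#' Frames must carry solvent coordinates (see [trajectory()]'s `solvent`
#' field, produced e.g. by [make_solvated_frame()]).
#'
#' @param traj a [trajectory()] with solvent, or a single
#'   [system_configuration()] with a `"solvent"` attribute.
#' @param selection bead indices of the selected residues.
#' @param cutoff distance, A (default 5, the water-coordination shell).
#' @return object of class `solvation_histogram`: data.frame with `count`
#'   and `frequency` (summing to 1).
#' @export
solvation_histogram <- function(traj, selection, cutoff = 5) {
  if (cutoff < 0) stop("cutoff must be non-negative")
  frames <- if (inherits(traj, "cg_trajectory")) {
    if (is.null(traj$solvent)) stop("trajectory carries no solvent particles")
    lapply(seq_len(n_frames(traj)), function(i)
      list(pos = traj$frames[, , i], sol = traj$solvent[[i]],
           box = traj$box[i, ]))
  } else {
    sol <- attr(traj, "solvent")
    if (is.null(sol)) stop("configuration carries no solvent particles")
    list(list(pos = traj$positions, sol = sol, box = traj$box))
  }
  counts <- integer(0)
  for (fr in frames) {
    if (is.null(fr$sol) || nrow(fr$sol) == 0)
      stop("frame carries no solvent particles")
    for (b in selection) {
      d <- sweep(fr$sol, 2, fr$pos[b, ])
      d <- d - sweep(round(sweep(d, 2, fr$box, "/")), 2, fr$box, "*")
      counts <- c(counts, sum(rowSums(d^2) < cutoff^2))
    }
  }
  tab <- table(factor(counts, levels = 0:max(counts, 0)))
  out <- data.frame(count = as.integer(names(tab)),
                    frequency = as.numeric(tab) / length(counts))
  structure(out, class = c("solvation_histogram", "data.frame"),
            cutoff = cutoff, n_observations = length(counts))
}
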