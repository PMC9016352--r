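# Trajectories: ordered frames of a fixed topology, with extended-XYZ and
# PDB input/output.

#' Trajectory of configurations
#'
#' Frames share one topology (chains, bead codes); each frame has a box and
#' a time.  Frames are stored as an `n_beads x 3 x n_frames` array.
#'
#' @param frames `n x 3 x f` array (or list of `n x 3` matrices) of positions.
#' @param times strictly increasing frame times, ps.
#' @param box either one length-3 vector shared by all frames, or an `f x 3`
#'   matrix of per-frame boxes.
#' @param chains,bead_codes topology, as in [system_configuration()].
#' @param phase optional character vector labelling each frame's protocol
#'   phase (e.g. "equilibration", "production").
#' @param solvent optional list of per-frame solvent coordinate matrices
#'   (used by solvation analysis of synthetic fixtures or external data).
#' @param provenance free-form list recorded with the trajectory.
#' @return an object of class `cg_trajectory`.
#' @export
trajectory <- function(frames, times, box, chains, bead_codes,
                       phase = NULL, solvent = NULL, provenance = list()) {
  if (is.list(frames)) frames <- simplify2array(frames)
  if (length(dim(frames)) == 2) frames <- array(frames, c(dim(frames), 1))
  nf <- dim(frames)[3]
  times <- as.numeric(times)
  if (length(times) != nf) stop("one time per frame required")
  if (nf > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) != nf) stop("one box per frame required")
  if (!is.null(phase) && length(phase) != nf)
    stop("one phase label per frame required")
  structure(list(frames = frames, times = times, box = box,
                 chains = as.matrix(chains), bead_codes = bead_codes,
                 phase = phase, solvent = solvent, provenance = provenance),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d frames x %d beads (%d chains), %.1f-%.1f ps\n",
              n_frames(x), dim(x$frames)[1], nrow(x$chains),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' Extract one frame as a configuration
#' @param traj a [trajectory()].
#' @param i frame index.
#' @return a [system_configuration()]; any solvent coordinates are attached
#'   as attribute `"solvent"`.
#' @export
get_frame <- function(traj, i) {
  cfg <- system_configuration(traj$frames[, , i], traj$box[i, ],
                              traj$chains, traj$bead_codes)
  if (!is.null(traj$solvent)) attr(cfg, "solvent") <- traj$solvent[[i]]
  cfg
}

#' Write a trajectory as extended XYZ
#'
#' One block per frame: bead count, a comment line carrying
#' `Lattice="Lx 0 0 0 Ly 0 0 0 Lz"`, `Time=<ps>` and the column layout, then
#' per-bead lines `code x y z chain`.  Solvent particles, if present, are
#' appended with code `W` and chain 0.
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  chain_of <- integer(dim(traj$frames)[1])
  for (k in seq_len(nrow(traj$chains)))
    chain_of[traj$chains[k, 1]:traj$chains[k, 2]] <- k
  for (i in seq_len(n_frames(traj))) {
    pos <- traj$frames[, , i]
    sol <- if (!is.null(traj$solvent)) traj$solvent[[i]] else NULL
    ntot <- nrow(pos) + if (is.null(sol)) 0L else nrow(sol)
    b <- traj$box[i, ]
    writeLines(as.character(ntot), con)
    writeLines(sprintf(
      'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3:chain:I:1 Time=%g',
      b[1], b[2], b[3], traj$times[i]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f %d", traj$bead_codes,
                       pos[, 1], pos[, 2], pos[, 3], chain_of), con)
    if (!is.null(sol) && nrow(sol))
      writeLines(sprintf("W %.6f %.6f %.6f 0", sol[, 1], sol[, 2], sol[, 3]),
                 con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory written by [write_xyz()]
#'
#' Lines with species `W` and chain 0 are collected as solvent.
#'
#' @param path file to read.
#' @return a [trajectory()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list(); times <- numeric(0); boxes <- NULL
  solvent <- list(); codes <- NULL; chain_of <- NULL
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- lines[i + 1L]
    lat <- regmatches(hdr, regexpr('Lattice="[^"]*"', hdr))
    nums <- as.numeric(strsplit(sub('Lattice="', '', sub('"$', '', lat)),
                                "\\s+")[[1]])
    box <- nums[c(1, 5, 9)]
    tm <- as.numeric(sub(".*Time=([-0-9.eE+]+).*", "\\1", hdr))
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    sp <- vapply(parts, `[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    ch <- as.integer(vapply(parts, `[`, "", 5L))
    issol <- sp == "W" & ch == 0L
    frames[[length(frames) + 1L]] <- xyz[!issol, , drop = FALSE]
    solvent[[length(solvent) + 1L]] <- xyz[issol, , drop = FALSE]
    if (is.null(codes)) { codes <- sp[!issol]; chain_of <- ch[!issol] }
    times <- c(times, tm); boxes <- rbind(boxes, box)
    i <- i + 2L + n
  }
  chains <- t(vapply(sort(unique(chain_of)),
                     function(k) range(which(chain_of == k)), integer(2)))
  colnames(chains) <- c("start", "end")
  any_sol <- any(vapply(solvent, nrow, 0L) > 0)
  trajectory(frames, times, boxes, chains, codes,
             solvent = if (any_sol) solvent else NULL)
}

#' Write a one-bead-per-residue PDB topology
#'
#' Writes CA-style records (one atom per residue) for the first frame, with
#' chain identifiers, suitable as a topology for molecular viewers.
#'
#' @param traj a [trajectory()] or [system_configuration()].
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_topology_pdb <- function(traj, path) {
  if (inherits(traj, "cg_trajectory")) {
    pos <- traj$frames[, , 1]; chains <- traj$chains; codes <- traj$bead_codes
  } else {
    pos <- traj$positions; chains <- traj$chains; codes <- traj$bead_codes
  }
  three <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
             E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
             M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
             Y = "TYR", V = "VAL", s = "SEP")
  n <- nrow(pos)
  chain_of <- integer(n)
  resno <- integer(n)
  for (k in seq_len(nrow(chains))) {
    idx <- chains[k, 1]:chains[k, 2]
    chain_of[idx] <- k
    resno[idx] <- seq_along(idx)
  }
  chain_ids <- rep(c(LETTERS, letters, 0:9), length.out = max(chain_of))
  bio3d::write.pdb(file = path, xyz = as.numeric(t(pos)),
                   resno = resno, resid = three[codes],
                   eleno = seq_len(n), elety = rep("CA", n),
                   chain = chain_ids[chain_of])
  invisible(path)
}
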