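# Residue alphabet: 20 canonical one-letter codes plus "s" for phosphoserine
# (SEP).  Sequences always carry full-length (1-based) numbering via `offset`.

AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
SEP_CODE <- "s"

#' Protein sequence with full-length numbering
#'
#' A light container for a one-letter-coded protein sequence.  The alphabet is
#' the 20 canonical residues plus `"s"` for phosphoserine (SEP).  `offset`
#' records the full-length position of the first residue, so that a
#' low-complexity domain extracted from a longer protein keeps its original
#' residue numbers (e.g. the TDP-43 LCD spans positions 261-414 of the
#' 414-residue protein).
#'
#' @param residues character vector of single-residue codes, or a single
#'   string that is split into characters.
#' @param id sequence identifier.
#' @param offset full-length position (1-based) of the first residue.
#' @return an object of class `protein_sequence` with fields `id`, `residues`
#'   and `offset`.
#' @examples
#' ps <- protein_sequence("GSGSGS", id = "toy")
#' seq_positions(ps)
#' @export
protein_sequence <- function(residues, id = "", offset = 1L) {
  if (length(residues) == 1L && nchar(residues[1]) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- as.character(residues)
  residues <- ifelse(residues == SEP_CODE, SEP_CODE, toupper(residues))
  if (length(residues) < 1L)
    stop("sequence must contain at least one residue")
  bad <- which(!residues %in% c(AA_CODES, SEP_CODE))
  if (length(bad))
    stop(sprintf("illegal residue code '%s' at position %d",
                 residues[bad[1]], bad[1]))
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 1L) stop("offset must be >= 1")
  structure(list(id = as.character(id), residues = residues, offset = offset),
            class = "protein_sequence")
}

#' @export
length.protein_sequence <- function(x) length(x$residues)

#' @export
as.character.protein_sequence <- function(x, ...) paste(x$residues, collapse = "")

#' @export
print.protein_sequence <- function(x, ...) {
  n <- length(x$residues)
  cat(sprintf("protein_sequence '%s': %d residues, positions %d-%d\n",
              x$id, n, x$offset, x$offset + n - 1L))
  cat(" ", substr(as.character(x), 1, 60),
      if (n > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Full-length residue positions of a sequence
#' @param seq a [protein_sequence()].
#' @return integer vector of full-length positions, one per residue.
#' @export
seq_positions <- function(seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  seq$offset + seq_along(seq$residues) - 1L
}

#' Read protein sequences from a FASTA file
#'
#' Records are returned in file order with `offset = 1`.  Lowercase letters
#' are uppercased, except `"s"` which is only interpreted as phosphoserine
#' when listed in the sidecar modification table; otherwise it is read as
#' serine.  The sidecar (as written by [write_fasta()]) is a CSV with columns
#' `record`, `position`, `modification`.
#'
#' @param path FASTA file.
#' @param modifications optional path to a sidecar modification CSV.
#' @return list of [protein_sequence()] objects.
#' @export
load_fasta <- function(path, modifications = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- lapply(seq_along(set), function(i) {
    chars <- strsplit(toupper(as.character(set[[i]])), "")[[1]]
    bad <- which(!chars %in% AA_CODES)
    if (length(bad))
      stop(sprintf("record '%s': illegal residue character '%s' at position %d",
                   ids[i], chars[bad[1]], bad[1]))
    protein_sequence(chars, id = ids[i], offset = 1L)
  })
  if (!is.null(modifications)) {
    mods <- utils::read.csv(modifications, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(mods))) {
      idx <- match(mods$record[k], ids)
      if (is.na(idx)) stop("modification table names unknown record: ",
                           mods$record[k])
      if (!identical(mods$modification[k], "SEP"))
        stop("unsupported modification: ", mods$modification[k])
      pos <- mods$position[k]
      if (seqs[[idx]]$residues[pos] != "S")
        stop("modification at non-serine position ", pos)
      seqs[[idx]]$residues[pos] <- SEP_CODE
    }
  }
  seqs
}

#' Write protein sequences to FASTA (phosphoserine as lowercase "s")
#'
#' Phosphoserines are encoded as lowercase `"s"` in the FASTA body and
#' additionally listed in a sidecar modification CSV so that standard tools
#' that uppercase sequences do not silently lose the modification.
#'
#' @param seqs a [protein_sequence()] or list of them.
#' @param path output FASTA path.
#' @param modifications path for the sidecar CSV; default `<path>.mods.csv`.
#'   Only written if any sequence carries a phosphoserine.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path,
                        modifications = paste0(path, ".mods.csv")) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  lines <- character(0)
  mods <- list()
  for (s in seqs) {
    lines <- c(lines, paste0(">", s$id),
               substring(as.character(s),
                         seq(1, length(s), 60),
                         pmin(seq(1, length(s), 60) + 59L, length(s))))
    hits <- which(s$residues == SEP_CODE)
    if (length(hits))
      mods[[length(mods) + 1L]] <- data.frame(
        record = s$id, position = seq_positions(s)[hits] - s$offset + 1L,
        modification = "SEP")
  }
  writeLines(lines, path)
  if (length(mods))
    utils::write.csv(do.call(rbind, mods), modifications, row.names = FALSE)
  invisible(path)
}

#' Extract a region by full-length residue numbers
#'
#' @param seq a [protein_sequence()].
#' @param start,end inclusive full-length positions; must satisfy
#'   `offset <= start <= end <= offset + length - 1`.
#' @return a [protein_sequence()] with `offset = start`.
#' @examples
#' lcd <- extract_region(tdp43_sequence(), 261, 414)  # 154-residue LCD
#' @export
extract_region <- function(seq, start, end) {
  stopifnot(inherits(seq, "protein_sequence"))
  lo <- seq$offset
  hi <- seq$offset + length(seq$residues) - 1L
  if (start > end) stop("inverted bounds: start > end")
  if (start < lo || end > hi)
    stop(sprintf("region %d-%d outside sequence positions %d-%d",
                 start, end, lo, hi))
  protein_sequence(seq$residues[(start - lo + 1L):(end - lo + 1L)],
                   id = sprintf("%s_%d-%d", seq$id, start, end),
                   offset = start)
}

#' The bundled canonical human TDP-43 sequence
#'
#' Returns the 414-residue canonical sequence of human TAR DNA-binding
#' protein 43 (UniProt Q13148), shipped as an in-package FASTA fixture.  The
#' transcription was validated against its documented length (414), average
#' mass (44,740 Da) and the identity of all C-terminal phosphosites.
#'
#' @return a [protein_sequence()] of length 414 with `offset = 1`.
#' @export
tdp43_sequence <- function() {
  path <- system.file("extdata", "tdp43_q13148.fasta", package = "hpslab")
  seq <- load_fasta(path)[[1]]
  seq$id <- "TDP43_Q13148"
  seq
}
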