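# Phosphosite sets and sequence variants of the TDP-43 C-terminal LCD, plus
# Henderson-Hasselbalch net-charge calculations.

#' C-terminal TDP-43 phosphosite sets
#'
#' Full-length residue numbers of the serines mutated or phosphorylated in
#' the standard TDP-43 variant series: the 2-site set (S409/S410, the
#' disease-diagnostic epitope), the 5-site set detected with phospho-specific
#' antibodies in patient tissue, and the 12-site set identified by mass
#' spectrometry in ALS spinal cord.  The sets are nested: 2 within 5 within 12.
#'
#' @param n one of 2, 5 or 12.
#' @return integer vector of full-length serine positions.
#' @export
phospho_sites <- function(n) {
  sets <- list(
    `2`  = c(409L, 410L),
    `5`  = c(379L, 403L, 404L, 409L, 410L),
    `12` = c(373L, 375L, 379L, 387L, 389L, 393L, 395L,
             403L, 404L, 407L, 409L, 410L))
  key <- as.character(n)
  if (!key %in% names(sets)) stop("no canonical site set of size ", n)
  sets[[key]]
}

#' Specify a sequence variant
#'
#' @param name variant label (e.g. "12D", "5pS").
#' @param sites full-length residue numbers to substitute; must be nonempty
#'   unless `substitution = "NONE"`.
#' @param substitution one of `"ASP"` (phosphomimetic S-to-D), `"ALA"`
#'   (control S-to-A), `"SEP"` (phosphoserine) or `"NONE"`.
#' @return an object of class `variant_spec`.
#' @export
variant_spec <- function(name, sites = integer(0),
                         substitution = c("ASP", "ALA", "SEP", "NONE")) {
  substitution <- match.arg(substitution)
  sites <- sort(unique(as.integer(sites)))
  if (substitution != "NONE" && length(sites) == 0L)
    stop("sites must be nonempty unless substitution is NONE")
  structure(list(name = as.character(name), sites = sites,
                 substitution = substitution), class = "variant_spec")
}

#' Standard TDP-43 variant specifications
#'
#' The variant series studied for TDP-43: wild type, phosphomimetic S-to-D
#' (2D/5D/12D), control S-to-A (2A/5A/12A) and phosphoserine (2pS/5pS/12pS)
#' at the canonical C-terminal site sets.
#'
#' @param names optional character vector to subset/order the returned list.
#' @return named list of [variant_spec()] objects.
#' @export
tdp43_variant_specs <- function(names = NULL) {
  specs <- list(Wt = variant_spec("Wt", substitution = "NONE"))
  for (n in c(2, 5, 12)) {
    s <- phospho_sites(n)
    specs[[paste0(n, "D")]]  <- variant_spec(paste0(n, "D"),  s, "ASP")
    specs[[paste0(n, "A")]]  <- variant_spec(paste0(n, "A"),  s, "ALA")
    specs[[paste0(n, "pS")]] <- variant_spec(paste0(n, "pS"), s, "SEP")
  }
  if (!is.null(names)) {
    missing <- setdiff(names, names(specs))
    if (length(missing)) stop("unknown variant name(s): ",
                              paste(missing, collapse = ", "))
    specs <- specs[names]
  }
  specs
}

#' Apply a variant specification to a sequence
#'
#' Substitutes the residues at the specified full-length positions, which
#' must all be serines in the input sequence.  All other residues are left
#' untouched and the variant name is appended to the sequence id.
#'
#' @param seq a [protein_sequence()].
#' @param spec a [variant_spec()].
#' @return the substituted [protein_sequence()].
#' @examples
#' lcd12D <- build_variant(extract_region(tdp43_sequence(), 261, 414),
#'                         tdp43_variant_specs()[["12D"]])
#' @export
build_variant <- function(seq, spec) {
  stopifnot(inherits(seq, "protein_sequence"), inherits(spec, "variant_spec"))
  out <- seq
  out$id <- paste0(seq$id, "_", spec$name)
  if (spec$substitution == "NONE") return(out)
  pos <- seq_positions(seq)
  idx <- match(spec$sites, pos)
  if (anyNA(idx))
    stop("site(s) out of range: ",
         paste(spec$sites[is.na(idx)], collapse = ", "))
  notser <- seq$residues[idx] != "S"
  if (any(notser))
    stop("site(s) not serine in input sequence: ",
         paste(spec$sites[notser], collapse = ", "))
  code <- switch(spec$substitution, ASP = "D", ALA = "A", SEP = SEP_CODE)
  out$residues[idx] <- code
  out
}

#' Side-chain pKa table for net-charge calculations
#'
#' The default pKa set (aspartate/glutamate 4.4, cysteine 8.5, tyrosine 10.0,
#' histidine 6.5, lysine 10.0, arginine 12.0, N-terminus 8.0, C-terminus 3.1;
#' the Scripps Protein Calculator set) was selected because, with termini
#' included, it reproduces the reference net charges of full-length TDP-43 at
#' pH 7.4: -4.1 (Wt), -16.1 (12D) and -28.1 (12pS).
#'
#' Phosphoserine is handled in one of two modes: `"fixed_minus2"` assigns
#' each phospho-group a charge of exactly -2 (the arithmetic implied by the
#' reference values), while `"henderson"` treats the second phosphate
#' ionization as a titratable acid with pKa `sep_pka` on top of a fixed -1.
#'
#' @param phospho_mode `"fixed_minus2"` or `"henderson"`.
#' @param sep_pka pKa of the second phosphate ionization (henderson mode).
#' @param path CSV with columns `group`, `pka`, `kind`; defaults to the
#'   bundled table.
#' @return an object of class `pka_table`.
#' @export
default_pka_table <- function(phospho_mode = c("fixed_minus2", "henderson"),
                              sep_pka = 6.0, path = NULL) {
  phospho_mode <- match.arg(phospho_mode)
  if (is.null(path))
    path <- system.file("extdata", "pka_protcalc.csv", package = "hpslab")
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (any(tab$pka <= 0 | tab$pka >= 14)) stop("pKa values must lie in (0, 14)")
  pka <- stats::setNames(tab$pka, tab$group)
  kind <- stats::setNames(tab$kind, tab$group)
  structure(list(pka = pka, kind = kind, phospho_mode = phospho_mode,
                 sep_pka = sep_pka), class = "pka_table")
}

#' Net charge of a protein sequence at a given pH
#'
#' Henderson-Hasselbalch fractional charges summed over all ionizable
#' groups: an acid with pKa \eqn{K} contributes \eqn{-1/(1+10^{K-pH})}, a
#' base \eqn{+1/(1+10^{pH-K})}.  Termini are included by default (the
#' convention under which the default pKa set reproduces the TDP-43
#' reference values).  Phosphoserine contributes exactly -2 in
#' `fixed_minus2` mode; in `henderson` mode it contributes
#' \eqn{-1 - 1/(1+10^{pKa_{SEP}-pH})}.
#'
#' @param seq a [protein_sequence()].
#' @param pH solution pH, in (0, 14).  "Physiological pH" is taken as 7.4.
#' @param pka a [default_pka_table()] object.
#' @param termini include N-/C-terminal charges?
#' @return net charge in elementary charges.
#' @examples
#' round(net_charge(tdp43_sequence()), 1)  # -4.1
#' @export
net_charge <- function(seq, pH = 7.4, pka = default_pka_table(),
                       termini = TRUE) {
  stopifnot(inherits(seq, "protein_sequence"), inherits(pka, "pka_table"))
  if (pH <= 0 || pH >= 14) stop("pH must lie in (0, 14)")
  acid <- function(k) -1 / (1 + 10^(k - pH))
  base <- function(k)  1 / (1 + 10^(pH - k))
  frac <- function(group) {
    k <- pka$pka[[group]]
    if (pka$kind[[group]] == "acid") acid(k) else base(k)
  }
  res <- seq$residues
  q <- 0
  for (group in intersect(names(pka$pka), AA_CODES)) {
    n <- sum(res == group)
    if (n > 0) q <- q + n * frac(group)
  }
  nsep <- sum(res == SEP_CODE)
  if (nsep > 0) {
    q <- q + nsep * if (pka$phospho_mode == "fixed_minus2") -2
                    else -1 + acid(pka$sep_pka)
  }
  if (termini) q <- q + frac("Nterm") + frac("Cterm")
  q
}
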