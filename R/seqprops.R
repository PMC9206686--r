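#' Translate a coding DNA sequence
#'
#' Codon-by-codon translation under the standard genetic code.  The
#' first stop codon terminates translation; codons containing `N` (or
#' otherwise untranslatable codons) become `X`; a trailing partial codon
#' is ignored.
#'
#' @param nucleotides a DNA string (alphabet `ACGTN`, case-insensitive;
#'   `U` accepted as `T`).
#' @param frame reading frame, 1 to 3.
#' @return the protein sequence as a single upper-case string.
#' @examples
#' translate_dna("ATGGGA")  # "MG"
#' translate_dna("ATGTAA")  # "M" (stop terminates)
#' @export
translate_dna <- function(nucleotides, frame = 1L) {
  stopifnot(length(nucleotides) == 1L, is.character(nucleotides))
  s <- toupper(gsub("\\s", "", nucleotides))
  s <- gsub("U", "T", s)
  if (nchar(s) < 3L || !grepl("^[ACGTN]+$", s))
    stop("invalid sequence: need at least one codon over the alphabet ACGTN")
  stopifnot(frame %in% 1:3)
  s <- substring(s, frame)
  n_codon <- nchar(s) %/% 3L
  if (n_codon < 1L) stop("invalid sequence: no complete codon in this frame")
  codons <- substring(s, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  # standard genetic code via seqinr; ambiguous codons fall back to X
  aa <- vapply(codons, function(cd) {
    if (grepl("N", cd)) return("X")
    seqinr::translate(strsplit(cd, "")[[1]])
  }, character(1))
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

#' Net charge of a protein at a given pH (Bjellqvist model)
#'
#' Sums the partial charges of the ionizable side chains (D, E, C, Y,
#' H, K, R) and both termini using the Bjellqvist pKa set, including the
#' residue-specific N-terminal pKa values and the special C-terminal
#' D/E values.  The charge is strictly decreasing in pH.
#'
#' @param protein protein string (standard 20-letter alphabet; `X`
#'   carries no charge).
#' @param pH pH value(s).
#' @return numeric net charge, vectorized over `pH`.
#' @examples
#' protein_charge("DDEE", 7) < 0
#' @export
protein_charge <- function(protein, pH) {
  aa <- .check_protein(protein)
  counts <- table(factor(aa, levels = .aa_letters))
  first <- aa[1L]; last <- aa[length(aa)]
  pos_pka <- c(.pka$positive[c("K", "R", "H")],
               Nterm = unname(if (first %in% names(.pka$nterm_by_residue))
                 .pka$nterm_by_residue[[first]] else .pka$positive[["Nterm"]]))
  pos_n <- c(counts[["K"]], counts[["R"]], counts[["H"]], 1)
  neg_pka <- c(.pka$negative[c("D", "E", "C", "Y")],
               Cterm = unname(if (last %in% names(.pka$cterm_by_residue))
                 .pka$cterm_by_residue[[last]] else .pka$negative[["Cterm"]]))
  neg_n <- c(counts[["D"]], counts[["E"]], counts[["C"]], counts[["Y"]], 1)
  vapply(pH, function(p) {
    pos <- sum(pos_n / (1 + 10^(p - pos_pka)))
    neg <- sum(neg_n / (1 + 10^(neg_pka - p)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point by bisection on the Bjellqvist charge function
#'
#' Bisects pH over `[0, 14]` until the net charge magnitude falls below
#' `tol` (or the bracket is exhausted, for sequences whose charge never
#' crosses zero inside the scale).
#'
#' @inheritParams protein_charge
#' @param tol convergence tolerance on the net charge (default 1e-4).
#' @return the isoelectric point (pH units).
#' @examples
#' isoelectric_point("DDEEDDEEGG")  # ~4.05
#' @export
isoelectric_point <- function(protein, tol = 1e-4) {
  lo <- 0; hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- protein_charge(protein, mid)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

.check_protein <- function(protein, allow_x = TRUE) {
  stopifnot(length(protein) == 1L, is.character(protein))
  s <- toupper(gsub("\\s", "", protein))
  if (nchar(s) == 0L) stop("invalid sequence: empty protein")
  aa <- strsplit(s, "")[[1]]
  ok <- c(.aa_letters, if (allow_x) "X")
  if (!all(aa %in% ok))
    stop("invalid sequence: unknown residue(s) ",
         paste(unique(setdiff(aa, ok)), collapse = ", "))
  aa
}

#' ProtParam-style physicochemical profile of a protein
#'
#' Computes the standard Expasy-style indices from a one-letter protein
#' sequence:
#'
#' * molecular weight: sum of average residue masses plus one water;
#' * isoelectric point: bisection on the Bjellqvist charge function;
#' * instability index: `(10 / L) * sum` of the published dipeptide
#'   weights (DIWV) over consecutive residue pairs;
#' * aliphatic index: `X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu)` with
#'   `X` the mole percent of each residue;
#' * GRAVY: mean Kyte-Doolittle hydropathy per residue.
#'
#' `X` (unknown) residues carry no mass contribution to the indices:
#' they are skipped and the effective length renormalized, with a
#' warning.
#'
#' @param protein protein string (20-letter alphabet, `X` allowed).
#' @param id optional identifier carried into the record.
#' @return An object of class `protein_record`: `id`, `sequence`,
#'   `length`, `mw_Da`, `pI`, `instability_index`, `aliphatic_index`,
#'   `gravy`, `n_unknown`.
#' @examples
#' protein_properties(strrep("A", 20))  # aliphatic index 100, GRAVY 1.8
#' @export
protein_properties <- function(protein, id = NA_character_) {
  aa_all <- .check_protein(protein)
  n_unknown <- sum(aa_all == "X")
  if (n_unknown > 0)
    warning(n_unknown, " unknown residue(s) skipped; indices renormalized")
  aa <- aa_all[aa_all != "X"]
  L <- length(aa)
  if (L == 0L) stop("invalid sequence: no standard residues")
  counts <- table(factor(aa, levels = .aa_letters))
  mw <- sum(.aa_mass[aa]) + .water_mass
  gravy <- mean(.kyte_doolittle[aa])
  molpct <- as.numeric(counts) / L * 100
  names(molpct) <- .aa_letters
  aliphatic <- molpct[["A"]] + 2.9 * molpct[["V"]] +
    3.9 * (molpct[["I"]] + molpct[["L"]])
  instability <- if (L >= 2L) {
    pairs <- cbind(aa[-L], aa[-1L])
    10 / L * sum(.diwv[pairs])
  } else NA_real_
  pI <- isoelectric_point(paste(aa, collapse = ""))
  out <- list(id = id, sequence = paste(aa_all, collapse = ""),
              length = length(aa_all), mw_Da = mw, pI = pI,
              instability_index = instability,
              aliphatic_index = aliphatic, gravy = gravy,
              n_unknown = n_unknown)
  class(out) <- "protein_record"
  out
}

#' @export
print.protein_record <- function(x, digits = 4, ...) {
  cat("Protein record", if (!is.na(x$id)) paste0(" [", x$id, "]"),
      ": ", x$length, " aa\n", sep = "")
  cat("  MW            = ", format(x$mw_Da / 1000, digits = 5), " kDa\n", sep = "")
  cat("  pI            = ", format(x$pI, digits = digits), "\n", sep = "")
  cat("  instability   = ", format(x$instability_index, digits = digits),
      if (is.finite(x$instability_index))
        if (x$instability_index < 40) " (predicted stable)" else " (predicted unstable)",
      "\n", sep = "")
  cat("  aliphatic     = ", format(x$aliphatic_index, digits = digits), "\n", sep = "")
  cat("  GRAVY         = ", format(x$gravy, digits = digits), "\n", sep = "")
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [seqinr::read.fasta()] returning plain upper-case
#' strings named by record id.
#'
#' @param path path to a FASTA file (nucleotide or protein).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  out <- toupper(vapply(recs, function(r) as.character(r)[1L], character(1)))
  names(out) <- names(recs)
  out
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  seqinr::write.fasta(as.list(unname(sequences)), names = names(sequences),
                      file.out = path)
  invisible(path)
}
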