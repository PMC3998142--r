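# Six-frame ORF discovery and protein->nucleotide coordinate back-mapping.
# Conventions: stop-to-stop maximal codon runs (not ATG-anchored), standard
# genetic code only, 1-based inclusive forward-strand coordinates for both
# strands; the terminating stop codon is included in the nucleotide span but
# excluded from the protein.

# Standard genetic code (translation table 1), taken from Biostrings.
codon_table <- function() {
  Biostrings::GENETIC_CODE
}

#' Reverse-complement a nucleotide string
#' @param x Nucleotide string (A/C/G/T/N, uppercase).
#' @return The reverse complement.
#' @export
revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

#' Translate an in-frame nucleotide string
#'
#' Standard genetic code; codons containing N translate to 'X'; stops to '*'.
#' @param nt In-frame nucleotide string (length a multiple of 3).
#' @return Amino-acid string.
#' @export
translate_codons <- function(nt) {
  n <- nchar(nt)
  stopifnot(n %% 3 == 0)
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  tab <- codon_table()
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Find open reading frames in all six frames
#'
#' Scans every reading frame on both strands for maximal stop-free codon
#' runs (stop-to-stop convention, not ATG-anchored) and reports those that
#' are terminated by a stop codon and whose translation is at least
#' `min_protein_length` residues. Coordinates are 1-based inclusive on the
#' forward strand for both strands; the terminating stop codon is included
#' in the nucleotide span but excluded from the protein. Minus-strand
#' proteins are translations of the reverse complement.
#'
#' @param seq A [nucleotide_sequence()].
#' @param min_protein_length Minimum translated length in residues
#'   (default 50).
#' @return List of `open_reading_frame` objects, each with `parent_id`,
#'   `strand`, `nt_start`, `nt_end`, `frame` and `protein` (a
#'   [canonicalize_and_checksum()] product with a derived id).
#' @export
find_orfs <- function(seq, min_protein_length = 50L) {
  stopifnot(inherits(seq, "nucleotide_sequence"), min_protein_length >= 1L)
  L <- seq$length
  orfs <- list()
  k <- 0L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq$residues else revcomp(seq$residues)
    for (off in 0:2) {
      n_codons <- (L - off) %/% 3L
      if (n_codons < 1L) next
      frame_nt <- substr(s, off + 1L, off + 3L * n_codons)
      aa <- strsplit(translate_codons(frame_nt), "")[[1]]
      # maximal stop-free runs over the codon index 1..n_codons
      is_stop <- aa == "*"
      run_id <- cumsum(c(TRUE, diff(is_stop) != 0))
      for (r in split(seq_len(n_codons), run_id)) {
        if (is_stop[r[1L]]) next
        a <- r[1L]; b <- r[length(r)]
        # complete ORFs only: the run must be terminated by a stop codon,
        # which is included in the nucleotide span
        if (b == n_codons || !is_stop[b + 1L]) next
        prot <- paste(aa[r], collapse = "")
        if (nchar(prot) < min_protein_length) next
        b_span <- b + 1L
        # coordinates on the scanned (possibly reverse-complemented) strand
        sc_start <- off + 3L * (a - 1L) + 1L
        sc_end <- off + 3L * b_span
        if (strand == "+") {
          nt_start <- sc_start; nt_end <- sc_end
        } else {
          nt_start <- L - sc_end + 1L; nt_end <- L - sc_start + 1L
        }
        k <- k + 1L
        orf_id <- sprintf("%s_orf%03d", seq$id, k)
        orfs[[k]] <- structure(
          list(parent_id = seq$id, strand = strand,
               nt_start = nt_start, nt_end = nt_end,
               frame = off + 1L,
               protein = canonicalize_and_checksum(orf_id, prot)),
          class = "open_reading_frame")
      }
    }
  }
  orfs
}

#' Map a protein residue interval back to nucleotide coordinates
#'
#' Projects residue coordinates on an ORF-derived protein onto the forward
#' strand of the parent nucleotide sequence. For a '+' ORF the first residue
#' occupies the first three bases of the span; for a '-' ORF it occupies the
#' last three (reading proceeds from `nt_end` downward on the forward
#' strand). The returned span always satisfies
#' `nt_end - nt_start + 1 == 3 * (stop - start + 1)`.
#'
#' @param orf An `open_reading_frame`.
#' @param start,stop 1-based inclusive residue coordinates,
#'   `1 <= start <= stop <= orf$protein$length`.
#' @return List with `nt_start`, `nt_end` (forward strand, 1-based
#'   inclusive, `nt_start <= nt_end`) and `strand`.
#' @export
map_to_nucleotide <- function(orf, start, stop) {
  stopifnot(inherits(orf, "open_reading_frame"))
  start <- as.integer(start); stop <- as.integer(stop)
  if (start < 1L || start > stop || stop > orf$protein$length) {
    stop(sprintf("residue interval [%d,%d] outside protein 1..%d",
                 start, stop, orf$protein$length), call. = FALSE)
  }
  if (orf$strand == "+") {
    list(nt_start = orf$nt_start + 3L * (start - 1L),
         nt_end = orf$nt_start + 3L * stop - 1L,
         strand = "+")
  } else {
    list(nt_start = orf$nt_end - 3L * stop + 1L,
         nt_end = orf$nt_end - 3L * (start - 1L),
         strand = "-")
  }
}
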