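#' Six-frame translation with coordinate maps
#'
#' Translates a DNA sequence in all six reading frames. Codons containing
#' N (or any ambiguity that cannot be resolved) translate to X; stop codons
#' are rendered as `*`. Each frame carries the arithmetic needed to map an
#' amino-acid position back to its 1-based inclusive DNA span on the input
#' (forward) strand.
#'
#' @param dna character scalar over A/C/G/T/N (case-insensitive).
#' @return a list of up to six `translated_segment` objects, one per frame
#'   `+1,+2,+3,-1,-2,-3`, each with elements `frame`, `aa` (protein with
#'   `*` stops), and `dna_len`. Frames shorter than one codon are dropped;
#'   empty input gives an empty list.
#' @export
six_frame_translate <- function(dna) {
  dna <- toupper(dna)
  if (nchar(dna) == 0) return(list())
  L <- nchar(dna)
  fwd <- Biostrings::DNAString(dna)
  rev <- Biostrings::reverseComplement(fwd)
  out <- list()
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    off <- abs(fr) - 1L
    src <- if (fr > 0) fwd else rev
    usable <- L - off
    n_codon <- usable %/% 3L
    if (n_codon < 1L) next
    sub <- Biostrings::subseq(src, start = off + 1L, width = n_codon * 3L)
    aa <- as.character(Biostrings::translate(sub, if.fuzzy.codon = "solve",
                                             no.init.codon = TRUE))
    out[[length(out) + 1L]] <- structure(
      list(frame = fr, aa = aa, dna_len = L),
      class = "translated_segment")
  }
  out
}

#' Map an amino-acid span of a frame back to forward-strand DNA coordinates
#'
#' @param frame one of +1,+2,+3,-1,-2,-3.
#' @param aa_start,aa_end 1-based amino-acid positions within the frame.
#' @param dna_len length of the source DNA.
#' @return integer vector `c(start, end)`, 1-based inclusive on the forward
#'   strand (for negative frames the span is reported on forward coordinates
#'   but corresponds to the reverse strand).
#' @export
aa_to_dna <- function(frame, aa_start, aa_end, dna_len) {
  off <- abs(frame) - 1L
  s <- off + 3L * (aa_start - 1L) + 1L
  e <- off + 3L * aa_end
  if (frame > 0) c(s, e) else c(dna_len - e + 1L, dna_len - s + 1L)
}

## Codon lookup used by the frameshift-aware gene aligner -------------------

base_code <- function(chars) {
  code <- match(chars, DNA_BASES) - 1L
  code[is.na(code)] <- 4L # N / ambiguity
  code
}

#' Codon-to-amino-acid lookup table for cpp_fs_align
#'
#' Index is d1*25 + d2*5 + d3 (bases coded A=0,C=1,G=2,T=3,N=4), value is a
#' 0-based column index into the protein scoring matrix; codons containing N
#' map to the X column.
#' @param alphabet scoring-matrix alphabet (character vector of residues).
#' @keywords internal
codon_aa_table <- function(alphabet) {
  x_col <- match("X", alphabet) - 1L
  tab <- rep(x_col, 125L)
  idx <- expand.grid(d3 = 0:3, d2 = 0:3, d1 = 0:3)
  codons <- paste0(DNA_BASES[idx$d1 + 1L], DNA_BASES[idx$d2 + 1L],
                   DNA_BASES[idx$d3 + 1L])
  aas <- as.character(Biostrings::translate(Biostrings::DNAStringSet(codons),
                                            no.init.codon = TRUE))
  cols <- match(aas, alphabet) - 1L
  cols[is.na(cols)] <- x_col
  tab[idx$d1 * 25L + idx$d2 * 5L + idx$d3 + 1L] <- cols
  as.integer(tab)
}
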