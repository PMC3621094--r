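#' @title Small sequence utilities shared across the pipeline
#' @name seq-utils
#' @keywords internal
NULL

DNA_BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

#' Reverse complement of a DNA string
#'
#' Accepts A/C/G/T/N; case-insensitive, returns upper case.
#' @param x character scalar DNA sequence.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

#' Random DNA sequence with a given GC content
#'
#' @param n length in nucleotides.
#' @param gc expected GC fraction, in (0, 1).
#' @return character scalar of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 1, gc > 0, gc < 1)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

subseq_chr <- function(x, start, end) substr(x, start, end)

#' Hamming distance on equal-length strings
#' @keywords internal
hamming <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  stopifnot(length(ca) == length(cb))
  sum(ca != cb)
}

#' Read a FASTA file into a named character vector
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output file path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Shannon entropy (bits) of a character window
#' @keywords internal
window_entropy <- function(chars) {
  tab <- table(chars)
  p <- tab / sum(tab)
  -sum(p * log2(p))
}

#' Mask low-complexity stretches of a protein sequence to X
#'
#' Simple sliding-window entropy mask standing in for SEG-style filtering:
#' windows whose residue entropy falls below `min_entropy` bits are
#' replaced by X (which scores 0 against everything).
#'
#' @param aa character scalar protein sequence.
#' @param window window width in residues.
#' @param min_entropy entropy threshold in bits.
#' @return masked protein sequence.
#' @export
mask_low_complexity <- function(aa, window = 12L, min_entropy = 2.2) {
  n <- nchar(aa)
  if (n < window) return(aa)
  ch <- seq_chars(aa)
  mask <- logical(n)
  for (s in 1:(n - window + 1L)) {
    w <- ch[s:(s + window - 1L)]
    if (window_entropy(w) < min_entropy) mask[s:(s + window - 1L)] <- TRUE
  }
  ch[mask] <- "X"
  paste(ch, collapse = "")
}
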