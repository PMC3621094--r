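#' Alignment parameters for the translated protein search
#'
#' Defaults mirror the protein search settings used throughout: BLOSUM62,
#' affine gap costs of existence 11 / extension 1, an E-value cutoff of
#' 1e-10, and low-complexity masking of the query. K and lambda are the
#' published Karlin-Altschul constants for gapped BLOSUM62 11/1 statistics
#' and can be overridden (e.g. after empirical calibration on shuffle
#' nulls).
#'
#' @param matrix substitution matrix (integer matrix with residue dimnames);
#'   default BLOSUM62 with X and N-derived positions scoring 0 against
#'   everything.
#' @param gap_open,gap_extend affine gap costs (a gap of length k costs
#'   `gap_open + k * gap_extend`).
#' @param K,lambda Karlin-Altschul constants.
#' @param evalue_cutoff report hits with E below this value.
#' @param low_complexity_filter mask low-complexity query stretches.
#' @return an object of class `alignment_params`.
#' @export
alignment_params <- function(matrix = blosum62_matrix(),
                             gap_open = 11L, gap_extend = 1L,
                             K = 0.041, lambda = 0.267,
                             evalue_cutoff = 1e-10,
                             low_complexity_filter = TRUE) {
  stopifnot(gap_open >= gap_extend, gap_extend >= 0, K > 0, lambda > 0)
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), K = K, lambda = lambda,
                 evalue_cutoff = evalue_cutoff,
                 low_complexity_filter = isTRUE(low_complexity_filter)),
            class = "alignment_params")
}

#' BLOSUM62 with neutral ambiguity scoring
#'
#' The stock BLOSUM62 matrix with the X row/column set to 0 so that
#' translated N runs (non-sequenced regions) neither reward nor penalize an
#' alignment passing through them.
#' @return integer matrix with residue dimnames.
#' @export
blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  m["X", ] <- 0L
  m[, "X"] <- 0L
  storage.mode(m) <- "integer"
  m
}

aa_codes <- function(aa, alphabet) {
  code <- match(seq_chars(aa), alphabet)
  code[is.na(code)] <- match("X", alphabet)
  code - 1L
}

#' Local protein alignment (affine-gap Smith-Waterman)
#'
#' Exact full-DP Smith-Waterman with affine gaps; no heuristic seeding.
#' Residues absent from the matrix alphabet are treated as X (score 0).
#' Empty optimum (all scores <= 0) returns score 0 with empty spans.
#' Tie-breaking is deterministic: the maximal cell with the smallest end
#' coordinates wins and the traceback prefers substitutions over gaps.
#'
#' @param query,target protein sequences (character scalars).
#' @param params an [alignment_params()] object.
#' @param score_only if TRUE skip the traceback (faster; spans omitted).
#' @return list with `score`, `qstart`, `qend`, `tstart`, `tend`,
#'   `matches`, `length` (alignment columns), `pident`.
#' @export
local_align_protein <- function(query, target, params = alignment_params(),
                                score_only = FALSE) {
  stopifnot(nchar(query) > 0, nchar(target) > 0)
  alpha <- rownames(params$matrix)
  q <- aa_codes(query, alpha)
  t <- aa_codes(target, alpha)
  r <- cpp_sw_align(q, t, params$matrix, params$gap_open, params$gap_extend,
                    traceback = !score_only)
  if (score_only) {
    return(list(score = r$score, qend = r$qend, tend = r$tend))
  }
  if (r$score <= 0) {
    return(list(score = 0L, qstart = 0L, qend = 0L, tstart = 0L, tend = 0L,
                matches = 0L, length = 0L, pident = NA_real_))
  }
  list(score = r$score, qstart = r$qstart, qend = r$qend,
       tstart = r$tstart, tend = r$tend, matches = r$matches,
       length = r$length,
       pident = 100 * r$matches / r$length,
       qpos = r$qpos, tpos = r$tpos)
}

#' Karlin-Altschul expectation for a local alignment score
#'
#' E = K * m * n * exp(-lambda * S) for a search space of m x n letters.
#'
#' @param score_S alignment score.
#' @param m,n query and database lengths (letters), both >= 1.
#' @param params an [alignment_params()] object supplying K and lambda.
#' @return the expectation E (numeric scalar).
#' @export
evalue <- function(score_S, m, n, params = alignment_params()) {
  stopifnot(m >= 1, n >= 1)
  params$K * m * n * exp(-params$lambda * score_S)
}

## Nucleotide alignments (Biostrings engine) --------------------------------

#' Nucleotide scoring matrix over A/C/G/T/N
#'
#' Match/mismatch scoring with N scoring 0 against everything (neutral
#' handling of non-sequenced regions).
#' @param match,mismatch scores.
#' @keywords internal
dna_matrix <- function(match = 1L, mismatch = -3L) {
  a <- c(DNA_BASES, "N")
  m <- matrix(as.integer(mismatch), 5, 5, dimnames = list(a, a))
  diag(m) <- as.integer(match)
  m["N", ] <- 0L
  m[, "N"] <- 0L
  m
}

#' Pairwise nucleotide alignment via Biostrings
#'
#' Thin wrapper used for the LTR self-alignment search, flank comparison and
#' LTR divergence. Default scores mirror the nucleotide self-alignment
#' settings used for repeat finding: match +1, mismatch -3, gap costs of
#' existence 5 and extension 2.
#'
#' @param a,b DNA sequences (character scalars over ACGTN).
#' @param type "local" or "global".
#' @param match,mismatch,gap_open,gap_extend scoring.
#' @return list with `score`, `astart`, `aend`, `bstart`, `bend`,
#'   `a_aln`, `b_aln` (gapped aligned strings), `matches`, `columns`,
#'   `identity` (matches / alignment columns).
#' @export
align_dna <- function(a, b, type = c("local", "global"),
                      match = 1L, mismatch = -3L,
                      gap_open = 5, gap_extend = 2) {
  type <- match.arg(type)
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = type,
    substitutionMatrix = dna_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)
  a_aln <- as.character(Biostrings::alignedPattern(pa))
  b_aln <- as.character(Biostrings::alignedSubject(pa))
  ca <- seq_chars(a_aln); cb <- seq_chars(b_aln)
  matches <- sum(ca == cb & ca != "-")
  list(score = Biostrings::score(pa),
       astart = Biostrings::start(Biostrings::pattern(pa)),
       aend = Biostrings::end(Biostrings::pattern(pa)),
       bstart = Biostrings::start(Biostrings::subject(pa)),
       bend = Biostrings::end(Biostrings::subject(pa)),
       a_aln = a_aln, b_aln = b_aln,
       matches = matches, columns = length(ca),
       identity = matches / length(ca))
}
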