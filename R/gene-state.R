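#' Call a gene intact, defective or unknown against a reference protein
#'
#' Aligns the gene's DNA to the reference protein with a frameshift-aware
#' dynamic program (global in the protein, local in the DNA): a residue
#' normally consumes one codon, while 2-nt or 4-nt consumptions model
#' frameshifting indels and internal stop codons are passed through at a
#' penalty but recorded. The gene is `intact` when the full-length
#' alignment carries no frameshift and no premature stop; `defective` genes
#' list every event with its nucleotide position (codon resolution);
#' genes whose span overlaps an N-run of at least `nsr_min` nt are
#' `unknown` (non-sequenced region semantics).
#'
#' @param gene_dna DNA of the gene region (may include some flanking
#'   context; the DNA ends are free).
#' @param ref_protein reference protein for this gene.
#' @param params an [alignment_params()] object (matrix and gap costs are
#'   reused; the frameshift penalty is `fs_penalty`).
#' @param fs_penalty frameshift penalty (positive).
#' @param stop_penalty score of a reference residue against a stop codon
#'   (negative; overrides the matrix `*` column).
#' @param min_identity identity floor below which the gene is reported
#'   `unknown` (reference alignment failed).
#' @param nsr_min minimum N-run length that triggers the `unknown` call.
#' @return list of class `gene_state`: `state`, `events` (data.frame
#'   type/pos/shift, positions 1-based in `gene_dna`), `identity`,
#'   `dna_start`, `dna_end`, `translation` (frame-corrected, stops as `*`).
#' @export
call_gene_state <- function(gene_dna, ref_protein,
                            params = alignment_params(low_complexity_filter = FALSE),
                            fs_penalty = 20L, stop_penalty = -6L,
                            min_identity = 0.5, nsr_min = 20L) {
  stopifnot(nchar(gene_dna) > 0, nchar(ref_protein) > 0)
  gene_dna <- toupper(gene_dna)

  n_run <- gregexpr("N+", gene_dna)[[1]]
  if (n_run[1] != -1 &&
      any(attr(n_run, "match.length") >= nsr_min)) {
    return(structure(list(state = "unknown",
                          events = empty_events(), identity = NA_real_,
                          dna_start = NA_integer_, dna_end = NA_integer_,
                          translation = NA_character_),
                     class = "gene_state"))
  }

  alpha <- rownames(params$matrix)
  mat <- params$matrix
  mat[, "*"] <- as.integer(stop_penalty)
  mat["*", ] <- as.integer(stop_penalty)
  r <- cpp_fs_align(aa_codes(ref_protein, alpha),
                    base_code(seq_chars(gene_dna)), mat,
                    codon_aa_table(alpha), params$gap_open,
                    params$gap_extend, as.integer(fs_penalty),
                    match("*", alpha) - 1L)

  events <- if (length(r$ev_type) == 0) empty_events() else data.frame(
    type = c("frameshift", "premature_stop")[r$ev_type],
    pos = r$ev_pos,
    shift = r$ev_shift, stringsAsFactors = FALSE)
  events <- events[order(events$pos), , drop = FALSE]
  rownames(events) <- NULL

  identity <- if (r$aligned > 0) r$matches / r$aligned else 0
  aa_emitted <- r$res_aa + 1L
  translation <- paste(ifelse(is.na(aa_emitted), "X", alpha[aa_emitted]),
                       collapse = "")
  state <- if (identity < min_identity) "unknown"
  else if (nrow(events) == 0 && r$aligned >= 0.9 * nchar(ref_protein))
    "intact"
  else "defective"
  structure(list(state = state, events = events, identity = identity,
                 dna_start = r$dna_start, dna_end = r$dna_end,
                 translation = translation), class = "gene_state")
}

empty_events <- function() {
  data.frame(type = character(0), pos = integer(0), shift = integer(0))
}

#' @export
print.gene_state <- function(x, ...) {
  cat("<gene_state>", x$state,
      if (!is.na(x$identity)) sprintf("(identity %.1f%%)", 100 * x$identity),
      "\n")
  if (nrow(x$events) > 0) {
    cat("  events:\n")
    for (i in seq_len(nrow(x$events)))
      cat("   ", x$events$type[i], "at", x$events$pos[i], "\n")
  }
  invisible(x)
}
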