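#' Export provirus records as GFF3
#'
#' One feature line per element (LTR5, LTR3, TSD, PPT, PBS, gag, pol, env,
#' ORF), 1-based inclusive coordinates per the GFF3 specification.
#'
#' @param records list of `provirus_record`s (or a `run_report`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(records, path) {
  if (inherits(records, "run_report")) records <- records$records
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  src <- "proviscan"
  for (r in records) {
    if (!identical(r$type, "provirus")) next
    line <- function(type, s, e, attrs) {
      paste(r$sid, src, type, s, e, ".", r$strand, ".", attrs, sep = "\t")
    }
    sp <- r$spans_scaffold
    writeLines(line("LTR5", sp$ltr5[1], sp$ltr5[2],
                    paste0("ID=", r$id, ".LTR5")), con)
    writeLines(line("LTR3", sp$ltr3[1], sp$ltr3[2],
                    paste0("ID=", r$id, ".LTR3")), con)
    for (g in c("gag", "pol", "env")) {
      writeLines(line(g, sp[[g]][1], sp[[g]][2],
                      paste0("ID=", r$id, ".", g, ";state=",
                             r$gene_states[[g]]$state)), con)
    }
    if (r$tsd$status == "present") {
      writeLines(line("TSD", r$locus_start + r$tsd$pos5 - 1L,
                      r$locus_start + r$tsd$pos5 + 2L,
                      paste0("ID=", r$id, ".TSD5;seq=", r$tsd$sequence)), con)
    }
    if (!is.null(r$ppt)) {
      writeLines(line("PPT", r$locus_start + r$ppt$start - 1L,
                      r$locus_start + r$ppt$end - 1L,
                      paste0("ID=", r$id, ".PPT")), con)
    }
  }
  invisible(path)
}

#' Write the machine-readable run outputs
#'
#' FASTA scaffolds, hit table TSV, summary TSVs, record JSON, GFF3 and the
#' run report JSON under `out_dir`. Deterministic for a fixed seed.
#'
#' @param report a `run_report`.
#' @param seq_by_id named character vector/list of scaffold sequences.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(report, seq_by_id, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(unlist(seq_by_id), file.path(out_dir, "scaffolds.fa"))
  write.table(report$hits, file.path(out_dir, "hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tabs <- summarize(report)
  write.table(tabs$census, file.path(out_dir, "census.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tabs$ages, file.path(out_dir, "ages.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_gff3(report, file.path(out_dir, "annotations.gff3"))
  jsonlite::write_json(serialize_report(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  if (length(report$truths) > 0) {
    jsonlite::write_json(lapply(report$truths, serialize_truth),
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         null = "null")
  }
  invisible(out_dir)
}

serialize_truth <- function(tr) {
  x <- unclass(tr)
  x$events <- lapply(x$events, function(e) if (nrow(e) == 0) NULL else e)
  x
}

serialize_report <- function(report) {
  recs <- lapply(report$records, function(r) {
    x <- unclass(r)
    for (nm in c("ltr", "tsd", "ppt", "pbs", "divergence", "age",
                 "features")) {
      if (!is.null(x[[nm]])) x[[nm]] <- unclass(x[[nm]])
    }
    if (!is.null(x$gene_states))
      x$gene_states <- lapply(x$gene_states, unclass)
    x
  })
  list(counts = report$counts, seed = report$seed,
       version = report$version, records = recs)
}
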