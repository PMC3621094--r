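#' Pipeline configuration
#'
#' Collects every stage parameter with its default. Either a genome FASTA
#' path or a simulation spec must be supplied. The configuration
#' round-trips losslessly through JSON ([write_config()] /
#' [read_config()]).
#'
#' @param seed master RNG seed for the run.
#' @param genome_fasta path to input scaffolds (NULL to simulate).
#' @param simulate list describing the synthetic genome: `groups` (template
#'   sub-groups, one provirus each), `ages_myr`, `background_len`,
#'   `n_empty` (provirus-free scaffolds), `gc`, `indel_rate`.
#' @param clade clade whose substitution rate is used for dating.
#' @param rates named rate vector (substitutions/site/year).
#' @param evalue_cutoff translated-search E-value cutoff.
#' @param max_span,flank locus intersection parameters (nt).
#' @param min_orf_codons ORF cutoff.
#' @param out_dir output directory (NULL: nothing written).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, genome_fasta = NULL,
                       simulate = list(groups = c("V", "VII", "VIII"),
                                       ages_myr = c(10, 15, 5),
                                       background_len = 4000L,
                                       n_empty = 1L, gc = 0.42,
                                       indel_rate = 0.05),
                       clade = "megabat", rates = default_rates(),
                       evalue_cutoff = 1e-10, max_span = 15000L,
                       flank = 2000L, min_orf_codons = 100L,
                       out_dir = NULL) {
  stopifnot(clade %in% names(rates))
  structure(list(seed = as.integer(seed), genome_fasta = genome_fasta,
                 simulate = simulate, clade = clade, rates = rates,
                 evalue_cutoff = evalue_cutoff,
                 max_span = as.integer(max_span),
                 flank = as.integer(flank),
                 min_orf_codons = as.integer(min_orf_codons),
                 out_dir = out_dir), class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  config <- unclass(config)
  config$rates <- as.list(config$rates) # keep clade names through JSON
  jsonlite::write_json(config, path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$rates <- unlist(x$rates)
  do.call(run_config, x[!vapply(x, is.null, TRUE)])
}

simulate_genome <- function(cfg, panel) {
  sim <- cfg$simulate
  scaffolds <- list()
  truths <- list()
  rate <- cfg$rates[[cfg$clade]]
  for (i in seq_along(sim$groups)) {
    tpl <- betaretro_template(sim$groups[i], panel)
    pv <- build_provirus(tpl)
    bg <- make_background(sim$background_len, gc = sim$gc,
                          id = sprintf("scaffold_%02d", i))
    res <- plant(bg, pv, decay_params(rate, sim$ages_myr[i] * 1e6,
                                      indel_rate = sim$indel_rate))
    scaffolds[[length(scaffolds) + 1L]] <- res$scaffold
    truths[[length(truths) + 1L]] <- res$truth
  }
  n_empty <- if (is.null(sim$n_empty)) 0L else sim$n_empty
  for (j in seq_len(n_empty)) {
    scaffolds[[length(scaffolds) + 1L]] <- make_background(
      sim$background_len, gc = sim$gc,
      id = sprintf("scaffold_%02d", length(sim$groups) + j))
  }
  list(scaffolds = scaffolds, truths = truths)
}

default_query_set <- function(panel) {
  list(gag = panel$proteins$gag,
       pol = panel$proteins$pol[c("TYPE_B", "TYPE_D")],
       env = c(setNames(panel$proteins$env_beta,
                        paste0("beta_", names(panel$proteins$env_beta))),
               setNames(panel$proteins$env_gamma[1],
                        paste0("gamma_", names(panel$proteins$env_gamma)[1]))))
}

#' Delineate and annotate one candidate locus into a provirus record
#'
#' Runs LTR-pair detection, TSD and PPT calls, PBS assignment, gene-state
#' calling for gag/pro/pol/env, the motif scan, the ORF scan, dating and
#' sub-group classification on a single candidate locus. Minus-strand loci
#' are processed on the reverse complement and reported back in forward
#' scaffold coordinates.
#'
#' @param scaffold_seq the scaffold DNA.
#' @param locus one row of [intersect_gene_hits()] output.
#' @param panel reference panel.
#' @param rate substitution rate for dating (subs/site/year).
#' @param min_orf_codons ORF cutoff.
#' @param full when FALSE only delineation and dating are run (LTR pair,
#'   TSD, PPT, PBS, divergence, age); gene states, motifs, ORFs and the
#'   sub-group classification are skipped.
#' @return a `provirus_record` (list), or NULL if no LTR pair qualifies.
#' @export
delineate_provirus <- function(scaffold_seq, locus, panel,
                               rate = default_rates()[["megabat"]],
                               min_orf_codons = 100L, full = TRUE) {
  L_sc <- nchar(scaffold_seq)
  ls <- max(1L, locus$start); le <- min(L_sc, locus$end)
  locus_seq <- substr(scaffold_seq, ls, le)
  Ll <- nchar(locus_seq)
  minus <- identical(locus$strand, "-")
  to_local <- function(p) {
    p <- p - ls + 1L
    if (minus) Ll - p + 1L else p
  }
  gene_spans <- data.frame(
    gene = c("gag", "pol", "env"),
    start = pmin(to_local(c(locus$gag_start, locus$pol_start,
                            locus$env_start)),
                 to_local(c(locus$gag_end, locus$pol_end, locus$env_end))),
    end = pmax(to_local(c(locus$gag_start, locus$pol_start,
                          locus$env_start)),
               to_local(c(locus$gag_end, locus$pol_end, locus$env_end))))
  if (minus) locus_seq <- revcomp(locus_seq)
  to_scaffold <- function(s, e) {
    if (minus) c(ls + (Ll - e), ls + (Ll - s)) else c(ls + s - 1L, ls + e - 1L)
  }

  ltr <- find_ltr_pair(locus_seq, gene_spans)
  if (is.null(ltr)) {
    return(structure(list(id = NA_character_, sid = locus$sid,
                          strand = locus$strand, type = "betaERV-like",
                          note = "no qualifying LTR pair"),
                     class = "provirus_record"))
  }
  tsd <- find_tsd(locus_seq, ltr)
  up0 <- max(1L, ltr$ltr3_start - 40L)
  ppt <- find_ppt(substr(locus_seq, up0, ltr$ltr3_start - 1L))
  if (!is.null(ppt)) {
    ppt$start <- ppt$start + up0 - 1L
    ppt$end <- ppt$end + up0 - 1L
  }
  gag_start <- gene_spans$start[gene_spans$gene == "gag"]
  # a few nt of LTR margin: boundary jitter must not clip the PBS head
  leader <- substr(locus_seq, max(1L, ltr$ltr5_end - 3L), gag_start - 1L)
  pbs <- assign_pbs(leader, panel$trna)

  ltr5_seq <- substr(locus_seq, ltr$ltr5_start, ltr$ltr5_end)
  ltr3_seq <- substr(locus_seq, ltr$ltr3_start, ltr$ltr3_end)
  div <- ltr_divergence(ltr5_seq, ltr3_seq)
  age <- estimate_age(div, rate)

  states <- NULL; motifs <- NULL; orfs <- NULL; n_extra <- NA_integer_
  el <- list(lineage = "unknown"); px <- list(cluster = "unknown")
  fv <- NULL; grp <- list(group = NA_character_, trace = character(0))

  if (full) {
  # per-gene state against the best-matching reference variant
  pick_ref <- function(gene, region) {
    refs <- switch(gene,
                   gag = panel$proteins$gag, pro = panel$proteins$pro,
                   pol = panel$proteins$pol[c("TYPE_B", "TYPE_D")],
                   env = c(panel$proteins$env_beta,
                           panel$proteins$env_gamma))
    sc <- vapply(refs, function(r) {
      st <- call_gene_state(region, r)
      if (is.na(st$identity)) -1 else st$identity
    }, 1)
    refs[[which.max(sc)]]
  }
  region_of <- function(s, e) substr(locus_seq, max(1L, s - 150L),
                                     min(Ll, e + 150L))
  regions <- list(
    gag = region_of(gene_spans$start[1], gene_spans$end[1]),
    pro = substr(locus_seq, gene_spans$end[1] - 60L,
                 gene_spans$start[2] + 60L),
    pol = region_of(gene_spans$start[2], gene_spans$end[2]),
    env = region_of(gene_spans$start[3], gene_spans$end[3]))
  region_offsets <- c(
    gag = max(1L, gene_spans$start[1] - 150L),
    pro = gene_spans$end[1] - 60L,
    pol = max(1L, gene_spans$start[2] - 150L),
    env = max(1L, gene_spans$start[3] - 150L))
  states <- lapply(names(regions), function(g) {
    call_gene_state(regions[[g]], pick_ref(g, regions[[g]]))
  })
  names(states) <- names(regions)

  translations <- vapply(states, function(s) s$translation, "")
  refs_used <- c(gag = panel$proteins$gag[["TYPE_B"]],
                 pro = panel$proteins$pro[["TYPE_B"]],
                 pol = panel$proteins$pol[["TYPE_B"]])
  motifs <- scan_motifs(translations[c("gag", "pro", "pol")], refs_used,
                        panel$motifs)

  map <- data.frame(
    element = c("ltr5", "gag", "pro", "pol", "env", "ltr3"),
    start = c(ltr$ltr5_start, gene_spans$start[1], gene_spans$end[1] + 1L,
              gene_spans$start[2], gene_spans$start[3], ltr$ltr3_start),
    end = c(ltr$ltr5_end, gene_spans$end[1], gene_spans$start[2] - 1L,
            gene_spans$end[2], gene_spans$end[3], ltr$ltr3_end))
  orfs <- find_orfs(locus_seq, min_codons = min_orf_codons,
                    provirus_map = map)
  # only ORFs inside the provirus, not the core genes themselves
  orfs <- orfs[orfs$start >= ltr$ltr5_start & orfs$end <= ltr$ltr3_end &
                 orfs$placement != "core-gene", , drop = FALSE]
  # extra-ORF census: pre-gag / post-env, plus in-LTR ORFs deduplicated
  # across the two (identical at integration) LTR copies
  in_ltr <- orfs[orfs$placement == "in-LTR", , drop = FALSE]
  ltr_off <- ifelse(in_ltr$start >= ltr$ltr3_start,
                    in_ltr$start - ltr$ltr3_start,
                    in_ltr$start - ltr$ltr5_start)
  n_extra <- sum(orfs$placement %in% c("pre-gag", "post-env")) +
    length(unique(round(ltr_off / 10)))

  el <- env_lineage(translations[["env"]], panel$proteins$env_beta,
                    panel$proteins$env_gamma)
  px <- phylo_proxy(translations[["pol"]], panel$proteins$pol)
  dut <- any(motifs$motif_id == "dUTPase" & motifs$status == "present")
  fv <- feature_vector(pbs_type = pbs$trna_id, ltr_len = ltr$len5,
                       env = el$lineage,
                       extra_orf_placements = unique(orfs$placement),
                       dutpase_present = dut, proxy = px$cluster)
  grp <- classify_group(fv)
  } # end full annotation

  spans_sc <- lapply(list(
    ltr5 = c(ltr$ltr5_start, ltr$ltr5_end),
    ltr3 = c(ltr$ltr3_start, ltr$ltr3_end),
    gag = c(gene_spans$start[1], gene_spans$end[1]),
    pol = c(gene_spans$start[2], gene_spans$end[2]),
    env = c(gene_spans$start[3], gene_spans$end[3])),
    function(sp) to_scaffold(sp[1], sp[2]))

  structure(list(
    id = paste0(locus$sid, ":", spans_sc$ltr5[1], "-", spans_sc$ltr3[2]),
    sid = locus$sid, strand = locus$strand, type = "provirus",
    size = ltr$ltr3_end - ltr$ltr5_start + 1L,
    ltr = ltr, ltr_len = ltr$len5, tsd = tsd, ppt = ppt, pbs = pbs,
    gene_states = states, motifs = motifs, orfs = orfs, n_extra = n_extra,
    divergence = div, age = age, env = el, proxy = px,
    features = fv, group = grp$group, group_trace = grp$trace,
    spans_scaffold = spans_sc, locus_start = ls, locus_end = le,
    note = ""), class = "provirus_record")
}

#' @export
print.provirus_record <- function(x, ...) {
  if (!identical(x$type, "provirus")) {
    cat("<provirus_record>", x$sid, "-", x$type, "\n")
    return(invisible(x))
  }
  cat("<provirus_record>", x$id, "\n")
  cat(sprintf("  %d nt | LTR %d nt (id %.1f%%) | TSD %s | PBS %s\n",
              x$size, x$ltr_len, 100 * x$ltr$identity,
              ifelse(x$tsd$status == "present", x$tsd$sequence,
                     x$tsd$status), x$pbs$trna_id))
  if (!is.null(x$gene_states)) {
    st <- vapply(x$gene_states, `[[`, "", "state")
    cat("  genes:", paste(names(st), st, sep = "=", collapse = " "), "\n")
  }
  if (is.na(x$age$T_myr)) cat("  age: ND")
  else cat(sprintf("  age: %.1f Myr (D = %.4f)", x$age$T_myr, x$divergence$D))
  cat("  | group", x$group, "\n")
  invisible(x)
}

#' Run the full discovery pipeline
#'
#' simulate/load -> translated search -> three-gene locus intersection ->
#' delineation -> annotation -> dating -> classification, deterministically
#' under the configured seed. When `out_dir` is set, scaffolds (FASTA),
#' hits (TSV), records (JSON), annotations (GFF3), summary tables (TSV) and
#' the run report (JSON) are written there.
#'
#' @param config a [run_config()].
#' @return list of class `run_report`: `counts`, `records`, `truths` (when
#'   simulated), `hits`, `loci`, `seed`, `version`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  panel <- load_reference_panel()

  truths <- list()
  if (!is.null(config$genome_fasta)) {
    seqs <- read_fasta(config$genome_fasta)
    scaffolds <- lapply(names(seqs), function(id)
      structure(list(id = id, seq = seqs[[id]],
                     n_runs = data.frame(start = integer(0),
                                         end = integer(0))),
                class = "synth_scaffold"))
  } else {
    sim <- simulate_genome(config, panel)
    scaffolds <- sim$scaffolds
    truths <- sim$truths
  }
  seq_by_id <- setNames(lapply(scaffolds, `[[`, "seq"),
                        vapply(scaffolds, `[[`, "", "id"))

  params <- alignment_params(evalue_cutoff = config$evalue_cutoff)
  hits <- search_genome(default_query_set(panel), scaffolds, params)
  loci <- intersect_gene_hits(
    hits, scaffold_lengths = vapply(seq_by_id, nchar, 1L),
    max_span = config$max_span, flank = config$flank)

  records <- list()
  for (i in seq_len(nrow(loci))) {
    rec <- delineate_provirus(seq_by_id[[loci$sid[i]]], loci[i, ], panel,
                              rate = config$rates[[config$clade]],
                              min_orf_codons = config$min_orf_codons)
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  prov <- Filter(function(r) identical(r$type, "provirus"), records)

  report <- structure(list(
    counts = list(
      scaffolds = length(scaffolds), hits = nrow(hits), loci = nrow(loci),
      proviruses = length(prov),
      dated = sum(vapply(prov, function(r) !is.na(r$age$T_myr), TRUE)),
      classified = sum(vapply(prov, function(r)
        !identical(r$group, "unclassified"), TRUE))),
    records = records, truths = truths, hits = hits, loci = loci,
    seed = config$seed,
    version = as.character(utils::packageVersion("proviscan"))),
    class = "run_report")

  if (!is.null(config$out_dir)) write_run_outputs(report, seq_by_id,
                                                  config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "\n")
  cat(sprintf("  %d scaffold(s), %d hit(s), %d locus/loci, %d provirus(es), %d dated, %d classified\n",
              x$counts$scaffolds, x$counts$hits, x$counts$loci,
              x$counts$proviruses, x$counts$dated, x$counts$classified))
  invisible(x)
}

#' Summary tables (census and ages)
#'
#' Builds the two report tables: a provirus census (name, size, per-gene
#' states, extra ORFs, LTR length, PBS) and an age table (divergence, age
#' in Myr with "ND" when the divergence is undefined, sub-group).
#'
#' @param records list of `provirus_record`s (or a `run_report`).
#' @return list with data.frames `census` and `ages`.
#' @export
summarize <- function(records) {
  if (inherits(records, "run_report")) records <- records$records
  records <- Filter(function(r) identical(r$type, "provirus"), records)
  census <- data.frame(name = character(0), size = integer(0),
                       gag = character(0), pro = character(0),
                       pol = character(0), env = character(0),
                       extra_orfs = integer(0), ltr_length = integer(0),
                       pbs = character(0), tsd = character(0),
                       notes = character(0))
  ages <- data.frame(name = character(0), divergence = numeric(0),
                     age_myr = character(0), group = character(0))
  for (r in records) {
    st <- vapply(r$gene_states, `[[`, "", "state")
    census <- rbind(census, data.frame(
      name = r$id, size = r$size,
      gag = st[["gag"]], pro = st[["pro"]], pol = st[["pol"]],
      env = st[["env"]], extra_orfs = r$n_extra,
      ltr_length = r$ltr_len, pbs = r$pbs$trna_id,
      tsd = if (r$tsd$status == "present") r$tsd$sequence else r$tsd$status,
      notes = r$note, stringsAsFactors = FALSE))
    ages <- rbind(ages, data.frame(
      name = r$id, divergence = round(r$divergence$D, 3),
      age_myr = if (is.na(r$age$T_myr)) "ND" else
        sprintf("%.1f", r$age$T_myr),
      group = r$group, stringsAsFactors = FALSE))
  }
  list(census = census, ages = ages)
}
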