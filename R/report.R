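# Orchestration: per-genome profiles, pairwise comparison reports, and
# TSV/JSON twins of both. Every number in a report is regenerable from the
# input genomes and the echoed parameter choices alone.

#' Profile one mitogenome
#'
#' @param genome a `mitogenome`.
#' @param table a [codon_table()].
#' @return List of class `genome_profile`: identity and length, whole-genome
#'   composition and skews, PCG-concatenate and control-region composition,
#'   codon-usage summary (top codons, absent codons), junction totals, gene
#'   order flags, and the full audit.
#' @export
profile_genome <- function(genome, table = codon_table()) {
  comp <- composition_report(genome$sequence)
  pcgs <- intersect(genome$features$name, PCG_GENES)
  pcg_seqs <- vapply(pcgs, function(g) extract_gene(genome, g), character(1))
  pcg_comp <- if (length(pcg_seqs)) composition_report(paste(pcg_seqs, collapse = "")) else NULL
  cr_comp <- if ("CR" %in% genome$features$name)
    composition_report(extract_gene(genome, "CR")) else NULL
  usage <- if (length(pcg_seqs)) codon_usage(pcg_seqs, table) else NULL
  audit <- audit_genome(genome, table)
  sig <- gene_order_signature(genome)
  structure(list(
    identifier = genome$identifier,
    length = genome$length,
    composition = comp,
    pcg_total_bp = sum(nchar(pcg_seqs)),
    pcg_composition = pcg_comp,
    cr_length = if (!is.null(cr_comp)) nchar(extract_gene(genome, "CR")) else NA_integer_,
    cr_composition = cr_comp,
    codon_usage = usage,
    top_codons = if (!is.null(usage)) top_codons(usage, 6) else NULL,
    absent_codons = if (!is.null(usage)) absent_codons(usage) else NULL,
    audit = audit,
    gene_order = sig,
    cw_swap = has_cw_swap(sig),
    family_mode = table$family_mode
  ), class = "genome_profile")
}

#' Compare two mitogenomes
#'
#' Runs the full pairwise analysis: per-gene p-distances over the 13 PCGs
#' and 2 rRNAs with class means, NG86 Ka/Ks per PCG (against each other, or
#' each against `reference` when one is supplied), control-region global
#' alignment gap count, per-tRNA sequence diffs, and the distance-threshold
#' conspecificity verdict.
#'
#' @param genome_a,genome_b `mitogenome` objects.
#' @param reference optional third `mitogenome`; when given, Ka/Ks is
#'   computed for each genome against the reference.
#' @param thresholds conspecific/distinct thresholds passed to
#'   [synonymy_assessment()].
#' @param model distance model, `"p"` (default) or `"jc"`.
#' @param table a [codon_table()].
#' @return List of class `compare_report`.
#' @export
compare_genomes <- function(genome_a, genome_b, reference = NULL,
                            thresholds = c(conspecific_below = 0.01,
                                           distinct_above = 0.03),
                            model = c("p", "jc"), table = codon_table()) {
  model <- match.arg(model)
  dist15 <- gene_set_distances(genome_a, genome_b, model = model)
  pg <- dist15$per_gene
  is_pcg <- pg$gene %in% PCG_GENES
  kaks <- if (is.null(reference)) {
    genome_kaks(genome_a, genome_b, table)
  } else {
    list(a_vs_ref = genome_kaks(genome_a, reference, table),
         b_vs_ref = genome_kaks(genome_b, reference, table))
  }
  cr_gaps <- if (all(c("CR") %in% genome_a$features$name) &&
                 "CR" %in% genome_b$features$name) {
    global_align(extract_gene(genome_a, "CR"), extract_gene(genome_b, "CR"))$gap_columns
  } else NA_integer_
  verdict <- synonymy_assessment(dist15$mean, thresholds, per_gene = pg)
  structure(list(
    a = genome_a$identifier, b = genome_b$identifier,
    parameters = list(thresholds = thresholds, model = model,
                      family_mode = table$family_mode,
                      gap_handling = "pairwise_deletion",
                      alignment = c(match = 1, mismatch = -1, gap = -2)),
    per_gene = pg,
    mean_p_all = dist15$mean_p,
    mean_p_pcg = mean(pg$p[is_pcg]),
    mean_p_rrna = mean(pg$p[!is_pcg]),
    kaks = kaks,
    cr_gap_columns = cr_gaps,
    trna_diffs = diff_trnas(genome_a, genome_b),
    verdict = verdict
  ), class = "compare_report")
}

#' @export
print.compare_report <- function(x, ...) {
  cat(sprintf("<compare_report> %s vs %s\n", x$a, x$b))
  cat(sprintf("  mean p (15 genes): %.4f  [PCG %.4f, rRNA %.4f]\n",
              x$mean_p_all, x$mean_p_pcg, x$mean_p_rrna))
  cat(sprintf("  verdict: %s (thresholds %.3g / %.3g)\n", x$verdict$verdict,
              x$verdict$thresholds[1], x$verdict$thresholds[2]))
  invisible(x)
}

# flatten a report into a numbers-only list for the JSON twin
.report_numbers <- function(report) {
  kk <- report$kaks
  kaks_df <- if (is.data.frame(kk)) kk else kk$a_vs_ref
  list(
    a = report$a, b = report$b,
    parameters = report$parameters,
    per_gene = report$per_gene,
    mean_p_all = report$mean_p_all,
    mean_p_pcg = report$mean_p_pcg,
    mean_p_rrna = report$mean_p_rrna,
    kaks = kaks_df,
    cr_gap_columns = report$cr_gap_columns,
    trna_diff_genes = names(Filter(length, report$trna_diffs)),
    verdict = report$verdict$verdict
  )
}

#' Write a comparison report as TSV and/or JSON twins
#'
#' The TSV carries one row per gene (gene, sites, diffs, p, Ka, Ks, omega)
#' followed by a summary block; the JSON twin contains identical numbers.
#'
#' @param report a [compare_genomes()] result.
#' @param dir output directory (created if needed).
#' @param format `"both"` (default), `"tsv"` or `"json"`.
#' @return Paths of the files written, invisibly.
#' @export
write_report <- function(report, dir, format = c("both", "tsv", "json")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  pg <- report$per_gene
  kk <- if (is.data.frame(report$kaks)) report$kaks else report$kaks$a_vs_ref
  tab <- merge(pg, kk[, c("gene", "Ka", "Ks", "omega")], by = "gene",
               all.x = TRUE, sort = FALSE)
  if (format %in% c("both", "tsv")) {
    p <- file.path(dir, "compare.tsv")
    con <- file(p, "w")
    writeLines(sprintf("# compare %s vs %s", report$a, report$b), con)
    writeLines(sprintf("# model=%s gap_handling=%s thresholds=%g/%g family_mode=%s",
                       report$parameters$model, report$parameters$gap_handling,
                       report$parameters$thresholds[1],
                       report$parameters$thresholds[2],
                       report$parameters$family_mode), con)
    utils::write.table(format(tab, digits = 6), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(sprintf("# mean_p_all\t%.6f", report$mean_p_all), con)
    writeLines(sprintf("# mean_p_pcg\t%.6f", report$mean_p_pcg), con)
    writeLines(sprintf("# mean_p_rrna\t%.6f", report$mean_p_rrna), con)
    writeLines(sprintf("# cr_gap_columns\t%s", report$cr_gap_columns), con)
    writeLines(sprintf("# verdict\t%s", report$verdict$verdict), con)
    close(con)
    paths <- c(paths, p)
  }
  if (format %in% c("both", "json")) {
    p <- file.path(dir, "compare.json")
    jsonlite::write_json(.report_numbers(report), p, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Emit a synthetic fixture to disk
#'
#' Writes GenBank, FASTA, the feature-table TSV, the tRNA structure TSV and
#' (for a mutated pair) the mutation-log JSON.
#'
#' @param genome a generated `mitogenome`.
#' @param dir output directory.
#' @param log optional `mutation_log`.
#' @return Paths written, invisibly.
#' @export
write_fixture <- function(genome, dir, log = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, genome$identifier)
  paths <- c(write_genbank(genome, paste0(base, ".gb")),
             write_fasta(genome, paste0(base, ".fasta")),
             write_feature_table(genome, paste0(base, ".features.tsv")))
  st <- attr(genome, "trna_structures")
  if (!is.null(st))
    paths <- c(paths, write_trna_structures(st, paste0(base, ".trna_structure.tsv")))
  if (!is.null(log)) {
    p <- paste0(base, ".mutation_log.json")
    jsonlite::write_json(list(events = log$events, cr_indels = log$cr_indels,
                              eligible = log$eligible, rates = log$rates,
                              seed = log$seed),
                         p, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    paths <- c(paths, p)
  }
  invisible(paths)
}
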