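# One-call characterization of an annotated mitogenome, and report writing.
# The report bundle mirrors the narrative order of a mitogenome paper:
# organization (annotation echo + junctions + gene order), composition and
# skew per region class, codon usage / RSCU, start/stop classification,
# tRNA summary, and reconciliation notes where printed advisory columns
# disagree with coordinate arithmetic.

#' Characterize an annotated mitogenome
#'
#' Runs every analysis stage this package provides on one genome and
#' returns a single classed result. Stages that need the nucleotide
#' sequence (composition, codon usage, sequence-based stop checks) are
#' skipped with a notice when `seq` is `NULL`; coordinate-based stages
#' always run.
#'
#' @param ann a `mito_annotation`.
#' @param seq optional genome sequence (reference strand).
#' @param codon_mode codon counting mode, see [count_codons()].
#' @param family_map RSCU family map, see [compute_rscu()].
#' @param remnant_threshold control-region remnant cut-off, see
#'   [classify_gene_order()].
#' @param orient_by_strand composition orientation, see
#'   [region_composition_table()].
#' @return an object of class `mito_characterization`: list with
#'   `annotation` (echo with recomputed length/intergenic), `composition`,
#'   `rscu`, `stops`, `architecture`, `gene_order`, `gene_order_class`,
#'   `trna`, `notes`, `config`.
#' @export
characterize <- function(ann, seq = NULL,
                         codon_mode = c("pcg_concat", "whole_genome_frame1"),
                         family_map = "standard", remnant_threshold = 0.5,
                         orient_by_strand = FALSE) {
  codon_mode <- match.arg(codon_mode)
  notes <- character()

  f <- ann$features
  jt <- junction_table(ann)
  echo <- f
  echo$length <- feature_length(f$start, f$stop, ann$length, ann$circular)
  echo$intergenic <- jt$gap[match(f$name, jt$prev)]

  ld <- attr(ann, "length_discrepancies")
  if (!is.null(ld))
    notes <- c(notes, sprintf(
      "printed length %d for %s disagrees with coordinates (recomputed %d)",
      ld$printed, ld$name, ld$recomputed))
  printed_gap <- attr(ann, "printed_intergenic")
  if (!is.null(printed_gap)) {
    cmp <- merge(data.frame(name = f$name, printed = printed_gap),
                 data.frame(name = jt$prev, recomputed = jt$gap), by = "name")
    bad <- cmp[!is.na(cmp$printed) & cmp$printed != cmp$recomputed, ,
               drop = FALSE]
    if (nrow(bad))
      notes <- c(notes, sprintf(
        "printed intergenic %d after %s disagrees with coordinates (recomputed %d)",
        bad$printed, bad$name, bad$recomputed))
  }

  arch <- architecture_summary(jt, ann = ann)
  order <- tryCatch(extract_gene_order(ann), error = function(e) NULL)
  cls <- if (is.null(order)) "unrecognized" else
    classify_gene_order(order, remnant_threshold = remnant_threshold)

  comp <- NULL; rscu <- NULL; stops <- NULL
  if (!is.null(seq) && nzchar(seq)) {
    comp <- region_composition_table(seq, ann,
                                     orient_by_strand = orient_by_strand)
    cc <- count_codons(ann, seq, mode = codon_mode)
    rscu <- compute_rscu(cc, family_map = family_map)
    stops <- withCallingHandlers(
      classify_start_stop(ann, seq),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  } else {
    notes <- c(notes,
               "no sequence supplied: composition and codon stages skipped")
    stops <- if (any(f$type == "PCG")) classify_start_stop(ann) else NULL
  }
  trna <- if (any(f$type == "tRNA")) trna_table(ann) else NULL

  structure(list(
    annotation = echo, composition = comp, rscu = rscu, stops = stops,
    architecture = arch, gene_order = order, gene_order_class = cls,
    trna = trna, notes = notes,
    config = list(codon_mode = codon_mode,
                  family_map = if (is.character(family_map) &&
                                   length(family_map) == 1) family_map
                               else "custom",
                  remnant_threshold = remnant_threshold,
                  orient_by_strand = orient_by_strand)),
    class = "mito_characterization")
}

#' @export
print.mito_characterization <- function(x, digits = 2, ...) {
  a <- x$annotation
  cat(sprintf("Mitogenome characterization (%d features, %s)\n",
              nrow(a), if (is.null(x$composition)) "no sequence"
                       else "with sequence"))
  tab <- table(factor(a$type, levels = c("PCG", "tRNA", "rRNA", "CR")))
  cat(sprintf("  organization: %d PCGs, %d tRNAs, %d rRNAs, %d CRs\n",
              tab["PCG"], tab["tRNA"], tab["rRNA"], tab["CR"]))
  ar <- x$architecture
  if (!is.null(ar$longest_overlap))
    cat(sprintf("  overlaps: %d pairs, %d nt; longest %d nt (%s-%s)\n",
                ar$overlap_pairs, ar$overlap_total, ar$longest_overlap$nt,
                ar$longest_overlap$prev, ar$longest_overlap$nxt))
  if (!is.null(ar$longest_spacer))
    cat(sprintf("  spacers: %d locations, %d nt; longest %d nt (%s-%s)\n",
                ar$spacer_count, ar$spacer_total, ar$longest_spacer$nt,
                ar$longest_spacer$prev, ar$longest_spacer$nxt))
  if (!is.null(x$gene_order))
    cat(sprintf("  gene order: %s -> %s\n",
                paste(x$gene_order, collapse = "/"), x$gene_order_class))
  if (!is.null(x$composition)) {
    cat("  composition (A+T% / AT-skew / GC-skew):\n")
    for (i in seq_len(nrow(x$composition)))
      cat(sprintf("    %-6s %8s bp  %6.2f  %5.2f  %5.2f\n",
                  x$composition$region[i],
                  format(x$composition$size_bp[i], big.mark = ","),
                  round_half_up(x$composition$at_content[i], digits),
                  round_half_up(x$composition$at_skew[i], digits),
                  round_half_up(x$composition$gc_skew[i], digits)))
  }
  if (!is.null(x$stops)) {
    inc <- x$stops$gene[x$stops$stop_kind != "complete"]
    cat(sprintf("  incomplete stop codons: %s\n",
                if (length(inc)) paste(inc, collapse = ", ") else "none"))
  }
  if (length(x$notes)) {
    cat("  reconciliation notes:\n")
    for (n in x$notes) cat("    - ", n, "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.mito_characterization <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$rscu)) {
    fam <- codon_family_totals(object$rscu)
    cat(sprintf("  codons: %d total; most frequent family %s, least %s\n",
                sum(object$rscu$count), attr(fam, "most_frequent"),
                attr(fam, "least_frequent")))
  }
  invisible(object)
}

# TSV with a '# key: value' metadata block recording the flags in force
.write_report_tsv <- function(df, path, config, decimals = 2) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(config))
    writeLines(sprintf("# %s: %s", k, config[[k]]), con)
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], round_half_up, digits = decimals)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a characterization report bundle
#'
#' Emits deterministic (timestamp-free) reports: annotation echo TSV,
#' composition TSV, codon/RSCU TSV, architecture JSON and a one-page text
#' summary. Stages absent from the characterization are skipped.
#'
#' @param x a `mito_characterization`.
#' @param prefix output path prefix.
#' @param decimals rounding for report TSVs (default 2; internal values
#'   are full precision).
#' @return character vector of written paths, invisibly.
#' @export
write_characterization <- function(x, prefix, decimals = 2) {
  cfg <- c(list(tool = "mitocharacter"), x$config)
  paths <- character()
  p <- paste0(prefix, ".annotation.tsv")
  .write_report_tsv(x$annotation, p, cfg, decimals); paths <- c(paths, p)
  if (!is.null(x$composition)) {
    p <- paste0(prefix, ".composition.tsv")
    .write_report_tsv(x$composition, p, cfg, decimals); paths <- c(paths, p)
  }
  if (!is.null(x$rscu)) {
    p <- paste0(prefix, ".codon_usage.tsv")
    .write_report_tsv(x$rscu, p, cfg, decimals); paths <- c(paths, p)
  }
  p <- paste0(prefix, ".architecture.json")
  arch <- x$architecture
  arch$gene_order <- if (is.null(x$gene_order)) NULL else
    paste(x$gene_order, collapse = "/")
  arch$gene_order_class <- x$gene_order_class
  arch$notes <- x$notes
  jsonlite::write_json(arch, p, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths <- c(paths, p)
  p <- paste0(prefix, ".summary.txt")
  con <- file(p, open = "wt"); sink(con)
  tryCatch(print(x), finally = { sink(); close(con) })
  paths <- c(paths, p)
  invisible(paths)
}

#' Run a characterization from file inputs
#'
#' File-level orchestration used by the command-line interface: reads a
#' GenBank record or a feature-table TSV (plus optional FASTA), runs
#' [characterize()], writes the report bundle.
#'
#' @param genbank path to a GenBank flat file (annotation + sequence), or
#'   `NULL`.
#' @param table path to a feature-table TSV (used when `genbank` is
#'   `NULL`).
#' @param fasta optional FASTA with the genome sequence (first record).
#' @param out_prefix output path prefix for the report bundle.
#' @param ... passed to [characterize()].
#' @return the `mito_characterization`, invisibly.
#' @export
run_characterize <- function(genbank = NULL, table = NULL, fasta = NULL,
                             out_prefix = NULL, ...) {
  if (!is.null(genbank)) {
    gb <- parse_genbank(genbank)
    ann <- gb$annotation
    seq <- if (nzchar(gb$sequence)) gb$sequence else NULL
  } else if (!is.null(table)) {
    ann <- read_feature_table(table)
    seq <- NULL
  } else .stop("supply --genbank or --table input")
  if (!is.null(fasta)) seq <- unname(read_fasta(fasta)[1])
  x <- characterize(ann, seq, ...)
  if (!is.null(out_prefix)) write_characterization(x, out_prefix)
  invisible(x)
}
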