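# Reading, validating and writing annotated circular mitogenomes.
#
# Coordinates are 1-based inclusive throughout, matching GenBank and the
# tabular annotations of mitogenome papers. A feature with start > stop on a
# circular genome wraps through the origin. The length and intergenic
# columns of input tables are treated as advisory: the package always
# recomputes them from coordinates and reports discrepancies.

#' Reverse complement of a nucleotide sequence
#'
#' Case-preserving, full-IUPAC reverse complement. Applying it twice returns
#' the input (involution). Characters outside the IUPAC alphabet (including
#' gaps) pass through unchanged.
#'
#' @param seq character vector of nucleotide strings.
#' @return character vector of reverse-complemented strings.
#' @export
#' @examples
#' reverse_complement("ATGAAATAA")  # "TTATTTCAT"
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    comp <- chartr("ACGTRYKMBDHVacgtrykmbdhv",
                   "TGCAYRMKVHDBtgcayrmkvhdb", s)
    .collapse(rev(strsplit(comp, "", fixed = TRUE)[[1]]))
  }, character(1), USE.NAMES = FALSE)
}

#' Length of a feature on a (possibly circular) genome
#'
#' Non-wrapping features have length `stop - start + 1`; a wrapping feature
#' (start > stop) on a circular genome runs through the origin and has
#' length `(genome_length - start + 1) + stop`.
#'
#' @param start,stop 1-based inclusive coordinates (vectorised).
#' @param genome_length total genome length in nucleotides.
#' @param circular is the genome circular? Wrapping features on a
#'   non-circular genome are an error.
#' @return integer vector of lengths in nucleotides.
#' @export
#' @examples
#' feature_length(11867, 13684, 17827)  # 1818
#' feature_length(98, 3, 100)           # wraps: 6
feature_length <- function(start, stop, genome_length, circular = TRUE) {
  wraps <- stop < start
  if (any(wraps) && !circular)
    .stop("wrapping feature (start > stop) on a non-circular genome")
  if (any(start < 1) || any(stop > genome_length))
    .stop("feature coordinates outside [1, genome_length]")
  as.integer(ifelse(wraps, (genome_length - start + 1) + stop,
                    stop - start + 1))
}

#' Extract a strand-oriented feature sequence
#'
#' H-strand features return the reference-strand slice as-is; L-strand
#' features return its reverse complement. Features wrapping the origin of a
#' circular genome are stitched tail + head.
#'
#' @param seq reference (H-strand) genome sequence, one string.
#' @param start,stop 1-based inclusive coordinates.
#' @param strand `"H"` or `"L"`.
#' @param circular is the genome circular?
#' @return the oriented feature sequence as one string.
#' @export
extract_feature_sequence <- function(seq, start, stop, strand = "H",
                                     circular = TRUE) {
  L <- nchar(seq)
  if (start < 1 || stop > L) .stop("feature coordinates outside the sequence")
  if (stop < start) {
    if (!circular) .stop("wrapping feature on a non-circular genome")
    slice <- paste0(substr(seq, start, L), substr(seq, 1, stop))
  } else {
    slice <- substr(seq, start, stop)
  }
  if (identical(strand, "L")) reverse_complement(slice) else slice
}

# feature type inferred from a canonical gene label
.infer_type <- function(name) {
  ifelse(grepl("^(nad|cox|atp|cob)", name), "PCG",
  ifelse(grepl("^trn", name), "tRNA",
  ifelse(grepl("^(12S|16S)", name), "rRNA",
  ifelse(grepl("^CR", name), "CR", "unknown"))))
}

# the versioned alias -> canonical label map shipped with the package
.name_map <- function() {
  .read_tsv_meta(.extdata("gene_name_map.tsv"))$table
}

# normalise a vector of raw gene labels; unknown labels pass through
.normalise_names <- function(raw) {
  map <- .name_map()
  idx <- match(toupper(trimws(raw)), map$alias)
  out <- ifelse(is.na(idx), trimws(raw), map$canonical[idx])
  out
}

#' Build a genome annotation from a feature table
#'
#' The in-memory form of a mitogenome annotation table: an ordered feature
#' list plus genome length and circularity flag. Gene names are normalised
#' through the bundled alias map (e.g. `ND5` -> `nad5`, `D-loop` -> `CR`),
#' control regions are numbered `CR1`, `CR2`, ... by order of appearance,
#' feature types are inferred from the canonical names, and features are
#' sorted by ascending start. A `length` column, when present, is
#' cross-checked against the coordinates; inconsistent rows produce a
#' warning (never an error) and are recorded in
#' `attr(ann, "length_discrepancies")`.
#'
#' @param rows data.frame with at least columns `gene`, `strand`, `start`,
#'   `stop`; optional `length`, `intergenic`, `anticodon`, `start_codon`,
#'   `stop_codon`.
#' @param genome_length total length in nucleotides; inferred as
#'   `max(stop)` (with a warning) when absent.
#' @param circular logical, default `TRUE`.
#' @param genome_id label for the genome.
#' @return an object of class `mito_annotation`: a list with elements
#'   `genome_id`, `length`, `circular` and `features` (a data.frame).
#' @export
parse_feature_table <- function(rows, genome_length = NULL, circular = TRUE,
                                genome_id = "genome") {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (nrow(rows) == 0) .stop("no features")
  need <- c("gene", "strand", "start", "stop")
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols))
    .stop("feature table lacks required column(s): ",
          paste(missing_cols, collapse = ", "))
  if (is.null(genome_length)) {
    genome_length <- max(rows$stop)
    warning("genome length not supplied; inferred as max(stop) = ",
            genome_length, call. = FALSE)
  }
  genome_length <- as.integer(genome_length)
  if (genome_length <= 0) .stop("genome length must be positive")

  name <- .normalise_names(rows$gene)
  # number control regions by order of appearance
  is_cr <- name == "CR" | grepl("^CR[0-9]*$", name)
  if (any(is_cr)) name[is_cr] <- paste0("CR", seq_len(sum(is_cr)))

  feats <- data.frame(
    name = name,
    type = .infer_type(name),
    strand = as.character(rows$strand),
    start = as.integer(rows$start),
    stop = as.integer(rows$stop),
    anticodon = if ("anticodon" %in% names(rows))
      as.character(rows$anticodon) else NA_character_,
    start_codon = if ("start_codon" %in% names(rows))
      as.character(rows$start_codon) else NA_character_,
    stop_codon = if ("stop_codon" %in% names(rows))
      as.character(rows$stop_codon) else NA_character_,
    stringsAsFactors = FALSE
  )
  feats$anticodon[!nzchar(feats$anticodon) | is.na(feats$anticodon)] <- NA
  feats$start_codon[!nzchar(feats$start_codon)] <- NA
  feats$stop_codon[!nzchar(feats$stop_codon)] <- NA
  feats <- feats[order(feats$start), , drop = FALSE]
  rownames(feats) <- NULL

  ann <- structure(
    list(genome_id = genome_id, length = genome_length,
         circular = isTRUE(circular), features = feats),
    class = "mito_annotation")
  .validate_annotation(ann)

  # advisory intergenic column: kept for reconciliation reports only
  if ("intergenic" %in% names(rows)) {
    ord <- order(as.integer(rows$start))
    attr(ann, "printed_intergenic") <-
      suppressWarnings(as.integer(rows$intergenic))[ord]
  }

  # advisory length column: recompute and flag, never trust
  if ("length" %in% names(rows)) {
    printed <- as.integer(rows$length)[order(as.integer(rows$start))]
    recomputed <- feature_length(feats$start, feats$stop, genome_length,
                                 circular = isTRUE(circular))
    bad <- which(!is.na(printed) & printed != recomputed)
    if (length(bad)) {
      attr(ann, "length_discrepancies") <- data.frame(
        name = feats$name[bad], printed = printed[bad],
        recomputed = recomputed[bad], stringsAsFactors = FALSE)
      warning("length column inconsistent with coordinates for: ",
              paste(feats$name[bad], collapse = ", "), call. = FALSE)
    }
  }
  ann
}

# structural checks shared by all constructors
.validate_annotation <- function(ann) {
  f <- ann$features
  if (anyDuplicated(f$name))
    .stop("duplicate feature names: ",
          paste(unique(f$name[duplicated(f$name)]), collapse = ", "))
  if (any(f$start < 1) || any(f$stop > ann$length))
    .stop("feature coordinates outside [1, genome length] for: ",
          paste(f$name[f$start < 1 | f$stop > ann$length], collapse = ", "))
  if (!ann$circular && any(f$stop < f$start))
    .stop("wrapping feature on a non-circular genome")
  if (!all(f$strand %in% c("H", "L")))
    .stop("strand must be 'H' or 'L'")
  invisible(ann)
}

#' Read a feature table TSV
#'
#' Reads a UTF-8 tab-delimited annotation with a header row and optional
#' `# key: value` metadata lines (`genome_id`, `length`, `circular`).
#'
#' @param path file path.
#' @inheritParams parse_feature_table
#' @return a `mito_annotation`.
#' @export
read_feature_table <- function(path, genome_length = NULL, circular = NULL,
                               genome_id = NULL) {
  parsed <- .read_tsv_meta(path)
  meta <- parsed$meta
  if (is.null(genome_length) && !is.null(meta$length))
    genome_length <- as.integer(meta$length)
  if (is.null(circular))
    circular <- if (!is.null(meta$circular))
      tolower(meta$circular) %in% c("true", "yes", "1") else TRUE
  if (is.null(genome_id))
    genome_id <- if (!is.null(meta$genome_id)) meta$genome_id
      else sub("\\.[^.]*$", "", basename(path))
  parse_feature_table(parsed$table, genome_length = genome_length,
                      circular = circular, genome_id = genome_id)
}

#' Write a normalised feature table TSV
#'
#' Emits the annotation with recomputed `length` and `intergenic` columns
#' and a `# key: value` metadata header, the inverse of
#' [read_feature_table()] (round-trip safe).
#'
#' @param ann a `mito_annotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ann, path) {
  f <- ann$features
  f$length <- feature_length(f$start, f$stop, ann$length, ann$circular)
  f$intergenic <- if (nrow(f) >= 2) {
    jt <- junction_table(ann)
    jt$gap[match(f$name, jt$prev)]
  } else NA_integer_
  out <- f[, c("name", "strand", "start", "stop", "length", "intergenic",
               "anticodon", "start_codon", "stop_codon")]
  names(out)[1] <- "gene"
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("# genome_id: ", ann$genome_id),
               paste0("# length: ", ann$length),
               paste0("# circular: ", tolower(as.character(ann$circular)))),
             con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @export
print.mito_annotation <- function(x, ...) {
  f <- x$features
  cat(sprintf("<mito_annotation> %s: %s bp, %s, %d features\n",
              x$genome_id, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear", nrow(f)))
  tab <- table(factor(f$type, levels = c("PCG", "tRNA", "rRNA", "CR",
                                         "unknown")))
  tab <- tab[tab > 0]
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Validate a sequence against its annotation
#'
#' Produces a machine-readable validation report: non-ACGT characters in the
#' sequence (flagged, never altered), features whose coordinates fall
#' outside the sequence, and advisory-column discrepancies carried by the
#' annotation.
#'
#' @param ann a `mito_annotation`.
#' @param seq optional genome sequence.
#' @return a list (JSON-serialisable) with elements `genome_id`, `ok`,
#'   `issues` (character vector) and `length_discrepancies`.
#' @export
validate_annotation <- function(ann, seq = NULL) {
  issues <- character()
  if (!is.null(seq)) {
    if (nchar(seq) != ann$length)
      issues <- c(issues, sprintf(
        "sequence length %d does not match annotated genome length %d",
        nchar(seq), ann$length))
    n_other <- nchar(gsub("[ACGTacgt]", "", seq))
    if (n_other > 0)
      issues <- c(issues, sprintf(
        "%d non-ACGT character(s) in the sequence (kept, excluded from composition denominators)",
        n_other))
  }
  ld <- attr(ann, "length_discrepancies")
  if (!is.null(ld))
    issues <- c(issues, sprintf(
      "length column disagrees with coordinates for %s",
      paste(ld$name, collapse = ", ")))
  list(genome_id = ann$genome_id, ok = length(issues) == 0L,
       issues = issues,
       length_discrepancies = if (is.null(ld)) list() else ld)
}

#' Read a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    .stop("reading FASTA requires the Biostrings package")
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    .stop("writing FASTA requires the Biostrings package")
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
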