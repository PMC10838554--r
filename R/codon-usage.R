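# Codon counting, relative synonymous codon usage (RSCU), and start/stop
# codon classification, including the incomplete (T--/TA-) stops completed
# post-transcriptionally by polyadenylation in animal mitochondria.

#' Split a CDS into codons
#'
#' @param cds nucleotide string (strand-oriented).
#' @return list with `codons` (character vector of uppercase DNA 3-mers, in
#'   order) and `tail` (the residual 0-2 nt, never counted as a codon).
#' @export
#' @examples
#' extract_codons("ATGAAAT")  # 2 codons, tail "T"
extract_codons <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  k <- n %/% 3
  codons <- if (k > 0)
    substring(cds, seq(1, by = 3, length.out = k),
              seq(3, by = 3, length.out = k))
  else character()
  list(codons = codons, tail = if (n %% 3) substr(cds, 3 * k + 1, n) else "")
}

#' Count codons over a genome annotation
#'
#' Two counting modes are provided because published mitogenome codon
#' tables are built both ways:
#' * `"pcg_concat"` (default): the strand-oriented CDS of each
#'   protein-coding gene, concatenated gene by gene; only complete codons
#'   are counted (a 1-2 nt incomplete terminal codon is dropped).
#' * `"whole_genome_frame1"`: the entire reference sequence read in frame 1
#'   (total = `floor(genome_length/3)`), the construction some published
#'   tables evidently use despite their caption.
#'
#' @param ann a `mito_annotation`.
#' @param seq genome sequence (reference strand).
#' @param mode `"pcg_concat"` or `"whole_genome_frame1"`.
#' @return an object of class `codon_counts`: list with `counts` (named
#'   integer vector over the 64 RNA codons), `total` and `source`.
#' @export
count_codons <- function(ann, seq,
                         mode = c("pcg_concat", "whole_genome_frame1")) {
  mode <- match.arg(mode)
  if (mode == "pcg_concat") {
    f <- ann$features
    pcgs <- which(f$type == "PCG")
    if (!length(pcgs)) .stop("annotation has no protein-coding genes")
    codons <- character()
    for (i in pcgs) {
      cds <- extract_feature_sequence(seq, f$start[i], f$stop[i],
                                      strand = f$strand[i],
                                      circular = ann$circular)
      if (nchar(cds) < 3)
        .stop("protein-coding gene shorter than one codon: ", f$name[i])
      codons <- c(codons, extract_codons(cds)$codons)
    }
  } else {
    codons <- extract_codons(seq)$codons
  }
  rna <- .to_rna(codons)
  counts <- table(factor(rna, levels = .codons_rna))
  counts <- stats::setNames(as.integer(counts), .codons_rna)
  structure(list(counts = counts, total = sum(counts), source = mode),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat(sprintf("<codon_counts> %d codons (%s), %d distinct\n",
              x$total, x$source, sum(x$counts > 0)))
  invisible(x)
}

#' Relative synonymous codon usage
#'
#' `RSCU(c) = count(c) * n_family / sum(family counts)`: the observed count
#' of a codon divided by its expectation under uniform usage within its
#' synonymous family. Within every family with a positive total the RSCU
#' values sum to the family size (mean 1); single-member families have
#' RSCU 1 whenever observed. Families with zero total get `NA`.
#'
#' @param cc a `codon_counts`, or a named count vector over the 64 codons
#'   (RNA or DNA alphabet).
#' @param family_map `"standard"` (default; the grouping conventional
#'   mitogenome RSCU tables obey) or `"vertmito"`, or a named
#'   codon -> family character vector partitioning all 64 codons.
#' @return data.frame with columns `codon` (RNA), `aa` (family label),
#'   `count`, `rscu` (full precision), ordered as the conventional codon
#'   table.
#' @export
#' @examples
#' cc <- c(UUU = 56, UUC = 154)
#' compute_rscu(cc)[compute_rscu(cc)$codon == "UUC", "rscu"]  # 1.4667
compute_rscu <- function(cc, family_map = "standard") {
  counts <- if (inherits(cc, "codon_counts")) cc$counts else cc
  if (is.null(names(counts))) .stop("counts must be named by codon")
  names(counts) <- .to_rna(names(counts))
  full <- stats::setNames(integer(64), .codons_rna)
  unknown <- setdiff(names(counts), .codons_rna)
  if (length(unknown)) .stop("unknown codon(s): ",
                             paste(unknown, collapse = ", "))
  full[names(counts)] <- as.integer(counts)

  fam <- if (is.character(family_map) && length(family_map) == 1)
    codon_family_map(family_map) else family_map
  if (!setequal(names(fam), .codons_rna) || anyDuplicated(names(fam)))
    .stop("family_map is not a partition of the 64 codons")
  fam <- fam[.codons_rna]

  rscu <- rep(NA_real_, 64)
  for (f in unique(fam)) {
    idx <- which(fam == f)
    tot <- sum(full[idx])
    if (tot > 0) rscu[idx] <- full[idx] * length(idx) / tot
  }
  data.frame(codon = .codons_rna, aa = unname(fam),
             count = unname(full), rscu = rscu, stringsAsFactors = FALSE)
}

# stop-codon kind implied by CDS length alone: a CDS whose length is
# 1 mod 3 ends in a single T completed to TAA by polyadenylation; 2 mod 3
# ends in TA
stop_kind_from_length <- function(len) {
  c("complete", "incomplete_T", "incomplete_TA")[(len %% 3) + 1]
}

#' Classify start and stop codons of protein-coding genes
#'
#' The stop kind is determined by CDS length modulo 3 (0: complete
#' three-base stop; 1: incomplete single-T stop rendered `"T(AA)"`; 2:
#' incomplete TA stop rendered `"TA(A)"`). With a sequence, the terminal
#' bases are checked: a complete stop outside \{TAA, TAG, AGA, AGG\} (the
#' vertebrate mitochondrial stops), an incomplete-T stop not ending in T,
#' or an incomplete-TA stop not ending in TA is flagged in the `note`
#' column. Without a sequence the classification relies on coordinates and
#' any start/stop codon columns carried by the annotation.
#'
#' @param ann a `mito_annotation`.
#' @param seq optional genome sequence.
#' @return data.frame with one row per PCG: `gene`, `length`,
#'   `start_codon`, `stop_kind`, `stop_text`, `note`.
#' @export
classify_start_stop <- function(ann, seq = NULL) {
  f <- ann$features
  pcgs <- which(f$type == "PCG")
  if (!length(pcgs)) .stop("annotation has no protein-coding genes")
  len <- feature_length(f$start[pcgs], f$stop[pcgs], ann$length,
                        ann$circular)
  kind <- stop_kind_from_length(len)
  start_codon <- f$start_codon[pcgs]
  stop_text <- character(length(pcgs))
  note <- rep("", length(pcgs))
  for (k in seq_along(pcgs)) {
    i <- pcgs[k]
    if (!is.null(seq)) {
      cds <- extract_feature_sequence(seq, f$start[i], f$stop[i],
                                      strand = f$strand[i],
                                      circular = ann$circular)
      start_codon[k] <- substr(cds, 1, 3)
      n <- nchar(cds)
      if (kind[k] == "complete") {
        last3 <- substr(cds, n - 2, n)
        stop_text[k] <- last3
        if (!last3 %in% .vertmito_stops)
          note[k] <- paste0("non-canonical complete stop ", last3)
      } else if (kind[k] == "incomplete_T") {
        last1 <- substr(cds, n, n)
        stop_text[k] <- "T(AA)"
        if (last1 != "T")
          note[k] <- paste0("incomplete stop expected terminal T, found ",
                            last1)
      } else {
        last2 <- substr(cds, n - 1, n)
        stop_text[k] <- "TA(A)"
        if (last2 != "TA")
          note[k] <- paste0("incomplete stop expected terminal TA, found ",
                            last2)
      }
      if (start_codon[k] != "ATG")
        note[k] <- trimws(paste(note[k], "non-ATG start"), which = "left")
    } else {
      stop_text[k] <- switch(kind[k],
        complete = if (!is.na(f$stop_codon[i])) f$stop_codon[i] else "",
        incomplete_T = "T(AA)", incomplete_TA = "TA(A)")
    }
  }
  for (msg in note[nzchar(note)])
    warning(msg, call. = FALSE)
  data.frame(gene = f$name[pcgs], length = len, start_codon = start_codon,
             stop_kind = kind, stop_text = stop_text, note = note,
             stringsAsFactors = FALSE)
}

#' Per-family codon totals and frequency ranking
#'
#' Sums codon counts within each amino-acid family and ranks families by
#' total usage, ties broken alphabetically. The stop family (`"*"`) is
#' excluded from the most/least-frequent call-out (it does not encode an
#' amino acid) but kept in the table.
#'
#' @param rt an RSCU table from [compute_rscu()].
#' @return data.frame `aa`, `total`, sorted by decreasing total then
#'   alphabetically, with attributes `most_frequent` and `least_frequent`
#'   (coding families only; `NULL` when all totals are zero).
#' @export
codon_family_totals <- function(rt) {
  tot <- stats::aggregate(count ~ aa, data = rt, FUN = sum)
  tot <- tot[order(-tot$count, tot$aa), , drop = FALSE]
  names(tot) <- c("aa", "total")
  rownames(tot) <- NULL
  coding <- tot[tot$aa != "*" & tot$total > 0, , drop = FALSE]
  attr(tot, "most_frequent") <- if (nrow(coding))
    sort(coding$aa[coding$total == max(coding$total)])[1] else NULL
  attr(tot, "least_frequent") <- if (nrow(coding))
    sort(coding$aa[coding$total == min(coding$total)])[1] else NULL
  tot
}
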