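# Seeded synthetic circular mitogenomes with recorded ground truth.
#
# The default spec is architecture-isomorphic to a real duplicate-CR avian
# mitogenome: gene order, per-gene lengths, strands and junction gaps follow
# the published annotation of the Pterorhinus chinensis mitogenome, and the
# default base composition matches its whole-genome composition — the
# generated genome shares that architecture without containing its
# sequence. Protein-coding genes begin with ATG and end with a planned
# complete or incomplete stop; L-strand features are embedded as reverse
# complements. All sampling flows through R's RNG seeded once per spec.

# architecture template tables ------------------------------------------

.template_duplicate_CR <- function() {
  # genome order, lengths and computed junction gaps of the reference
  # duplicate-CR annotation (gap = nucleotides after the feature; the last
  # gap closes the circle)
  name <- c("trnF", "12S", "trnV", "16S", "trnL2", "nad1", "trnI", "trnQ",
            "trnM", "nad2", "trnW", "trnA", "trnN", "trnC", "trnY", "cox1",
            "trnS2", "trnD", "cox2", "trnK", "atp8", "atp6", "cox3", "trnG",
            "nad3", "trnR", "nad4l", "nad4", "trnH", "trnS1", "trnL1",
            "nad5", "cob", "trnT", "CR1", "trnP", "nad6", "trnE", "CR2")
  length <- c(70, 987, 70, 1590, 75, 978, 74, 71, 69, 1041, 71, 69, 73, 66,
              71, 1551, 73, 69, 684, 70, 168, 684, 784, 69, 351, 70, 297,
              1378, 70, 66, 71, 1818, 1143, 69, 664, 69, 519, 72, 679)
  gap <- c(-1, -1, 7, 1, 14, 8, 5, -1, 0, -1, 1, 10, 1, -1, 1, -9, 4, 10,
           0, 1, -10, 5, 0, 0, -1, 1, -7, 0, 0, -1, 0, 8, 3, 311, 126, 6,
           1, 297, 176)
  strand <- ifelse(name %in% c("trnQ", "trnA", "trnN", "trnC", "trnY",
                               "trnS2", "trnP", "nad6", "trnE"), "L", "H")
  data.frame(name = name, strand = strand, length = length, gap = gap,
             stringsAsFactors = FALSE)
}

.template_ancestral <- function() {
  t <- .template_duplicate_CR()
  # single control region between trnE and trnF; drop CR1, put trnP
  # directly after trnT
  t <- t[t$name != "CR1", , drop = FALSE]
  t$name[t$name == "CR2"] <- "CR"
  t$length[t$name == "CR"] <- 1158   # typical single avian control region
  t$gap[t$name == "trnT"] <- 1
  rownames(t) <- NULL
  t
}

.template_remnant_CR2 <- function() {
  t <- .template_duplicate_CR()
  t$length[t$name == "CR2"] <- 60    # degenerate second copy
  t
}

.template_duplicate_trnT_CR <- function() {
  t <- .template_duplicate_CR()
  i <- which(t$name == "CR1")
  dup <- t[t$name == "trnT", , drop = FALSE]
  dup$name <- "trnT_2"
  dup$gap <- 2
  t <- rbind(t[1:i, , drop = FALSE], dup,
             t[(i + 1):nrow(t), , drop = FALSE])
  rownames(t) <- NULL
  t
}

.templates <- function() list(
  duplicate_CR = .template_duplicate_CR,
  ancestral = .template_ancestral,
  remnant_CR2 = .template_remnant_CR2,
  duplicate_trnT_CR = .template_duplicate_trnT_CR)

#' Specify a synthetic mitogenome
#'
#' Describes the world to generate: a gene-order template, per-feature
#' lengths, a per-junction signed gap plan (negative = overlap; the last
#' gap closes the circle), a base-composition target and optional
#' per-codon sampling weights. Defaults are the published duplicate-CR
#' architecture and whole-genome composition (A 29.45%, C 32.81%,
#' G 14.48%, T 23.26%).
#'
#' @param template one of `"duplicate_CR"`, `"ancestral"`,
#'   `"remnant_CR2"`, `"duplicate_trnT_CR"`.
#' @param gene_lengths optional named vector overriding template lengths.
#' @param gaps optional named vector overriding template junction gaps
#'   (named by the preceding feature).
#' @param base_comp length-4 named vector (A, C, G, T) of target
#'   proportions; normalised to sum to 1.
#' @param rscu_weights optional named per-codon weights (RNA alphabet) for
#'   protein-coding body codons; default uniform.
#' @param seed integer RNG seed.
#' @return an object of class `mito_synthetic_spec`.
#' @export
synthetic_spec <- function(template = "duplicate_CR", gene_lengths = NULL,
                           gaps = NULL,
                           base_comp = c(A = 0.2945, C = 0.3281,
                                         G = 0.1448, T = 0.2326),
                           rscu_weights = NULL, seed = 1L) {
  tpl <- .templates()
  if (!template %in% names(tpl))
    .stop("unknown template: ", template, " (available: ",
          paste(names(tpl), collapse = ", "), ")")
  plan <- tpl[[template]]()
  if (!is.null(gene_lengths)) {
    bad <- setdiff(names(gene_lengths), plan$name)
    if (length(bad)) .stop("gene_lengths names not in template: ",
                           paste(bad, collapse = ", "))
    plan$length[match(names(gene_lengths), plan$name)] <-
      as.integer(gene_lengths)
  }
  if (!is.null(gaps)) {
    bad <- setdiff(names(gaps), plan$name)
    if (length(bad)) .stop("gap names not in template: ",
                           paste(bad, collapse = ", "))
    plan$gap[match(names(gaps), plan$name)] <- as.integer(gaps)
  }
  if (any(plan$length < 1)) .stop("all gene lengths must be >= 1")
  if (!setequal(names(base_comp), c("A", "C", "G", "T")))
    .stop("base_comp must be named A, C, G, T")
  if (any(base_comp < 0) || sum(base_comp) <= 0)
    .stop("base_comp must be a non-negative simplex")
  base_comp <- base_comp[c("A", "C", "G", "T")] / sum(base_comp)
  genome_length <- sum(plan$length) + sum(plan$gap)
  if (genome_length <= 0)
    .stop("unrealizable spec: genome length ", genome_length)
  structure(list(template = template, plan = plan, base_comp = base_comp,
                 rscu_weights = rscu_weights,
                 genome_length = as.integer(genome_length),
                 seed = as.integer(seed)),
            class = "mito_synthetic_spec")
}

#' @export
print.mito_synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<mito_synthetic_spec> template %s: %d features, %d bp, seed %d\n",
    x$template, nrow(x$plan), x$genome_length, x$seed))
  invisible(x)
}

#' Sample codons with a target usage bias
#'
#' Multinomial codon sampling with probabilities proportional to per-codon
#' weights, so within each synonymous family the expected usage is
#' proportional to the weights (empirical RSCU converges to the weights'
#' RSCU as n grows). Used by the genome generator for protein-coding gene
#' bodies (with stop codons excluded) and directly for calibration checks.
#'
#' @param rscu_target named non-negative weights over codons (RNA or DNA
#'   alphabet); default uniform over all 64.
#' @param n number of codons to draw.
#' @param seed optional seed applied before sampling.
#' @param exclude codons (RNA or DNA) to exclude (weight forced to 0).
#' @return character vector of `n` RNA codons.
#' @export
sample_codons <- function(rscu_target = NULL, n, seed = NULL,
                          exclude = character()) {
  if (n < 0) .stop("n must be non-negative")
  w <- stats::setNames(rep(1, 64), .codons_rna)
  if (!is.null(rscu_target)) {
    if (is.null(names(rscu_target))) .stop("rscu_target must be named")
    if (any(rscu_target < 0)) .stop("weights must be non-negative")
    w[] <- 0
    w[.to_rna(names(rscu_target))] <- rscu_target
  }
  if (length(exclude)) w[.to_rna(exclude)] <- 0
  if (sum(w) <= 0) .stop("all codon weights are zero")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(character())
  sample(.codons_rna, n, replace = TRUE, prob = w)
}

# write an oriented base string into the circular genome character vector;
# 'pos1' is the oriented 1-based offset of 'content' within the feature
.stamp <- function(chars, start, stop, strand, L, pos1, content) {
  b <- strsplit(content, "", fixed = TRUE)[[1]]
  for (k in seq_along(b)) {
    j <- pos1 + k - 1                       # oriented position in feature
    ref <- if (strand == "H") start + j - 1 else stop - j + 1
    ref <- ((ref - 1) %% L) + 1
    chars[ref] <- if (strand == "H") b[k] else
      chartr("ACGT", "TGCA", b[k])
  }
  chars
}

#' Generate a synthetic annotated mitogenome
#'
#' Lays the template's features around the circle according to the gap
#' plan, fills the genome from the base-composition model, writes codon
#' content into every protein-coding gene (ATG start, biased body codons
#' free of in-frame stops, and a complete TAA or length-determined
#' incomplete T/TA stop), then re-stamps each PCG's start and stop bases so
#' the start/stop contract survives gene overlaps. Deterministic given the
#' spec's seed.
#'
#' @param spec a `mito_synthetic_spec`.
#' @return list with `sequence` (uppercase string), `annotation` (a
#'   `mito_annotation`) and `truth` (recorded ground truth: junction gaps,
#'   per-class base tallies, per-gene codon lists and counts, stop plan,
#'   gene-order class, seed). Use [write_synthetic()] to emit files.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "mito_synthetic_spec"))
  plan <- spec$plan
  L <- spec$genome_length
  set.seed(spec$seed)

  # coordinates from the gap plan
  start <- integer(nrow(plan)); stop <- integer(nrow(plan))
  pos <- 1L
  for (i in seq_len(nrow(plan))) {
    start[i] <- ((pos - 1L) %% L) + 1L
    stop_raw <- pos + plan$length[i] - 1L
    stop[i] <- ((stop_raw - 1L) %% L) + 1L
    pos <- stop_raw + plan$gap[i] + 1L
  }
  if (pos != L + 1L)
    .stop("unrealizable spec: features + gaps do not close the circle")

  # base fill from the composition model
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = spec$base_comp)

  # protein-coding content
  is_pcg <- .infer_type(plan$name) == "PCG"
  stop_plan <- character(nrow(plan))
  for (i in which(is_pcg)) {
    len <- plan$length[i]
    if (len < 6) .stop("PCG too short for start + stop: ", plan$name[i])
    r <- len %% 3
    n_body <- (len - 3 - r) / 3 - (if (r == 0) 1 else 0)
    body <- .to_dna(sample_codons(spec$rscu_weights, n_body,
                                  exclude = .vertmito_stops))
    tail <- switch(as.character(r), "0" = "TAA", "1" = "T", "2" = "TA")
    stop_plan[i] <- switch(as.character(r),
                           "0" = "TAA", "1" = "T(AA)", "2" = "TA(A)")
    cds <- paste0("ATG", .collapse(body), tail)
    chars <- .stamp(chars, start[i], stop[i], plan$strand[i], L, 1, cds)
  }
  # re-stamp starts and stop tails so overlapping neighbours cannot have
  # clobbered them
  for (i in which(is_pcg)) {
    len <- plan$length[i]
    r <- len %% 3
    tail <- switch(as.character(r), "0" = "TAA", "1" = "T", "2" = "TA")
    chars <- .stamp(chars, start[i], stop[i], plan$strand[i], L, 1, "ATG")
    chars <- .stamp(chars, start[i], stop[i], plan$strand[i], L,
                    len - nchar(tail) + 1, tail)
  }
  seq <- .collapse(chars)

  anticodons <- local({
    canon <- utils::read.delim(.extdata("vertebrate_mito_anticodons.tsv"),
                               stringsAsFactors = FALSE)
    canon$anticodon[match(sub("_.*$", "", plan$name), canon$gene)]
  })
  ann <- parse_feature_table(
    data.frame(gene = plan$name, strand = plan$strand, start = start,
               stop = stop, anticodon = anticodons,
               stringsAsFactors = FALSE),
    genome_length = L, circular = TRUE,
    genome_id = paste0("synthetic_", spec$template, "_seed", spec$seed))

  # ground truth, measured on the realized sequence
  f_order <- order(start)
  class_tally <- function(type) {
    idx <- f_order[.infer_type(plan$name[f_order]) == type]
    if (!length(idx)) return(NULL)
    s <- .collapse(vapply(idx, function(i) extract_feature_sequence(
      seq, start[i], stop[i], strand = "H", circular = TRUE), character(1)))
    ch <- .chars(s)
    c(A = sum(ch == "A"), C = sum(ch == "C"),
      G = sum(ch == "G"), T = sum(ch == "T"))
  }
  ch_all <- .chars(seq)
  tallies <- Filter(Negate(is.null), list(
    mtDNA = c(A = sum(ch_all == "A"), C = sum(ch_all == "C"),
              G = sum(ch_all == "G"), T = sum(ch_all == "T")),
    PCGs = class_tally("PCG"), tRNAs = class_tally("tRNA"),
    rRNAs = class_tally("rRNA"), CRs = class_tally("CR")))

  pcg_codons <- list()
  for (i in which(is_pcg)) {
    cds <- extract_feature_sequence(seq, start[i], stop[i],
                                    strand = plan$strand[i], circular = TRUE)
    pcg_codons[[plan$name[i]]] <- extract_codons(cds)$codons
  }
  codon_counts <- table(factor(.to_rna(unlist(pcg_codons)),
                               levels = .codons_rna))
  codon_counts <- stats::setNames(as.integer(codon_counts), .codons_rna)

  # name junction gaps by the annotation's (possibly renumbered) labels
  gaps <- stats::setNames(plan$gap,
                          ann$features$name[match(start,
                                                  ann$features$start)])
  truth <- list(
    template = spec$template,
    gene_order_class = spec$template,
    genome_length = L,
    junction_gaps = gaps,
    class_tallies = tallies,
    pcg_codon_counts = codon_counts,
    pcg_codons = pcg_codons,
    stop_plan = stats::setNames(stop_plan[is_pcg], plan$name[is_pcg]),
    seed = spec$seed)
  list(sequence = seq, annotation = ann, truth = truth)
}

#' Write a generated genome to FASTA, GenBank and truth JSON
#'
#' @param genome result of [generate_genome()].
#' @param prefix output path prefix; writes `<prefix>.fasta`, `<prefix>.gb`
#'   and `<prefix>.truth.json`.
#' @return character vector of written paths, invisibly.
#' @export
write_synthetic <- function(genome, prefix) {
  fa <- paste0(prefix, ".fasta")
  gb <- paste0(prefix, ".gb")
  js <- paste0(prefix, ".truth.json")
  write_fasta(stats::setNames(genome$sequence,
                              genome$annotation$genome_id), fa)
  write_genbank(genome$annotation, genome$sequence, gb)
  truth <- genome$truth
  truth$pcg_codons <- NULL   # bulky; counts carry the same information
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA)
  invisible(c(fa, gb, js))
}
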