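# 13-PCG supermatrix preparation and a light distance-tree preview.
# Heavy inference (model selection, Bayesian/ML search) stays external;
# this module only concatenates, measures p-distances and builds a
# neighbor-joining preview tree.

# fixed concatenation order for the 13 vertebrate mitochondrial PCGs
.pcg_order <- c("nad1", "nad2", "cox1", "cox2", "atp8", "atp6", "cox3",
                "nad3", "nad4l", "nad4", "nad5", "cob", "nad6")

#' Concatenate the 13 protein-coding genes across genomes
#'
#' Builds a supermatrix from strand-oriented CDS blocks in the fixed gene
#' order nad1, nad2, cox1, cox2, atp8, atp6, cox3, nad3, nad4l, nad4,
#' nad5, cob, nad6. No alignment is performed: within each gene block the
#' sequences are padded with `-` at the 3' end to the longest copy. Use
#' pre-aligned per-gene sequences (all the same length) to bypass padding.
#'
#' @param genomes named list; each element a list with `annotation` (a
#'   `mito_annotation`) and `sequence` (reference-strand string). Names are
#'   the taxon labels.
#' @return an object of class `pcg_supermatrix`: list with `taxa`,
#'   `sequences` (named equal-length strings) and `partitions` (data.frame
#'   `gene`, `start`, `end`, 1-based inclusive columns).
#' @export
concatenate_pcgs <- function(genomes) {
  if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
    .stop("genomes must be a named list (taxon labels)")
  taxa <- names(genomes)
  per_gene <- list()
  for (g in .pcg_order) {
    block <- vapply(taxa, function(tx) {
      ann <- genomes[[tx]]$annotation
      f <- ann$features
      i <- which(f$name == g)
      if (!length(i))
        .stop("taxon ", tx, " lacks protein-coding gene ", g)
      extract_feature_sequence(genomes[[tx]]$sequence, f$start[i], f$stop[i],
                               strand = f$strand[i], circular = ann$circular)
    }, character(1))
    width <- max(nchar(block))
    block <- vapply(block, function(s)
      paste0(s, strrep("-", width - nchar(s))), character(1))
    per_gene[[g]] <- block
  }
  widths <- vapply(per_gene, function(b) nchar(b[1]), integer(1))
  ends <- cumsum(widths)
  parts <- data.frame(gene = .pcg_order,
                      start = c(1L, utils::head(ends, -1) + 1L),
                      end = ends, stringsAsFactors = FALSE)
  seqs <- vapply(taxa, function(tx)
    .collapse(vapply(per_gene, `[[`, character(1), tx)), character(1))
  structure(list(taxa = taxa, sequences = seqs, partitions = parts),
            class = "pcg_supermatrix")
}

#' @export
print.pcg_supermatrix <- function(x, ...) {
  cat(sprintf("<pcg_supermatrix> %d taxa x %d columns, %d partitions\n",
              length(x$taxa), nchar(x$sequences[1]), nrow(x$partitions)))
  invisible(x)
}

#' Write a supermatrix to FASTA, relaxed PHYLIP and a partition file
#'
#' @param sm a `pcg_supermatrix`.
#' @param prefix output path prefix; writes `<prefix>.fasta`,
#'   `<prefix>.phy` and `<prefix>.partitions.txt` (RAxML-style `DNA, gene =
#'   start-end` lines).
#' @return character vector of the written paths, invisibly.
#' @export
write_supermatrix <- function(sm, prefix) {
  fa <- paste0(prefix, ".fasta")
  phy <- paste0(prefix, ".phy")
  part <- paste0(prefix, ".partitions.txt")
  write_fasta(sm$sequences, fa)
  writeLines(c(sprintf("%d %d", length(sm$taxa), nchar(sm$sequences[1])),
               sprintf("%s  %s", sm$taxa, sm$sequences)), phy)
  writeLines(sprintf("DNA, %s = %d-%d", sm$partitions$gene,
                     sm$partitions$start, sm$partitions$end), part)
  invisible(c(fa, phy, part))
}

#' Pairwise p-distance matrix
#'
#' Proportion of differing sites over the sites where both sequences carry
#' an unambiguous A/C/G/T base (gaps and ambiguity codes are pairwise
#' deleted). `NA` where no site is comparable.
#'
#' @param sm a `pcg_supermatrix`, or a named character vector of
#'   equal-length sequences.
#' @return symmetric matrix with zero diagonal, taxa as dimnames.
#' @export
p_distance_matrix <- function(sm) {
  seqs <- if (inherits(sm, "pcg_supermatrix")) sm$sequences else sm
  if (length(seqs) < 2) .stop("need at least two taxa")
  if (length(unique(nchar(seqs))) != 1)
    .stop("sequences must be equal length")
  m <- do.call(rbind, lapply(seqs, .chars))
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- ok[i, ] & ok[j, ]
    d[i, j] <- d[j, i] <- if (!any(comp)) NA_real_ else
      sum(m[i, comp] != m[j, comp]) / sum(comp)
  }
  d
}

#' Neighbor-joining preview tree
#'
#' Standard neighbor-joining agglomeration (via `ape::nj`) on a symmetric
#' distance matrix, returned as newick text. Taxa are canonicalised to
#' label order before agglomeration so ties resolve deterministically;
#' negative branch lengths are clamped to zero with a warning.
#'
#' @param dm symmetric numeric matrix with taxon dimnames (e.g. from
#'   [p_distance_matrix()]).
#' @return newick string (also of class `mito_njtree`; `ape::read.tree`
#'   parses it).
#' @export
neighbor_joining <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    .stop("distance matrix must be square")
  if (nrow(dm) < 3) .stop("neighbor joining needs at least three taxa")
  if (any(is.na(dm))) .stop("distance matrix contains missing values")
  if (max(abs(dm - t(dm))) > 1e-8) .stop("distance matrix is not symmetric")
  if (is.null(rownames(dm)))
    rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  ord <- order(rownames(dm))
  dm <- dm[ord, ord]
  tree <- ape::nj(stats::as.dist(dm))
  if (any(tree$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0", call. = FALSE)
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  structure(ape::write.tree(tree), class = c("mito_njtree", "character"))
}
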