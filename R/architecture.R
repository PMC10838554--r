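# Circular junction analysis (gene overlaps and intergenic spacers),
# tRNA summaries, and avian control-region gene-order classification.
#
# Gaps are always recomputed from coordinates: gap = next.start - prev.stop
# - 1, with the circular wrap junction closing the circle (+genome length).
# A negative gap is an overlap. Control regions are features, not spacers.

#' Junction table of an annotation
#'
#' All adjacent-feature junctions in genome order: N junctions for N
#' features on a circular genome (the wrap junction closes the circle),
#' N - 1 otherwise. Gaps are computed from coordinates only; intergenic
#' columns of the input are never trusted.
#'
#' @param ann a `mito_annotation` with at least two features.
#' @return data.frame with columns `prev`, `nxt`, `prev_stop`,
#'   `next_start`, `gap` (signed; negative = overlap), `wraps`.
#' @export
junction_table <- function(ann) {
  f <- ann$features
  if (nrow(f) < 2) .stop("junction analysis needs at least two features")
  n <- nrow(f)
  idx_next <- c(2:n, 1)
  gap <- f$start[idx_next] - f$stop - 1L
  wraps <- c(rep(FALSE, n - 1), TRUE)
  gap[n] <- f$start[1] + ann$length - f$stop[n] - 1L
  out <- data.frame(prev = f$name, nxt = f$name[idx_next],
                    prev_stop = f$stop, next_start = f$start[idx_next],
                    gap = as.integer(gap), wraps = wraps,
                    stringsAsFactors = FALSE)
  if (!ann$circular) out <- out[-n, , drop = FALSE]
  # three features sharing a position: both consecutive gaps overlap the
  # same neighbour
  triple <- which(out$gap < 0 & c(out$gap[-1] < 0, FALSE) &
                  out$prev_stop >= out$next_start)
  if (length(triple) && any(out$next_start[triple + 1] <=
                            out$prev_stop[triple]))
    warning("three features share a position near ",
            paste(out$prev[triple], collapse = ", "), call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Overlap/spacer summary of a junction table
#'
#' Overlaps are junctions with negative gap, intergenic spacers those with
#' positive gap. Extremum ties are broken by first occurrence in genome
#' order from position 1. A spacer longer than `cr_warn` nucleotides with
#' no control-region feature on either side triggers a warning (a long
#' unannotated gap usually is an unannotated control region inflating
#' spacer totals).
#'
#' @param junctions a junction table from [junction_table()], or a
#'   `mito_annotation` (the table is computed).
#' @param ann optional `mito_annotation` used for the unannotated-CR check.
#' @param cr_warn spacer length above which a missing adjacent CR is
#'   flagged (default 500).
#' @return list with `overlap_pairs`, `overlap_total`, `longest_overlap`
#'   (list: `prev`, `nxt`, `nt`), `spacer_count`, `spacer_total`,
#'   `longest_spacer`, and the junction table itself.
#' @export
architecture_summary <- function(junctions, ann = NULL, cr_warn = 500) {
  if (inherits(junctions, "mito_annotation")) {
    ann <- junctions
    junctions <- junction_table(ann)
  }
  j <- junctions
  ov <- j[j$gap < 0, , drop = FALSE]
  sp <- j[j$gap > 0, , drop = FALSE]
  pick <- function(d, col) {
    if (!nrow(d)) return(NULL)
    i <- which.max(abs(d$gap))  # first occurrence wins ties
    list(prev = d$prev[i], nxt = d$nxt[i], nt = abs(d$gap[i]))
  }
  if (!is.null(ann) && nrow(sp)) {
    types <- ann$features$type
    names(types) <- ann$features$name
    lone <- sp$gap > cr_warn & types[sp$prev] != "CR" & types[sp$nxt] != "CR"
    if (any(lone))
      warning("spacer > ", cr_warn, " bp with no adjacent control region: ",
              paste(sprintf("%s-%s (%d bp)", sp$prev[lone], sp$nxt[lone],
                            sp$gap[lone]), collapse = ", "), call. = FALSE)
  }
  list(overlap_pairs = nrow(ov), overlap_total = sum(-ov$gap),
       longest_overlap = pick(ov),
       spacer_count = nrow(sp), spacer_total = sum(sp$gap),
       longest_spacer = pick(sp),
       junctions = j)
}

#' Extract the gene order through an anchor window
#'
#' Walks the circular feature order from the first anchor label to the
#' second (inclusive) and returns the labels in between, with control
#' regions relabelled `CR1`, `CR2`, ... by order of occurrence inside the
#' window. The result is invariant under rotation of the coordinate origin.
#'
#' @param ann a `mito_annotation`.
#' @param anchor_window two labels delimiting the window (default
#'   `c("nad5", "12S")`, the rearrangement-diagnostic window of avian
#'   mitogenomes).
#' @return character vector of labels, with attribute `cr_lengths` (named
#'   lengths of the CR features in window order).
#' @export
#' @examples
#' # on a duplicate-CR genome:
#' # nad5 cob trnT CR1 trnP nad6 trnE CR2 trnF 12S
extract_gene_order <- function(ann, anchor_window = c("nad5", "12S")) {
  f <- ann$features
  missing <- setdiff(anchor_window, f$name)
  if (length(missing))
    .stop("anchor label(s) absent from annotation: ",
          paste(missing, collapse = ", "))
  n <- nrow(f)
  from <- match(anchor_window[1], f$name)
  to <- match(anchor_window[2], f$name)
  idx <- if (from <= to) from:to else c(from:n, 1:to)
  labels <- f$name[idx]
  lens <- feature_length(f$start[idx], f$stop[idx], ann$length, ann$circular)
  is_cr <- f$type[idx] == "CR"
  # a single control region keeps the generic label; multiple copies are
  # numbered by occurrence inside the window (rotation-invariant)
  if (sum(is_cr) == 1) labels[is_cr] <- "CR"
  else if (any(is_cr)) labels[is_cr] <- paste0("CR", seq_len(sum(is_cr)))
  structure(labels,
            cr_lengths = stats::setNames(lens[is_cr], labels[is_cr]))
}

#' Classify an avian mitochondrial gene order
#'
#' Pattern-matches the control-region neighbourhood of the gene order
#' against the four named avian rearrangement classes:
#' * `ancestral` — a single control region between `trnE` and `trnF`;
#' * `duplicate_CR` — a control region between `trnT` and `trnP` *and* one
#'   between `trnE` and `trnF`, both at least `remnant_threshold` of the
#'   longer copy's length;
#' * `remnant_CR2` — two control regions where the second falls below
#'   `remnant_threshold` of the first's length;
#' * `duplicate_trnT_CR` — `trnT` present twice, each copy adjacent to a
#'   control region;
#' * otherwise `unrecognized`.
#'
#' The 50% remnant threshold is this package's operational rule; the class
#' names come from the standard avian gene-order nomenclature, which gives
#' no numeric cut-off.
#'
#' @param order label vector from [extract_gene_order()].
#' @param cr_lengths named lengths of the CR features; taken from
#'   `attr(order, "cr_lengths")` when absent.
#' @param remnant_threshold relative-length cut-off separating a duplicate
#'   from a remnant second control region (default 0.5).
#' @return one of `"ancestral"`, `"remnant_CR2"`, `"duplicate_CR"`,
#'   `"duplicate_trnT_CR"`, `"unrecognized"`.
#' @export
classify_gene_order <- function(order, cr_lengths = NULL,
                                remnant_threshold = 0.5) {
  if (is.null(cr_lengths)) cr_lengths <- attr(order, "cr_lengths")
  order <- as.character(order)
  crs <- grep("^CR[0-9]*$", order, value = TRUE)
  n <- length(order)
  # labels strictly between a and b walking forward circularly
  between <- function(a, b) {
    ia <- match(a, order); ib <- match(b, order)
    if (is.na(ia) || is.na(ib)) return(character())
    if (ia < ib) {
      if (ib - ia < 2) character() else order[(ia + 1):(ib - 1)]
    } else {
      c(if (ia < n) order[(ia + 1):n] else character(),
        if (ib > 1) order[1:(ib - 1)] else character())
    }
  }
  adjacent_cr <- function(i) {
    nb <- order[c(if (i > 1) i - 1 else n, if (i < n) i + 1 else 1)]
    any(grepl("^CR[0-9]*$", nb))
  }
  trnT_at <- which(order == "trnT" | grepl("^trnT_", order))
  if (length(trnT_at) >= 2 && all(vapply(trnT_at, adjacent_cr, logical(1))))
    return("duplicate_trnT_CR")
  cr_T_P <- grep("^CR[0-9]*$", between("trnT", "trnP"), value = TRUE)
  cr_E_F <- grep("^CR[0-9]*$", between("trnE", "trnF"), value = TRUE)
  if (length(cr_T_P) && length(cr_E_F) && !is.null(cr_lengths)) {
    l1 <- cr_lengths[cr_T_P[1]]
    l2 <- cr_lengths[cr_E_F[1]]
    if (min(l1, l2) >= remnant_threshold * max(l1, l2))
      return("duplicate_CR")
  }
  if (length(crs) == 2 && !is.null(cr_lengths) &&
      all(crs %in% names(cr_lengths))) {
    if (cr_lengths[crs[2]] < remnant_threshold * cr_lengths[crs[1]])
      return("remnant_CR2")
  }
  if (length(crs) == 1 && crs[1] %in% cr_E_F &&
      !length(grep("^CR", between("trnT", "trnP"))))
    return("ancestral")
  "unrecognized"
}

#' Per-tRNA report and summary
#'
#' Lengths, strands and anticodons of all tRNA features, with anticodons
#' checked against the bundled canonical vertebrate mitochondrial anticodon
#' table (mismatches flagged, not corrected).
#'
#' @param ann a `mito_annotation` with at least one tRNA feature.
#' @return list with `table` (per-tRNA data.frame: `name`, `length`,
#'   `strand`, `anticodon`, `canonical_anticodon`, `mismatch`) and
#'   `summary` (list: `count`, `total_length`, `genome_fraction_percent`,
#'   `mean_length`, `longest`/`shortest` — all tied names with the length —
#'   and `strand_counts`).
#' @export
trna_table <- function(ann) {
  f <- ann$features
  tr <- f[f$type == "tRNA", , drop = FALSE]
  if (!nrow(tr)) .stop("annotation has no tRNA features")
  len <- feature_length(tr$start, tr$stop, ann$length, ann$circular)
  canon <- utils::read.delim(.extdata("vertebrate_mito_anticodons.tsv"),
                             stringsAsFactors = FALSE)
  expected <- canon$anticodon[match(tr$name, canon$gene)]
  tab <- data.frame(name = tr$name, length = len, strand = tr$strand,
                    anticodon = tr$anticodon,
                    canonical_anticodon = expected,
                    mismatch = !is.na(tr$anticodon) & !is.na(expected) &
                      tr$anticodon != expected,
                    stringsAsFactors = FALSE)
  longest <- tab$name[len == max(len)]
  shortest <- tab$name[len == min(len)]
  list(table = tab, summary = list(
    count = nrow(tab),
    total_length = sum(len),
    genome_fraction_percent = 100 * sum(len) / ann$length,
    mean_length = mean(len),
    longest = list(names = longest, length = max(len)),
    shortest = list(names = shortest, length = min(len)),
    strand_counts = c(H = sum(tab$strand == "H"),
                      L = sum(tab$strand == "L"))))
}
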