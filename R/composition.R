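# Base composition, AT/GC content and strand skews, per region class.
#
# Skews follow the standard definitions AT-skew = (A - T)/(A + T) and
# GC-skew = (G - C)/(G + C) on the reference (H) strand. Both are
# scale-invariant: counts and percentages give the same value.

#' AT skew
#'
#' `(a - t) / (a + t)`. Accepts counts or percentages (the skew is
#' scale-invariant). Undefined (returned as `NA`) when `a + t == 0`.
#'
#' @param a,t numeric vectors on a common scale.
#' @return numeric vector in `[-1, 1]`, `NA` where undefined.
#' @export
#' @examples
#' at_skew(29.45, 23.26)  # 0.117..., prints as 0.12
at_skew <- function(a, t) {
  ifelse(a + t == 0, NA_real_, (a - t) / (a + t))
}

#' GC skew
#'
#' `(g - c) / (g + c)`. See [at_skew()] for conventions.
#'
#' @param g,c numeric vectors on a common scale.
#' @return numeric vector in `[-1, 1]`, `NA` where undefined.
#' @export
gc_skew <- function(g, c) {
  ifelse(g + c == 0, NA_real_, (g - c) / (g + c))
}

#' Base composition of a nucleotide sequence
#'
#' Counts A/C/G/T (case-insensitive). Characters outside ACGT (ambiguity
#' codes, gaps) are excluded from the denominator and reported in
#' `n_other`. Fractions are percentages at full precision; round only for
#' display.
#'
#' @param seq one nucleotide string.
#' @return an object of class `composition_stats`: a list with `n` (ACGT
#'   count), `n_other`, `counts` (named A/C/G/T), `fracA`/`fracC`/`fracG`/
#'   `fracT` (percent), `at_content`, `gc_content`, `at_skew`, `gc_skew`.
#' @export
#' @examples
#' base_composition("ACGT")$at_skew  # 0
base_composition <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq))
    .stop("empty sequence")
  ch <- .chars(seq)
  counts <- c(A = sum(ch == "A"), C = sum(ch == "C"),
              G = sum(ch == "G"), T = sum(ch == "T"))
  n <- sum(counts)
  if (n == 0) .stop("sequence contains no A/C/G/T characters")
  frac <- 100 * counts / n
  structure(list(
    n = n, n_other = length(ch) - n, counts = counts,
    fracA = unname(frac["A"]), fracC = unname(frac["C"]),
    fracG = unname(frac["G"]), fracT = unname(frac["T"]),
    at_content = unname(frac["A"] + frac["T"]),
    gc_content = unname(frac["G"] + frac["C"]),
    at_skew = unname(at_skew(counts["A"], counts["T"])),
    gc_skew = unname(gc_skew(counts["G"], counts["C"]))
  ), class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, digits = 2, ...) {
  cat(sprintf(
    "<composition_stats> n=%d  A %.2f%%  C %.2f%%  G %.2f%%  T %.2f%%  A+T %.2f%%  G+C %.2f%%  AT-skew %.2f  GC-skew %.2f\n",
    x$n, x$fracA, x$fracC, x$fracG, x$fracT, x$at_content, x$gc_content,
    round_half_up(x$at_skew, digits), round_half_up(x$gc_skew, digits)))
  invisible(x)
}

#' Per-region-class composition table
#'
#' One composition row per region class (whole genome, PCGs, tRNAs, rRNAs,
#' CRs), the shape of the composition/skew table of a mitogenome paper.
#' Class sequences are the concatenation, in annotation order, of member
#' feature slices. By default slices are taken on the reference (H) strand
#' regardless of feature strand — composition is reported on the reference
#' strand; set `orient_by_strand = TRUE` to reverse-complement L-strand
#' members first. Classes with no members are omitted.
#'
#' @param seq genome sequence (reference strand).
#' @param ann a `mito_annotation`.
#' @param orient_by_strand orient member slices by their annotated strand
#'   before counting (default `FALSE`).
#' @return data.frame with columns `region`, `size_bp`, `A`, `C`, `T`, `G`
#'   (percent), `at_content`, `gc_content`, `at_skew`, `gc_skew`, full
#'   precision. The `orient_by_strand` choice is recorded in
#'   `attr(, "orient_by_strand")`.
#' @export
region_composition_table <- function(seq, ann, orient_by_strand = FALSE) {
  if (nchar(seq) != ann$length)
    .stop("sequence length does not match annotation length")
  f <- ann$features
  classes <- list(mtDNA = rep(TRUE, nrow(f)),
                  PCGs = f$type == "PCG",
                  tRNAs = f$type == "tRNA",
                  rRNAs = f$type == "rRNA",
                  CRs = f$type == "CR")
  rows <- list()
  for (cls in names(classes)) {
    if (cls == "mtDNA") {
      s <- seq
    } else {
      idx <- which(classes[[cls]])
      if (!length(idx)) {
        message("region class with no members omitted: ", cls)
        next
      }
      s <- .collapse(vapply(idx, function(i) extract_feature_sequence(
        seq, f$start[i], f$stop[i],
        strand = if (orient_by_strand) f$strand[i] else "H",
        circular = ann$circular), character(1)))
    }
    st <- base_composition(s)
    rows[[cls]] <- data.frame(
      region = cls, size_bp = nchar(s),
      A = st$fracA, C = st$fracC, T = st$fracT, G = st$fracG,
      at_content = st$at_content, gc_content = st$gc_content,
      at_skew = st$at_skew, gc_skew = st$gc_skew,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "orient_by_strand") <- orient_by_strand
  out
}
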