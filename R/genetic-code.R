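# Genetic-code tables and synonymous-family maps.
#
# Two codes matter for mitogenome work:
#   * the standard nuclear code, whose synonymous families (6-member
#     Leu/Ser/Arg, a 3-member {UAA,UAG,UGA} stop family) are the grouping
#     that published mitogenome RSCU tables conventionally follow (MEGA's
#     default), and
#   * the vertebrate mitochondrial code (AGA/AGG are stops, UGA is Trp,
#     AUA is Met), which governs translation and stop-codon classification.

# the 64 RNA codons in the conventional U/C/A/G x U/C/A/G x U/C/A/G order
.codons_rna <- local({
  b <- c("U", "C", "A", "G")
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
})

# standard code, one-letter amino acids, '*' = stop
.standard_code <- c(
  UUU = "F", UUC = "F", UUA = "L", UUG = "L",
  CUU = "L", CUC = "L", CUA = "L", CUG = "L",
  AUU = "I", AUC = "I", AUA = "I", AUG = "M",
  GUU = "V", GUC = "V", GUA = "V", GUG = "V",
  UCU = "S", UCC = "S", UCA = "S", UCG = "S",
  CCU = "P", CCC = "P", CCA = "P", CCG = "P",
  ACU = "T", ACC = "T", ACA = "T", ACG = "T",
  GCU = "A", GCC = "A", GCA = "A", GCG = "A",
  UAU = "Y", UAC = "Y", UAA = "*", UAG = "*",
  CAU = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAU = "N", AAC = "N", AAA = "K", AAG = "K",
  GAU = "D", GAC = "D", GAA = "E", GAG = "E",
  UGU = "C", UGC = "C", UGA = "*", UGG = "W",
  CGU = "R", CGC = "R", CGA = "R", CGG = "R",
  AGU = "S", AGC = "S", AGA = "R", AGG = "R",
  GGU = "G", GGC = "G", GGA = "G", GGG = "G"
)

# vertebrate mitochondrial code: four differences from the standard code
.vertmito_code <- local({
  code <- .standard_code
  code[c("AGA", "AGG")] <- "*"
  code["UGA"] <- "W"
  code["AUA"] <- "M"
  code
})

# stop codons that can terminate a vertebrate mitochondrial CDS
.vertmito_stops <- c("TAA", "TAG", "AGA", "AGG")

#' Synonymous-family map for RSCU computation
#'
#' Returns a named character vector mapping each of the 64 RNA codons to a
#' family label (the amino acid's one-letter code, or `"*"` for the stop
#' family). The `"standard"` map uses the standard-code families (6-member
#' Leu/Ser/Arg and a 3-member stop family), which is the grouping that
#' published mitogenome RSCU tables obey; `"vertmito"` uses vertebrate
#' mitochondrial families (AGA/AGG join the stop family, UGA pairs with UGG
#' as Trp, AUA with AUG as Met).
#'
#' @param code `"standard"` (default) or `"vertmito"`.
#' @return named character vector of length 64 (names are RNA codons).
#' @export
#' @examples
#' table(codon_family_map("standard"))
codon_family_map <- function(code = c("standard", "vertmito")) {
  code <- match.arg(code)
  map <- if (code == "standard") .standard_code else .vertmito_code
  map[.codons_rna]
}

#' Translate a DNA codon under the vertebrate mitochondrial code
#'
#' @param codons character vector of 3-mers (DNA or RNA alphabet).
#' @return one-letter amino-acid codes, `"*"` for stops, `NA` for codons
#'   containing non-ACGU letters.
#' @export
translate_vertmito <- function(codons) {
  rna <- chartr("Tt", "Uu", toupper(codons))
  out <- unname(.vertmito_code[rna])
  out
}

# internal: convert DNA codon(s) to RNA representation
.to_rna <- function(x) chartr("T", "U", toupper(x))

# internal: convert RNA codon(s) to DNA representation
.to_dna <- function(x) chartr("U", "T", toupper(x))
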