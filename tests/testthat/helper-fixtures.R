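# Shared fixtures: the bundled published-table transcriptions and small
# toy genomes built in code.

fixture_annotation <- function() {
  read_feature_table(system.file("extdata", "pchinensis_annotation.tsv",
                                 package = "mitocharacter"))
}

fixture_composition <- function() {
  utils::read.delim(system.file("extdata", "pchinensis_composition.tsv",
                                package = "mitocharacter"),
                    stringsAsFactors = FALSE)
}

fixture_codon_usage <- function() {
  utils::read.delim(system.file("extdata", "pchinensis_codon_usage.tsv",
                                package = "mitocharacter"),
                    stringsAsFactors = FALSE)
}

# a 60 bp circular toy genome with one PCG, one tRNA and a control region
toy_annotation <- function(circular = TRUE) {
  parse_feature_table(
    data.frame(gene = c("nad1", "trnF", "D-loop"),
               strand = c("H", "L", "H"),
               start = c(1, 22, 31), stop = c(21, 28, 50)),
    genome_length = 60, circular = circular, genome_id = "toy")
}

toy_sequence <- function() {
  # nad1: ATG + 5 codons + TAA (21 nt); the rest arbitrary
  paste0("ATGAAACCCGGGTTTACATAA",  # 1-21 PCG
         "GCGCGCG",                # 22-28 tRNA (L strand)
         "AT",                     # 29-30
         "ACGTACGTACGTACGTACGT",   # 31-50 CR
         "TTTTTAAAAA")             # 51-60
}

# minimal single-record GenBank text
toy_genbank_text <- function() {
  c("LOCUS       toyrec 60 bp    DNA     circular     VRT",
    "DEFINITION  toy record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             1..21",
    "                     /gene=\"ND1\"",
    "     tRNA            complement(22..28)",
    "                     /gene=\"trnF\"",
    "     D-loop          31..50",
    "ORIGIN",
    paste0("        1 ", tolower("ATGAAACCCG GGTTTACATA AGCGCGCGAT")),
    paste0("       31 ", tolower("ACGTACGTAC GTACGTACGT TTTTTAAAAA")),
    "//")
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}
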