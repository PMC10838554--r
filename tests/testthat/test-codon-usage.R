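# codon extraction, counting, RSCU and stop-codon classification

test_that("extract_codons splits into complete codons plus residual tail", {
  r <- extract_codons("ATGAAATAA")
  expect_equal(r$codons, c("ATG", "AAA", "TAA"))
  expect_equal(r$tail, "")
  r2 <- extract_codons("ATGAAAT")
  expect_equal(r2$codons, c("ATG", "AAA"))
  expect_equal(r2$tail, "T")
  # a 784 nt CDS yields 261 codons and a 1 nt tail (cox3 geometry)
  set.seed(41)
  r3 <- extract_codons(random_dna(784))
  expect_length(r3$codons, 261)
  expect_equal(nchar(r3$tail), 1)
  expect_equal(extract_codons("")$codons, character())
})

test_that("count_codons covers both construction modes", {
  ann <- toy_annotation()
  seq <- toy_sequence()
  cc <- count_codons(ann, seq, mode = "pcg_concat")
  expect_equal(cc$total, 7L)  # 21 nt PCG
  expect_equal(unname(cc$counts[c("AUG", "UAA")]), c(1L, 1L))
  expect_equal(sum(cc$counts), cc$total)
  cc2 <- count_codons(ann, seq, mode = "whole_genome_frame1")
  expect_equal(cc2$total, 20L)  # floor(60/3)
  # frame-1 total on a 17827 nt genome is floor(17827/3) = 5942
  g <- generate_genome(synthetic_spec(seed = 42))
  expect_equal(count_codons(g$annotation, g$sequence,
                            mode = "whole_genome_frame1")$total, 5942L)
  short <- parse_feature_table(
    data.frame(gene = "nad1", strand = "H", start = 1, stop = 2),
    genome_length = 60, genome_id = "s")
  expect_error(count_codons(short, seq), "nad1")
})

test_that("synthetic per-gene codon lists are counted back exactly", {
  g <- generate_genome(synthetic_spec(seed = 43))
  cc <- count_codons(g$annotation, g$sequence, mode = "pcg_concat")
  expect_identical(cc$counts, g$truth$pcg_codon_counts)
  expect_equal(cc$total,
               sum(vapply(g$truth$pcg_codons, length, integer(1))))
  # total = sum over PCGs of floor(length/3)
  f <- g$annotation$features
  pcg_len <- feature_length(f$start[f$type == "PCG"],
                            f$stop[f$type == "PCG"], g$annotation$length)
  expect_equal(cc$total, sum(pcg_len %/% 3))
})

test_that("compute_rscu matches closed-form family arithmetic", {
  # two-member Phe family
  r <- compute_rscu(c(UUU = 56, UUC = 154))
  expect_equal(round_half_up(r$rscu[r$codon == "UUC"]), 1.47)
  expect_equal(r$rscu[r$codon == "UUC"], 154 * 2 / 210)
  # six-member Ser family
  r2 <- compute_rscu(c(UCU = 93, UCC = 123, UCA = 93, UCG = 31,
                       AGU = 53, AGC = 126))
  expect_equal(round_half_up(r2$rscu[r2$codon == "AGC"]), 1.46)
  # equal counts within a family give RSCU 1 everywhere observed
  r3 <- compute_rscu(c(GUU = 7, GUC = 7, GUA = 7, GUG = 7))
  expect_equal(r3$rscu[r3$aa == "V"], rep(1, 4))
  # DNA input is accepted
  r4 <- compute_rscu(c(TTT = 56, TTC = 154))
  expect_equal(r4$rscu[r4$codon == "UUC"], 154 * 2 / 210)
  expect_error(compute_rscu(c(XXX = 3)), "unknown codon")
  expect_error(compute_rscu(1:64), "named")
  bad_map <- codon_family_map("standard")[1:63]
  expect_error(compute_rscu(c(UUU = 1), family_map = bad_map), "partition")
})

test_that("RSCU family sums equal family size and survive uniform scaling", {
  set.seed(44)
  fam <- codon_family_map("standard")
  for (i in 1:20) {
    counts <- stats::setNames(rpois(64, 40), names(fam))
    rt <- compute_rscu(counts)
    for (f in unique(fam)) {
      idx <- rt$aa == f
      if (sum(rt$count[idx]) > 0)
        expect_equal(sum(rt$rscu[idx]), sum(idx))
    }
    rt2 <- compute_rscu(counts * 7L)
    expect_equal(rt2$rscu, rt$rscu)
  }
  # vertebrate-mito grouping: UGA is Trp, AGA/AGG are stops
  vm <- codon_family_map("vertmito")
  expect_equal(unname(vm[c("UGA", "UGG")]), c("W", "W"))
  expect_equal(unname(vm[c("AGA", "AGG", "UAA", "UAG")]), rep("*", 4))
})

test_that("stop kinds follow CDS length modulo 3, with sequence checks", {
  ann <- toy_annotation()
  ss <- classify_start_stop(ann, toy_sequence())
  expect_equal(ss$gene, "nad1")
  expect_equal(ss$start_codon, "ATG")
  expect_equal(ss$stop_kind, "complete")
  expect_equal(ss$stop_text, "TAA")
  expect_equal(ss$note, "")
  # incomplete_T: length 1 mod 3 ending in T
  ann1 <- parse_feature_table(
    data.frame(gene = "cox3", strand = "H", start = 1, stop = 7),
    genome_length = 30, genome_id = "t")
  s1 <- classify_start_stop(ann1, paste0("ATGAAAT", strrep("C", 23)))
  expect_equal(s1$stop_kind, "incomplete_T")
  expect_equal(s1$stop_text, "T(AA)")
  # incomplete_TA
  ann2 <- parse_feature_table(
    data.frame(gene = "nad4", strand = "H", start = 1, stop = 8),
    genome_length = 30, genome_id = "t")
  s2 <- classify_start_stop(ann2, paste0("ATGAAATA", strrep("C", 22)))
  expect_equal(s2$stop_kind, "incomplete_TA")
  expect_equal(s2$stop_text, "TA(A)")
  # non-canonical complete stop is flagged, not an error
  ann3 <- parse_feature_table(
    data.frame(gene = "nad1", strand = "H", start = 1, stop = 6),
    genome_length = 30, genome_id = "t")
  expect_warning(s3 <- classify_start_stop(ann3,
                                           paste0("ATGAAA", strrep("C", 24))),
                 "non-canonical")
  expect_equal(s3$stop_kind, "complete")
  expect_match(s3$note, "AAA")
  # coordinates-only classification (no sequence)
  ssl <- classify_start_stop(fixture_annotation())
  expect_equal(sort(ssl$gene[ssl$stop_kind == "incomplete_T"]),
               c("cox3", "nad4"))
})

test_that("family totals rank amino acids with alphabetical tie-breaks", {
  rt <- compute_rscu(stats::setNames(fixture_codon_usage()$count,
                                     fixture_codon_usage()$codon))
  tot <- codon_family_totals(rt)
  expect_equal(tot$total[tot$aa == "P"], 715)
  expect_equal(attr(tot, "most_frequent"), "P")
  expect_equal(tot$total[tot$aa == "W"], 30)
  expect_equal(attr(tot, "least_frequent"), "W")
  empty <- compute_rscu(stats::setNames(integer(64),
                                        codon_family_map() |> names()))
  tot0 <- codon_family_totals(empty)
  expect_null(attr(tot0, "most_frequent"))
})
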