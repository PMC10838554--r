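# junction arithmetic, gene order extraction/classification, tRNA summary

test_that("junction gaps are recomputed from coordinates, wrap included", {
  ann <- fixture_annotation()
  jt <- junction_table(ann)
  expect_equal(nrow(jt), 39)  # N junctions on a circular genome
  gap_after <- stats::setNames(jt$gap, jt$prev)
  expect_equal(gap_after[["trnT"]], 311L)   # trnT -> CR1 spacer
  expect_equal(gap_after[["atp8"]], -10L)   # atp8/atp6 overlap
  expect_equal(gap_after[["nad4l"]], -7L)
  expect_equal(gap_after[["atp6"]], 5L)
  expect_equal(gap_after[["nad5"]], 8L)
  expect_equal(gap_after[["CR2"]], 176L)    # circular wrap junction
  expect_true(jt$wraps[jt$prev == "CR2"])
  # abutting features
  ab <- parse_feature_table(
    data.frame(gene = c("a", "b"), strand = "H", start = c(1, 11),
               stop = c(10, 20)),
    genome_length = 30, circular = FALSE, genome_id = "ab")
  expect_equal(junction_table(ab)$gap, 0L)
  single <- parse_feature_table(
    data.frame(gene = "a", strand = "H", start = 1, stop = 10),
    genome_length = 30, genome_id = "one")
  expect_error(junction_table(single), "two features")
})

test_that("architecture summary finds extrema and totals", {
  ann <- fixture_annotation()
  s <- architecture_summary(ann)
  expect_equal(s$overlap_pairs, 10)
  expect_equal(s$overlap_total, 33)
  expect_equal(s$longest_overlap,
               list(prev = "atp8", nxt = "atp6", nt = 10L))
  expect_equal(s$spacer_count, 22)   # 21 internal + the circular wrap
  expect_equal(s$longest_spacer,
               list(prev = "trnT", nxt = "CR1", nt = 311L))
  # a long spacer with no adjacent control region is flagged
  lone <- parse_feature_table(
    data.frame(gene = c("nad1", "nad2"), strand = "H",
               start = c(1, 1001), stop = c(300, 1600)),
    genome_length = 2000, genome_id = "lone")
  expect_warning(architecture_summary(lone), "no adjacent control region")
})

test_that("feature lengths + spacers - overlaps tile the circle", {
  for (seed in c(51, 52, 53)) {
    g <- generate_genome(synthetic_spec(seed = seed))
    f <- g$annotation$features
    jt <- junction_table(g$annotation)
    total <- sum(feature_length(f$start, f$stop, g$annotation$length)) +
      sum(jt$gap[jt$gap > 0]) - sum(-jt$gap[jt$gap < 0])
    expect_equal(total, g$annotation$length)
  }
})

test_that("gene order extraction is rotation invariant", {
  ann <- fixture_annotation()
  ord <- extract_gene_order(ann)
  expect_equal(as.character(ord),
               c("nad5", "cob", "trnT", "CR1", "trnP", "nad6", "trnE",
                 "CR2", "trnF", "12S"))
  expect_equal(attr(ord, "cr_lengths"), c(CR1 = 664L, CR2 = 679L))
  # rotate the origin by k and re-extract
  f <- ann$features
  for (k in c(4016L, 9000L, 15000L)) {
    st <- ((f$start - 1L + k) %% ann$length) + 1L
    sp <- ((f$stop - 1L + k) %% ann$length) + 1L
    rot <- parse_feature_table(
      data.frame(gene = f$name, strand = f$strand, start = st, stop = sp),
      genome_length = ann$length, genome_id = "rot")
    ord2 <- extract_gene_order(rot)
    expect_equal(as.character(ord2), as.character(ord))
    expect_equal(classify_gene_order(ord2), classify_gene_order(ord))
  }
  expect_error(extract_gene_order(ann, c("nad5", "nope")), "nope")
})

test_that("gene order classification follows the control-region rules", {
  dup <- c("nad5", "cob", "trnT", "CR1", "trnP", "nad6", "trnE", "CR2",
           "trnF", "12S")
  expect_equal(classify_gene_order(dup, c(CR1 = 664, CR2 = 679)),
               "duplicate_CR")
  anc <- c("nad5", "cob", "trnT", "trnP", "nad6", "trnE", "CR", "trnF",
           "12S")
  expect_equal(classify_gene_order(anc, c(CR = 1158)), "ancestral")
  expect_equal(classify_gene_order(dup, c(CR1 = 664, CR2 = 60)),
               "remnant_CR2")
  # threshold is configurable
  expect_equal(classify_gene_order(dup, c(CR1 = 664, CR2 = 340),
                                   remnant_threshold = 0.5),
               "duplicate_CR")
  expect_equal(classify_gene_order(dup, c(CR1 = 664, CR2 = 340),
                                   remnant_threshold = 0.6),
               "remnant_CR2")
  dup_t <- c("nad5", "cob", "trnT", "CR1", "trnT_2", "trnP", "nad6",
             "trnE", "CR2", "trnF", "12S")
  expect_equal(classify_gene_order(dup_t, c(CR1 = 664, CR2 = 679)),
               "duplicate_trnT_CR")
  expect_equal(classify_gene_order(c("nad5", "cob", "trnF", "12S"), NULL),
               "unrecognized")
})

test_that("tRNA table reports extrema, ties, strands and anticodon checks", {
  tt <- trna_table(fixture_annotation())
  expect_equal(tt$summary$count, 22)
  expect_equal(tt$summary$longest, list(names = "trnL2", length = 75L))
  expect_equal(tt$summary$shortest,
               list(names = c("trnC", "trnS1"), length = 66L))
  expect_equal(unname(tt$summary$strand_counts["L"]), 8L)
  expect_equal(round(tt$summary$mean_length), 70)
  expect_false(any(tt$table$mismatch))
  # genome fraction reported from recomputed totals
  expect_equal(tt$summary$total_length, 1547L)
  expect_equal(round(tt$summary$genome_fraction_percent, 2), 8.68)
  # a wrong anticodon is flagged
  ann <- fixture_annotation()
  ann$features$anticodon[ann$features$name == "trnF"] <- "AAA"
  expect_true(trna_table(ann)$table$mismatch[
    trna_table(ann)$table$name == "trnF"])
})
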