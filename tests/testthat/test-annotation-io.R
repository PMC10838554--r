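# annotation parsing, coordinate arithmetic and sequence extraction

test_that("reverse_complement complements, preserves case, and is an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAA"), "TTT")
  expect_equal(reverse_complement("ATGAAATAA"), "TTATTTCAT")
  expect_equal(reverse_complement("acGT"), "ACgt")
  expect_equal(reverse_complement("ARYN"), "NRYT")
  set.seed(11)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "N", "R", "Y", "a", "c", "g",
                        "t"), 1000, replace = TRUE), collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("feature_length handles plain and origin-wrapping features", {
  expect_equal(feature_length(11867, 13684, 17827), 1818)
  expect_equal(feature_length(15219, 15882, 17827), 664)
  expect_equal(feature_length(98, 3, 100), 6)
  expect_equal(feature_length(1, 70, 17827), 70)
  expect_error(feature_length(98, 3, 100, circular = FALSE), "non-circular")
  expect_error(feature_length(5, 200, 100), "outside")
})

test_that("extract_feature_sequence orients by strand and handles wraps", {
  s <- "ATGAAATAA"
  expect_equal(extract_feature_sequence(s, 1, 9, "H"), "ATGAAATAA")
  expect_equal(extract_feature_sequence(s, 1, 9, "L"), "TTATTTCAT")
  # wrap equals rotating the genome so the feature is contiguous
  set.seed(21)
  g <- random_dna(100)
  rot <- paste0(substr(g, 91, 100), substr(g, 1, 90))  # origin moved to 91
  expect_equal(extract_feature_sequence(g, 91, 10, "H"),
               substr(rot, 1, 20))
  expect_equal(extract_feature_sequence(g, 91, 10, "L"),
               reverse_complement(substr(rot, 1, 20)))
  expect_error(extract_feature_sequence(g, 91, 10, "H", circular = FALSE),
               "non-circular")
})

test_that("parse_feature_table normalises names, sorts and validates", {
  ann <- toy_annotation()
  expect_s3_class(ann, "mito_annotation")
  expect_equal(ann$features$name, c("nad1", "trnF", "CR1"))
  expect_equal(ann$features$type, c("PCG", "tRNA", "CR"))
  expect_error(parse_feature_table(data.frame()), "no features")
  expect_error(
    parse_feature_table(data.frame(gene = "x", strand = "H",
                                   start = 5, stop = 200),
                        genome_length = 100),
    "outside")
  expect_warning(
    parse_feature_table(data.frame(gene = c("a", "b"), strand = "H",
                                   start = c(1, 11), stop = c(10, 30),
                                   length = c(10, 99)),
                        genome_length = 50),
    "inconsistent.*b")
})

test_that("bundled annotation parses to 13 PCGs + 22 tRNAs + 2 rRNAs + 2 CRs", {
  ann <- fixture_annotation()
  expect_equal(ann$length, 17827L)
  expect_true(ann$circular)
  tab <- table(ann$features$type)
  expect_equal(as.integer(tab[c("PCG", "tRNA", "rRNA", "CR")]),
               c(13L, 22L, 2L, 2L))
  # printed length column is consistent for every row of this annotation
  expect_null(attr(ann, "length_discrepancies"))
  # spot checks against the printed table
  f <- ann$features
  expect_equal(f$stop[f$name == "trnF"] - f$start[f$name == "trnF"] + 1, 70)
  expect_equal(feature_length(f$start[f$name == "nad6"],
                              f$stop[f$name == "nad6"], ann$length), 519)
  expect_equal(f$strand[f$name == "nad6"], "L")
})

test_that("feature table writing round-trips through reading", {
  ann <- fixture_annotation()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ann, path)
  ann2 <- read_feature_table(path)
  expect_identical(ann2$features[, c("name", "type", "strand", "start",
                                     "stop", "anticodon")],
                   ann$features[, c("name", "type", "strand", "start",
                                    "stop", "anticodon")])
  expect_identical(ann2$length, ann$length)
  expect_identical(ann2$circular, ann$circular)
})

test_that("parse_genbank reads locus, strands and sequence", {
  gb <- parse_genbank(toy_genbank_text())
  expect_equal(gb$annotation$length, 60L)
  expect_true(gb$annotation$circular)
  f <- gb$annotation$features
  expect_equal(f$name, c("nad1", "trnF", "CR1"))
  expect_equal(f$strand, c("H", "L", "H"))
  expect_equal(nchar(gb$sequence), 60)
  expect_equal(substr(gb$sequence, 1, 3), "ATG")
  expect_error(parse_genbank(c("NOT A HEADER", "x")), "line 1")
  bad <- toy_genbank_text()
  bad[5] <- "     CDS             1..99"
  expect_error(parse_genbank(bad), "beyond sequence length")
})

test_that("genbank writing round-trips through parsing", {
  set.seed(5)
  g <- generate_genome(synthetic_spec(seed = 5))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g$annotation, g$sequence, path)
  back <- parse_genbank(path)
  expect_identical(back$sequence, g$sequence)
  expect_identical(
    back$annotation$features[, c("name", "strand", "start", "stop")],
    g$annotation$features[, c("name", "strand", "start", "stop")])
})

test_that("validate_annotation reports non-ACGT characters and mismatches", {
  ann <- toy_annotation()
  rep <- validate_annotation(ann, gsub("^ATG", "NTG", toy_sequence()))
  expect_false(rep$ok)
  expect_match(rep$issues, "non-ACGT", all = FALSE)
  rep2 <- validate_annotation(ann, toy_sequence())
  expect_true(rep2$ok)
})
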