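test_that("amino-acid index tables follow the published coding", {
  expect_identical(encode_aa_index("Arg", "ref"), 1L)
  expect_identical(encode_aa_index("His", "ref"), 2L)
  expect_identical(encode_aa_index("Cys", "ref"), 21L)
  expect_identical(encode_aa_index("Leu", "ref"), 17L)
  # mutant dialect adds the shared non-residue code
  for (tok in c("fs", "Ter", "del")) {
    expect_identical(encode_aa_index(tok, "mut"), 22L)
    expect_error(encode_aa_index(tok, "ref"), "no code")
  }
  # one-letter input normalizes
  expect_identical(encode_aa_index("K", "ref"), 3L)
  # ref dialect covers exactly 21 residues, mut exactly 21 + the 22-codes
  expect_equal(sort(unique(unname(myelotune:::AA_INDEX_REF))), 1:21)
  expect_setequal(unname(myelotune:::AA_INDEX_MUT), c(1:21, 22))
})

test_that("polarity codes match the published table exactly", {
  expect_equal(chemical_value("Lys"), 4.2)
  expect_equal(chemical_value("Asp"), 3.1)
  expect_equal(chemical_value("Gly"), 1.9)
  expect_equal(chemical_value("Ter"), 0.0)
  expect_equal(chemical_value("p.?"), 0.0)
  # the image of the map is exactly the printed code set
  printed <- c(1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8, 1.9,
               2.1, 2.3, 2.4, 2.5, 2.6, 2.7, 3.1, 3.2, 4.1, 4.2, 4.3, 0.0)
  expect_setequal(unname(myelotune:::AA_CHEMICAL), printed)
  expect_error(chemical_value("Xyz"), "no polarity code")
})

test_that("the Grantham table is symmetric with the published extremes", {
  g <- myelotune:::GRANTHAM_MATRIX
  expect_true(isSymmetric(g))
  expect_true(all(diag(g) == 0))
  off <- g[upper.tri(g)]
  expect_true(all(off >= 5 & off <= 215))
  expect_identical(max(off), 215)
  expect_identical(min(off), 5)
  expect_equal(grantham_distance("Leu", "Ile"), 5)
  expect_equal(grantham_distance("Ala", "Ala"), 0)
  expect_equal(grantham_distance("Cys", "Trp"), 215)
  # symmetry through the lookup, one-letter tolerated
  expect_equal(grantham_distance("W", "C"), 215)
  # non-residues give the sentinel
  expect_equal(grantham_distance("Ter", "Lys"), -1)
  expect_equal(grantham_distance("fs", "Ala"), -1)
  expect_equal(grantham_distance("NA", "Ala"), -1)
})

test_that("protein-change parsing covers the HGVS dialects seen in panels", {
  expect_equal(parse_protein_change("p.?"),
               list(ref = "NA", mut = "NA", prot_class = 0L))
  expect_equal(parse_protein_change("p.(=)"),
               list(ref = "NA", mut = "NA", prot_class = 1L))
  expect_equal(parse_protein_change("p.Leu422="),
               list(ref = "Leu", mut = "NA", prot_class = 1L))
  expect_equal(parse_protein_change("p.Lys385Thr"),
               list(ref = "Lys", mut = "Thr", prot_class = 2L))
  expect_equal(parse_protein_change("p.Ser1518Ter"),
               list(ref = "Ser", mut = "Ter", prot_class = 2L))
  expect_equal(parse_protein_change("p.Lys385IlefsTer"),
               list(ref = "Lys", mut = "fs", prot_class = 2L))
  expect_equal(parse_protein_change("p.Arg123fs"),
               list(ref = "Arg", mut = "fs", prot_class = 2L))
  expect_equal(parse_protein_change("p.Gly104del"),
               list(ref = "Gly", mut = "del", prot_class = 2L))
  expect_equal(parse_protein_change("p.Leu747_Ala750delinsPro"),
               list(ref = "Leu", mut = "del", prot_class = 2L))
  expect_equal(parse_protein_change("p.Glu746dup"),
               list(ref = "Glu", mut = "dup", prot_class = 2L))
  # one-letter substitution
  expect_equal(parse_protein_change("p.V617F"),
               list(ref = "Val", mut = "Phe", prot_class = 2L))
  expect_error(parse_protein_change("p.garbage!!"), "cannot parse")
  expect_error(parse_protein_change(""), "non-empty")
})

test_that("scalar encoders apply the published code maps and reject junk", {
  expect_identical(encode_variant_type("SNV"), 0L)
  expect_identical(encode_variant_type("MNV"), 1L)
  expect_identical(encode_variant_type("indel"), 2L)
  expect_error(encode_variant_type("CNV"), "unknown")

  expect_equal(encode_maf(0.224), 0.224)
  expect_equal(encode_maf(NA), -1)
  expect_equal(encode_maf(0), 0)
  expect_error(encode_maf(1.5), "out of range")

  expect_identical(encode_variant_effect("missense"), 1L)
  expect_identical(encode_variant_effect("frameshift"), 3L)
  expect_identical(encode_variant_effect("nonsense"), 2L)
  expect_identical(encode_variant_effect("synonymous"), 0L)
  expect_identical(encode_variant_effect("unknown"), -1L)
  expect_error(encode_variant_effect("splice"), "unknown variant effect")

  expect_identical(encode_chromosome("chr7"), 7L)
  expect_identical(encode_chromosome("X"), 23L)
  expect_identical(encode_chromosome("Y"), 24L)
  expect_error(encode_chromosome("MT"), "unsupported")
})

test_that("encoders reject arbitrary fuzzed tokens", {
  set.seed(404)
  for (i in 1:50) {
    junk <- paste(sample(c(letters, LETTERS, 0:9), 6, replace = TRUE),
                  collapse = "")
    if (junk %in% c("SNV", "MNV", "INDEL")) next
    expect_error(encode_variant_type(junk))
    expect_error(encode_aa_index(junk, "mut"))
  }
})

test_that("a record becomes the expected 14-feature vector", {
  rec <- list(chrom = "2", pos = 25468888, gene = "DNMT3A",
              variant_type = "SNV", exon = 11, coding = "c.1266G>A",
              protein = "p.Leu422=", vaf = 0.49, maf = 0.224,
              coverage = 1810, effect = "synonymous", label = 0)
  v <- build_feature_vector(rec)
  expect_equal(v[["chr"]], 2)
  expect_equal(v[["TypeBin"]], 0)
  expect_equal(v[["Protbin"]], 1)
  expect_equal(v[["varEffectBin"]], 0)
  expect_equal(v[["MAFbin"]], 0.224)
  expect_equal(v[["aarefbin"]], 17)
  expect_equal(v[["aarefChemical"]], 1.4)
  expect_equal(v[["aamutbin"]], 0)
  expect_equal(v[["aamutChemicalVal"]], 0)
  expect_equal(v[["Grantham"]], -1)
  expect_equal(v[["isMut"]], 0)
  expect_named(v, c(myelotune:::FEATURE_NAMES, "isMut"))

  # intronic record carries sentinels throughout the residue block
  rec$protein <- "p.?"
  rec$effect <- "unknown"
  rec$exon <- 0
  v2 <- build_feature_vector(rec)
  expect_equal(v2[["Protbin"]], 0)
  expect_equal(v2[["aarefbin"]], 0)
  expect_equal(v2[["aamutbin"]], 0)
  expect_equal(v2[["Grantham"]], -1)

  # substitution record fills the residue block
  rec$protein <- "p.Lys385Thr"
  rec$effect <- "missense"
  rec$exon <- 9
  v3 <- build_feature_vector(rec)
  expect_equal(v3[["aarefbin"]], 3)
  expect_equal(v3[["aamutbin"]], 7)
  expect_equal(v3[["Grantham"]], 78)

  rec$coverage <- NA
  expect_error(build_feature_vector(rec), "coverage")
})

test_that("encoding is pure and the substitution sentinels are coherent", {
  co <- generate_cohort(cohort_config(n_snv = 120, n_mnv = 5, n_indel = 35,
                                      n_benign = 140, n_pathogenic = 20,
                                      seed = 5))
  t1 <- build_feature_table(co)
  t2 <- build_feature_table(co)
  expect_identical(t1, t2)
  # Protbin = 2 with a residue mutant token <=> Grantham in [5,215]
  has_sub <- t1$Protbin == 2 & t1$aamutbin >= 1 & t1$aamutbin <= 21
  expect_true(all(t1$Grantham[has_sub] >= 5 & t1$Grantham[has_sub] <= 215))
  expect_true(all(t1$Grantham[!has_sub] == -1))
  expect_true(all(t1$aarefbin[t1$Protbin == 2] > 0))
  expect_true(all(t1$aarefbin[t1$Protbin == 0] == 0))
})

test_that("annotation tables load with the declared dialect rules", {
  path <- write_tiny_tsv()
  rec <- load_annotation_table(path)
  expect_equal(nrow(rec), 3)
  expect_true(is.na(rec$maf[2]))
  expect_equal(rec$maf[1], 0.224)

  # percent dialect rescales VAF
  rec_pct <- load_annotation_table(path, codec_dialect(vaf_unit = "percent"))
  expect_equal(rec_pct$vaf, rec$vaf / 100)

  # missing mandatory column is a configuration error naming it
  expect_error(load_annotation_table(write_tiny_tsv(drop_column = "protein")),
               "protein")

  # header-only file warns and yields zero records
  empty <- tempfile(fileext = ".tsv")
  writeLines(paste(myelotune:::RECORD_COLUMNS, collapse = "\t"), empty)
  expect_warning(out <- load_annotation_table(empty), "no data rows")
  expect_equal(nrow(out), 0)
})

test_that("coverage binarization is off by default and honors the threshold", {
  rec <- load_annotation_table(write_tiny_tsv())
  raw <- build_feature_table(rec)
  expect_equal(raw$Coverage, c(1810, 900, 1500))
  bin <- build_feature_table(rec, codec_dialect(binarize_coverage = 1000))
  expect_equal(bin$Coverage, c(1, 0, 1))
})

test_that("table encoding reports all failing rows at once", {
  rec <- load_annotation_table(write_tiny_tsv())
  rec10 <- rec[rep(1, 10), ]
  rec10$protein[4] <- "p.bogus!!"
  err <- tryCatch(build_feature_table(rec10), error = function(e)
    conditionMessage(e))
  expect_match(err, "1 record\\(s\\) failed")
  expect_match(err, "row 4")
  ok <- build_feature_table(rec)
  expect_equal(dim(ok), c(3, 15))
  expect_equal(ok$isMut, c(0, 1, 1))
})
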