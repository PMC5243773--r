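test_that("FASTA round-trip preserves ids, order and sequences", {
  seqs <- c(g1 = "ACGTACGTAA", g2 = "TTTTCCCCGG")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  got <- read_fasta(path)
  expect_identical(got, seqs)

  set.seed(11)
  long <- c(x = random_seq(500))
  write_fasta(long, path)
  expect_identical(read_fasta(path), long)
})

test_that("FASTA reader normalizes case, U and ambiguity codes", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acguRYacg"), path)
  got <- read_fasta(path)
  expect_identical(unname(got), "ACGTNNACG")
})

test_that("degenerate FASTA inputs raise format errors", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(">x", path)
  expect_error(read_fasta(path), class = "sargtype_format_error")
  writeLines(character(0), path)
  expect_error(read_fasta(path), class = "sargtype_format_error")
  expect_error(read_fasta(file.path(tempdir(), "does-not-exist.fa")),
               class = "sargtype_format_error")
})

test_that("GFF3 round-trip preserves intervals, strands and kinds", {
  feats <- data.frame(
    locus = c("rpl5", "orf129", "trnW(cca)"),
    start = c(10268L, 10781L, 7868L),
    end = c(10387L, 10900L, 7938L),
    strand = c("+", "-", "+"),
    kind = c("CDS", "CDS", "tRNA"),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(feats, path)
  got <- read_gff3(path)
  ord <- order(feats$start)
  expect_equal(got$locus, feats$locus[ord])
  expect_equal(got$start, feats$start[ord])
  expect_equal(got$end, feats$end[ord])
  expect_equal(got$strand, feats$strand[ord])
  expect_equal(got$kind, feats$kind[ord])
})

test_that("malformed GFF3 lines are rejected", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tCDS\t100\t50\t.\t+\t.\tID=bad"), path)
  expect_error(read_gff3(path), class = "sargtype_format_error")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tpseudogene\t10\t50\t.\t+\t.\tID=x"), path)
  expect_error(read_gff3(path), class = "sargtype_format_error")
})

test_that("packaged variant table matches the published counts", {
  v <- sarg_variants()
  expect_equal(nrow(v), 98L)
  # pairwise differing rows: 7 within S. natans, 93 and 96 vs S. fluitans
  expect_equal(sum(v$nt_natansI != v$nt_natansVIII), 7L)
  expect_equal(sum(v$nt_fluitans != v$nt_natansI), 93L)
  expect_equal(sum(v$nt_fluitans != v$nt_natansVIII), 96L)
  expect_true(all(diff(v$position) > 0))

  row <- v[v$position == 10313, ]
  expect_equal(row$locus, "rpl5")
  expect_equal(c(row$nt_fluitans, row$nt_natansI, row$nt_natansVIII),
               c("C", "C", "T"))
  expect_equal(row$aa_chain, "Pro > Ser")
})

test_that("variant table validation rejects bad rows", {
  v <- sarg_variants()
  path <- withr::local_tempfile(fileext = ".tsv")
  mono <- v
  mono$nt_natansVIII[1] <- mono$nt_fluitans[1] <- mono$nt_natansI[1]
  write.table(mono, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_variant_table(path), class = "sargtype_validation_error")

  dup <- v
  dup$position[2] <- dup$position[1]
  write.table(dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_variant_table(path), class = "sargtype_validation_error")

  bad <- v
  bad$nt_fluitans[5] <- "X"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_variant_table(path), class = "sargtype_validation_error")
})

test_that("packaged primer panel carries the published oligos", {
  p <- sarg_primers()
  expect_equal(p$fwd_seq[p$name == "cox2"], "CAAAGATGGATTCGACGGTTGG")
  expect_equal(p$rev_seq[p$name == "cox2"], "CCGGTATCAAACTCGCCCTT")
  expect_equal(nchar(p$fwd_seq[p$name == "cox3"]), 19L)
  expect_equal(p$rev_seq[p$name == "cox3"], "TAGCGTGATGAGCCCATG")
})

test_that("primer panel validation rejects non-ACGT oligos", {
  p <- sarg_primers()
  p$fwd_seq[1] <- sub("A", "X", p$fwd_seq[1])
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_primer_panel(path), class = "sargtype_validation_error")
})
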