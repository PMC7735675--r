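test_that("every format round-trips taxa, labels and matrix exactly", {
  cases <- list(
    random_alignment(3, 8, seed = 101, strict_labels = TRUE),
    random_alignment(5, 73, seed = 102, strict_labels = TRUE),   # interleaved blocks
    random_alignment(4, 130, seed = 103, strict_labels = TRUE),  # 3 strict blocks
    random_alignment(6, 24, seed = 104, strict_labels = TRUE,
                     alphabet = c("M", "K", "L", "w", "E", "-", "?"))
  )
  for (aln in cases) {
    for (fmt in alignment_formats()) {
      path <- withr::local_tempfile()
      write_alignment(aln, path, fmt)
      back <- read_alignment(path, fmt)
      expect_identical(back$taxa, aln$taxa, label = sprintf("taxa (%s)", fmt))
      expect_identical(back$seqs, aln$seqs, label = sprintf("seqs (%s)", fmt))
    }
  }
})

test_that("the sniffer identifies each of the eight formats it wrote", {
  aln <- random_alignment(4, 65, seed = 110, strict_labels = TRUE)
  for (fmt in alignment_formats()) {
    path <- withr::local_tempfile()
    write_alignment(aln, path, fmt)
    expect_identical(detect_format(path), fmt)
    back <- read_alignment(path, "auto")
    expect_identical(back$seqs, aln$seqs)
  }
})

test_that("fasta sentinel and stockholm magic header are recognized", {
  p1 <- withr::local_tempfile(lines = c(">t1", "ACGT"))
  expect_identical(detect_format(p1), "fasta")
  p2 <- withr::local_tempfile(lines = c("# STOCKHOLM 1.0", "t1 ACGT", "//"))
  expect_identical(detect_format(p2), "stockholm")
})

test_that("phylip-relaxed preserves labels longer than the strict field", {
  aln <- alignment(c("a_label_of_23_characters", "short"),
                   c("ACGTACGTACGT", "ACGTACGTACGT"))
  path <- withr::local_tempfile()
  write_alignment(aln, path, "phylip_relaxed")
  back <- read_alignment(path, "auto")
  expect_identical(detect_format(path), "phylip_relaxed")
  expect_identical(back$taxa, aln$taxa)
  # and strict refuses such labels rather than truncating them
  expect_error(write_alignment(aln, withr::local_tempfile(), "phylip"),
               class = "malformed_alignment")
})

test_that("clustal output interleaves long alignments and re-parses", {
  aln <- random_alignment(3, 120, seed = 115, strict_labels = TRUE)
  path <- withr::local_tempfile()
  write_alignment(aln, path, "clustal")
  body <- readLines(path)
  seq_lines <- body[!grepl("^CLUSTAL", body) & trimws(body) != ""]
  chunks <- vapply(strsplit(seq_lines, "\\s+"), function(x) nchar(x[2]), integer(1))
  expect_true(all(chunks <= 60))
  expect_gt(length(seq_lines), 3)  # > one block
  expect_identical(read_alignment(path, "clustal")$seqs, aln$seqs)
})

test_that("multi-block maf and xmfa files yield the first block plus a warning", {
  aln <- alignment(c("t1", "t2"), c("A-CT", "AGCT"))
  p <- withr::local_tempfile()
  write_alignment(aln, p, "maf")
  writeLines(c(readLines(p), "", "a", "s t1 0 2 + 2 GG", "s t2 0 2 + 2 CC"), p)
  expect_warning(first <- read_alignment(p, "maf"), class = "multi_block")
  expect_identical(first$seqs, aln$seqs)

  p2 <- withr::local_tempfile()
  write_alignment(aln, p2, "mauve")
  writeLines(c(readLines(p2), "> 1:1-2 + t1", "GG", "> 2:1-2 + t2", "CC", "="), p2)
  expect_identical(detect_format(p2), "mauve")
  expect_warning(first2 <- read_alignment(p2, "mauve"), class = "multi_block")
  expect_identical(first2$seqs, aln$seqs)
})

test_that("dots are read as gaps in stockholm and maf dialects", {
  p <- withr::local_tempfile(lines = c("# STOCKHOLM 1.0", "t1 AC.T", "t2 ACGT", "//"))
  expect_identical(read_alignment(p)$seqs, c("AC-T", "ACGT"))
})

test_that("zero-length alignments are written with a warning and read back", {
  aln <- alignment(c("t1", "t2"), c("", ""))
  for (fmt in alignment_formats()) {
    path <- withr::local_tempfile()
    expect_warning(write_alignment(aln, path, fmt), class = "empty_alignment")
    back <- suppressWarnings(read_alignment(path, fmt))
    expect_identical(back$taxa, aln$taxa, label = fmt)
    expect_identical(back$seqs, aln$seqs, label = fmt)
  }
})

test_that("malformed inputs raise classed errors", {
  ragged <- withr::local_tempfile(lines = c(">t1", "ACGT", ">t2", "ACG"))
  expect_error(read_alignment(ragged), class = "malformed_alignment")
  dup <- withr::local_tempfile(lines = c(">t1", "ACGT", ">t1", "ACGT"))
  expect_error(read_alignment(dup), class = "duplicate_taxon")
  junk <- withr::local_tempfile(lines = c("not an alignment at all"))
  expect_error(detect_format(junk), class = "unknown_format")
  expect_error(read_alignment(withr::local_tempfile(), "fasta"), class = "io_error")
})

test_that("sequence type detection uses the 0.8 nucleotide fraction rule", {
  expect_identical(detect_sequence_type(alignment("t1", "ACGTACGT")), "nucleotide")
  expect_identical(
    detect_sequence_type(alignment(c("t1", "t2"), c("MKLWE", "MKLWE"))),
    "amino_acid")
  # 50 nucleotide chars + 1 E: fraction 50/51 > 0.8
  mixed <- alignment("t1", paste0(strrep("ACGTA", 10), "E"))
  expect_identical(detect_sequence_type(mixed), "nucleotide")
  allgap <- alignment(c("t1", "t2"), c("--", "--"))
  expect_error(detect_sequence_type(allgap), class = "sequence_type_undetermined")
})
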