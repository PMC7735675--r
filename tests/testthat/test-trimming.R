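test_that("keep_site implements the five mode rules with a strict threshold", {
  expect_true(keep_site("parsimony-informative", 0.95, "kpi", 0.9))
  expect_false(keep_site("constant", 0.0, "kpi", 0.9))
  expect_true(keep_site("constant", 0.0, "kpic", 0.9))
  expect_false(keep_site("other", 0.9, "gappy", 0.9))   # 0.9 is not < 0.9
  expect_true(keep_site("other", 0.89, "gappy", 0.9))
  expect_false(keep_site("parsimony-informative", 0.95, "kpi-gappy", 0.9))
  expect_true(keep_site("parsimony-informative", 0.5, "kpi-gappy", 0.9))
  expect_false(keep_site("constant", 0.5, "kpi-gappy", 0.9))
  expect_true(keep_site("constant", 0.5, "kpic-gappy", 0.9))
  expect_error(keep_site("constant", 0.5, "nonsense", 0.9), class = "unknown_mode")
})

# columns: AABB / AAAA / A-CG / ----
example_aln <- function() {
  alignment(paste0("t", 1:4), c("AAA-", "AA--", "BAC-", "BAG-"))
}

test_that("trim keeps exactly the columns the mode rule selects, in order", {
  res_kpi <- trim(example_aln(), mode = "kpi")
  expect_identical(res_kpi$trimmed$seqs, c("A", "A", "B", "B"))
  expect_identical(res_kpi$log$kept, c(TRUE, FALSE, FALSE, FALSE))

  res_kpic <- trim(example_aln(), mode = "kpic")
  expect_identical(res_kpic$trimmed$seqs, c("AA", "AA", "BA", "BA"))

  res_gappy <- trim(example_aln(), mode = "gappy", g = 0.9)
  expect_identical(res_gappy$trimmed$seqs, c("AAA", "AA-", "BAC", "BAG"))
  expect_identical(res_gappy$log$gappyness, c(0, 0, 0.25, 1))
})

test_that("every mode is idempotent", {
  for (seed in 1:10) {
    aln <- random_designed(seed + 300)$alignment
    for (mode in trim_modes()) {
      once <- suppressWarnings(trim(aln, mode))
      twice <- suppressWarnings(trim(once$trimmed, mode))
      expect_identical(twice$trimmed$seqs, once$trimmed$seqs,
                       label = sprintf("mode %s seed %d", mode, seed))
    }
  }
})

test_that("kept-column sets form the expected lattice across modes", {
  for (seed in 1:25) {
    aln <- random_designed(seed + 400)$alignment
    kept <- lapply(trim_modes(), function(m) {
      which(suppressWarnings(trim(aln, m))$log$kept)
    })
    names(kept) <- trim_modes()
    expect_true(all(kept$kpi %in% kept$kpic))
    expect_identical(kept$`kpi-gappy`, intersect(kept$kpi, kept$gappy))
    expect_identical(kept$`kpic-gappy`, intersect(kept$kpic, kept$gappy))
    expect_true(all(kept$`kpi-gappy` %in% kept$`kpic-gappy`))
  }
})

test_that("raising the gappy threshold only ever keeps more sites", {
  aln <- random_designed(555)$alignment
  thresholds <- c(0, 0.25, 0.5, 0.75, 0.9, 1)
  kept <- lapply(thresholds, function(g) {
    which(suppressWarnings(trim(aln, "gappy", g = g))$log$kept)
  })
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i]] %in% kept[[i + 1]]))
  }
})

test_that("threshold extremes behave exactly as specified", {
  aln <- example_aln()
  # g = 0: nothing has gappyness < 0, everything removed (with a warning)
  expect_warning(res0 <- trim(aln, "gappy", g = 0), class = "empty_trim_result")
  expect_identical(alignment_length(res0$trimmed), 0L)
  # g = 1: only fully gapped columns (gappyness == 1) removed
  res1 <- trim(aln, "gappy", g = 1)
  expect_identical(res1$log$kept, c(TRUE, TRUE, TRUE, FALSE))
  expect_error(trim(aln, "gappy", g = 1.5), class = "bad_threshold")
})

test_that("the log conserves every input column and matches the file format", {
  res <- trim(example_aln(), mode = "kpi")
  path <- withr::local_tempfile()
  write_log(res, path)
  rows <- readLines(path)
  expect_length(rows, alignment_length(example_aln()))
  expect_identical(rows[1], "1 keep parsimony-informative 0.0000")
  expect_identical(rows[4], "4 trim other 1.0000")
  fields <- strsplit(rows, " ")
  expect_true(all(lengths(fields) == 4))
  expect_identical(as.integer(vapply(fields, `[`, "", 1)),
                   seq_along(rows))
  expect_identical(sum(vapply(fields, `[`, "", 2) == "keep"),
                   alignment_length(res$trimmed))
})

test_that("trimming preserves taxa and concatenated kept columns equal the output", {
  fx <- random_designed(777)
  res <- suppressWarnings(trim(fx$alignment, "kpic-gappy"))
  expect_identical(res$trimmed$taxa, fx$alignment$taxa)
  rebuilt <- subset_columns(fx$alignment, res$log$kept)
  expect_identical(rebuilt$seqs, res$trimmed$seqs)
})
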