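test_that("read_fasta parses single and multi-record files and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "MKV"), f)
  r <- read_fasta(f)
  expect_equal(nrow(r), 1L)
  expect_equal(r$id, "s1")
  expect_equal(r$sequence, "MKV")

  writeLines(c(">a desc here", "MK", "VL", ">b", "ACGT"), f)
  r <- read_fasta(f)
  expect_equal(r$id, c("a", "b"))
  expect_equal(r$sequence, c("MKVL", "ACGT"))
  expect_equal(r$description, c("desc here", ""))

  # write -> read identity on (id, sequence)
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(r, f2, width = 3L)
  r2 <- read_fasta(f2)
  expect_equal(r2$id, r$id)
  expect_equal(r2$sequence, r$sequence)
})

test_that("read_fasta rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines("MKV", f)
  expect_error(read_fasta(f), "header")
  expect_error(read_fasta(file.path(tempdir(), "no-such-file.fa")), "not found")
})

test_that("validators return length for canonical sequences and 0 otherwise", {
  expect_identical(validate_protein("MKV"), 3L)
  expect_identical(validate_protein("MKB1"), 0L)
  expect_identical(validate_protein(""), 0L)
  expect_identical(validate_protein("mkv"), 3L)        # case-folded
  expect_identical(validate_protein("M K\nV"), 3L)     # whitespace stripped
  for (bad in c("B", "Z", "X", "U", "O", "-", "*"))
    expect_identical(validate_protein(paste0("MK", bad)), 0L)

  expect_identical(validate_dna("ACGT"), 4L)
  expect_identical(validate_dna("ACGU"), 0L)           # RNA rejected
  expect_identical(validate_dna("acgt"), 4L)
  expect_identical(validate_dna(""), 0L)
})

test_that("validator result is always 0 or the stripped length", {
  set.seed(42)
  pool <- c(LETTERS, letters, as.character(0:9), " ", "-", "*")
  for (i in 1:50) {
    s <- paste(sample(pool, sample(0:30, 1), replace = TRUE), collapse = "")
    stripped <- toupper(gsub("\\s+", "", s))
    expect_true(validate_protein(s) %in% c(0L, nchar(stripped)))
    expect_true(validate_dna(s) %in% c(0L, nchar(stripped)))
  }
})

test_that("random_sequences is seed-deterministic and validator-closed", {
  a <- random_sequences("dna", 2, 4, seed = 1)
  b <- random_sequences("dna", 2, 4, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, random_sequences("dna", 2, 4, seed = 2)))

  p <- random_sequences("protein", 1, 50, seed = 7)
  expect_identical(validate_protein(p), 50L)

  # base frequencies concentrate near 1/4 (binomial bound at n = 1000 x 100)
  d <- random_sequences("dna", 1000, 100, seed = 3)
  all_chars <- unlist(strsplit(d, ""))
  freq <- table(all_chars) / length(all_chars)
  expect_true(all(freq > 0.2 & freq < 0.3))

  expect_error(random_sequences("rna", 1, 10, seed = 1))
})
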