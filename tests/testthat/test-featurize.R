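test_that("a protein FASTA batch produces the expected table shape", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(data.frame(id = paste0("p", 1:3),
                         sequence = random_sequences("protein", 3, 50, 101)),
              fa)
  out <- withr::local_tempfile(fileext = ".csv")
  cfg <- load_config(input = fa, kind = "protein", families = "aac",
                     output = out)
  res <- suppressMessages(run_featurize(cfg))
  expect_equal(res$status, 0L)
  expect_equal(res$written, 3L)
  tab <- utils::read.csv(out, check.names = FALSE)
  expect_equal(dim(tab), c(3L, 21L))   # id + 20 composition columns
  expect_equal(tab$id, paste0("p", 1:3))
})

test_that("invalid records are skipped with accounting, never silently", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">d1", "ACGTACGTACGTACGT", ">bad", "ACGUACGU",
               ">d2", "TTTTCCCCGGGGAAAA"), fa)
  out <- withr::local_tempfile(fileext = ".csv")
  cfg <- load_config(input = fa, kind = "dna", families = "kmer",
                     output = out)
  msgs <- capture.output(res <- run_featurize(cfg), type = "message")
  expect_equal(res$written, 2L)
  expect_equal(res$skipped, 1L)
  expect_equal(res$written + res$skipped, 3L)
  expect_true(any(grepl("bad", msgs)))
  expect_true(any(grepl("skipped 1 of 3", msgs)))
})

test_that("identical configurations produce byte-identical output", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(data.frame(id = "p1",
                         sequence = random_sequences("protein", 1, 60, 5)), fa)
  o1 <- withr::local_tempfile(fileext = ".csv")
  o2 <- withr::local_tempfile(fileext = ".csv")
  suppressMessages({
    run_featurize(load_config(input = fa, kind = "protein",
                              families = c("aac", "ctd"), output = o1))
    run_featurize(load_config(input = fa, kind = "protein",
                              families = c("aac", "ctd"), output = o2))
  })
  expect_identical(readLines(o1), readLines(o2))
})

test_that("config validation catches unknown families and bad parameters", {
  expect_error(load_config(kind = "protein", families = "nope"),
               "unknown famil")
  expect_error(load_config(kind = "squid"), "kind must be")
  # precondition errors surface per record (lambda too large for length 40)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(data.frame(id = "p1",
                         sequence = random_sequences("protein", 1, 40, 5)), fa)
  out <- withr::local_tempfile(fileext = ".csv")
  cfg <- load_config(input = fa, kind = "protein", families = "pseaac",
                     params = list(lambda = 60), output = out)
  res <- suppressMessages(run_featurize(cfg))
  expect_equal(res$status, 1L)
  expect_equal(res$skipped, 1L)
})

test_that("flags override config-file values", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("kind: protein", "families: aac", "digits: 4"), yml)
  cfg <- load_config(yml, families = "ctd")
  expect_equal(cfg$families, "ctd")
  expect_equal(cfg$digits, 4L)
  expect_equal(cfg$kind, "protein")
})

test_that("write_table round-trips values and rejects heterogeneous rows", {
  rows <- list(feature_vector(c(1.234567, 2), c("a", "b")),
               feature_vector(c(3, 4.7654321), c("a", "b")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_table(rows, "csv", f)
  tab <- utils::read.csv(f, check.names = FALSE)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$a, c(1.23457, 3), tolerance = 1e-5)

  fj <- withr::local_tempfile(fileext = ".json")
  write_table(rows, "json", fj, ids = c("x", "y"))
  j <- jsonlite::fromJSON(fj)
  expect_equal(j$id, c("x", "y"))
  expect_equal(j$b, c(2, 4.76543), tolerance = 1e-5)

  bad <- list(rows[[1]], feature_vector(1, "z"))
  expect_error(write_table(bad, "csv", f), "heterogeneous")
})

test_that("chemical SMILES batches featurize through the same driver", {
  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO\tethanol", "CCCC\tbutane", "((bad", "c1ccccc1\tbenzene"), smi)
  out <- withr::local_tempfile(fileext = ".tsv")
  cfg <- load_config(input = smi, kind = "chem",
                     families = c("constitution", "kappa"),
                     out_format = "tsv", output = out)
  res <- suppressMessages(run_featurize(cfg))
  expect_equal(res$written, 3L)
  expect_equal(res$skipped, 1L)
  tab <- utils::read.delim(out, check.names = FALSE)
  expect_equal(dim(tab), c(3L, 38L))   # id + 30 + 7
  expect_equal(tab$id, c("ethanol", "butane", "benzene"))
})

test_that("pair featurization joins tables and combines rows", {
  ta <- data.frame(id = c("p1", "p2"), f1 = c(1, 2), f2 = c(3, 4))
  pairs <- data.frame(id_a = c("p1", "p2"), id_b = c("p2", "p1"))
  rows <- featurize_pairs(pairs, ta, ta, mode = "same", strategy = "tensor")
  expect_length(rows, 2L)
  # p1 = (1, 3), p2 = (2, 4): tensor = (1*2, 1*4, 3*2, 3*4)
  expect_equal(as.numeric(rows[[1]]$values), c(2, 4, 6, 12))
  both <- featurize_pairs(pairs, ta, ta, mode = "same", strategy = "concat",
                          ordering = "both")
  expect_length(both, 4L)
  expect_error(featurize_pairs(data.frame(id_a = "zz", id_b = "p1"), ta, ta),
               "zz")
})
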