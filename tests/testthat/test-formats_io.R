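test_that("FASTA reading preserves order, uppercases, and validates", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1 some description", "ACDEFGH", ">c2", "mklv"), path)
  chains <- read_fasta(path)
  expect_s3_class(chains, "chain_set")
  expect_equal(chains$chain_id, c("c1", "c2"))
  expect_equal(nchar(chains$sequence), c(7L, 4L))
  expect_equal(chains$sequence[2], "MKLV")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1", "ACD", ">c1", "EFG"), dup)
  expect_error(read_fasta(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1", "ACZD"), bad)
  expect_error(read_fasta(bad), "illegal residue.*position 3.*c1")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty")
})

test_that("FASTA write/read round trip is the identity", {
  ds <- small_dataset(n_chains = 3L)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ds$chains, path)
  back <- read_fasta(path)
  expect_equal(back$chain_id, ds$chains$chain_id)
  expect_equal(back$sequence, ds$chains$sequence)
})

test_that("PSSM parser reads the log-odds block and validates the chain", {
  seq7 <- "ACDEFGH"
  raw <- matrix(round(rnorm(7 * 20, sd = 3)), 7, 20)
  path <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(raw, seq7, path)
  prof <- read_pssm(path, "c1", seq7)
  expect_equal(unname(prof$raw), raw, ignore_attr = TRUE)
  expect_equal(dim(prof$raw), c(7L, 20L))

  # all-zero score rows are read literally
  zpath <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(matrix(0, 3, 20), "ACD", zpath)
  expect_true(all(read_pssm(zpath, "z", "ACD")$raw == 0))

  # length and residue cross-checks
  expect_error(read_pssm(path, "c1", "ACDEFG"), "7 rows.*length is 6")
  expect_error(read_pssm(path, "c1", "ACDEFGY"), "mismatch.*position 7")
})

test_that("SS predictions round trip and validate structure", {
  ds <- small_dataset(n_chains = 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ss_predictions(ds$ss, path)
  back <- read_ss_predictions(path, ds$chains)
  expect_equal(back, ds$ss)
  # four sources per chain
  expect_length(back[[1]], 4L)

  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gap <- df[!(df$chain_id == df$chain_id[1] & df$source == df$source[1] & df$pos == 3L), ]
  gpath <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(gap, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_ss_predictions(gpath), "non-contiguous")

  bad <- df
  bad$state[5] <- "Q"
  bpath <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(bad, bpath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_ss_predictions(bpath), "outside \\{H,E,C\\}")

  badc <- df
  badc$conf[2] <- 12L
  cpath <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(badc, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_ss_predictions(cpath), "0-9")
})

test_that("turn labels round trip and validate alphabet and length", {
  ds <- small_dataset(n_chains = 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_turn_labels(ds$labels, path)
  expect_equal(read_turn_labels(path, ds$chains), ds$labels)

  bad <- ds$labels
  bad[1] <- "ttnnx"
  bpath <- withr::local_tempfile(fileext = ".tsv")
  write_turn_labels(bad, bpath)
  expect_error(read_turn_labels(bpath), "outside \\{t,n\\}")
})

test_that("prediction records round trip within 1e-6 and refuse bad probabilities", {
  records <- data.frame(chain_id = rep("c1", 5), pos = 1:5,
                        prob = c(0, 0.1234567, 0.5, 0.999999, 1),
                        raw = c("n", "n", "t", "t", "t"),
                        smoothed = c("n", "n", "t", "t", "t"),
                        stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(records, path)
  back <- read_predictions(path)
  expect_lt(max(abs(back$prob - records$prob)), 1e-6)
  expect_equal(back$raw, records$raw)
  expect_equal(back$smoothed, records$smoothed)

  records$prob[2] <- 1.5
  expect_error(write_predictions(records, path), "outside \\[0,1\\]")

  # header-only output for empty input
  epath <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(records[0, ], epath)
  expect_equal(length(readLines(epath)), 1L)
})
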