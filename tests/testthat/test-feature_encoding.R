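test_that("PSSM scaling is the logistic squashing", {
  expect_equal(scale_pssm(matrix(0, 2, 20))[1, 1], 0.5)
  expect_equal(scale_pssm(matrix(2, 1, 20))[1, 1], 1 / (1 + exp(-2)))
  big <- scale_pssm(matrix(c(100, -100), 1, 20))
  expect_true(big[1, 1] > 1 - 1e-12 && big[1, 2] < 1e-12)
  expect_true(all(diff(scale_pssm(matrix(seq(-5, 5, length.out = 20), 1, 20))[1, ]) > 0))
  expect_error(scale_pssm(matrix(c(1, NA), 1, 2)), "non-finite")
})

test_that("PSSM window encoding pads termini with zeros", {
  scaled <- matrix(0.5, 7, 20)
  v <- encode_pssm_window(scaled, 4L, 7L)
  expect_length(v, 140L)
  expect_true(all(v == 0.5))

  # position 1: three off-chain positions contribute 60 zeros, then rows 1..4
  scaled2 <- matrix(runif(7 * 20), 7, 20)
  v1 <- encode_pssm_window(scaled2, 1L, 7L)
  expect_equal(v1[1:60], rep(0, 60))
  expect_equal(v1[61:140], as.vector(t(scaled2[1:4, ])))

  expect_error(encode_pssm_window(scaled, 4L, 6L), "odd")
  expect_error(encode_pssm_window(scaled, 8L, 7L), "out of range")
})

test_that("SS block follows the documented 12+4+48+12 layout", {
  ds <- tiny_manual_dataset()
  v <- encode_ss_block(ds$ss$c1, 4L)
  expect_length(v, 76L)

  # central states C,C,C,C -> one-hot block (per source: H,E,C)
  expect_equal(v[1:12], rep(c(0, 0, 1), 4))
  # confidence block: digits / 10
  expect_equal(v[13:16], c(0.9, 0.5, 0.3, 0.7))
  # psipred is all-C: its C patterns are CCC=(1,0,0,0), C ratio 1
  expect_equal(v[16 + 9:12], c(1, 0, 0, 0))
  expect_equal(v[64 + 3], 1.0)

  # the published worked example: central residue H,C,H,H across sources
  ss2 <- list(psipred = list(states = "HHH", conf = c(5L, 5L, 5L)),
              jnet = list(states = "CCC", conf = c(5L, 5L, 5L)),
              transec = list(states = "HHH", conf = c(5L, 5L, 5L)),
              proteus = list(states = "HHH", conf = c(5L, 5L, 5L)))
  v2 <- encode_ss_block(ss2, 2L)
  expect_equal(v2[1:12], c(1, 0, 0, 0, 0, 1, 1, 0, 0, 1, 0, 0))

  # boundary residues have no 3-residue pattern
  v_edge <- encode_ss_block(ds$ss$c1, 1L)
  expect_true(all(v_edge[17:64] == 0))

  expect_error(encode_ss_block(ds$ss$c1[1:3], 1L), "missing SS sources")
})

test_that("dataset encoding has the documented geometry and provenance", {
  ds <- small_dataset(n_chains = 4L)
  enc <- encode_dataset(ds)
  expect_equal(ncol(enc$X), 216L)
  expect_equal(nrow(enc$X), sum(nchar(ds$chains$sequence)))
  expect_equal(length(enc$y), nrow(enc$X))
  expect_true(all(enc$X >= 0 & enc$X <= 1))
  # indicator blocks are exactly binary
  onehot_cols <- 141:152
  pattern_cols <- 157:204
  expect_true(all(enc$X[, c(onehot_cols, pattern_cols)] %in% c(0, 1)))

  # provenance of a row maps back to the correct (chain, pos)
  set.seed(1)
  for (k in sample(nrow(enc$X), 5L)) {
    cid <- enc$provenance$chain_id[k]
    pos <- enc$provenance$pos[k]
    scaled <- scale_pssm(ds$pssms[[cid]])
    expect_equal(unname(enc$X[k, 1:140]), encode_pssm_window(scaled, pos, 7L))
    expect_equal(unname(enc$X[k, 141:216]), encode_ss_block(ds$ss[[cid]], pos, 7L))
  }

  # width law for other odd windows
  expect_equal(ncol(encode_dataset(ds, window = 5L)$X), 20L * 5L + 76L)
  expect_equal(ncol(encode_dataset(ds, window = 9L)$X), 20L * 9L + 76L)

  ds$pssms[[1]] <- NULL
  expect_error(encode_dataset(ds), "missing PSSM")
})

test_that("feature ranking rewards class-identical features and zeroes constants", {
  set.seed(7)
  n <- 300L
  y <- rep(c(1, -1), length.out = n)
  X <- cbind(ifelse(y > 0, 0.9, 0.1),   # class indicator
             runif(n),                  # noise
             rep(0.5, n))               # constant
  sel <- rank_features(X, y)
  expect_equal(sel$ranked_indices[1], 1L)
  expect_equal(which.max(sel$scores$information_gain), 1L)
  expect_equal(which.max(sel$scores$chi_squared), 1L)
  expect_equal(sel$scores$information_gain[3], 0)
  expect_equal(sel$scores$chi_squared[3], 0)

  # permuting feature columns permutes ranks consistently
  perm <- c(2L, 3L, 1L)
  sel_p <- rank_features(X[, perm], y)
  expect_equal(perm[sel_p$ranked_indices], sel$ranked_indices)

  expect_error(rank_features(X, rep(1, n)), "both classes")
})

test_that("feature selection keeps top-k columns in original order", {
  ds <- small_dataset(n_chains = 8L)
  enc <- encode_dataset(ds)
  sel <- rank_features(enc$X, enc$y)
  X90 <- select_features(sel, enc$X, k = 90L)
  expect_equal(ncol(X90), 90L)
  expect_equal(select_features(sel, enc$X, k = ncol(enc$X)), enc$X)
  expect_error(select_features(sel, enc$X, k = 300L), "exceeds")

  # a selector fitted on one split applies identical indices to another
  half <- seq_len(nrow(enc$X) %/% 2L)
  sel_a <- rank_features(enc$X[half, ], enc$y[half])
  idx <- selected_indices(sel_a, 90L)
  expect_equal(colnames(select_features(sel_a, enc$X[-half, , drop = FALSE], 90L)),
               colnames(enc$X)[idx])

  # selector JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_selector(sel, path)
  back <- read_selector(path)
  expect_equal(back$ranked_indices, sel$ranked_indices)
})

test_that("encoding is position-local", {
  ds <- small_dataset(n_chains = 1L)
  enc <- encode_dataset(ds)
  cid <- ds$chains$chain_id[1]
  ds2 <- ds
  j <- 15L
  ds2$pssms[[cid]][j, ] <- ds2$pssms[[cid]][j, ] + 5L
  enc2 <- encode_dataset(ds2)
  changed <- which(rowSums(abs(enc$X - enc2$X)) > 0)
  expect_true(all(abs(changed - j) <= 3L))
})
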