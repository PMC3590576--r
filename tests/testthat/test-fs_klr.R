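test_that("prototype selection is a seeded k-center surrogate", {
  set.seed(2)
  blob1 <- matrix(rnorm(40, mean = 0), 20, 2)
  blob2 <- matrix(rnorm(40, mean = 8), 20, 2)
  X <- rbind(blob1, blob2)

  pv <- select_prototypes(X, 2L, seed = 11L)
  expect_s3_class(pv, "prototype_set")
  expect_equal(pv$m, 2L)
  # one prototype per blob
  expect_equal(sort(as.integer(pv$indices <= 20)), c(0L, 1L))

  # determinism given the seed; a different seed may differ
  pv2 <- select_prototypes(X, 2L, seed = 11L)
  expect_identical(pv$indices, pv2$indices)

  # m = n keeps every point
  pv_all <- select_prototypes(X, 40L, seed = 1L)
  expect_equal(pv_all$indices, 1:40)

  expect_error(select_prototypes(X, 41L, seed = 1L), "1 <= m <= n")
  expect_error(select_prototypes(X[0, , drop = FALSE], 1L), "empty")

  # prototypes are actual data rows
  pv5 <- select_prototypes(X, 5L, seed = 3L)
  expect_equal(pv5$vectors, X[pv5$indices, , drop = FALSE])
})

test_that("outlier clusters are dropped and re-seeded from large clusters", {
  set.seed(4)
  X <- rbind(matrix(rnorm(100, 0, 0.3), 50, 2),
             matrix(rnorm(100, 5, 0.3), 50, 2),
             matrix(c(50, 50), 1, 2))  # single far outlier
  pv <- select_prototypes(X, 3L, seed = 5L, outlier_min_frac = 0.05)
  # the outlier row must not survive as a prototype
  expect_false(101L %in% pv$indices)
})

test_that("Nystrom map reconstructs the kernel where it should", {
  set.seed(6)
  X <- matrix(rnorm(30), 10, 3)
  gamma <- 0.6

  # m = 1: trivial map
  pv1 <- prototype_set(X, 1L)
  map1 <- build_nystrom_map(pv1, gamma)
  expect_equal(map1$p, 1L)
  expect_equal(map1$eigvals, 1)

  # duplicated prototype rows are rank-deficient
  Xdup <- X[c(1, 1, 2, 3), ]
  mapd <- build_nystrom_map(prototype_set(Xdup, 1:4), gamma)
  expect_lt(mapd$p, 4L)

  # exactness on the landmarks
  pv <- prototype_set(X, 1:6)
  map <- build_nystrom_map(pv, gamma)
  Phi_pv <- apply_nystrom_map(map, X[1:6, ])
  expect_equal(tcrossprod(Phi_pv), gram_matrix(X[1:6, ], X[1:6, ], gamma),
               tolerance = 1e-8)

  # full-sample Nystrom is exact everywhere
  map_full <- build_nystrom_map(prototype_set(X, 1:10), gamma)
  Phi <- apply_nystrom_map(map_full, X)
  expect_equal(tcrossprod(Phi), gram_matrix(X, X, gamma), tolerance = 1e-8)

  expect_error(apply_nystrom_map(map, matrix(0, 2, 5)), "width mismatch")
})

test_that("the out-of-sample eigen-extension carries the n/m scalings", {
  set.seed(10)
  X <- matrix(rnorm(30), 10, 3)
  gamma <- 0.9
  m <- 4L
  pv <- prototype_set(X, 1:m)
  map <- build_nystrom_map(pv, gamma)
  ext <- nystrom_extension(map, X)

  Kmm <- gram_matrix(X[1:m, ], X[1:m, ], gamma)
  Knm <- gram_matrix(X, X[1:m, ], gamma)
  ee <- eigen(Kmm, symmetric = TRUE)
  n <- 10
  for (i in seq_len(map$p)) {
    expect_equal(ext$values[i], (n / m) * ee$values[i], tolerance = 1e-8)
    u_ext <- sqrt(m / n) * (1 / ee$values[i]) * drop(Knm %*% ee$vectors[, i])
    # eigenvectors are determined up to sign
    expect_equal(abs(ext$vectors[, i]), abs(u_ext), tolerance = 1e-8)
  }
})

test_that("Nystrom reconstruction error is non-increasing on nested prototype sets", {
  set.seed(12)
  X <- matrix(rnorm(40 * 4), 40, 4)
  gamma <- 0.4
  K <- gram_matrix(X, X, gamma)
  errs <- vapply(c(5L, 10L, 20L, 40L), function(m) {
    map <- build_nystrom_map(prototype_set(X, seq_len(m)), gamma)
    Phi <- apply_nystrom_map(map, X)
    norm(K - tcrossprod(Phi), "F")
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  expect_lt(errs[4], 1e-8)
})

test_that("trust-region Newton solves the primal to oracle accuracy", {
  toy <- toy_problem(20L, 5L, seed = 42L)
  fit <- fit_primal_tron(toy$X, toy$y, lambda = 1.5)
  expect_equal(fit$objective, primal_optim_oracle(toy$X, toy$y, 1.5),
               tolerance = 1e-6)
  # the objective can never exceed the value at zero
  expect_lte(fit$objective, (1.5 / 2) * 20 * log(2))

  # balanced labels on identical rows admit only the symmetric solution
  Phi_const <- matrix(1, 10, 3)
  y_bal <- rep(c(1, -1), 5)
  fit_sym <- fit_primal_tron(Phi_const, y_bal, lambda = 1)
  expect_lt(max(abs(c(fit_sym$w, fit_sym$b))), 1e-6)

  expect_error(fit_primal_tron(toy$X, rep(1, 20), 1), "both classes")
})

test_that("late trust-region iterations converge faster than early ones", {
  toy <- toy_problem(60L, 5L, seed = 17L)
  fit <- fit_primal_tron(toy$X, toy$y, lambda = 1, tol = 1e-10)
  g <- fit$grad_norms
  expect_gte(length(g), 3L)
  ratios <- g[-1] / utils::head(g, -1)
  # the final contraction is much stronger than the first: full Newton tail
  expect_lt(utils::tail(ratios, 1), 0.2 * ratios[1])
})

test_that("fixed-size KLR at m = n matches exact dual KLR", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(50 * 5), 50, 5)
    y <- ifelse(X[, 1] - X[, 2] + rnorm(50, sd = 0.4) > 0, 1, -1)
    if (length(unique(y)) < 2L) next
    hyper <- hyperparams(1, 0.5)
    model <- fs_klr_train(X, y, hyper, m = 50L, seed = seed)
    dual <- klr_fit_dual(X, y, lambda = 1, gamma = 0.5)
    expect_lt(max(abs(fs_klr_predict(model, X)$prob - predict_dual(dual, X))),
              1e-3)
  }
})

test_that("training is deterministic and rejects degenerate inputs", {
  set.seed(31)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- ifelse(X[, 1] > 0, 1, -1)
  hyper <- hyperparams(1, 0.3)
  m1 <- fs_klr_train(X, y, hyper, m = 20L, seed = 9L)
  m2 <- fs_klr_train(X, y, hyper, m = 20L, seed = 9L)
  expect_identical(m1$w, m2$w)
  expect_identical(m1$map$prototypes$indices, m2$map$prototypes$indices)
  expect_error(fs_klr_train(X, rep(1, 60), hyper, m = 10L), "both classes")
  expect_error(fs_klr_train(X, y, hyper, m = 100L), "exceed")
})

test_that("prediction applies the >= threshold rule monotonically", {
  set.seed(33)
  X <- matrix(rnorm(80 * 3), 80, 3)
  y <- ifelse(X[, 1] > 0, 1, -1)
  model <- fs_klr_train(X, y, hyperparams(1, 0.4, threshold = 0.5), m = 30L,
                        seed = 2L)
  pred <- fs_klr_predict(model, X)
  expect_equal(pred$label, ifelse(pred$prob >= 0.5, "t", "n"))

  # boundary: p exactly at the threshold counts as a turn
  model_b <- model
  model_b$w <- numeric(model$map$p)
  model_b$b <- 0
  pb <- fs_klr_predict(model_b, X)
  expect_true(all(pb$prob == 0.5) && all(pb$label == "t"))

  # raising the threshold never increases the number of turns
  n_t <- vapply(c(0.2, 0.45, 0.7, 0.9), function(th) {
    m <- model; m$hyper$threshold <- th
    sum(fs_klr_predict(m, X)$label == "t")
  }, numeric(1))
  expect_true(all(diff(n_t) <= 0))
})

test_that("model JSON serialization reproduces predictions exactly", {
  set.seed(40)
  X <- matrix(rnorm(50 * 4), 50, 4)
  y <- ifelse(X[, 2] > 0, 1, -1)
  model <- fs_klr_train(X, y, hyperparams(2, 0.6), m = 15L, seed = 4L)
  path <- withr::local_tempfile(fileext = ".json")
  write_fsklr_model(model, path)
  back <- read_fsklr_model(path)
  expect_equal(fs_klr_predict(back, X)$prob, fs_klr_predict(model, X)$prob,
               tolerance = 1e-12)
  expect_equal(back$hyper, model$hyper)
})
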