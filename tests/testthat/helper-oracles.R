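# Independent reference implementations used as oracles.  These are kept
# deliberately naive and structurally different from the package code.

# Brute-force state-changing rule engine: literal pattern scans with
# per-pattern flip functions, matches collected on the pass input.
brute_rules <- function(s, probs, stop_after = 4L) {
  lab <- strsplit(s, "")[[1]]
  L <- length(lab)
  scan <- function(lab, pat) {
    w <- length(pat)
    hits <- integer(0)
    if (L >= w) {
      for (i in seq_len(L - w + 1L)) {
        if (all(lab[i:(i + w - 1L)] == pat)) hits <- c(hits, i)
      }
    }
    hits
  }
  # rule 1: tnt -> ttt
  out <- lab
  for (i in scan(lab, c("t", "n", "t"))) out[i + 1L] <- "t"
  lab <- out
  # rule 2: ntn -> nnn
  out <- lab
  for (i in scan(lab, c("n", "t", "n"))) out[i + 1L] <- "n"
  lab <- out
  # rule 3: nttn -> tttt
  out <- lab
  for (i in scan(lab, c("n", "t", "t", "n"))) { out[i] <- "t"; out[i + 3L] <- "t" }
  lab <- out
  if (stop_after < 4L) return(paste(lab, collapse = ""))
  # rule 4: ntttn -> ttttn or ntttt, by flank probabilities (tie: left)
  out <- lab
  for (i in scan(lab, c("n", "t", "t", "t", "n"))) {
    if (probs[i] >= probs[i + 4L]) out[i] <- "t" else out[i + 4L] <- "t"
  }
  paste(out, collapse = "")
}

# lengths of maximal 't' runs with a flag for touching a chain end
turn_runs <- function(s) {
  r <- rle(strsplit(s, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == "t"
  data.frame(length = r$lengths[keep],
             interior = starts[keep] > 1L & ends[keep] < nchar(s))
}

# AUC as the normalized Mann-Whitney rank statistic (ties by mid-ranks)
auc_rank_oracle <- function(probs, truth) {
  pos <- truth == "t"
  r <- rank(probs)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

# entrywise RBF Gram loop
gram_loop_oracle <- function(A, B, gamma) {
  K <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      K[i, j] <- exp(-gamma * sum((A[i, ] - B[j, ])^2))
    }
  }
  K
}

# term-by-term dual PNLL loop
pnll_loop_oracle <- function(alpha, b, K, y, lambda) {
  n <- length(y)
  quad <- 0
  loss <- 0
  for (i in seq_len(n)) {
    fi <- b
    for (j in seq_len(n)) {
      quad <- quad + 0.5 * alpha[i] * K[i, j] * alpha[j]
      fi <- fi + K[i, j] * alpha[j]
    }
    loss <- loss + log(1 + exp(-y[i] * fi))
  }
  quad + (lambda / 2) * loss
}

# generic convex-optimizer solution of the primal objective (w, b)
primal_optim_oracle <- function(Phi, y, lambda) {
  p <- ncol(Phi)
  obj <- function(theta) {
    f <- drop(Phi %*% theta[seq_len(p)]) + theta[p + 1L]
    0.5 * sum(theta[seq_len(p)]^2) +
      (lambda / 2) * sum(log(1 + exp(-pmin(pmax(y * f, -500), 500))))
  }
  fit <- optim(numeric(p + 1L), obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  fit$value
}

# small separable classification problem for solver tests
toy_problem <- function(n = 20L, d = 5L, seed = 42L) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  y <- ifelse(X[, 1] + 0.5 * rnorm(n) > 0, 1, -1)
  if (length(unique(y)) < 2L) y[1] <- -y[1]
  list(X = X, y = y)
}
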