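# Per-residue feature construction: a sliding window of logistic-scaled PSSM
# columns plus four secondary-structure blocks from four predictor sources,
# then information-gain / chi-squared feature ranking and selection.

#' Scale a raw PSSM to the unit interval
#'
#' Elementwise logistic squashing `1 / (1 + exp(-raw))`.  The transform is
#' position-independent and monotone, so profile signal ordering is preserved
#' and no dataset-level statistics (which would leak across train/test
#' splits) are involved.
#'
#' @param raw L x 20 numeric matrix of log-odds scores.
#' @return L x 20 matrix with entries in (0, 1).
#' @export
scale_pssm <- function(raw) {
  raw <- as.matrix(raw)
  if (!all(is.finite(raw))) stop("non-finite entries in raw PSSM")
  stats::plogis(raw)
}

#' Encode the PSSM window feature block for one residue
#'
#' Concatenates the scaled profile rows for positions `pos - h .. pos + h`
#' (`h = (window-1)/2`); off-chain positions contribute 20 zeros each.  At
#' the default window of 7 the block has 20 * 7 = 140 entries.
#'
#' @param scaled L x 20 scaled profile matrix.
#' @param pos 1-based residue position.
#' @param window Odd window size (default 7).
#' @return Numeric vector of length `window * 20`.
#' @export
encode_pssm_window <- function(scaled, pos, window = 7L) {
  if (window %% 2L == 0L) stop("window size must be odd")
  L <- nrow(scaled)
  if (pos < 1L || pos > L) stop("position out of range")
  h <- (window - 1L) %/% 2L
  out <- numeric(window * 20L)
  for (k in seq_len(window)) {
    j <- pos - h + (k - 1L)
    if (j >= 1L && j <= L) out[(k - 1L) * 20L + 1:20] <- scaled[j, ]
  }
  out
}

# Column layout of the 76 secondary-structure features:
# (a) 12 per-source one-hot (H,E,C) of the central residue;
# (b)  4 per-source central confidence / 10;
# (c) 48 per-source, per-state, pattern indicators SSS, SSX, XSS, XSX over
#     (pos-1, pos, pos+1), zero when either neighbour is off-chain;
# (d) 12 per-source, per-state, window occupancy ratio.
ss_block_layout <- function(n_sources = 4L) {
  c(onehot = 3L * n_sources, confidence = n_sources,
    pattern = 4L * 3L * n_sources, ratio = 3L * n_sources)
}

#' Encode the secondary-structure feature block for one residue
#'
#' Builds the 76 secondary-structure features from exactly four prediction
#' sources, in the fixed source order given: per-source one-hot of the
#' central state (12), central confidence divided by 10 (4), 3-residue
#' pattern indicators per source and state (48), and per-source per-state
#' occupancy ratios over the window (12).
#'
#' @param ss_chain List of per-source predictions for one chain, each a list
#'   with `states` (string over H/E/C) and `conf` (integer digits 0-9).
#' @param pos 1-based residue position.
#' @param window Window for the occupancy-ratio block (default 7).
#' @param sources Required source order (default [default_ss_sources()]).
#' @return Numeric vector of length 76.
#' @export
encode_ss_block <- function(ss_chain, pos, window = 7L,
                            sources = default_ss_sources()) {
  if (length(sources) != 4L) stop("exactly four SS prediction sources required")
  if (!all(sources %in% names(ss_chain))) {
    stop("missing SS sources: ",
         paste(setdiff(sources, names(ss_chain)), collapse = ", "))
  }
  mat <- encode_ss_chain(ss_chain, window = window, sources = sources)
  mat[pos, ]
}

# Vectorised SS encoding for a whole chain: returns L x 76.
encode_ss_chain <- function(ss_chain, window = 7L,
                            sources = default_ss_sources()) {
  states_l <- lapply(sources, function(s) strsplit(ss_chain[[s]]$states, "")[[1]])
  conf_l <- lapply(sources, function(s) ss_chain[[s]]$conf)
  L <- length(states_l[[1]])
  for (i in seq_along(sources)) {
    if (length(states_l[[i]]) != L || length(conf_l[[i]]) != L) {
      stop("SS sources disagree on chain length")
    }
  }
  h <- (window - 1L) %/% 2L
  blk_a <- matrix(0, L, 3L * length(sources))
  blk_b <- matrix(0, L, length(sources))
  blk_c <- matrix(0, L, 12L * length(sources))
  blk_d <- matrix(0, L, 3L * length(sources))
  for (si in seq_along(sources)) {
    st <- states_l[[si]]
    for (gi in seq_along(SS_STATES)) {
      is_s <- st == SS_STATES[gi]
      blk_a[, (si - 1L) * 3L + gi] <- as.numeric(is_s)
      # patterns over (pos-1, pos, pos+1); center must be S; X = exists & != S
      if (L >= 3L) {
        core <- 2:(L - 1L)
        left_s <- is_s[core - 1L]
        right_s <- is_s[core + 1L]
        ctr <- is_s[core]
        pat <- cbind(ctr & left_s & right_s,    # SSS
                     ctr & left_s & !right_s,   # SSX
                     ctr & !left_s & right_s,   # XSS
                     ctr & !left_s & !right_s)  # XSX
        cols <- (si - 1L) * 12L + (gi - 1L) * 4L + 1:4
        blk_c[core, cols] <- pat + 0
      }
      # occupancy ratio in the window (off-chain positions count as no state)
      counts <- vapply(seq_len(L), function(p) {
        lo <- max(1L, p - h); hi <- min(L, p + h)
        sum(is_s[lo:hi])
      }, numeric(1))
      blk_d[, (si - 1L) * 3L + gi] <- counts / window
    }
    blk_b[, si] <- conf_l[[si]] / 10
  }
  cbind(blk_a, blk_b, blk_c, blk_d)
}

# Vectorised PSSM-window encoding for a whole chain: returns L x (window*20).
encode_pssm_chain <- function(scaled, window = 7L) {
  if (window %% 2L == 0L) stop("window size must be odd")
  L <- nrow(scaled)
  h <- (window - 1L) %/% 2L
  padded <- rbind(matrix(0, h, 20L), scaled, matrix(0, h, 20L))
  out <- matrix(0, L, window * 20L)
  for (k in seq_len(window)) {
    out[, (k - 1L) * 20L + 1:20] <- padded[(k - 1L) + seq_len(L), , drop = FALSE]
  }
  out
}

#' Encode a full dataset into a per-residue feature matrix
#'
#' One row per residue; at the default window of 7 the row has
#' 20 * 7 + 76 = 216 features.  The response is +1 for beta-turn residues
#' ('t') and -1 otherwise.
#'
#' @param dataset A list with `chains` (a `chain_set`), `pssms` (named list
#'   of raw L x 20 matrices), `ss` (nested per-chain per-source predictions)
#'   and optionally `labels` (named \{t,n\} strings), as produced by
#'   [simulate_dataset()] or assembled from the readers.
#' @param window Odd PSSM window size (default 7).
#' @param sources Fixed SS source order (default [default_ss_sources()]).
#' @return Object of class `feature_matrix`: list with `X` (N x d matrix),
#'   `y` (+1/-1 vector, or NULL when no labels), and `provenance`
#'   (data frame `chain_id`, `pos`).
#' @export
encode_dataset <- function(dataset, window = 7L,
                           sources = default_ss_sources()) {
  chains <- dataset$chains
  blocks <- vector("list", nrow(chains))
  ys <- vector("list", nrow(chains))
  prov <- vector("list", nrow(chains))
  has_labels <- !is.null(dataset$labels)
  for (i in seq_len(nrow(chains))) {
    cid <- chains$chain_id[i]
    L <- nchar(chains$sequence[i])
    raw <- dataset$pssms[[cid]]
    if (is.null(raw)) stop("missing PSSM for chain ", cid)
    if (is.list(raw) && !is.null(raw$raw)) raw <- raw$raw
    if (nrow(raw) != L) stop("PSSM row count mismatch for chain ", cid)
    ss_chain <- dataset$ss[[cid]]
    if (is.null(ss_chain)) stop("missing SS predictions for chain ", cid)
    Xp <- encode_pssm_chain(scale_pssm(raw), window = window)
    Xs <- encode_ss_chain(ss_chain, window = window, sources = sources)
    blocks[[i]] <- cbind(Xp, Xs)
    prov[[i]] <- data.frame(chain_id = cid, pos = seq_len(L),
                            stringsAsFactors = FALSE)
    if (has_labels) {
      lab <- dataset$labels[[cid]]
      if (is.null(lab) || nchar(lab) != L) stop("missing or mismatched labels for chain ", cid)
      ys[[i]] <- ifelse(strsplit(lab, "")[[1]] == "t", 1, -1)
    }
  }
  X <- do.call(rbind, blocks)
  colnames(X) <- feature_names(window, sources)
  structure(list(X = X,
                 y = if (has_labels) unlist(ys) else NULL,
                 provenance = do.call(rbind, prov)),
            class = "feature_matrix")
}

feature_names <- function(window = 7L, sources = default_ss_sources()) {
  h <- (window - 1L) %/% 2L
  offs <- -h:h
  pssm <- as.vector(vapply(offs, function(o) {
    paste0("pssm.", ifelse(o < 0, paste0("m", -o), ifelse(o > 0, paste0("p", o), "c")),
           ".", PSSM_COLUMNS)
  }, character(20)))
  a <- as.vector(vapply(sources, function(s) paste0("ss.", s, ".is", SS_STATES),
                        character(3)))
  b <- paste0("ss.", sources, ".conf")
  pats <- c("SSS", "SSX", "XSS", "XSX")
  cblk <- as.vector(vapply(sources, function(s)
    as.vector(vapply(SS_STATES, function(g) paste0("ss.", s, ".", g, ".", pats),
                     character(4))), character(12)))
  d <- as.vector(vapply(sources, function(s) paste0("ss.", s, ".ratio", SS_STATES),
                        character(3)))
  c(pssm, a, b, cblk, d)
}

#' Rank features by information gain and chi-squared
#'
#' Each feature (all lie in \[0,1\] by construction) is discretised into
#' `bins` equal-width bins; the information gain `H(y) - H(y | bin)` and the
#' chi-squared statistic of the bin-by-class contingency table are computed,
#' and features are ranked by the average of their two rank positions
#' (smaller is better), ties broken by lower feature index.
#'
#' @param X N x d feature matrix with entries in \[0,1\].
#' @param y Class vector in \{+1, -1\} (both classes present).
#' @param bins Number of equal-width bins (default 10).
#' @return Object of class `feature_selector`: list with `ranked_indices`
#'   (permutation of 1..d, best first), `scores` (data frame with
#'   `information_gain` and `chi_squared`), and `bins`.
#' @export
rank_features <- function(X, y, bins = 10L) {
  if (length(unique(y)) < 2L) stop("both classes must be present to rank features")
  if (nrow(X) < 2L) stop("need at least two rows")
  n <- length(y)
  pos <- y > 0
  entropy <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  h_y <- entropy(c(mean(pos), 1 - mean(pos)))
  d <- ncol(X)
  ig <- numeric(d)
  chi <- numeric(d)
  for (j in seq_len(d)) {
    b <- pmin(floor(X[, j] * bins) + 1L, bins)
    tab <- table(factor(b, levels = seq_len(bins)), pos)
    tab <- tab[rowSums(tab) > 0L, , drop = FALSE]
    rs <- rowSums(tab)
    # conditional entropy of the class given the bin
    h_cond <- sum((rs / n) * apply(tab / rs, 1L, entropy))
    ig[j] <- h_y - h_cond
    if (nrow(tab) > 1L && ncol(tab) > 1L) {
      expd <- outer(rs, colSums(tab)) / n
      chi[j] <- sum((tab - expd)^2 / expd)
    } else {
      chi[j] <- 0
    }
  }
  r_ig <- rank(-ig, ties.method = "average")
  r_chi <- rank(-chi, ties.method = "average")
  combined <- (r_ig + r_chi) / 2
  ranked <- order(combined, seq_len(d))
  structure(list(ranked_indices = ranked,
                 scores = data.frame(information_gain = ig, chi_squared = chi),
                 bins = bins),
            class = "feature_selector")
}

#' Keep the top-k ranked feature columns
#'
#' Retained columns are returned in their original column order, so a
#' selector fitted on training rows applies unchanged to test rows.
#'
#' @param selector A `feature_selector` from [rank_features()].
#' @param X Feature matrix with the same columns the selector was fitted on.
#' @param k Number of features to retain (default 90).
#' @return N x k matrix of the selected columns.
#' @export
select_features <- function(selector, X, k = 90L) {
  d <- length(selector$ranked_indices)
  if (k > d) stop("k exceeds the number of available features")
  if (ncol(X) != d) stop("X has ", ncol(X), " columns; selector was fitted on ", d)
  idx <- sort(selector$ranked_indices[seq_len(k)])
  X[, idx, drop = FALSE]
}

#' Indices of the columns a selector retains
#'
#' @param selector A `feature_selector`.
#' @param k Number of features to retain.
#' @return Sorted integer vector of retained column indices.
#' @export
selected_indices <- function(selector, k = 90L) {
  sort(selector$ranked_indices[seq_len(k)])
}

#' Serialise a feature selector to JSON
#'
#' @param selector A `feature_selector`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selector <- function(selector, path) {
  jsonlite::write_json(list(ranked_indices = selector$ranked_indices,
                            bins = selector$bins),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature selector written by [write_selector()]
#'
#' @param path Path to the JSON file.
#' @return A `feature_selector` (without scores).
#' @export
read_selector <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(ranked_indices = as.integer(obj$ranked_indices),
                 scores = NULL, bins = as.integer(obj$bins)),
            class = "feature_selector")
}
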