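# Chain-level sevenfold cross-validation, hyperparameter selection, and the
# incremental prototype-count search.

#' Assign chains to cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment at the chain level
#' (all residues of a chain share a fold), so fold sizes differ by at most
#' one chain.  Folds are unbalanced with respect to class: each keeps the
#' naturally occurring turn proportion of its chains.
#'
#' @param chain_ids Character vector of chain identifiers.
#' @param k Number of folds (default 7).
#' @param seed Integer RNG seed.
#' @return Object of class `fold_plan`: list with `assignments` (named
#'   integer vector of fold indices 1..k), `k`, `seed`.
#' @export
make_folds <- function(chain_ids, k = 7L, seed = 1L) {
  if (length(chain_ids) < k) stop("fewer chains than folds")
  set.seed(seed)
  # sort before the seeded shuffle so the plan depends only on the ID set
  shuffled <- sample(sort(chain_ids))
  assignments <- stats::setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  structure(list(assignments = assignments, k = k, seed = seed),
            class = "fold_plan")
}

# Fit on the training chains of one fold and predict its held-out chains.
# `enc` is the full encoded dataset (encode_dataset output); test labels are
# never read before scoring.
cv_fit_fold <- function(enc, plan, fold, hyper, m, seed, k_features = 90L,
                        outlier_min_frac = 0.001) {
  test_chains <- names(plan$assignments)[plan$assignments == fold]
  is_test <- enc$provenance$chain_id %in% test_chains
  y_tr <- enc$y[!is_test]
  if (length(unique(y_tr)) < 2L) {
    stop("training split of fold ", fold, " contains a single class")
  }
  X_tr <- enc$X[!is_test, , drop = FALSE]
  selector <- rank_features(X_tr, y_tr)
  X_tr_sel <- select_features(selector, X_tr, k = k_features)
  X_te_sel <- select_features(selector, enc$X[is_test, , drop = FALSE],
                              k = k_features)
  m_fold <- min(m, nrow(X_tr_sel))
  model <- fs_klr_train(X_tr_sel, y_tr, hyper, m = m_fold,
                        seed = seed + fold, outlier_min_frac = outlier_min_frac,
                        selector = selector, k_features = k_features)
  pred <- fs_klr_predict(model, X_te_sel)
  list(model = model, pred = pred,
       provenance = enc$provenance[is_test, , drop = FALSE],
       y_true = enc$y[is_test])
}

# Per-chain rule smoothing of a fold's predictions.
smooth_fold_labels <- function(pred, provenance) {
  out <- pred$label
  for (cid in unique(provenance$chain_id)) {
    rows <- which(provenance$chain_id == cid)
    rows <- rows[order(provenance$pos[rows])]
    out[rows] <- apply_state_rules(pred$label[rows], pred$prob[rows])
  }
  out
}

#' Chain-level k-fold cross-validation of the full pipeline
#'
#' For every fold: the feature selector and the fixed-size KLR model are
#' fitted on the other k-1 folds' residues, the held-out chains are
#' predicted, labels are optionally smoothed per chain with the
#' state-changing rules, and residue-pooled metrics are computed.  The
#' summary row is the arithmetic mean of the per-fold metrics; AUC is
#' computed on the raw pre-smoothing probabilities.
#'
#' @param dataset Dataset list (chains, pssms, ss, labels) as produced by
#'   [simulate_dataset()] or the readers.
#' @param hyper A `klr_hyperparams` object.
#' @param m Number of prototype vectors.
#' @param k Number of folds (default 7).
#' @param seed Integer seed driving fold assignment and prototype selection.
#' @param apply_rules Smooth labels with [apply_state_rules()] (default
#'   TRUE).
#' @param window,sources,k_features Encoding parameters.
#' @param outlier_min_frac Passed to [select_prototypes()].
#' @return Object of class `cv_result`: list with `per_fold` (data frame:
#'   fold, n, auc, and raw/smoothed metric columns), `average` (one-row
#'   mean), and `plan`.
#' @export
cross_validate <- function(dataset, hyper, m, k = 7L, seed = 1L,
                           apply_rules = TRUE, window = 7L,
                           sources = default_ss_sources(), k_features = 90L,
                           outlier_min_frac = 0.001) {
  enc <- encode_dataset(dataset, window = window, sources = sources)
  # canonical row order: results must not depend on input chain order
  ord <- order(enc$provenance$chain_id, enc$provenance$pos)
  enc$X <- enc$X[ord, , drop = FALSE]
  enc$y <- enc$y[ord]
  enc$provenance <- enc$provenance[ord, , drop = FALSE]
  plan <- make_folds(dataset$chains$chain_id, k = k, seed = seed)
  for (fold in seq_len(k)) {
    test_chains <- names(plan$assignments)[plan$assignments == fold]
    y_tr <- enc$y[!enc$provenance$chain_id %in% test_chains]
    if (length(unique(y_tr)) < 2L) {
      stop("training split of fold ", fold, " contains a single class")
    }
  }
  rows <- vector("list", k)
  for (fold in seq_len(k)) {
    ff <- cv_fit_fold(enc, plan, fold, hyper, m, seed,
                      k_features = k_features,
                      outlier_min_frac = outlier_min_frac)
    true_lab <- ifelse(ff$y_true > 0, "t", "n")
    raw <- compute_metrics(confusion(ff$pred$label, true_lab))
    names(raw) <- paste0(names(raw), "_raw")
    sm_lab <- if (apply_rules) smooth_fold_labels(ff$pred, ff$provenance)
              else ff$pred$label
    sm <- compute_metrics(confusion(sm_lab, true_lab))
    names(sm) <- paste0(names(sm), "_smoothed")
    # a held-out fold may by chance contain a single class; its AUC is
    # undefined and reported as NA
    auc <- if (length(unique(true_lab)) == 2L) {
      roc_auc(ff$pred$prob, true_lab)$auc
    } else NA_real_
    rows[[fold]] <- cbind(data.frame(fold = fold, n = length(ff$y_true),
                                     auc = auc), raw, sm)
  }
  per_fold <- do.call(rbind, rows)
  avg <- as.data.frame(t(colMeans(per_fold[, setdiff(names(per_fold), "fold")])))
  structure(list(per_fold = per_fold, average = avg, plan = plan),
            class = "cv_result")
}

#' Grid search for the regularization and kernel parameters
#'
#' Exhaustive search over the (lambda, gamma) grid; the objective is the
#' mean cross-validated MCC of the final pipeline.  Ties are broken by
#' higher mean Q_total, then smaller gamma, then larger lambda.
#'
#' @param dataset Dataset list.
#' @param lambda_grid,gamma_grid Non-empty numeric grids.
#' @param m Number of prototype vectors.
#' @param k,seed,apply_rules,... Passed to [cross_validate()].
#' @return Object of class `tuning_result`: list with `grid` (data frame
#'   lambda, gamma, mcc, q_total) and `best` (one row).
#' @export
tune_hyperparams <- function(dataset, lambda_grid, gamma_grid, m, k = 7L,
                             seed = 1L, apply_rules = TRUE, ...) {
  if (length(lambda_grid) == 0L || length(gamma_grid) == 0L) {
    stop("hyperparameter grids must be non-empty")
  }
  cells <- expand.grid(lambda = lambda_grid, gamma = gamma_grid)
  metric_suffix <- if (apply_rules) "_smoothed" else "_raw"
  res <- lapply(seq_len(nrow(cells)), function(i) {
    cv <- cross_validate(dataset, hyperparams(cells$lambda[i], cells$gamma[i]),
                         m = m, k = k, seed = seed,
                         apply_rules = apply_rules, ...)
    data.frame(lambda = cells$lambda[i], gamma = cells$gamma[i],
               mcc = cv$average[[paste0("mcc", metric_suffix)]],
               q_total = cv$average[[paste0("q_total", metric_suffix)]])
  })
  grid <- do.call(rbind, res)
  # an undefined MCC (e.g. no predicted positives in some fold) ranks worst
  mcc_rank <- ifelse(is.na(grid$mcc), -Inf, grid$mcc)
  ord <- order(-mcc_rank, -grid$q_total, grid$gamma, -grid$lambda)
  structure(list(grid = grid, best = grid[ord[1], , drop = FALSE]),
            class = "tuning_result")
}

#' Incremental search for the prototype count m
#'
#' Evaluates m = m_start, m_start + m_step, ... by cross-validation and
#' stops when the mean CV MCC has failed to improve on the running best by
#' more than `tol` for two consecutive steps, or when m would exceed the
#' smallest training-split size.  The full trace (m, Q_total, MCC) is
#' reported.
#'
#' @param dataset Dataset list.
#' @param hyper A `klr_hyperparams` object.
#' @param m_start First prototype count (default 20).
#' @param m_step Increment (default 10).
#' @param tol Minimum MCC improvement that counts as progress (default
#'   0.005).
#' @param max_evals Safety cap on the number of evaluated m values.
#' @param k,seed,apply_rules,... Passed to [cross_validate()].
#' @return Data frame trace with columns `m`, `q_total`, `mcc`, one row per
#'   evaluated m.
#' @export
search_m <- function(dataset, hyper, m_start = 20L, m_step = 10L, tol = 0.005,
                     max_evals = 50L, k = 7L, seed = 1L, apply_rules = TRUE,
                     ...) {
  if (m_start < 1L) stop("m_start must be at least 1")
  n_total <- sum(nchar(dataset$chains$sequence))
  metric_suffix <- if (apply_rules) "_smoothed" else "_raw"
  trace <- list()
  best <- -Inf
  stall <- 0L
  m <- m_start
  for (i in seq_len(max_evals)) {
    if (m > n_total) {
      warning("m exceeds the number of training residues; stopping search")
      break
    }
    cv <- cross_validate(dataset, hyper, m = m, k = k, seed = seed,
                         apply_rules = apply_rules, ...)
    mcc <- cv$average[[paste0("mcc", metric_suffix)]]
    trace[[i]] <- data.frame(m = m, q_total = cv$average[[paste0("q_total", metric_suffix)]],
                             mcc = mcc)
    if (is.finite(mcc) && mcc > best + tol) {
      best <- max(best, mcc)
      stall <- 0L
    } else {
      best <- max(best, mcc, na.rm = TRUE)
      stall <- stall + 1L
      if (stall >= 2L) break
    }
    m <- m + m_step
  }
  do.call(rbind, trace)
}
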