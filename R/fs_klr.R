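# Fixed-size kernel logistic regression: k-means prototype vectors, the
# Nystrom low-rank eigen-approximation of the RBF kernel, and a primal fit
# with a trust-region Newton method (truncated conjugate-gradient inner
# solves, TRON-style radius control).

squared_dists <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

# seeded k-means++ initialisation followed by Lloyd iterations; returns
# list(assign, centers, sizes)
kmeans_fit <- function(X, k, max_iter = 100L, rel_tol = 1e-4) {
  n <- nrow(X)
  centers_idx <- integer(k)
  centers_idx[1] <- sample.int(n, 1L)
  mind2 <- squared_dists(X, X[centers_idx[1], , drop = FALSE])[, 1]
  if (k > 1L) {
    for (j in 2:k) {
      if (all(mind2 <= 0)) {
        centers_idx[j] <- sample.int(n, 1L)
      } else {
        centers_idx[j] <- sample.int(n, 1L, prob = mind2 / sum(mind2))
      }
      d2 <- squared_dists(X, X[centers_idx[j], , drop = FALSE])[, 1]
      mind2 <- pmin(mind2, d2)
    }
  }
  centers <- X[centers_idx, , drop = FALSE]
  inertia <- Inf
  assign <- integer(n)
  for (it in seq_len(max_iter)) {
    D2 <- squared_dists(X, centers)
    assign <- max.col(-D2, ties.method = "first")
    new_inertia <- sum(D2[cbind(seq_len(n), assign)])
    for (j in seq_len(k)) {
      members <- which(assign == j)
      if (length(members) > 0L) {
        centers[j, ] <- colMeans(X[members, , drop = FALSE])
      }
      # empty clusters keep their previous centre
    }
    if (is.finite(inertia) &&
        (inertia - new_inertia) <= rel_tol * max(inertia, .Machine$double.eps)) {
      inertia <- new_inertia
      break
    }
    inertia <- new_inertia
  }
  D2 <- squared_dists(X, centers)
  assign <- max.col(-D2, ties.method = "first")
  list(assign = assign, centers = centers, d2 = D2,
       sizes = tabulate(assign, nbins = k))
}

#' Select prototype vectors by seeded k-means
#'
#' Runs k-means with `m` clusters (k-means++-style seeding, Lloyd
#' iterations) as the k-center surrogate, then snaps each centroid to its
#' nearest cluster member so every prototype is an actual data row.
#' Clusters smaller than `outlier_min_frac * n` are treated as outlier
#' clusters: their prototypes are discarded and replaced once by additional
#' members drawn from the largest remaining clusters.  Deterministic given
#' `seed`.
#'
#' @param X n x d feature matrix.
#' @param m Number of prototypes, 1 <= m <= n.
#' @param seed Integer RNG seed.
#' @param outlier_min_frac Minimum cluster size as a fraction of n below
#'   which a cluster counts as outliers (default 0.001).
#' @return Object of class `prototype_set`: list with `indices` (distinct,
#'   ascending), `vectors` (the prototype rows), and `m`.
#' @export
select_prototypes <- function(X, m, seed = 1L, outlier_min_frac = 0.001) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 0L) stop("empty input")
  if (m < 1L || m > n) stop("m must satisfy 1 <= m <= n")
  if (m == n) return(prototype_set(X, seq_len(n)))
  set.seed(seed)
  km <- kmeans_fit(X, m)
  medoid_of <- function(j, taken) {
    members <- which(km$assign == j)
    members <- setdiff(members, taken)
    if (length(members) == 0L) return(NA_integer_)
    members[which.min(km$d2[members, j])]
  }
  idx <- integer(0)
  for (j in seq_len(m)) {
    cand <- medoid_of(j, idx)
    if (!is.na(cand)) idx <- c(idx, cand)
  }
  min_size <- outlier_min_frac * n
  keep_cluster <- km$sizes >= min_size & km$sizes > 0L
  dropped <- sum(!keep_cluster[km$assign[idx] ])
  idx <- idx[keep_cluster[km$assign[idx]]]
  if (dropped > 0L) {
    # re-seed once: extra members from the largest remaining clusters
    order_big <- order(-km$sizes)
    order_big <- order_big[keep_cluster[order_big]]
    for (j in rep(order_big, length.out = max(dropped, 0L))) {
      cand <- medoid_of(j, idx)
      if (!is.na(cand)) idx <- c(idx, cand)
    }
  }
  prototype_set(X, sort(unique(idx)))
}

#' Construct a prototype set from explicit row indices
#'
#' @param X The data matrix the indices refer to.
#' @param indices Distinct row indices.
#' @return Object of class `prototype_set`.
#' @export
prototype_set <- function(X, indices) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("prototype indices must be distinct")
  structure(list(indices = indices,
                 vectors = as.matrix(X)[indices, , drop = FALSE],
                 m = length(indices)),
            class = "prototype_set")
}

#' Build the Nystrom eigen-map from a prototype set
#'
#' Eigendecomposes the m x m RBF kernel of the prototypes and keeps the
#' components with eigenvalue above `eps` times the largest, defining a
#' p-dimensional explicit feature map.
#'
#' @param prototypes A `prototype_set`.
#' @param gamma RBF width.
#' @param eps Relative eigenvalue cutoff (default 1e-12).
#' @return Object of class `nystrom_map`: list with `prototypes`, `gamma`,
#'   `eigvals` (descending, positive), `eigvecs`, `p`, `eps`.
#' @export
build_nystrom_map <- function(prototypes, gamma, eps = 1e-12) {
  Kmm <- gram_matrix(prototypes$vectors, prototypes$vectors, gamma)
  ee <- eigen(Kmm, symmetric = TRUE)
  keep <- ee$values > eps * max(ee$values) & ee$values > 0
  p <- sum(keep)
  if (p == 0L) stop("all eigenvalues below cutoff; cannot build map")
  structure(list(prototypes = prototypes, gamma = gamma,
                 eigvals = ee$values[keep],
                 eigvecs = ee$vectors[, keep, drop = FALSE],
                 p = p, eps = eps),
            class = "nystrom_map")
}

#' Apply the Nystrom map to data
#'
#' `Phi = K_{n,m} U_p Lambda_p^{-1/2}`, so `Phi Phi'` equals the Nystrom
#' approximation `K_{n,m} K_{m,m}^+ K_{m,n}`; the classical out-of-sample
#' eigen-extension (eigenvalues scaled by n/m, eigenvectors by
#' sqrt(m/n) / lambda_i times `K_{n,m} u_i`) is recovered as the scaled
#' singular structure of `Phi`.
#'
#' @param map A `nystrom_map`.
#' @param X n x d matrix with the prototype feature width.
#' @return n x p matrix of mapped features.
#' @export
apply_nystrom_map <- function(map, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(map$prototypes$vectors)) {
    stop("feature width mismatch with prototype vectors")
  }
  Knm <- gram_matrix(X, map$prototypes$vectors, map$gamma)
  Knm %*% sweep(map$eigvecs, 2L, sqrt(map$eigvals), "/")
}

#' Nystrom out-of-sample eigen-extension
#'
#' Returns the extended eigenvalues `(n/m) lambda_i^(m)` and eigenvectors
#' `sqrt(m/n) (1/lambda_i^(m)) K_{n,m} u_i^(m)` for all mapped points.
#'
#' @param map A `nystrom_map`.
#' @param X n x d matrix.
#' @return List with `values` (length p) and `vectors` (n x p).
#' @export
nystrom_extension <- function(map, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  m <- map$prototypes$m
  Knm <- gram_matrix(X, map$prototypes$vectors, map$gamma)
  values <- (n / m) * map$eigvals
  vectors <- sqrt(m / n) * Knm %*% sweep(map$eigvecs, 2L, map$eigvals, "/")
  list(values = values, vectors = vectors)
}

#' Fit regularized logistic regression in the primal by trust-region Newton
#'
#' Minimises `(1/2) w'w + (lambda/2) sum log(1 + exp(-y (w'phi_i + b)))`
#' over (w, b), with b appended as an unpenalized coordinate.  Inner Newton
#' systems are solved approximately by conjugate gradients truncated at the
#' trust-region boundary (Steihaug); the radius shrinks when the
#' actual-to-predicted reduction ratio falls below 0.25 and doubles when it
#' exceeds 0.75 at the boundary, so early iterations take cheap approximate
#' steps and late iterations full Newton directions.
#'
#' @param Phi n x p feature matrix.
#' @param y Labels in \{+1, -1\}, both classes present.
#' @param lambda Positive loss weight.
#' @param tol Relative gradient-norm tolerance (default 1e-6).
#' @param max_iter Maximum outer iterations (default 200).
#' @return List with `w` (length p), `b`, `objective`, `grad_norms`
#'   (per accepted iterate), `iterations`.
#' @export
fit_primal_tron <- function(Phi, y, lambda, tol = 1e-6, max_iter = 200L) {
  Phi <- as.matrix(Phi)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  n <- nrow(Phi)
  p <- ncol(Phi)
  reg <- c(rep(1, p), 0)          # the intercept coordinate is unpenalized
  theta <- numeric(p + 1L)
  zmul <- function(v) drop(Phi %*% v[seq_len(p)]) + v[p + 1L]
  ztmul <- function(r) c(drop(crossprod(Phi, r)), sum(r))
  obj_fun <- function(theta) {
    f <- zmul(theta)
    0.5 * sum(reg * theta^2) + (lambda / 2) * sum(log1pexp(-y * f))
  }
  grad_fun <- function(theta) {
    f <- zmul(theta)
    u <- -(lambda / 2) * y * stats::plogis(-y * f)
    list(g = reg * theta + ztmul(u), f = f)
  }
  obj <- obj_fun(theta)
  gr <- grad_fun(theta)
  g <- gr$g
  gnorm0 <- sqrt(sum(g^2))
  gnorm <- gnorm0
  grad_norms <- gnorm
  if (gnorm0 == 0) {
    return(list(w = theta[seq_len(p)], b = theta[p + 1L], objective = obj,
                grad_norms = grad_norms, iterations = 0L))
  }
  delta <- gnorm0
  converged <- gnorm <= tol * max(1, gnorm0)
  it <- 0L
  while (!converged && it < max_iter) {
    it <- it + 1L
    pr <- stats::plogis(gr$f)
    dvec <- (lambda / 2) * pr * (1 - pr)
    hess_v <- function(v) reg * v + ztmul(dvec * zmul(v))
    # truncated CG with trust-region boundary (Steihaug)
    s <- numeric(p + 1L)
    r <- -g
    d <- r
    rr <- sum(r^2)
    cg_tol <- min(0.1, sqrt(gnorm / gnorm0)) * gnorm
    hit_boundary <- FALSE
    for (cg in seq_len(2L * (p + 1L))) {
      if (sqrt(rr) <= cg_tol) break
      Hd <- hess_v(d)
      dHd <- sum(d * Hd)
      if (dHd <= 0) { hit_boundary <- TRUE }
      alpha_cg <- if (dHd > 0) rr / dHd else Inf
      s_try <- s + alpha_cg * d
      if (hit_boundary || sqrt(sum(s_try^2)) >= delta) {
        # step to the boundary along d
        sd <- sum(s * d); dd <- sum(d^2); ss <- sum(s^2)
        tau <- (-sd + sqrt(sd^2 + dd * (delta^2 - ss))) / dd
        s <- s + tau * d
        hit_boundary <- TRUE
        break
      }
      s <- s_try
      r <- r - alpha_cg * Hd
      rr_new <- sum(r^2)
      d <- r + (rr_new / rr) * d
      rr <- rr_new
    }
    pred_red <- -(sum(g * s) + 0.5 * sum(s * hess_v(s)))
    obj_new <- obj_fun(theta + s)
    act_red <- obj - obj_new
    rho <- if (pred_red > 0) act_red / pred_red else -1
    snorm <- sqrt(sum(s^2))
    if (rho > 1e-4) {
      theta <- theta + s
      obj <- obj_new
      gr <- grad_fun(theta)
      g <- gr$g
      gnorm <- sqrt(sum(g^2))
      grad_norms <- c(grad_norms, gnorm)
      converged <- gnorm <= tol * max(1, gnorm0)
    }
    if (rho < 0.25) {
      delta <- max(min(delta, snorm) / 4, 1e-14)
    } else if (rho > 0.75 && hit_boundary) {
      delta <- min(2 * delta, 1e10)
    }
    if (delta <= 1e-13 && !converged) {
      stop("trust-region collapsed before convergence; gradient norm ",
           format(gnorm))
    }
  }
  if (!converged) {
    stop("trust-region Newton did not converge in ", max_iter,
         " iterations; gradient norm ", format(gnorm))
  }
  list(w = theta[seq_len(p)], b = theta[p + 1L], objective = obj,
       grad_norms = grad_norms, iterations = it)
}

#' Train a fixed-size KLR model
#'
#' Composition of the sparse pipeline: prototype selection, Nystrom map,
#' explicit feature mapping, and the primal trust-region Newton fit.
#'
#' @param X n x d training feature matrix (post feature selection).
#' @param y Labels in \{+1, -1\}, both classes present.
#' @param hyper A `klr_hyperparams` object (lambda, gamma, threshold).
#' @param m Number of prototype vectors, m <= n.
#' @param seed Integer seed for the prototype selection.
#' @param outlier_min_frac Passed to [select_prototypes()].
#' @param selector Optional `feature_selector` to record with the model.
#' @param k_features Retained feature count recorded with the model.
#' @return Object of class `fsklr_model`.
#' @export
fs_klr_train <- function(X, y, hyper, m, seed = 1L, outlier_min_frac = 0.001,
                         selector = NULL, k_features = NULL) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("both classes must be present for training")
  if (m > nrow(X)) stop("m must not exceed the number of training rows")
  protos <- select_prototypes(X, m, seed = seed,
                              outlier_min_frac = outlier_min_frac)
  map <- build_nystrom_map(protos, hyper$gamma)
  Phi <- apply_nystrom_map(map, X)
  fit <- fit_primal_tron(Phi, y, hyper$lambda)
  structure(list(map = map, w = fit$w, b = fit$b, hyper = hyper,
                 seed = seed, m_requested = m, m_effective = protos$m,
                 objective = fit$objective, iterations = fit$iterations,
                 selector = selector, k_features = k_features),
            class = "fsklr_model")
}

#' Predict turn probabilities and labels with a fixed-size KLR model
#'
#' A residue is labelled 't' when its turn probability is greater than or
#' equal to the model threshold (boundary cases count as turns).
#'
#' @param model A fitted `fsklr_model`.
#' @param X_new Matrix of rows in the model's feature space.
#' @return List with `prob` (turn probabilities), `f` (decision values) and
#'   `label` (character vector over \{t,n\}).
#' @export
fs_klr_predict <- function(model, X_new) {
  Phi <- apply_nystrom_map(model$map, X_new)
  f <- drop(Phi %*% model$w) + model$b
  prob <- stats::plogis(f)
  list(prob = prob, f = f,
       label = ifelse(prob >= model$hyper$threshold, "t", "n"))
}

#' Serialise a fixed-size KLR model to JSON
#'
#' The container carries gamma, lambda, threshold, the prototype vectors,
#' retained eigenpairs, the primal weights, intercept, selector indices and
#' seed: everything needed for reproducible prediction.
#'
#' @param model A fitted `fsklr_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fsklr_model <- function(model, path) {
  obj <- list(
    lambda = model$hyper$lambda, gamma = model$hyper$gamma,
    threshold = model$hyper$threshold,
    prototype_vectors = model$map$prototypes$vectors,
    prototype_indices = model$map$prototypes$indices,
    eigvals = model$map$eigvals, eigvecs = model$map$eigvecs,
    eps = model$map$eps,
    w = model$w, b = model$b, seed = model$seed,
    m_requested = model$m_requested,
    selector_ranked = if (!is.null(model$selector)) model$selector$ranked_indices,
    selector_bins = if (!is.null(model$selector)) model$selector$bins,
    k_features = model$k_features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fixed-size KLR model written by [write_fsklr_model()]
#'
#' @param path Path to the JSON file.
#' @return A `fsklr_model`.
#' @export
read_fsklr_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  pv <- as.matrix(o$prototype_vectors)
  protos <- structure(list(indices = as.integer(o$prototype_indices),
                           vectors = pv, m = nrow(pv)),
                      class = "prototype_set")
  map <- structure(list(prototypes = protos, gamma = o$gamma,
                        eigvals = as.numeric(o$eigvals),
                        eigvecs = as.matrix(o$eigvecs),
                        p = length(o$eigvals), eps = o$eps),
                   class = "nystrom_map")
  selector <- NULL
  if (!is.null(o$selector_ranked)) {
    selector <- structure(list(ranked_indices = as.integer(o$selector_ranked),
                               scores = NULL, bins = o$selector_bins),
                          class = "feature_selector")
  }
  structure(list(map = map, w = as.numeric(o$w), b = o$b,
                 hyper = hyperparams(o$lambda, o$gamma, o$threshold),
                 seed = o$seed, m_requested = o$m_requested,
                 m_effective = protos$m,
                 selector = selector, k_features = o$k_features),
            class = "fsklr_model")
}
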