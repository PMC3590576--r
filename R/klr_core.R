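# Exact (dense, dual-form) kernel logistic regression with the RBF kernel.
# Used directly on small problems and as the correctness reference for the
# fixed-size approximation.

# overflow-safe log(1 + exp(x))
log1pexp <- function(x) {
  out <- numeric(length(x))
  lo <- x <= 0
  out[lo] <- log1p(exp(x[lo]))
  out[!lo] <- x[!lo] + log1p(exp(-x[!lo]))
  out
}

#' RBF kernel value between two vectors
#'
#' `K(x, x') = exp(-gamma * ||x - x'||^2)`.
#'
#' @param x,xp Equal-length finite numeric vectors.
#' @param gamma Non-negative kernel width parameter.
#' @return Kernel value in (0, 1\].
#' @export
rbf_kernel <- function(x, xp, gamma) {
  if (length(x) != length(xp)) stop("vectors must have equal length")
  exp(-gamma * sum((x - xp)^2))
}

#' RBF Gram matrix between two point sets
#'
#' @param A n x d matrix.
#' @param B m x d matrix.
#' @param gamma Non-negative kernel width parameter.
#' @return n x m matrix with entries `exp(-gamma * ||A_i - B_j||^2)`.
#' @export
gram_matrix <- function(A, B, gamma) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("dimension mismatch between point sets")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2 <- pmax(d2, 0)
  exp(-gamma * d2)
}

#' Posterior class probabilities from a decision value
#'
#' `f` is the log-odds of the beta-turn (positive) class, so
#' `P(turn | x) = 1 / (1 + exp(-f))`.
#'
#' @param f Numeric vector of decision values.
#' @return Matrix with columns `p_turn` and `p_nonturn` summing to 1 rowwise.
#' @export
predict_proba_from_f <- function(f) {
  p <- stats::plogis(f)
  cbind(p_turn = p, p_nonturn = 1 - p)
}

#' Penalized negative log-likelihood of a dual KLR solution
#'
#' `(1/2) a' K a + (lambda/2) sum log(1 + exp(-y f))` with `f = K a + b`:
#' the dual form of the primal objective
#' `(1/2) w'w + (lambda/2) sum log(1 + exp(-y f))` via `w = sum a_i phi(x_i)`.
#'
#' @param alpha Dual coefficient vector of length N.
#' @param b Intercept.
#' @param K N x N PSD kernel matrix.
#' @param y Labels in \{+1, -1\}.
#' @param lambda Positive loss weight.
#' @return Objective value.
#' @export
pnll_objective <- function(alpha, b, K, y, lambda) {
  f <- drop(K %*% alpha) + b
  quad <- 0.5 * drop(crossprod(alpha, K %*% alpha))
  if (quad < -1e-8) stop("kernel matrix is not positive semidefinite")
  quad + (lambda / 2) * sum(log1pexp(-y * f))
}

#' Fit exact dual-form kernel logistic regression by IRLS
#'
#' Newton / iteratively-reweighted-least-squares iterations on (alpha, b)
#' for the convex objective of [pnll_objective()].  Each step solves the
#' weighted least-squares subproblem with weights `(lambda/2) p (1 - p)`;
#' step halving guards the objective against increase, and a 1e-10 jitter
#' is added to the linear-system diagonal.  The intercept is unpenalized
#' and updated jointly.
#'
#' @param K N x N PSD kernel matrix of the training points.
#' @param y Labels in \{+1, -1\}, both classes present.
#' @param lambda Positive loss weight.
#' @param tol Gradient-norm convergence tolerance (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 100).
#' @return Object of class `klr_dual_solution`: list with `alpha`, `b`,
#'   `objective`, `grad_norm`, `iterations`.
#' @export
fit_dual_irls <- function(K, y, lambda, tol = 1e-8, max_iter = 100L) {
  n <- length(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  alpha <- numeric(n)
  b <- 0
  obj <- pnll_objective(alpha, b, K, y, lambda)
  for (it in seq_len(max_iter)) {
    f <- drop(K %*% alpha) + b
    u <- -(lambda / 2) * y * stats::plogis(-y * f)
    g_alpha <- drop(K %*% (alpha + u))
    g_b <- sum(u)
    gnorm <- sqrt(sum(g_alpha^2) + g_b^2)
    if (gnorm <= tol) {
      return(structure(list(alpha = alpha, b = b, objective = obj,
                            grad_norm = gnorm, iterations = it - 1L),
                       class = "klr_dual_solution"))
    }
    p <- stats::plogis(f)
    w <- (lambda / 2) * p * (1 - p)
    # Newton system reduced through the shared factor K of the alpha block:
    # (I + W K) da + W 1 db = -(alpha + u);  1'W K da + 1'W 1 db = -1'u
    M <- rbind(cbind(diag(n) + w * K, w),
               c(drop(crossprod(K, w)), sum(w)))
    diag(M) <- diag(M) + 1e-10
    delta <- unname(solve(M, c(-(alpha + u), -g_b)))
    step <- 1
    repeat {
      alpha_new <- alpha + step * delta[seq_len(n)]
      b_new <- b + step * delta[n + 1L]
      obj_new <- pnll_objective(alpha_new, b_new, K, y, lambda)
      if (obj_new <= obj + 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    alpha <- alpha_new
    b <- b_new
    obj <- obj_new
  }
  f <- drop(K %*% alpha) + b
  u <- -(lambda / 2) * y * stats::plogis(-y * f)
  gnorm <- sqrt(sum(drop(K %*% (alpha + u))^2) + sum(u)^2)
  if (gnorm > tol) {
    stop("IRLS did not converge in ", max_iter,
         " iterations; gradient norm ", format(gnorm))
  }
  structure(list(alpha = alpha, b = b, objective = obj,
                 grad_norm = gnorm, iterations = max_iter),
            class = "klr_dual_solution")
}

#' Fit exact dual KLR from a feature matrix
#'
#' Convenience wrapper: materialises the RBF Gram matrix, runs
#' [fit_dual_irls()], and keeps the training points for prediction.
#'
#' @param X N x d training feature matrix.
#' @param y Labels in \{+1, -1\}.
#' @param lambda Positive loss weight.
#' @param gamma RBF width.
#' @param ... Passed to [fit_dual_irls()].
#' @return Object of class `klr_dual`: the IRLS solution plus `X_train`,
#'   `gamma`, `lambda`.
#' @export
klr_fit_dual <- function(X, y, lambda, gamma, ...) {
  X <- as.matrix(X)
  K <- gram_matrix(X, X, gamma)
  sol <- fit_dual_irls(K, y, lambda, ...)
  sol$X_train <- X
  sol$gamma <- gamma
  sol$lambda <- lambda
  class(sol) <- c("klr_dual", class(sol))
  sol
}

#' Decision values of a dual KLR solution on new points
#'
#' `f_j = sum_i alpha_i K(x_j, x_i) + b`.
#'
#' @param sol A fitted `klr_dual` solution.
#' @param X_new Matrix of new points (columns match training features).
#' @return Numeric vector of decision values.
#' @export
decision_function_dual <- function(sol, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(sol$X_train)) {
    stop("feature width mismatch with training data")
  }
  drop(gram_matrix(X_new, sol$X_train, sol$gamma) %*% sol$alpha) + sol$b
}

#' Turn probabilities of a dual KLR solution on new points
#'
#' @param sol A fitted `klr_dual` solution.
#' @param X_new Matrix of new points.
#' @return Numeric vector of `P(turn | x)`.
#' @export
predict_dual <- function(sol, X_new) {
  stats::plogis(decision_function_dual(sol, X_new))
}

#' Hyperparameter container for the turn classifier
#'
#' @param lambda Positive loss weight of the penalized likelihood.
#' @param gamma Positive RBF kernel width.
#' @param threshold Decision threshold on the turn probability (default
#'   0.45); a residue is labelled 't' when `p_turn >= threshold`.
#' @return List of class `klr_hyperparams`.
#' @export
hyperparams <- function(lambda, gamma, threshold = 0.45) {
  if (lambda <= 0) stop("lambda must be positive")
  if (gamma < 0) stop("gamma must be non-negative")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  structure(list(lambda = lambda, gamma = gamma, threshold = threshold),
            class = "klr_hyperparams")
}
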