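# Logistic-regression fitters.
#
# Two fitters are used throughout: an L1-penalised full-batch (proximal)
# gradient fit for resolving promiscuous clonotype-allele associations, and
# a ridge-stabilised IRLS fit for the unpenalised per-clonotype weight and
# per-allele carriership models. Both are deterministic given their inputs.

soft_threshold <- function(w, t) sign(w) * pmax(abs(w) - t, 0)

#' L1-regularised logistic regression by full-batch proximal gradient
#'
#' Minimises mean cross-entropy of `y` on `X` plus `lambda * sum(|w_j|)`
#' over the `penalized` coefficients; the remaining coefficients (by
#' default the last column, the sqrt-depth feature) and the intercept are
#' unpenalised. The fit runs exactly `epochs` full-batch iterations of
#' proximal gradient descent (gradient step followed by soft-thresholding of
#' the penalised weights, which produces exact zeros) from zero
#' initialisation. The default step size is 1/L with
#' L = sigma_max([1 X])^2 / (4n), the Lipschitz bound of the logistic loss
#' gradient, which keeps the iteration stable for unscaled feature columns
#' such as sqrt(C(R)); a fixed `lr` can be supplied instead.
#'
#' @param X numeric matrix (n x d); by convention the first d-1 columns are
#'   binary allele-carriership indicators and the last is sqrt(C(R)).
#' @param y binary response (presence of the clonotype per sample).
#' @param lambda non-negative L1 penalty.
#' @param epochs number of full-batch iterations (default 1000).
#' @param lr step size; `NULL` (default) uses 1/L as above.
#' @param penalized integer indices of penalised columns; default all but
#'   the last.
#' @return list with `W` (length d), `b`, `lambda`, `epochs_run`, `lr`.
#' @export
fit_l1_logistic <- function(X, y, lambda, epochs = 1000L, lr = NULL,
                            penalized = seq_len(max(ncol(X) - 1L, 0L))) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  d <- ncol(X)
  stopifnot(length(y) == n, lambda >= 0, d >= 1L)
  if (is.null(lr)) {
    L <- (svd(cbind(1, X), nu = 0, nv = 0)$d[1L]^2) / (4 * n)
    lr <- 1 / max(L, .Machine$double.eps)
  }
  W <- numeric(d)
  b <- 0
  for (e in seq_len(epochs)) {
    p <- plogis(drop(X %*% W) + b)
    r <- (p - y) / n
    W <- W - lr * drop(crossprod(X, r))
    b <- b - lr * sum(r)
    if (length(penalized)) {
      W[penalized] <- soft_threshold(W[penalized], lr * lambda)
    }
  }
  if (!all(is.finite(W)) || !is.finite(b)) {
    stop("non-finite weights in L1 logistic fit (lambda = ", lambda,
         ", epoch = ", epochs, ")")
  }
  list(W = W, b = b, lambda = lambda, epochs_run = as.integer(epochs),
       lr = lr)
}

#' Ridge-stabilised logistic regression (IRLS)
#'
#' Standard unpenalised logistic fit with a small ridge term (default 1e-6)
#' on the non-intercept coefficients and an iteration cap, so that perfectly
#' separated inputs - common in small synthetic cohorts - yield finite,
#' reproducible coefficients instead of a divergent fit.
#'
#' @param X numeric matrix of features (no intercept column).
#' @param y binary response.
#' @param ridge ridge penalty on the slope coefficients.
#' @param max_iter IRLS iteration cap.
#' @param tol convergence tolerance on the step.
#' @return list with `coefficients` (intercept first), `iterations`,
#'   `converged`.
#' @export
ridge_logistic <- function(X, y, ridge = 1e-6, max_iter = 100L, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  Xa <- cbind(1, X)
  d <- ncol(Xa)
  pen <- diag(c(0, rep(ridge, d - 1L)), d)
  beta <- numeric(d)
  step <- Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Xa, Xa * w) + pen
    g <- drop(crossprod(Xa, y - p)) - drop(pen %*% beta)
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  names(beta) <- c("(Intercept)",
                   colnames(X) %||% paste0("x", seq_len(d - 1L)))
  list(coefficients = beta, iterations = it,
       converged = max(abs(step)) < tol)
}
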