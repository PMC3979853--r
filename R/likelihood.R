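#' Expected super-population abundance under the log link
#'
#' @param beta abundance coefficients on the log scale.
#' @param x a design row (or matrix of rows) conformable with `beta`.
#' @return `exp(x %*% beta)`, the expected number of birds whose range
#'   overlaps the transect; strictly positive.
#' @export
expected_abundance <- function(beta, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(beta))
    stop("dimension mismatch between beta and x", call. = FALSE)
  lam <- drop(exp(x %*% beta))
  if (any(!is.finite(lam)))
    stop("expected abundance overflowed; coefficients too extreme",
         call. = FALSE)
  lam
}

#' Per-visit detection probability under the logit link
#'
#' @param alpha detection coefficients on the logit scale.
#' @param w a design row (or matrix of rows) conformable with `alpha`.
#' @return `plogis(w %*% alpha)`, clamped away from exact 0 and 1 by
#'   machine tolerance so downstream logs stay finite.
#' @export
detection_prob <- function(alpha, w) {
  if (!is.matrix(w)) w <- matrix(w, nrow = 1)
  if (ncol(w) != length(alpha))
    stop("dimension mismatch between alpha and w", call. = FALSE)
  p <- drop(plogis(w %*% alpha))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Marginal log-likelihood of one transect-year
#'
#' Computes \eqn{\log \sum_{N=\max y}^{K} \mathrm{Pois}(N;\lambda)\,
#' \prod_j \mathrm{Bin}(y_j; N, p_j)}, the binomial mixture likelihood with
#' the latent site abundance summed out up to the truncation bound `K`.
#' All sums run in log space (log-sum-exp) and the probability mass
#' functions are evaluated through log-gamma, so counts in the hundreds do
#' not underflow.  Missing visits (`NA` in `y`) are skipped.
#'
#' @param lambda expected abundance (positive scalar).
#' @param p vector of per-visit detection probabilities in (0, 1).
#' @param y vector of per-visit counts (`NA` allowed).
#' @param K integer truncation bound; must be at least `max(y)`.
#' @return The log marginal probability of `y`.
#' @export
site_marginal_loglik <- function(lambda, p, y, K) {
  stopifnot(length(p) == length(y), lambda > 0)
  keep <- !is.na(y)
  y <- as.integer(y[keep]); p <- p[keep]
  if (length(y) && max(y) > K)
    stop("truncation bound K = ", K, " is below max(y) = ", max(y),
         "; increase K", call. = FALSE)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ym <- matrix(c(y, rep(NA_integer_, max(0, 1 - length(y)))), nrow = 1)
  if (!length(y)) ym <- matrix(NA_integer_, 1, 1)
  A <- nm_lchoose_table(ym, as.integer(K))
  maxy <- if (length(y)) max(y) else 0L
  em <- matrix(qlogis(p), nrow = 1)
  if (!length(y)) em <- matrix(0, 1, 1)
  nm_siteyear_loglik(log(lambda), em, ym, A, as.integer(maxy), as.integer(K))[1]
}

# Precompute everything that does not change with the parameters: designs,
# the count matrix and the lchoose table.  Returns a closure evaluating the
# per-site-year marginal log-likelihood for (beta, alpha [, b]).
marginal_loglik_fun <- function(design, K) {
  y <- design$y
  storage.mode(y) <- "integer"
  if (any(design$maxy > K))
    stop("truncation bound K = ", K, " is below the maximum observed count ",
         max(design$maxy), "; increase K", call. = FALSE)
  A <- nm_lchoose_table(y, as.integer(K))
  n <- nrow(y); J <- ncol(y)
  X <- design$X; W <- design$W
  maxy <- design$maxy
  K <- as.integer(K)
  trans_idx <- as.integer(design$transect)
  function(beta, alpha, b = NULL) {
    eta_lam <- drop(X %*% beta)
    if (!is.null(b)) eta_lam <- eta_lam + b[trans_idx]
    eta_p <- matrix(drop(W %*% alpha), n, J, byrow = TRUE)
    nm_siteyear_loglik(eta_lam, eta_p, y, A, maxy, K)
  }
}

#' Dataset log-likelihood of a binomial mixture model
#'
#' Sums [site_marginal_loglik()] over all transect-years of a dataset under
#' the designs implied by a model specification.  Transect-years are treated
#' as independent (the model's assumption at the maximum-likelihood stage).
#'
#' @param theta parameter vector: abundance coefficients first (matching the
#'   columns of the abundance design), then detection coefficients.
#' @param dataset a [survey_dataset()].
#' @param spec an [nmix_spec()].
#' @param K truncation bound for the latent abundance sum; defaults to the
#'   maximum observed count plus 100.
#' @return The total log-likelihood (a scalar).
#' @export
dataset_loglik <- function(theta, dataset, spec, K = NULL) {
  design <- build_design(dataset, spec)
  if (is.null(K)) K <- default_K(dataset)
  P <- ncol(design$X)
  if (length(theta) != design$k)
    stop("theta must have length ", design$k, " (", P, " abundance + ",
         ncol(design$W), " detection coefficients)", call. = FALSE)
  f <- marginal_loglik_fun(design, K)
  sum(f(theta[seq_len(P)], theta[-seq_len(P)]))
}

#' Default truncation bound for the latent abundance sum
#'
#' Maximum observed count plus 100, the usual safety margin for N-mixture
#' fitting at the count magnitudes seen in transect surveys of songbirds.
#'
#' @param dataset a [survey_dataset()].
#' @return An integer bound `K`.
#' @export
default_K <- function(dataset) {
  max(dataset$counts$count, 0L, na.rm = TRUE) + 100L
}
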