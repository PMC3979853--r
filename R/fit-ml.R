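#' Fit a binomial mixture model by maximum likelihood
#'
#' Maximises the marginal likelihood of the Poisson-binomial mixture (latent
#' transect-year abundance summed out to the truncation bound `K`) with
#' quasi-Newton optimisation (`optim(method = "BFGS")`, numerical gradients).
#' The N-mixture likelihood surface is known to be multimodal, so the fit is
#' repeated from `nstarts` starting points (a data-driven start plus seeded
#' random perturbations) and the best solution is returned.
#'
#' This maximum-likelihood stage treats transect-years as independent; the
#' random transect effect for repeated annual surveys of the same transects
#' is introduced by the Bayesian stage, [nmix_trend()].
#'
#' @param dataset a [survey_dataset()].
#' @param spec an [nmix_spec()]; alternatively pass `abundance`/`detection`.
#' @param abundance,detection shorthand forwarded to [nmix_spec()] when
#'   `spec` is `NULL`.
#' @param K truncation bound (default: maximum observed count + 100).
#' @param nstarts number of optimisation starts.
#' @param seed seed for the random starting perturbations.
#' @param hessian compute the Hessian at the optimum for standard errors.
#' @return An object of class `nmix` with components `coefficients`
#'   (named, abundance block prefixed `lam.`, detection block `det.`),
#'   `loglik`, `k`, `AIC`, `K`, `convergence` (TRUE if the best start
#'   reported successful convergence), `vcov`, `design`, `spec`, `dataset`.
#' @examples
#' sim <- simulate_survey(generator_config(n_transects = 15, n_years = 2, seed = 1))
#' fit <- nmix(sim$dataset, abundance = "water", detection = "constant",
#'             nstarts = 2)
#' summary(fit)
#' @seealso [fit_candidates()], [aic_table()], [nmix_trend()]
#' @export
nmix <- function(dataset, spec = NULL, abundance = "water",
                 detection = "constant", K = NULL, nstarts = 5, seed = 1,
                 hessian = TRUE) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (is.null(spec)) spec <- nmix_spec(abundance, detection)
  if (is.null(K)) K <- default_K(dataset)
  design <- build_design(dataset, spec)
  P <- ncol(design$X); Q <- ncol(design$W)
  f <- marginal_loglik_fun(design, K)

  negll <- function(theta) {
    v <- -sum(f(theta[seq_len(P)], theta[-seq_len(P)]))
    if (!is.finite(v)) 1e10 else v
  }

  # data-driven central start: log mean of max counts, mid-range detection
  start0 <- numeric(P + Q)
  start0[1] <- log(mean(design$maxy) + 0.5)
  starts <- list(start0)
  if (nstarts > 1) {
    set.seed(seed)
    for (i in seq_len(nstarts - 1))
      starts[[i + 1]] <- start0 + rnorm(P + Q, 0, 0.5)
  }

  best <- NULL
  for (st in starts) {
    op <- tryCatch(
      optim(st, negll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best))
    stop("no optimisation start converged", call. = FALSE)

  theta <- best$par
  names(theta) <- c(paste0("lam.", colnames(design$X)),
                    paste0("det.", colnames(design$W)))
  V <- NULL
  if (hessian) {
    H <- tryCatch(optim(theta, negll, method = "BFGS",
                        control = list(maxit = 1), hessian = TRUE)$hessian,
                  error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) dimnames(V) <- list(names(theta), names(theta))
    }
  }

  structure(list(call = match.call(), spec = spec,
                 coefficients = theta, loglik = -best$value,
                 k = design$k, AIC = 2 * design$k + 2 * best$value,
                 K = K, convergence = best$convergence == 0,
                 vcov = V, design = design, dataset = dataset),
            class = "nmix")
}

nmix_theta_split <- function(object) {
  P <- ncol(object$design$X)
  list(beta = unname(object$coefficients[seq_len(P)]),
       alpha = unname(object$coefficients[-seq_len(P)]))
}

#' @export
print.nmix <- function(x, ...) {
  cat("Binomial mixture model (ML):", x$spec$label, "\n")
  cat(sprintf("  logLik %.2f on k = %d parameters, AIC %.2f (K = %d)%s\n",
              x$loglik, x$k, x$AIC, x$K,
              if (!x$convergence) " [NOT CONVERGED]" else ""))
  print(round(x$coefficients, 3))
  invisible(x)
}

#' @export
summary.nmix <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(pmax(diag(object$vcov), 0)) else
    rep(NA_real_, length(object$coefficients))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * (1 - stats::pnorm(abs(z))))
  out <- list(spec = object$spec, coefficients = tab, loglik = object$loglik,
              k = object$k, AIC = object$AIC, convergence = object$convergence)
  class(out) <- "summary.nmix"
  out
}

#' @export
print.summary.nmix <- function(x, ...) {
  cat("Binomial mixture model (ML):", x$spec$label, "\n\n")
  stats::printCoefmat(x$coefficients, digits = 3)
  cat(sprintf("\nlogLik %.2f, k = %d, AIC %.2f%s\n", x$loglik, x$k, x$AIC,
              if (!x$convergence) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @export
coef.nmix <- function(object, ...) object$coefficients

#' @export
vcov.nmix <- function(object, ...) object$vcov

#' @export
logLik.nmix <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' @export
#' @method predict nmix
predict.nmix <- function(object, type = c("lambda", "p", "expected"),
                         newdata = NULL, ...) {
  type <- match.arg(type)
  design <- if (is.null(newdata)) object$design else
    build_design(newdata, object$spec)
  th <- nmix_theta_split(object)
  lam <- expected_abundance(th$beta, design$X)
  p <- detection_prob(th$alpha, design$W)
  pm <- matrix(p, nrow(design$y), design$J, byrow = TRUE)
  switch(type,
         lambda = lam,
         p = pm,
         expected = lam * pm)
}

#' @export
fitted.nmix <- function(object, ...) predict(object, type = "expected")

#' @export
residuals.nmix <- function(object, ...) {
  object$design$y - fitted(object)
}

#' Simulate replicate surveys from a fitted model
#'
#' Draws latent abundances `N ~ Poisson(lambda)` and counts
#' `y ~ Binomial(N, p)` at the fitted parameter values, keeping the design
#' (covariates, years, visits) of the original data.
#'
#' @param object a fitted [nmix()] model.
#' @param nsim number of replicate count tables.
#' @param seed optional seed.
#' @param ... unused.
#' @return A list of `nsim` count data frames shaped like
#'   `object$dataset$counts`.
#' @export
#' @method simulate nmix
simulate.nmix <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  design <- object$design
  th <- nmix_theta_split(object)
  lam <- expected_abundance(th$beta, design$X)
  pm <- matrix(detection_prob(th$alpha, design$W), nrow(design$y), design$J,
               byrow = TRUE)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    N <- rpois(length(lam), lam)
    y <- matrix(rbinom(length(pm), rep(N, design$J), as.vector(pm)),
                nrow(pm), ncol(pm))
    y[is.na(design$y)] <- NA_integer_
    cnt <- object$dataset$counts
    cnt$count <- as.integer(t(y))
    out[[s]] <- cnt
  }
  out
}

#' @export
plot.nmix <- function(x, ...) {
  obs <- as.vector(x$design$y)
  pred <- as.vector(fitted(x))
  plot(pred, obs, xlab = "Fitted mean count (lambda * p)",
       ylab = "Observed count",
       main = x$spec$label, ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Fit a set of candidate models
#'
#' @param dataset a [survey_dataset()].
#' @param specs list of [nmix_spec()] objects (default: the full 45-model
#'   candidate set of [candidate_specs()]).
#' @param ... passed on to [nmix()].
#' @param progress print one line per fitted model.
#' @return A list of `nmix` fits, class `nmix_candidates`.
#' @export
fit_candidates <- function(dataset, specs = candidate_specs(), ...,
                           progress = FALSE) {
  fits <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    fits[[i]] <- nmix(dataset, spec = specs[[i]], ...)
    if (progress)
      message(sprintf("[%2d/%d] %-45s AIC %.2f", i, length(specs),
                      specs[[i]]$label, fits[[i]]$AIC))
  }
  structure(fits, class = "nmix_candidates")
}

#' Model-selection table with Akaike weights
#'
#' Orders models by AIC and reports \eqn{\Delta}AIC (difference to the best
#' model) and Akaike weights
#' \eqn{\omega_i = \exp(-\Delta_i/2) / \sum_m \exp(-\Delta_m/2)}.
#'
#' @param x a list of [nmix()] fits (e.g. from [fit_candidates()]), or a
#'   numeric vector of AIC values (as printed in a published selection
#'   table).
#' @param ... further arguments; for the numeric method, `k` (parameter
#'   counts) and `labels`.
#' @return A data frame with columns `model`, `k`, `AIC`, `delta`, `weight`,
#'   sorted by AIC.
#' @examples
#' aic_table(c(m1 = 100.0, m2 = 102.5, m3 = 110.1))
#' @export
aic_table <- function(x, ...) UseMethod("aic_table")

#' @rdname aic_table
#' @export
aic_table.numeric <- function(x, k = NA_integer_, labels = NULL, ...) {
  labels <- labels %||% names(x) %||% paste0("model", seq_along(x))
  tab <- data.frame(model = labels, k = k, AIC = as.numeric(x))
  tab <- tab[order(tab$AIC), , drop = FALSE]
  tab$delta <- tab$AIC - tab$AIC[1]
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  tab
}

#' @rdname aic_table
#' @export
aic_table.list <- function(x, ...) {
  aic_table(vapply(x, function(f) f$AIC, 0),
            k = vapply(x, function(f) f$k, 0L),
            labels = vapply(x, function(f) f$spec$label, ""))
}

#' @rdname aic_table
#' @export
aic_table.nmix_candidates <- function(x, ...) aic_table.list(unclass(x), ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
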