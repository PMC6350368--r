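# Overflow-safe softplus: log(1 + exp(eta)) without overflow for large eta.
softplus <- function(eta) {
  out <- numeric(length(eta))
  pos <- eta > 0
  out[pos] <- eta[pos] + log1p(exp(-eta[pos]))
  out[!pos] <- log1p(exp(eta[!pos]))
  out
}

#' Bernoulli log-likelihood of a logistic model
#'
#' \deqn{L(w) = \sum_i \left[ y_i (w \cdot x_i) - \log(1 + e^{w \cdot x_i}) \right]}
#' computed with an overflow-safe softplus.
#'
#' @param w Weight vector.
#' @param X Design matrix (first column all ones).
#' @param y Binary 0/1 response.
#' @return The log-likelihood, a scalar (0 or negative).
#' @export
logistic_loglik <- function(w, X, y) {
  eta <- as.vector(X %*% w)
  sum(y * eta - softplus(eta))
}

#' Fit the per-disease logistic model by maximum likelihood
#'
#' Newton-Raphson with step-halving on the (optionally ridge-stabilized)
#' log-likelihood. The objective is concave, so with step-halving the
#' accepted log-likelihood trace is non-decreasing; convergence is declared
#' when the gradient infinity-norm falls below `tol`. A tiny default ridge
#' guards against complete separation (which makes the unpenalized MLE
#' diverge) while perturbing well-posed fits far below reporting precision;
#' set `ridge = 0` for the exact MLE.
#'
#' @param features Feature tibble from [build_features()] (columns `phi1`,
#'   `phi0`, `label`), or a numeric design matrix if `y` is given.
#' @param y Binary response when `features` is a matrix; ignored otherwise.
#' @param tol Gradient infinity-norm tolerance; default `1e-8`.
#' @param ridge Ridge penalty on the coefficients; default `1e-8`.
#' @param max_iter Newton iteration cap; default 100.
#' @return An object of class `mda_logit`: weights `w` (named), `loglik`,
#'   `grad_norm`, `iterations`, `converged`, and the accepted `loglik_trace`.
#' @export
#' @examples
#' walks_free <- cbind(1, c(1, 1, 0, 0))  # intercept + one binary feature
#' fit_logistic(walks_free, y = c(1, 1, 0, 1), ridge = 0)
fit_logistic <- function(features, y = NULL, tol = 1e-8, ridge = 1e-8,
                         max_iter = 100L) {
  if (is.data.frame(features)) {
    stopifnot(all(c("phi1", "phi0", "label") %in% names(features)))
    X <- cbind(intercept = 1, phi1 = features$phi1, phi0 = features$phi0)
    y <- features$label
  } else {
    X <- as.matrix(features)
    if (is.null(colnames(X))) {
      colnames(X) <- c("intercept", paste0("x", seq_len(ncol(X) - 1)))
    }
  }
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (all(y == 1) || all(y == 0)) {
    stop("disease has no known associations (or no candidates); ",
         "model cannot be trained", call. = FALSE)
  }
  p <- ncol(X)
  w <- numeric(p)
  obj <- function(w) logistic_loglik(w, X, y) - 0.5 * ridge * sum(w^2)
  ll <- obj(w)
  trace <- ll
  grad_norm <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- as.vector(X %*% w)
    pi_hat <- stats::plogis(eta)
    grad <- as.vector(crossprod(X, y - pi_hat)) - ridge * w
    grad_norm <- max(abs(grad))
    if (grad_norm < tol) { converged <- TRUE; break }
    wt <- pi_hat * (1 - pi_hat)
    H <- crossprod(X * wt, X) + diag(ridge + 1e-12, p)
    step <- solve(H, grad)
    # step-halving: accept the first step that does not decrease the objective
    alpha <- 1
    repeat {
      w_new <- w + alpha * step
      ll_new <- obj(w_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) { w_new <- w; ll_new <- ll; break }
    }
    w <- w_new
    ll <- ll_new
    trace <- c(trace, ll)
  }
  if (converged) {
    # recompute final diagnostics at the accepted w
    pi_hat <- stats::plogis(as.vector(X %*% w))
    grad_norm <- max(abs(as.vector(crossprod(X, y - pi_hat)) - ridge * w))
  }
  names(w) <- colnames(X)
  structure(list(w = w, loglik = logistic_loglik(w, X, y),
                 grad_norm = grad_norm, iterations = it,
                 converged = converged, loglik_trace = trace,
                 ridge = ridge, tol = tol),
            class = "mda_logit")
}

#' @export
print.mda_logit <- function(x, ...) {
  cat("<mda_logit>  logLik =", format(x$loglik, digits = 6),
      if (x$converged) "(converged," else "(NOT converged,",
      x$iterations, "iterations)\n")
  print(round(x$w, 6))
  invisible(x)
}

#' Posterior association probability
#'
#' \deqn{P(y = 1 \mid x) = \frac{e^{w^* \cdot x}}{1 + e^{w^* \cdot x}}}
#' with `P(y = 0 | x)` computed as the exact complement.
#'
#' @param object A fitted `mda_logit`.
#' @param newdata Feature tibble with `phi1` and `phi0` columns, or a
#'   design matrix matching the fitted weights.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.mda_logit <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) {
    cbind(1, newdata$phi1, newdata$phi0)
  } else {
    as.matrix(newdata)
  }
  stopifnot(ncol(X) == length(object$w))
  stats::plogis(as.vector(X %*% object$w))
}

#' Tidy the fitted weights
#' @param x An `mda_logit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`.
#' @method tidy mda_logit
#' @export
tidy.mda_logit <- function(x, ...) {
  tibble::tibble(term = names(x$w), estimate = unname(x$w))
}

#' One-row fit summary
#' @param x An `mda_logit`.
#' @param ... Unused.
#' @return Tibble with `loglik`, `grad_norm`, `iterations`, `converged`.
#' @method glance mda_logit
#' @export
glance.mda_logit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, grad_norm = x$grad_norm,
                 iterations = x$iterations, converged = x$converged)
}

#' Export a fitted model as JSON
#'
#' @param model An `mda_logit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "mda_logit"))
  jsonlite::write_json(
    list(weights = as.list(model$w), loglik = model$loglik,
         grad_norm = model$grad_norm, iterations = model$iterations,
         converged = model$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
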