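#' Fit a binomial (logit) GLM by iteratively reweighted least squares
#'
#' Plain logit-link maximum likelihood used for the host-specificity stage
#' (probability that a trapped individual belongs to a usual-host pollinator
#' species). Complete or quasi-complete separation is detected and flagged,
#' not raised.
#'
#' @param formula model formula; the response may be a 0/1 vector, a logical,
#'   or a two-column matrix \code{cbind(successes, failures)}.
#' @param data data.frame.
#' @return object of class \code{"binom_fit"} with \code{coefficients},
#'   \code{vcov}, \code{loglik} (including the binomial coefficient term),
#'   \code{deviance}, \code{AIC}, \code{k}, \code{separated} and
#'   \code{converged}.
#' @export
fit_binomial_glm <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  r <- stats::model.response(mf)
  if (is.matrix(r)) {
    s <- r[, 1]
    m <- r[, 1] + r[, 2]
  } else {
    s <- as.numeric(r)
    m <- rep(1, length(s))
  }
  if (any(s < 0) || any(s > m)) stop("need 0 <= successes <= trials")
  X <- model.matrix(formula, data)
  p <- ncol(X)
  beta <- rep(0, p)
  dev_old <- Inf
  converged <- FALSE
  for (it in 1:100) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- m * mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (s - m * mu) / w
    fit <- tryCatch(solve(crossprod(X, X * w), crossprod(X, w * z)),
                    error = function(e) NULL)
    if (is.null(fit)) break
    beta <- drop(fit)
    eta <- drop(X %*% beta)
    mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    dev <- -2 * sum(s * log(mu) + (m - s) * log(1 - mu)) +
      2 * sum(ifelse(s > 0, s * log(s / m), 0) +
              ifelse(m - s > 0, (m - s) * log((m - s) / m), 0))
    if (is.finite(dev_old) && abs(dev - dev_old) < 1e-10 * (abs(dev) + 1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  ll <- sum(lchoose(m, s) + s * log(mu) + (m - s) * log(1 - mu))
  w <- m * mu * (1 - mu)
  vc <- tryCatch(solve(crossprod(X, X * w)),
                 error = function(e) matrix(NA_real_, p, p))
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(vc), 0))
  separated <- any(abs(beta) > 15) || any(!is.finite(se)) ||
    any(se > 100, na.rm = TRUE)
  structure(list(coefficients = setNames(beta, colnames(X)), vcov = vc,
                 loglik = ll, deviance = dev_old, AIC = 2 * p - 2 * ll,
                 k = p, n_obs = length(s),
                 data_sig = c(length(s), sum(s), sum(m)),
                 fitted = mu, separated = separated, converged = converged,
                 xlevels = .design_levels(formula, data)),
            class = "binom_fit")
}

#' @export
print.binom_fit <- function(x, ...) {
  cat("Binomial GLM (IRLS", if (!x$converged) ", NOT converged" else "",
      if (x$separated) ", separation flagged" else "", ")\n", sep = "")
  cat("  log-likelihood:", format(x$loglik), "  AIC:", format(x$AIC), "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
logLik.binom_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}
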