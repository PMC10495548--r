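#' Rank fitted models by AIC
#'
#' All fits must be on identical data (checked by n and a response checksum);
#' fits that did not produce a likelihood (non-convergent typed failures) are
#' reported with \code{NA} and ranked last.
#'
#' @param fits named list of fits with \code{AIC}, \code{loglik}, \code{k},
#'   \code{data_sig} fields.
#' @return data.frame ordered by ascending AIC with a \code{dAIC} column
#'   relative to the best fit.
#' @export
aic_rank <- function(fits) {
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  sigs <- lapply(fits, function(f) f$data_sig)
  sigs <- sigs[!vapply(sigs, is.null, logical(1))]
  if (length(sigs) > 1) {
    ref <- sigs[[1]]
    same <- vapply(sigs, function(s) length(s) == length(ref) &&
                     all(abs(s - ref) < 1e-8), logical(1))
    if (!all(same)) stop("fits are not all on identical data")
  }
  tab <- data.frame(
    model = names(fits),
    k = vapply(fits, function(f) if (is.null(f$k)) NA_integer_ else f$k,
               integer(1)),
    loglik = vapply(fits, function(f)
      if (is.null(f$loglik)) NA_real_ else f$loglik, numeric(1)),
    AIC = vapply(fits, function(f)
      if (is.null(f$AIC)) NA_real_ else f$AIC, numeric(1)),
    status = vapply(fits, function(f)
      if (is.null(f$status)) "converged" else f$status, character(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AIC), , drop = FALSE]
  tab$dAIC <- tab$AIC - min(tab$AIC, na.rm = TRUE)
  rownames(tab) <- NULL
  tab
}

# joint fixed-effect coefficient vector / covariance of a fit
.coef_full <- function(fit) fit$coefficients
.vcov_full <- function(fit) fit$vcov

#' Wald z-test for a linear contrast of model coefficients
#'
#' @param fit fitted model with \code{coefficients} and \code{vcov}.
#' @param contrast numeric contrast vector, either the full length of the
#'   coefficient vector or named by a subset of coefficients.
#' @return list with \code{estimate}, \code{se}, \code{z} and two-sided
#'   \code{p}.
#' @export
wald_z <- function(fit, contrast) {
  co <- .coef_full(fit)
  V <- .vcov_full(fit)
  if (is.null(co) || is.null(V) || all(is.na(V))) {
    stop("no covariance available (non-convergent fit)")
  }
  if (!is.null(names(contrast))) {
    cv <- setNames(rep(0, length(co)), names(co))
    unknown <- setdiff(names(contrast), names(co))
    if (length(unknown) > 0) {
      stop("unknown coefficient(s): ", paste(unknown, collapse = ", "))
    }
    cv[names(contrast)] <- contrast
    contrast <- cv
  }
  if (length(contrast) != length(co)) {
    stop("contrast length does not match coefficient vector")
  }
  est <- sum(contrast * co)
  v <- drop(t(contrast) %*% V %*% contrast)
  if (!is.finite(v) || v < 0) {
    stop("contrast variance not available (covariance not positive definite)")
  }
  se <- sqrt(v)
  z <- if (se == 0) 0 else est / se
  list(estimate = est, se = se, z = z, p = 2 * pnorm(-abs(z)))
}

#' Likelihood-ratio test between nested fits
#'
#' @param fit_full,fit_reduced fits on identical data, reduced nested in
#'   full.
#' @return list with \code{chisq}, \code{df}, \code{p}.
#' @export
lrt <- function(fit_full, fit_reduced) {
  if (!is.null(fit_full$data_sig) && !is.null(fit_reduced$data_sig) &&
      !all(abs(fit_full$data_sig - fit_reduced$data_sig) < 1e-8)) {
    stop("fits are not on identical data")
  }
  if (fit_full$k < fit_reduced$k) stop("reduced model must have fewer parameters")
  stat <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (stat < -1e-6) {
    stop("full-model likelihood below reduced-model likelihood: optimizer failure")
  }
  stat <- max(stat, 0)
  df <- fit_full$k - fit_reduced$k
  list(chisq = stat, df = df,
       p = if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE))
}

#' Single-step (Tukey-type) simultaneous confidence intervals for contrasts
#'
#' Given estimates and covariance of a set of linear contrasts, computes
#' simultaneous \code{level} intervals using the equicoordinate quantile of
#' the multivariate normal with the contrasts' correlation matrix, plus
#' single-step adjusted p-values. The multivariate-normal quantile is
#' evaluated with a fixed internal RNG state so results are deterministic.
#'
#' @param est named vector of contrast estimates.
#' @param V covariance matrix of the estimates.
#' @param level simultaneous confidence level.
#' @return data.frame with estimate, se, z, adjusted interval and adjusted
#'   p-value per contrast; the critical value is in attribute
#'   \code{"crit"}.
#' @export
simultaneous_contrasts <- function(est, V, level = 0.95) {
  m <- length(est)
  se <- sqrt(pmax(diag(as.matrix(V)), 0))
  if (m == 0) return(data.frame())
  corr <- as.matrix(V) / outer(se, se)
  corr[!is.finite(corr)] <- 0
  diag(corr) <- 1
  seed_exists <- exists(".Random.seed", envir = globalenv())
  if (seed_exists) old_seed <- get(".Random.seed", envir = globalenv())
  set.seed(20230911L)
  on.exit({
    if (seed_exists) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  alg <- mvtnorm::GenzBretz(abseps = 1e-6, maxpts = 100000)
  if (m == 1) {
    crit <- qnorm(1 - (1 - level) / 2)
  } else {
    crit <- mvtnorm::qmvnorm(level, tail = "both.tails", corr = corr,
                             algorithm = alg)$quantile
  }
  z <- ifelse(se > 0, est / se, 0)
  p_adj <- vapply(z, function(zz) {
    if (!is.finite(zz)) return(NA_real_)
    if (m == 1) return(2 * pnorm(-abs(zz)))
    1 - mvtnorm::pmvnorm(lower = rep(-abs(zz), m), upper = rep(abs(zz), m),
                         corr = corr, algorithm = alg)[1]
  }, numeric(1))
  out <- data.frame(contrast = names(est), estimate = unname(est), se = se,
                    z = z, lower = est - crit * se, upper = est + crit * se,
                    p_adj = pmin(pmax(p_adj, 0), 1), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "crit") <- crit
  out
}

#' Tukey-adjusted pairwise comparisons of a factor's levels
#'
#' Builds all pairwise differences between the levels of a model factor
#' (treatment coding, reference level at zero) in the chosen model part and
#' returns single-step simultaneous intervals via
#' \code{\link{simultaneous_contrasts}}.
#'
#' @param fit \code{zip_fit} / \code{zip_mixed_fit} / \code{binom_fit}.
#' @param factor_name name of the factor (must appear in the fit's stored
#'   levels).
#' @param component \code{"cond"} or \code{"zi"} for ZIP fits; ignored for
#'   binomial fits (coefficients are unprefixed).
#' @param level simultaneous confidence level.
#' @return data.frame as in \code{\link{simultaneous_contrasts}}; empty for a
#'   single-level factor.
#' @export
tukey_pairwise <- function(fit, factor_name, component = "cond",
                           level = 0.95) {
  lev <- fit$xlevels[[factor_name]]
  if (is.null(lev)) stop("factor ", factor_name, " not found in fit")
  m <- length(lev)
  if (m < 2) return(data.frame())
  co <- .coef_full(fit)
  V <- .vcov_full(fit)
  prefix <- if (inherits(fit, "binom_fit")) "" else paste0(component, "_")
  cn <- paste0(prefix, factor_name, lev)
  idx <- match(cn, names(co))          # NA for the reference level
  if (all(is.na(idx))) stop("factor ", factor_name, " has no coefficients in ",
                            component, " part")
  pairs <- utils::combn(m, 2)
  C <- matrix(0, ncol(pairs), length(co))
  labs <- character(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (!is.na(idx[j])) C[k, idx[j]] <- 1
    if (!is.na(idx[i])) C[k, idx[i]] <- -1
    labs[k] <- paste(lev[j], "-", lev[i])
  }
  est <- setNames(drop(C %*% co), labs)
  Vc <- C %*% V %*% t(C)
  simultaneous_contrasts(est, Vc, level = level)
}
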