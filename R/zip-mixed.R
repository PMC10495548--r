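# scatter-accumulate: sum w by integer group id into a length-q vector
.accum <- function(w, id, q) {
  out <- numeric(q)
  tmp <- rowsum(w, id)
  out[as.integer(rownames(tmp))] <- tmp
  out
}

#' Fit a zero-inflated Poisson mixed model (Laplace approximation)
#'
#' Fixed effects in both model parts plus independent Gaussian random
#' intercepts: any number of grouping factors in the conditional (Poisson)
#' part and optionally in the zero-inflation part, each with its own
#' variance. The marginal likelihood is approximated by Laplace's method
#' (random-effect mode by damped Newton on the analytic joint gradient and
#' Hessian); the outer optimization over fixed effects and log-SDs uses BFGS
#' with warm-started inner modes and a Nelder-Mead fallback.
#'
#' @param formula conditional model formula (count response).
#' @param zi_formula one-sided zero-inflation formula.
#' @param data data.frame.
#' @param offset optional numeric vector for the conditional part only.
#' @param random character vector of grouping-factor column names for the
#'   conditional part (e.g. \code{c("fig_species", "date_start")}).
#' @param zi_random character vector of grouping factors for the
#'   zero-inflation part (may be empty).
#' @param control list: \code{maxit} outer iterations (default 400),
#'   \code{reltol} outer relative tolerance (default 1e-9),
#'   \code{sigma_start} starting SD for all variance components.
#' @return object of class \code{c("zip_mixed_fit", "zip_fit")} with
#'   coefficients, random-effect SDs \code{sigma}, conditional modes
#'   \code{ranef}, Laplace \code{loglik}, \code{AIC}, fixed-effect
#'   \code{vcov}, and \code{status} among \code{"converged"},
#'   \code{"boundary"} (a variance at zero) and \code{"non_convergence"}.
#'   Fitting failures yield a typed object with the appropriate status rather
#'   than an error.
#' @export
fit_zip_mixed <- function(formula, zi_formula = ~1, data, offset = NULL,
                          random = character(0), zi_random = character(0),
                          control = list()) {
  ctl <- modifyList(list(maxit = 400, reltol = 1e-9, sigma_start = 0.5),
                    control)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y < 0) || any(y != round(y))) {
    stop("response must be non-negative integers")
  }
  X <- model.matrix(formula, data)
  W <- model.matrix(zi_formula, data)
  if (is.null(offset)) offset <- rep(0, length(y))
  n <- length(y)
  pb <- ncol(X)
  pg <- ncol(W)

  groups <- c(lapply(random, function(g) list(name = g, part = "cond",
                                              f = factor(data[[g]]))),
              lapply(zi_random, function(g) list(name = g, part = "zi",
                                                 f = factor(data[[g]]))))
  if (length(groups) == 0) {
    stop("no random effects requested; use fit_zip_glm()")
  }
  for (g in groups) {
    if (anyNA(g$f)) stop("grouping factor ", g$name, " has missing values")
  }
  ng <- length(groups)
  q_each <- vapply(groups, function(g) nlevels(g$f), integer(1))
  q_tot <- sum(q_each)
  offs <- cumsum(c(0, q_each))
  # per-observation index into the stacked random-effect vector, per group
  gidx <- lapply(seq_len(ng), function(gi)
    as.integer(groups[[gi]]$f) + offs[gi])
  lidx <- lapply(seq_len(ng), function(gi) as.integer(groups[[gi]]$f))
  is_cond <- vapply(groups, function(g) g$part == "cond", logical(1))
  cond_g <- which(is_cond)
  zi_g <- which(!is_cond)

  start_fit <- tryCatch(fit_zip_glm(formula, zi_formula, data, offset),
                        error = function(e) NULL)
  beta0 <- if (!is.null(start_fit) && all(is.finite(start_fit$beta))) {
    start_fit$beta
  } else rep(0, pb)
  gamma0 <- if (!is.null(start_fit) && all(is.finite(start_fit$gamma))) {
    start_fit$gamma
  } else rep(0, pg)
  phi0 <- c(beta0, gamma0, rep(log(ctl$sigma_start), ng))

  env <- new.env()
  env$theta <- rep(0, q_tot)

  re_eta <- function(th) {
    v <- numeric(n)
    for (gi in cond_g) v <- v + th[gidx[[gi]]]
    v
  }
  re_zeta <- function(th) {
    v <- numeric(n)
    for (gi in zi_g) v <- v + th[gidx[[gi]]]
    v
  }

  inner <- function(phi, keep_mode = TRUE) {
    beta <- phi[1:pb]
    gamma <- phi[(pb + 1):(pb + pg)]
    lsig <- phi[(pb + pg + 1):length(phi)]
    sig2 <- exp(2 * lsig)
    prec <- rep(1 / sig2, q_each)
    const <- -sum(q_each * (lsig + 0.5 * log(2 * pi)))
    eta0 <- drop(X %*% beta) + offset
    zeta0 <- drop(W %*% gamma)
    theta <- env$theta
    h_of <- function(th) {
      sum(.zip_ll_vec(y, eta0 + re_eta(th), zeta0 + re_zeta(th))) -
        0.5 * sum(prec * th^2) + const
    }
    h_cur <- h_of(theta)
    if (!is.finite(h_cur)) {
      theta <- rep(0, q_tot)
      h_cur <- h_of(theta)
    }
    H <- NULL
    ok <- FALSE
    for (it in 1:100) {
      d <- .zip_ll_deriv(y, eta0 + re_eta(theta), zeta0 + re_zeta(theta))
      gr <- -prec * theta
      H <- diag(-prec, q_tot)
      for (gi in seq_len(ng)) {
        rng_i <- (offs[gi] + 1):offs[gi + 1]
        gvec <- if (is_cond[gi]) d$g_eta else d$g_zeta
        gr[rng_i] <- gr[rng_i] + .accum(gvec, lidx[[gi]], q_each[gi])
        for (gj in seq_len(ng)) {
          if (gj < gi) next
          w <- if (is_cond[gi] && is_cond[gj]) d$h_ee
          else if (!is_cond[gi] && !is_cond[gj]) d$h_zz
          else d$h_ez
          rng_j <- (offs[gj] + 1):offs[gj + 1]
          if (gi == gj) {
            dg <- .accum(w, lidx[[gi]], q_each[gi])
            H[cbind(rng_i, rng_i)] <- H[cbind(rng_i, rng_i)] + dg
          } else {
            key <- lidx[[gi]] + (lidx[[gj]] - 1L) * q_each[gi]
            blk <- matrix(0, q_each[gi], q_each[gj])
            blk[] <- .accum(w, key, q_each[gi] * q_each[gj])
            H[rng_i, rng_j] <- H[rng_i, rng_j] + blk
            H[rng_j, rng_i] <- H[rng_j, rng_i] + t(blk)
          }
        }
      }
      if (max(abs(gr)) < 1e-8) { ok <- TRUE; break }
      ridge <- 0
      ch <- NULL
      repeat {
        ch <- tryCatch(chol(-(H - diag(ridge, q_tot))), error = function(e) NULL)
        if (!is.null(ch)) break
        ridge <- if (ridge == 0) 1e-8 else ridge * 10
        if (ridge > 1e8) return(NULL)
      }
      step <- backsolve(ch, backsolve(ch, gr, transpose = TRUE))
      s <- 1
      repeat {
        h_new <- h_of(theta + s * step)
        if (is.finite(h_new) && h_new >= h_cur - 1e-12) break
        s <- s / 2
        if (s < 1e-10) break
      }
      if (s < 1e-10) { ok <- max(abs(gr)) < 1e-5; break }
      theta <- theta + s * step
      h_cur <- h_new
    }
    # Even without full inner convergence return a finite Laplace value so
    # the outer objective has no cliffs (finite-difference gradients stay
    # well defined); poorly approximated regions score poorly and are left.
    ch <- tryCatch(chol(-H), error = function(e) NULL)
    if (is.null(ch)) {
      ridge <- 1e-8
      while (is.null(ch) && ridge <= 1e8) {
        ch <- tryCatch(chol(-(H - diag(ridge, q_tot))), error = function(e) NULL)
        ridge <- ridge * 10
      }
      if (is.null(ch)) return(NULL)
    }
    if (keep_mode && ok) env$theta <- theta
    lap <- h_cur + 0.5 * q_tot * log(2 * pi) - sum(log(diag(ch)))
    list(lap = lap, theta = theta, converged = ok)
  }

  neg <- function(phi) {
    if (any(abs(phi) > 50)) return(1e8 + sum(phi^2))
    res <- inner(phi)
    if (is.null(res) || !is.finite(res$lap)) return(1e8)
    -res$lap
  }

  opt <- tryCatch(
    optim(phi0, neg, method = "BFGS",
          control = list(maxit = ctl$maxit, reltol = ctl$reltol)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0) {
    start2 <- if (!is.null(opt)) opt$par else phi0
    opt2 <- tryCatch(
      optim(start2, neg, method = "Nelder-Mead",
            control = list(maxit = 1000, reltol = 1e-9)),
      error = function(e) NULL)
    if (!is.null(opt2)) opt <- opt2
  }
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e7) {
    return(structure(list(coefficients = NULL, status = "non_convergence",
                          message = "outer optimization failed",
                          n_obs = n, data_sig = .data_signature(y)),
                     class = c("zip_mixed_fit", "zip_fit")))
  }
  phi <- opt$par
  res <- inner(phi)
  sigma <- exp(phi[(pb + pg + 1):length(phi)])
  status <- if (opt$convergence == 0) "converged" else "non_convergence"
  boundary <- any(sigma < 1e-3)
  if (boundary && status == "converged") status <- "boundary"

  k <- pb + pg + ng
  vc_phi <- tryCatch({
    Hn <- optimHess(phi, neg)
    solve(Hn)
  }, error = function(e) matrix(NA_real_, length(phi), length(phi)))
  co <- setNames(phi[1:(pb + pg)],
                 c(paste0("cond_", colnames(X)), paste0("zi_", colnames(W))))
  sig_names <- vapply(groups, function(g) paste0(g$part, "_", g$name),
                      character(1))
  vc <- vc_phi[1:(pb + pg), 1:(pb + pg), drop = FALSE]
  dimnames(vc) <- list(names(co), names(co))
  ranef <- split(res$theta, rep(seq_len(ng), q_each))
  names(ranef) <- sig_names
  for (gi in seq_len(ng)) {
    names(ranef[[gi]]) <- levels(groups[[gi]]$f)
  }
  se_g <- sqrt(pmax(diag(vc)[(pb + 1):(pb + pg)], 0))
  separated <- any(abs(co) > 15) || any(!is.finite(se_g)) ||
    any(se_g > 100, na.rm = TRUE)
  structure(list(coefficients = co, beta = co[1:pb],
                 gamma = co[(pb + 1):(pb + pg)],
                 sigma = setNames(sigma, sig_names), ranef = ranef,
                 vcov = vc, vcov_phi = vc_phi, loglik = res$lap,
                 AIC = 2 * k - 2 * res$lap, k = k, n_obs = n,
                 data_sig = .data_signature(y), status = status,
                 separated = separated, xlevels = .design_levels(formula, data)),
            class = c("zip_mixed_fit", "zip_fit"))
}

#' @export
print.zip_mixed_fit <- function(x, ...) {
  cat("Zero-inflated Poisson mixed fit (Laplace; ", x$status, ")\n", sep = "")
  if (is.null(x$coefficients)) {
    cat("  ", x$message, "\n")
    return(invisible(x))
  }
  cat("  log-likelihood:", format(x$loglik), "  AIC:", format(x$AIC),
      "  k:", x$k, "  n:", x$n_obs, "\n")
  print(x$coefficients)
  cat("  random-effect SDs:\n")
  print(x$sigma)
  invisible(x)
}
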