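# Tree types as a factor with non-Ficus as reference level, so conditional
# and zero-inflation coefficients are directly the "receptive vs non-Ficus"
# and "vegetative vs non-Ficus" differences.
.tree_type_factor <- function(x) {
  lev <- c("non_ficus", "vegetative", "receptive")
  factor(x, levels = lev[lev %in% unique(x)])
}

.pois_glm_wrap <- function(formula, data, offset) {
  X <- model.matrix(formula, data)
  y <- stats::model.response(stats::model.frame(formula, data))
  g <- glm.fit(X, y, family = poisson(), offset = offset)
  ll <- sum(dpois(y, g$fitted.values, log = TRUE))
  nm <- paste0("cond_", colnames(X))
  v <- solve(crossprod(X, X * g$fitted.values))
  dimnames(v) <- list(nm, nm)
  list(coefficients = setNames(g$coefficients, nm), vcov = v,
       loglik = ll, AIC = 2 * ncol(X) - 2 * ll, k = ncol(X),
       n_obs = length(y), data_sig = .data_signature(y),
       status = "converged", separated = FALSE,
       xlevels = .design_levels(formula, data))
}

#' Stage 1: compare capture counts across tree types
#'
#' Fits the model ladder for pooled Pegoscapus counts — the most elaborate
#' zero-inflated Poisson mixed model (zero-inflation: tree type + random fig
#' species; conditional: tree type + log-days offset + random fig species
#' and date effects), simplifications with random and fixed effects removed,
#' a ZIP GLM and a plain Poisson GLM — ranks them by AIC, and reports Wald
#' z-tests and Tukey-adjusted pairwise intervals for tree-type differences
#' from the best-ranked converged fit.
#'
#' @param events trapping-event data.frame.
#' @param ladder optional character subset of
#'   \code{c("zipm_full", "zipm_nodate", "zip_glm", "pois_glm")}.
#' @return list of class \code{"stage1_report"}: \code{aic} table,
#'   \code{best} fit name, \code{fits}, \code{contrasts_cond},
#'   \code{contrasts_zi} (Tukey tables), \code{wald} per-coefficient tests.
#' @export
run_stage1_treetype <- function(events,
                                ladder = c("zipm_full", "zipm_nodate",
                                           "zip_glm", "pois_glm")) {
  d <- events
  d$tree_type <- .tree_type_factor(d$tree_type)
  off <- log(d$exposure_days)
  multi <- nlevels(d$tree_type) > 1
  f_cond <- if (multi) count_pegoscapus ~ tree_type else count_pegoscapus ~ 1
  f_zi <- if (multi) ~tree_type else ~1
  fits <- list()
  if ("zipm_full" %in% ladder) {
    fits$zipm_full <- fit_zip_mixed(f_cond, f_zi, d, offset = off,
                                    random = c("fig_species", "date_start"),
                                    zi_random = "fig_species")
  }
  if ("zipm_nodate" %in% ladder) {
    fits$zipm_nodate <- fit_zip_mixed(f_cond, f_zi, d, offset = off,
                                      random = "fig_species",
                                      zi_random = "fig_species")
  }
  if ("zip_glm" %in% ladder) {
    fits$zip_glm <- fit_zip_glm(f_cond, f_zi, d, offset = off)
  }
  if ("pois_glm" %in% ladder) {
    fits$pois_glm <- .pois_glm_wrap(f_cond, d, off)
  }
  ok <- vapply(fits, function(f)
    !is.null(f$loglik) && f$status != "non_convergence", logical(1))
  if (!any(ok)) {
    return(structure(list(aic = NULL, best = NULL, fits = fits,
                          status = "all_models_failed"),
                     class = "stage1_report"))
  }
  aic <- aic_rank(fits[ok])
  best_name <- aic$model[1]
  best <- fits[[best_name]]
  contrasts_cond <- contrasts_zi <- data.frame()
  wald <- list()
  if (multi) {
    contrasts_cond <- tryCatch(tukey_pairwise(best, "tree_type", "cond"),
                               error = function(e) data.frame())
    if (!is.null(best$gamma) &&
        any(grepl("^zi_tree_type", names(best$coefficients)))) {
      contrasts_zi <- tryCatch(tukey_pairwise(best, "tree_type", "zi"),
                               error = function(e) data.frame())
    }
    for (nm in grep("^(cond|zi)_tree_type", names(best$coefficients),
                    value = TRUE)) {
      wald[[nm]] <- tryCatch(wald_z(best, setNames(1, nm)),
                             error = function(e)
                               list(estimate = NA, se = NA, z = NA, p = NA))
    }
  }
  structure(list(aic = aic, best = best_name, fits = fits,
                 contrasts_cond = contrasts_cond, contrasts_zi = contrasts_zi,
                 wald = wald, status = "ok"),
            class = "stage1_report")
}

#' Fitted marginal capture rates per tree type
#'
#' Population-level expected captures per trap-day by tree type from a ZIP
#' fit: (1 - p_type) * lambda_type with random effects at zero. This is the
#' quantity the capture-rate figure displays.
#'
#' @param fit \code{zip_fit} with a tree-type factor in both parts.
#' @return data.frame with \code{tree_type}, \code{log_lambda},
#'   \code{logit_p}, \code{marginal} (captures/day).
#' @export
marginal_rates <- function(fit) {
  lev <- fit$xlevels[["tree_type"]]
  if (is.null(lev)) stop("fit has no tree_type factor")
  co <- fit$coefficients
  val <- function(prefix, l) {
    base <- co[[paste0(prefix, "(Intercept)")]]
    nm <- paste0(prefix, "tree_type", l)
    if (nm %in% names(co)) base + co[[nm]] else base
  }
  ll <- vapply(lev, function(l) val("cond_", l), numeric(1))
  has_zi <- any(startsWith(names(co), "zi_"))
  lp <- if (has_zi) vapply(lev, function(l) val("zi_", l), numeric(1)) else
    rep(-Inf, length(lev))
  data.frame(tree_type = lev, log_lambda = ll, logit_p = lp,
             marginal = (1 - plogis(lp)) * exp(ll),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Does a stage-1 report show the expected host-phase pattern?
#'
#' Checks the three qualitative claims of the tree-type comparison against
#' the best-ranked model:
#' \enumerate{
#'   \item receptive trees attract significantly more pollinators than
#'     vegetative trees (Tukey-adjusted conditional interval above zero);
#'   \item receptive trees attract significantly more than non-Ficus trees:
#'     a Wald z-test on the receptive vs non-Ficus difference in the
#'     conditional or the zero-inflation part at p < 0.05. When the
#'     non-Ficus parameters are degenerate (boundary/separation, typical
#'     when controls yield no or almost no captures) the claim is instead
#'     checked descriptively: the observed non-Ficus rate must be below 5
#'     percent of the receptive rate;
#'   \item vegetative and non-Ficus trees sit together far below receptive
#'     trees: on the pseudolog (asinh) scale of fitted marginal rates, the
#'     vegetative to non-Ficus gap is smaller than either gap to receptive.
#' }
#'
#' @param report \code{stage1_report}.
#' @param events the trapping events the report was computed from (used only
#'   for the descriptive fallback of claim 2).
#' @return logical.
#' @export
stage1_pattern <- function(report, events = NULL) {
  if (is.null(report$best)) return(FALSE)
  best <- report$fits[[report$best]]
  cc <- report$contrasts_cond
  if (is.null(cc) || nrow(cc) == 0) return(FALSE)
  rv <- cc[cc$contrast == "receptive - vegetative", ]
  claim1 <- nrow(rv) == 1 && is.finite(rv$lower) && rv$lower > 0
  z_cond <- report$wald[["cond_tree_typereceptive"]]
  z_zi <- report$wald[["zi_tree_typereceptive"]]
  sig <- function(w, sign) !is.null(w) && is.finite(w$p) && w$p < 0.05 &&
    sign * w$estimate > 0
  claim2 <- sig(z_cond, +1) || sig(z_zi, -1)
  if (!claim2 && (isTRUE(best$separated) || !is.null(events))) {
    if (!is.null(events)) {
      obs <- tapply(events$count_pegoscapus, events$tree_type, sum) /
        tapply(events$exposure_days, events$tree_type, sum)
      claim2 <- isTRUE(obs[["non_ficus"]] < 0.05 * obs[["receptive"]])
    }
  }
  mr <- tryCatch(marginal_rates(best), error = function(e) NULL)
  if (is.null(mr)) return(FALSE)
  g <- setNames(asinh(mr$marginal), mr$tree_type)
  claim3 <- all(c("receptive", "vegetative", "non_ficus") %in% names(g)) &&
    abs(g[["vegetative"]] - g[["non_ficus"]]) <
    min(g[["receptive"]] - g[["vegetative"]], g[["receptive"]] - g[["non_ficus"]])
  isTRUE(claim1) && isTRUE(claim2) && isTRUE(claim3)
}

#' Select fig species for the per-species count analysis
#'
#' A species qualifies when pollinators were trapped in both the receptive
#' and vegetative phase and each phase has at least one event with more than
#' a single pollinator counted.
#'
#' @param events trapping-event data.frame.
#' @return character vector of fig species.
#' @export
select_focal_species <- function(events) {
  fic <- events[events$tree_type != "non_ficus", , drop = FALSE]
  out <- character(0)
  for (f in sort(unique(fic$fig_species))) {
    sub <- fic[fic$fig_species == f, , drop = FALSE]
    ok <- vapply(c("receptive", "vegetative"), function(ph) {
      s <- sub[sub$tree_type == ph, , drop = FALSE]
      nrow(s) > 0 && sum(s$count_pegoscapus) > 0 &&
        any(s$count_pegoscapus > 1)
    }, logical(1))
    if (all(ok)) out <- c(out, f)
  }
  out
}

#' Stage 2: per-fig-species ZIP GLMs
#'
#' For each qualifying fig species (see \code{\link{select_focal_species}})
#' fits a zero-inflated Poisson GLM with tree-type effects in both parts
#' (no date effects) to that species' receptive and vegetative events pooled
#' with all non-Ficus control events, and reports simultaneous 95\% intervals
#' for the pairwise tree-type differences of both parts.
#'
#' @param events trapping-event data.frame.
#' @param species optional explicit species selection.
#' @param level confidence level.
#' @return list with \code{species}, \code{fits} and a long-format \code{ci}
#'   table (species, part, contrast, estimate, lower, upper, separated).
#' @export
run_stage2_perspecies <- function(events, species = NULL, level = 0.95) {
  if (is.null(species)) species <- select_focal_species(events)
  nf <- events[events$tree_type == "non_ficus", , drop = FALSE]
  fits <- list()
  rows <- list()
  for (f in species) {
    sub <- rbind(events[events$fig_species == f, , drop = FALSE], nf)
    sub$tree_type <- .tree_type_factor(sub$tree_type)
    if (nlevels(sub$tree_type) < 2) next
    fit <- tryCatch(
      fit_zip_glm(count_pegoscapus ~ tree_type, ~tree_type, sub,
                  offset = log(sub$exposure_days)),
      error = function(e) NULL)
    if (is.null(fit)) next
    fits[[f]] <- fit
    for (part in c("cond", "zi")) {
      tk <- tryCatch(tukey_pairwise(fit, "tree_type", part, level = level),
                     error = function(e) data.frame())
      if (nrow(tk) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        fig_species = f, part = part, contrast = tk$contrast,
        estimate = tk$estimate, lower = tk$lower, upper = tk$upper,
        separated = fit$separated, stringsAsFactors = FALSE)
    }
  }
  ci <- if (length(rows) > 0) do.call(rbind, rows) else data.frame()
  list(species = species, fits = fits, ci = ci)
}

#' Stage 3: host specificity of barcoded individuals
#'
#' Builds the per-individual indicator of being trapped at a usual host via
#' the association registry, fits binomial GLMs (tree type + host fig
#' species, their simplifications, and the interaction model), ranks them by
#' AIC, and reports likelihood-ratio tests for the tree-type and host-species
#' effects plus Wald 95\% intervals for the tree-type coefficients of the
#' additive model.
#'
#' @param barcodes assigned barcode data.frame.
#' @param registry host registry.
#' @return list with \code{data} (individuals used), \code{fits}, \code{aic},
#'   \code{lrt_tree_type}, \code{lrt_host}, \code{ci} (tree-type coefficient
#'   interval), \code{p_usual} (per-phase observed fractions).
#' @export
run_stage3_specificity <- function(barcodes, registry) {
  sp <- barcodes$assigned_species
  usual <- is_usual_host(registry, sp, barcodes$host_fig_species)
  keep <- !is.na(usual) & !is.na(sp) & sp != "new sp."
  d <- data.frame(success = as.integer(usual[keep]),
                  tree_type = factor(barcodes$host_tree_type[keep],
                                     levels = c("vegetative", "receptive")),
                  host = factor(barcodes$host_fig_species[keep]),
                  stringsAsFactors = FALSE)
  names(d)[names(d) == "host"] <- "host_fig_species"
  multi_host <- nlevels(droplevels(d$host_fig_species)) > 1
  d$host_fig_species <- droplevels(d$host_fig_species)
  f_full <- if (multi_host) success ~ tree_type + host_fig_species else
    success ~ tree_type
  fits <- list(full = fit_binomial_glm(f_full, d),
               no_tree_type = fit_binomial_glm(
                 if (multi_host) success ~ host_fig_species else success ~ 1, d),
               intercept = fit_binomial_glm(success ~ 1, d))
  if (multi_host) {
    fits$no_host <- fit_binomial_glm(success ~ tree_type, d)
    fits$interaction <- tryCatch(
      fit_binomial_glm(success ~ tree_type * host_fig_species, d),
      error = function(e) NULL)
    if (is.null(fits$interaction)) fits$interaction <- NULL
  }
  lrt_tree <- lrt(fits$full, fits$no_tree_type)
  lrt_host <- if (multi_host) lrt(fits$full, fits$no_host) else NULL
  co <- fits$full$coefficients
  ci <- NULL
  if ("tree_typereceptive" %in% names(co)) {
    w <- wald_z(fits$full, setNames(1, "tree_typereceptive"))
    ci <- data.frame(term = "receptive - vegetative", estimate = w$estimate,
                     lower = w$estimate - qnorm(0.975) * w$se,
                     upper = w$estimate + qnorm(0.975) * w$se,
                     z = w$z, p = w$p)
  }
  p_usual <- tapply(d$success, d$tree_type, mean)
  list(data = d, fits = fits, aic = aic_rank(fits),
       lrt_tree_type = lrt_tree, lrt_host = lrt_host, ci = ci,
       p_usual = p_usual, separated = fits$full$separated)
}

#' Stage 4: species-level abundance via the joint bootstrap
#'
#' Delegates to \code{\link{abundance_bootstrap}} and formats the result as a
#' category-by-species grid of percentile intervals, with pairwise
#' CI-disjointness calls per wasp species (disjoint intervals are read as
#' significant differences).
#'
#' @param events trapping-event data.frame.
#' @param barcodes assigned barcode data.frame.
#' @param registry host registry.
#' @param B bootstrap replicates (default 200).
#' @param seed integer seed.
#' @param level confidence level.
#' @param species optional wasp-species subset for the report.
#' @param ... passed to \code{\link{abundance_bootstrap}}.
#' @return list with \code{estimates} (long table), \code{grid} (category x
#'   species "low-high" strings), \code{disjoint} (per-wasp logical matrix).
#' @export
run_stage4_bootstrap <- function(events, barcodes, registry, B = 200,
                                 seed = 1, level = 0.95, species = NULL, ...) {
  if (B == 1) warning("B = 1 gives degenerate intervals")
  est <- abundance_bootstrap(events, barcodes, registry, B = B, seed = seed,
                             level = level, ...)
  if (!is.null(species)) {
    est <- est[est$wasp_species %in% species, , drop = FALSE]
  }
  wasps <- unique(est$wasp_species)
  grid <- matrix(NA_character_, length(.categories), length(wasps),
                 dimnames = list(.categories, wasps))
  for (i in seq_len(nrow(est))) {
    grid[est$category[i], est$wasp_species[i]] <-
      if (!est$estimable[i]) "NA" else
        sprintf("%.4g-%.4g", est$ci_low[i], est$ci_high[i])
  }
  disjoint <- lapply(setNames(wasps, wasps), function(w) {
    sub <- est[est$wasp_species == w & est$estimable, , drop = FALSE]
    m <- matrix(NA, nrow(sub), nrow(sub),
                dimnames = list(sub$category, sub$category))
    for (i in seq_len(nrow(sub))) for (j in seq_len(nrow(sub))) {
      m[i, j] <- sub$ci_low[i] > sub$ci_high[j] || sub$ci_low[j] > sub$ci_high[i]
    }
    m
  })
  list(estimates = est, grid = grid, disjoint = disjoint, B = B, seed = seed)
}
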