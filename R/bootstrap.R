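#' Percentile confidence interval (inverse empirical CDF)
#'
#' Type-1 (inverse-ECDF) empirical quantiles at (1-level)/2 and
#' 1-(1-level)/2. Replicate vectors dominated by zeros legitimately yield a
#' lower bound of exactly 0.
#'
#' @param replicates numeric vector (length >= 2).
#' @param level confidence level in (0, 1).
#' @return named numeric vector \code{c(low, high)}.
#' @export
percentile_ci <- function(replicates, level = 0.95) {
  n <- length(replicates)
  if (n == 0) stop("empty replicate vector")
  if (n < 2) stop("need at least 2 replicates")
  a <- (1 - level) / 2
  s <- sort(replicates)
  # fuzz keeps n * p at integer values from rounding up (as quantile type 1)
  k <- function(p) min(n, max(1, ceiling(n * p - 1e-9)))
  c(low = s[k(a)], high = s[k(1 - a)])
}

#' Bootstrap trap-count rate summaries by stratum
#'
#' Resamples trapping events with replacement within each fig-species by
#' tree-type stratum, preserving stratum sizes, and summarizes each replicate
#' as total Pegoscapus captures per 24 trap-hours (sum of counts / sum of
#' exposure days). With \code{rates = FALSE} the summary is the raw total
#' count instead.
#'
#' @param events trapping-event data.frame.
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @param unit \code{"event"} (default) or \code{"tree"}: the exchangeable
#'   resampling unit within each stratum.
#' @param rates summarize as per-day rates (default) or raw totals.
#' @return list with \code{reps} (B x strata matrix of summaries),
#'   \code{observed} (named vector), and \code{strata} (data.frame with
#'   \code{fig_species}, \code{tree_type}, \code{n_events}).
#' @export
bootstrap_counts <- function(events, B, seed = 1, unit = c("event", "tree"),
                             rates = TRUE) {
  if (B < 1) stop("B must be >= 1")
  unit <- match.arg(unit)
  if (nrow(events) == 0) stop("no trapping events")
  set.seed(seed)
  key <- interaction(events$fig_species, events$tree_type, drop = TRUE,
                     sep = "||")
  strata <- levels(key)
  reps <- matrix(0, B, length(strata), dimnames = list(NULL, strata))
  obs <- numeric(length(strata))
  info <- list()
  for (si in seq_along(strata)) {
    sub <- events[key == strata[si], , drop = FALSE]
    cnt <- sub$count_pegoscapus
    day <- sub$exposure_days
    obs[si] <- if (rates) sum(cnt) / sum(day) else sum(cnt)
    if (unit == "event") {
      m <- nrow(sub)
      idx <- matrix(sample.int(m, m * B, replace = TRUE), m, B)
      tot_c <- colSums(matrix(cnt[idx], m, B))
      tot_d <- colSums(matrix(day[idx], m, B))
    } else {
      trees <- unique(sub$tree_id)
      tmat <- matrix(sample(trees, length(trees) * B, replace = TRUE),
                     length(trees), B)
      c_by_tree <- tapply(cnt, sub$tree_id, sum)
      d_by_tree <- tapply(day, sub$tree_id, sum)
      tot_c <- colSums(matrix(c_by_tree[tmat], nrow(tmat), B))
      tot_d <- colSums(matrix(d_by_tree[tmat], nrow(tmat), B))
    }
    reps[, si] <- if (rates) tot_c / tot_d else tot_c
    info[[si]] <- data.frame(
      fig_species = sub$fig_species[1], tree_type = sub$tree_type[1],
      n_events = nrow(sub), stringsAsFactors = FALSE)
  }
  names(obs) <- strata
  list(reps = reps, observed = obs, strata = do.call(rbind, info), B = B,
       rates = rates)
}

#' Bootstrap barcode composition tables by stratum
#'
#' Resamples barcoded individuals with replacement within each fig-species by
#' tree-type stratum and records each replicate's relative species
#' frequencies (rows sum to 1).
#'
#' @param barcodes barcode data.frame with \code{host_fig_species},
#'   \code{host_tree_type} and \code{assigned_species}.
#' @param B number of replicates.
#' @param seed integer seed.
#' @param species optional character vector fixing the wasp-species
#'   dimension; defaults to the species observed.
#' @return list with \code{reps} (B x strata x species array),
#'   \code{observed} (strata x species matrix), \code{strata} data.frame and
#'   \code{n} per-stratum sample sizes.
#' @export
bootstrap_proportions <- function(barcodes, B, seed = 1, species = NULL) {
  if (B < 1) stop("B must be >= 1")
  if (nrow(barcodes) == 0) stop("no barcode records")
  set.seed(seed)
  sp <- barcodes$assigned_species
  keep <- !is.na(sp) & sp != "new sp."
  barcodes <- barcodes[keep, , drop = FALSE]
  sp <- sp[keep]
  if (is.null(species)) species <- sort(unique(sp))
  key <- interaction(barcodes$host_fig_species, barcodes$host_tree_type,
                     drop = TRUE, sep = "||")
  strata <- levels(key)
  reps <- array(0, c(B, length(strata), length(species)),
                dimnames = list(NULL, strata, species))
  obs <- matrix(0, length(strata), length(species),
                dimnames = list(strata, species))
  nn <- integer(length(strata))
  info <- list()
  for (si in seq_along(strata)) {
    in_s <- key == strata[si]
    counts <- table(factor(sp[in_s], levels = species))
    n <- sum(counts)
    nn[si] <- n
    obs[si, ] <- counts / n
    # resampling n individuals with replacement == multinomial(n, p-hat)
    draw <- stats::rmultinom(B, n, prob = counts / n)
    reps[, si, ] <- t(draw) / n
    info[[si]] <- data.frame(
      fig_species = barcodes$host_fig_species[in_s][1],
      tree_type = barcodes$host_tree_type[in_s][1],
      n_individuals = n, stringsAsFactors = FALSE)
  }
  list(reps = reps, observed = obs, strata = do.call(rbind, info), n = nn,
       B = B, species = species)
}

.categories <- c("receptive_usual", "receptive_other",
                 "vegetative_usual", "vegetative_other")

#' Combine count and composition bootstrap replicates into species-level
#' abundance estimates
#'
#' For replicate b, wasp species w and category (phase, usualness), sums
#' count_rep_b(f, phase) * prop_rep_b(f, phase, w) over the fig species f in
#' that phase whose usual-host status for w matches the category. Wasps with
#' two usual hosts aggregate over both in the "usual" categories. Cells with
#' no stratum support (no barcoded individuals in any contributing stratum)
#' are marked not estimable.
#'
#' @param count_boot result of \code{\link{bootstrap_counts}}.
#' @param prop_boot result of \code{\link{bootstrap_proportions}} (same B).
#' @param registry host registry resolving usual hosts.
#' @param level confidence level for percentile intervals.
#' @return data.frame with one row per wasp x category: \code{point} (mean of
#'   replicates), \code{ci_low}, \code{ci_high}, \code{estimable}; replicate
#'   matrices are in attribute \code{"replicates"} (list by category of
#'   B x wasp matrices).
#' @export
combine_bootstrap <- function(count_boot, prop_boot, registry, level = 0.95) {
  if (count_boot$B != prop_boot$B) stop("count and proportion replicate counts differ")
  B <- count_boot$B
  wasps <- prop_boot$species
  pstr <- prop_boot$strata
  rep_list <- list()
  support <- list()
  for (cat in .categories) {
    rep_list[[cat]] <- matrix(0, B, length(wasps),
                              dimnames = list(NULL, wasps))
    support[[cat]] <- setNames(rep(FALSE, length(wasps)), wasps)
  }
  for (si in seq_len(nrow(pstr))) {
    fig <- pstr$fig_species[si]
    phase <- pstr$tree_type[si]
    if (!phase %in% c("receptive", "vegetative")) next
    ckey <- paste(fig, phase, sep = "||")
    if (!ckey %in% colnames(count_boot$reps)) next
    cr <- count_boot$reps[, ckey]
    for (wi in seq_along(wasps)) {
      usual <- is_usual_host(registry, wasps[wi], fig)
      if (is.na(usual)) next
      cat <- paste(phase, if (usual) "usual" else "other", sep = "_")
      rep_list[[cat]][, wi] <- rep_list[[cat]][, wi] +
        cr * prop_boot$reps[, si, wi]
      support[[cat]][wi] <- TRUE
    }
  }
  out <- list()
  for (cat in .categories) {
    for (wi in seq_along(wasps)) {
      r <- rep_list[[cat]][, wi]
      estimable <- support[[cat]][wi]
      ci <- if (estimable && B >= 2) percentile_ci(r, level) else
        c(low = NA_real_, high = NA_real_)
      out[[length(out) + 1]] <- data.frame(
        wasp_species = wasps[wi], category = cat,
        point = if (estimable) mean(r) else NA_real_,
        ci_low = ci[["low"]], ci_high = ci[["high"]],
        estimable = estimable, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "replicates") <- rep_list
  res
}

#' Joint bootstrap estimator of species-level pollinator abundance
#'
#' Convenience wrapper: bootstraps trap-count rates and barcode compositions
#' with independent seeds derived from \code{seed}, pairs replicates by
#' index, and combines them into the four host categories.
#'
#' @param events trapping-event data.frame.
#' @param barcodes barcode data.frame (assigned).
#' @param registry host registry.
#' @param B replicates (default 200).
#' @param seed integer seed.
#' @param level confidence level.
#' @param exclude optional logical vector marking barcode rows to drop
#'   (sensitivity analyses).
#' @param unit resampling unit for counts, passed to
#'   \code{\link{bootstrap_counts}}.
#' @param rates use per-day rates (default) or raw totals.
#' @return as \code{\link{combine_bootstrap}}.
#' @export
abundance_bootstrap <- function(events, barcodes, registry, B = 200,
                                seed = 1, level = 0.95, exclude = NULL,
                                unit = "event", rates = TRUE) {
  if (!is.null(exclude)) barcodes <- barcodes[!exclude, , drop = FALSE]
  cb <- bootstrap_counts(events, B, seed = seed, unit = unit, rates = rates)
  pb <- bootstrap_proportions(barcodes, B, seed = seed + 500009L)
  combine_bootstrap(cb, pb, registry, level = level)
}
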