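#' True species-level abundance per wasp and host category under the
#' generator
#'
#' The estimand targeted by the joint bootstrap: for each wasp species and
#' category, the sum over the contributing fig-by-phase strata of the
#' stratum's true per-day capture rate (realized conditional expectation
#' given the drawn random effects, sum((1 - p) lambda) / sum(days)) times the
#' stratum's true species composition probability.
#'
#' @param sim result of \code{\link{simulate_trapping}}.
#' @param registry host registry used for the barcodes.
#' @param config \code{\link{sim_config}}.
#' @return data.frame wasp_species x category with column \code{truth}.
#' @export
true_category_abundance <- function(sim, registry, config) {
  ev <- sim$events
  mu <- sim$truth$mu
  fic <- ev$tree_type != "non_ficus"
  key <- interaction(ev$fig_species[fic], ev$tree_type[fic], drop = TRUE,
                     sep = "||")
  rate <- tapply(mu[fic], key, sum) / tapply(ev$exposure_days[fic], key, sum)
  wasps <- names(registry)
  out <- expand.grid(wasp_species = wasps, category = .categories,
                     stringsAsFactors = FALSE)
  out$truth <- 0
  for (k in names(rate)) {
    parts <- strsplit(k, "||", fixed = TRUE)[[1]]
    fig <- parts[1]
    phase <- parts[2]
    probs <- barcode_truth_probs(fig, phase, registry, config)
    for (w in wasps) {
      usual <- is_usual_host(registry, w, fig)
      cat <- paste(phase, if (usual) "usual" else "other", sep = "_")
      i <- out$wasp_species == w & out$category == cat
      out$truth[i] <- out$truth[i] + rate[[k]] * probs[[w]]
    }
  }
  out
}

#' Empirical coverage of the joint-bootstrap percentile intervals
#'
#' Repeatedly simulates the synthetic design with known truth, runs the
#' two-stream bootstrap, and records for every estimable wasp-by-category
#' cell whether the percentile interval covers the true abundance.
#'
#' @param n_reps number of outer replications.
#' @param config \code{\link{sim_config}}; the default drops the non-Ficus
#'   arm (the estimator only uses fig strata).
#' @param B bootstrap replicates per run (default 200).
#' @param seed base seed; run r uses seed + r.
#' @param level nominal coverage.
#' @return list with \code{coverage} (percent), \code{n_cells},
#'   \code{by_category} (percent per category).
#' @export
bootstrap_coverage_study <- function(n_reps = 500,
                                     config = sim_config(n_nonficus_trees = 0),
                                     B = 200, seed = 1, level = 0.95) {
  registry <- synthetic_registry(config$n_fig_species)
  hits <- list()
  for (r in seq_len(n_reps)) {
    s <- seed + r
    sim <- simulate_trapping(config, seed = s)
    bar <- simulate_barcodes(sim$events, config, registry, seed = s)
    est <- abundance_bootstrap(sim$events, bar, registry, B = B, seed = s,
                               level = level)
    truth <- true_category_abundance(sim, registry, config)
    m <- merge(est, truth, by = c("wasp_species", "category"))
    m <- m[m$estimable, , drop = FALSE]
    hits[[r]] <- data.frame(
      category = m$category,
      covered = m$ci_low <= m$truth & m$truth <= m$ci_high)
  }
  all <- do.call(rbind, hits)
  list(coverage = 100 * mean(all$covered), n_cells = nrow(all),
       by_category = 100 * tapply(all$covered, all$category, mean))
}
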