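#' Configuration for the synthetic trapping / barcoding generator
#'
#' Defaults encode the study conditions the analysis assumes. Marginal
#' per-tree-day capture rates are calibrated to the field totals
#' (7580 wasps / 150 trap-days at receptive trees, 580 / 1198 at vegetative
#' trees, 4 / 287 at non-Ficus controls) and split between a structural-zero
#' probability and a conditional Poisson rate; most of the non-Ficus deficit
#' is placed in the structural-zero part, since captures at non-fig trees are
#' accidental strays. Specificity defaults are the observed fractions of
#' barcoded individuals on their usual host (284/316 receptive,
#' 138/215 vegetative).
#'
#' @param n_fig_species number of fig species (each with one associated wasp
#'   species in the default synthetic registry).
#' @param trees_per_species trees per fig species.
#' @param events_per_tree named vector: trapping events per tree for the
#'   \code{receptive} and \code{vegetative} phases.
#' @param n_nonficus_trees,events_per_nonficus_tree non-Ficus control design.
#' @param p_zero named per-tree-type structural-zero probabilities.
#' @param log_rate named per-tree-type log conditional rates (captures per
#'   trap-day, log scale).
#' @param sigma_species,sigma_date SDs of the conditional-model random
#'   effects for fig species and trapping date (log scale).
#' @param sigma_zi_species SD of an optional fig-species random effect in the
#'   zero-inflation part (0 = off, the default, for identifiability at small n).
#' @param exposure_probs sampling distribution of exposure days over 1..6.
#' @param n_dates size of the pool of trapping dates.
#' @param s_receptive,s_vegetative probability that a trapped individual
#'   belongs to a usual-host pollinator species of its tree, by phase.
#' @param barcode_per_tree_phase barcode subsample size per tree and phase.
#' @param seq_length COI fragment length (nt).
#' @param d_inter,d_intra expected inter- and intraspecific per-site
#'   divergence of simulated COI sequences (must satisfy
#'   \code{d_intra < d_inter}).
#' @param titv transition:transversion bias of the mutation model.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_fig_species = 5,
                       trees_per_species = 2,
                       events_per_tree = c(receptive = 25, vegetative = 25),
                       n_nonficus_trees = 3,
                       events_per_nonficus_tree = 4,
                       p_zero = c(receptive = 0.25, vegetative = 0.70,
                                  non_ficus = 0.95),
                       log_rate = log(c(receptive = (7580 / 150) / 0.75,
                                        vegetative = (580 / 1198) / 0.30,
                                        non_ficus = (4 / 287) / 0.05)),
                       sigma_species = 0.5,
                       sigma_date = 0.5,
                       sigma_zi_species = 0,
                       exposure_probs = c(0.40, 0.30, 0.15, 0.08, 0.05, 0.02),
                       n_dates = 40,
                       s_receptive = 284 / 316,
                       s_vegetative = 138 / 215,
                       barcode_per_tree_phase = 20,
                       seq_length = 503,
                       d_inter = 0.10,
                       d_intra = 0.005,
                       titv = 4) {
  stopifnot(all(p_zero >= 0 & p_zero <= 1),
            sigma_species >= 0, sigma_date >= 0, sigma_zi_species >= 0,
            s_receptive >= 0, s_receptive <= 1,
            s_vegetative >= 0, s_vegetative <= 1)
  if (d_intra >= d_inter) {
    stop("intraspecific divergence must be below interspecific divergence")
  }
  cfg <- as.list(environment())
  if (is.list(exposure_probs)) {
    stopifnot(all(TREE_TYPES %in% names(exposure_probs)),
              all(lengths(exposure_probs) == 6))
    cfg$exposure_probs <- lapply(exposure_probs, function(p) p / sum(p))
  } else {
    stopifnot(length(exposure_probs) == 6, all(exposure_probs >= 0))
    cfg$exposure_probs <- exposure_probs / sum(exposure_probs)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Synthetic design at the scale of the field study
#'
#' Sizes match the field effort: 13 fig species with about 10 receptive and
#' 45 vegetative trapping events each, 15 non-Ficus trees with 4 events each,
#' and per-phase exposure-day distributions whose means reproduce the field
#' means (about 1.2 days at receptive trees, 2.0 at vegetative trees, 4.8 at
#' non-Ficus controls).
#'
#' @param ... overrides passed to \code{\link{sim_config}}.
#' @return \code{"sim_config"} object.
#' @export
field_scale_config <- function(...) {
  args <- list(
    n_fig_species = 13,
    trees_per_species = 3,
    events_per_tree = c(receptive = 3, vegetative = 15),
    n_nonficus_trees = 15,
    events_per_nonficus_tree = 4,
    exposure_probs = list(
      receptive = c(0.85, 0.12, 0.02, 0.01, 0, 0),
      vegetative = c(0.45, 0.30, 0.12, 0.07, 0.04, 0.02),
      non_ficus = c(0.03, 0.05, 0.08, 0.15, 0.32, 0.37)),
    n_dates = 60)
  do.call(sim_config, modifyList(args, list(...)))
}

.fig_names <- function(k) sprintf("F. synthetica %02d", seq_len(k))
.wasp_names <- function(k) sprintf("P. syntheticus %02d", seq_len(k))

#' One-to-one synthetic host-association registry
#'
#' Wasp species i is the usual pollinator of fig species i.
#'
#' @param n_fig_species number of fig (= wasp) species.
#' @return \code{"host_registry"} object.
#' @export
synthetic_registry <- function(n_fig_species) {
  make_registry(setNames(as.list(.fig_names(n_fig_species)),
                         .wasp_names(n_fig_species)))
}

#' Simulate a trapping-event table with known truth
#'
#' Counts follow a zero-inflated Poisson: with probability
#' \code{p_zero[type]} the event is a structural zero; otherwise the count is
#' Poisson with log mean \code{log_rate[type] + b_species + b_date +
#' log(exposure_days)}. Random effects are normal with the configured SDs.
#'
#' @param config \code{\link{sim_config}} object.
#' @param seed integer seed; identical seeds give identical tables.
#' @return list with \code{events} (trapping-event data.frame, including a
#'   \code{date_start} grouping label) and \code{truth} (drawn random effects
#'   and per-event \code{lambda}, \code{p_zero}, structural-zero indicator and
#'   conditional expectation \code{mu = (1 - p) * lambda}).
#' @export
simulate_trapping <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  figs <- .fig_names(config$n_fig_species)
  b_species <- setNames(rnorm(length(figs), 0, config$sigma_species), figs)
  dates <- sprintf("d%03d", seq_len(config$n_dates))
  b_date <- setNames(rnorm(length(dates), 0, config$sigma_date), dates)
  u_species <- setNames(rnorm(length(figs), 0, config$sigma_zi_species), figs)

  rows <- list()
  for (f in figs) {
    for (tr in seq_len(config$trees_per_species)) {
      tree <- sprintf("%s tree%02d", f, tr)
      for (ph in c("receptive", "vegetative")) {
        n_ev <- config$events_per_tree[[ph]]
        if (n_ev > 0) {
          rows[[length(rows) + 1]] <- data.frame(
            tree_id = tree, fig_species = f, tree_type = ph,
            n = n_ev, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (config$n_nonficus_trees > 0 && config$events_per_nonficus_tree > 0) {
    for (tr in seq_len(config$n_nonficus_trees)) {
      rows[[length(rows) + 1]] <- data.frame(
        tree_id = sprintf("nonficus tree%02d", tr), fig_species = NON_FICUS,
        tree_type = "non_ficus", n = config$events_per_nonficus_tree,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    ev <- data.frame(event_id = character(), tree_id = character(),
                     fig_species = character(), tree_type = character(),
                     date_start = character(), exposure_days = numeric(),
                     n_traps = integer(), count_pegoscapus = integer(),
                     count_tetrapus = integer())
    return(list(events = ev, truth = list(config = config)))
  }
  plan <- do.call(rbind, rows)
  ev <- plan[rep(seq_len(nrow(plan)), plan$n), c("tree_id", "fig_species",
                                                 "tree_type")]
  n <- nrow(ev)
  ev$event_id <- sprintf("ev%05d", seq_len(n))
  ev$date_start <- sample(dates, n, replace = TRUE)
  if (is.list(config$exposure_probs)) {
    ev$exposure_days <- NA_real_
    for (tt in unique(ev$tree_type)) {
      i <- ev$tree_type == tt
      ev$exposure_days[i] <- sample(1:6, sum(i), replace = TRUE,
                                    prob = config$exposure_probs[[tt]])
    }
  } else {
    ev$exposure_days <- sample(1:6, n, replace = TRUE,
                               prob = config$exposure_probs)
  }
  ev$n_traps <- 4L

  bs <- ifelse(ev$fig_species == NON_FICUS, 0, b_species[ev$fig_species])
  bd <- b_date[ev$date_start]
  eta <- config$log_rate[ev$tree_type] + bs + bd + log(ev$exposure_days)
  lambda <- exp(eta)
  us <- ifelse(ev$fig_species == NON_FICUS, 0, u_species[ev$fig_species])
  p <- plogis(qlogis(config$p_zero[ev$tree_type]) + us)
  structural <- runif(n) < p
  ev$count_pegoscapus <- ifelse(structural, 0L, rpois(n, lambda))
  ev$count_tetrapus <- NA_integer_
  ev <- ev[, c("event_id", "tree_id", "fig_species", "tree_type",
               "date_start", "exposure_days", "n_traps",
               "count_pegoscapus", "count_tetrapus")]
  rownames(ev) <- NULL
  list(events = validate_trapping_events(ev),
       truth = list(b_species = b_species, b_date = b_date,
                    u_species = u_species, lambda = unname(lambda),
                    p_zero = unname(p), structural = structural,
                    mu = unname((1 - p) * lambda), config = config))
}

#' Species sampling probabilities for barcoded individuals in one stratum
#'
#' With probability \code{s_phase} an individual belongs to one of the usual
#' pollinator species of the stratum's fig (uniform among them when the fig
#' has several); otherwise it is uniform over the remaining wasp species.
#'
#' @param fig fig species of the stratum.
#' @param phase \code{"receptive"} or \code{"vegetative"}.
#' @param registry host registry.
#' @param config \code{\link{sim_config}}.
#' @return named probability vector over all wasp species in the registry.
#' @export
barcode_truth_probs <- function(fig, phase, registry, config) {
  wasps <- names(registry)
  usual <- vapply(wasps, function(w) fig %in% registry[[w]], logical(1))
  if (!any(usual)) stop("no usual-host pollinator in registry for ", fig)
  s <- if (phase == "receptive") config$s_receptive else config$s_vegetative
  p <- numeric(length(wasps))
  p[usual] <- s / sum(usual)
  if (any(!usual)) p[!usual] <- (1 - s) / sum(!usual)
  setNames(p / sum(p), wasps)
}

#' Simulate barcoded individuals for a trapping-event table
#'
#' For each Ficus tree-by-phase combination with a positive total count, up
#' to \code{barcode_per_tree_phase} individuals are sampled; each individual's
#' true species is drawn from \code{\link{barcode_truth_probs}} for its
#' stratum.
#'
#' @param events trapping-event data.frame.
#' @param config \code{\link{sim_config}}.
#' @param registry host registry; default is the one-to-one synthetic
#'   registry matching \code{config$n_fig_species}.
#' @param seed integer seed.
#' @return data.frame of barcode records: \code{individual_id},
#'   \code{tree_id}, \code{host_fig_species}, \code{host_tree_type},
#'   \code{true_species}; \code{assigned_species} is initialized to the true
#'   species (sequence-based assignment can overwrite it).
#' @export
simulate_barcodes <- function(events, config = sim_config(),
                              registry = synthetic_registry(config$n_fig_species),
                              seed = 1) {
  set.seed(seed + 1000003L)
  fic <- events[events$tree_type != "non_ficus", , drop = FALSE]
  out <- list()
  if (nrow(fic) > 0) {
    key <- interaction(fic$tree_id, fic$tree_type, drop = TRUE)
    for (k in levels(key)) {
      sub <- fic[key == k, , drop = FALSE]
      total <- sum(sub$count_pegoscapus)
      n_bar <- min(config$barcode_per_tree_phase, total)
      if (n_bar < 1) next
      probs <- barcode_truth_probs(sub$fig_species[1], sub$tree_type[1],
                                   registry, config)
      sp <- sample(names(probs), n_bar, replace = TRUE, prob = probs)
      out[[length(out) + 1]] <- data.frame(
        tree_id = sub$tree_id[1],
        host_fig_species = sub$fig_species[1],
        host_tree_type = sub$tree_type[1],
        true_species = sp, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(individual_id = character(), tree_id = character(),
                      host_fig_species = character(),
                      host_tree_type = character(),
                      true_species = character(),
                      assigned_species = character(),
                      stringsAsFactors = FALSE))
  }
  bar <- do.call(rbind, out)
  bar$individual_id <- sprintf("ind%05d", seq_len(nrow(bar)))
  bar$assigned_species <- bar$true_species
  rownames(bar) <- NULL
  bar[, c("individual_id", "tree_id", "host_fig_species", "host_tree_type",
          "true_species", "assigned_species")]
}

#' Simulate COI reference and query sequences
#'
#' References descend from a common ancestral coding sequence, each mutated
#' at half the interspecific divergence so that pairwise reference divergence
#' is approximately \code{d_inter}; queries mutate their species reference at
#' the intraspecific rate. Mutations use a transition:transversion bias and
#' never introduce internal stop codons in reading frame 0 under the
#' invertebrate mitochondrial code.
#'
#' @param species character vector of species names needing references.
#' @param config \code{\link{sim_config}}.
#' @param seed integer seed.
#' @param queries_for optional character vector of species (one entry per
#'   query individual, names used as sequence ids) for which query sequences
#'   are generated.
#' @return list with \code{references} (named character vector) and
#'   \code{queries} (named character vector, possibly empty).
#' @export
simulate_sequences <- function(species, config = sim_config(), seed = 1,
                               queries_for = NULL) {
  if (config$seq_length < 60) stop("seq_length must be at least 60")
  if (config$d_intra >= config$d_inter) {
    stop("intraspecific divergence must be below interspecific divergence")
  }
  set.seed(seed + 2000003L)
  n_codon <- ceiling(config$seq_length / 3)
  sense <- names(.mito_code)[.mito_code != "*"]
  ancestor <- paste(sample(sense, n_codon, replace = TRUE), collapse = "")
  ancestor <- substr(ancestor, 1, config$seq_length)
  refs <- vapply(species, function(s) {
    .mutate_seq(ancestor, config$d_inter / 2, config$titv)
  }, character(1))
  queries <- character(0)
  if (!is.null(queries_for)) {
    unknown <- setdiff(unique(queries_for), species)
    if (length(unknown) > 0) {
      stop("no reference for species: ", paste(unknown, collapse = ", "))
    }
    queries <- vapply(queries_for, function(s) {
      .mutate_seq(refs[[s]], config$d_intra, config$titv)
    }, character(1))
    if (is.null(names(queries_for))) {
      names(queries) <- sprintf("q%05d", seq_along(queries))
    } else {
      names(queries) <- names(queries_for)
    }
  }
  list(references = refs, queries = queries)
}
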