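#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rpois rbinom runif optim nlminb quantile pnorm qnorm
#'   pchisq glm poisson binomial coef dpois plogis qlogis sd aggregate
#'   model.matrix as.formula setNames optimHess complete.cases ptukey qtukey
#' @importFrom utils read.csv write.csv head modifyList combn
#' @importFrom stats glm.fit logLik AIC vcov lchoose
#'   delete.response terms model.frame model.response
NULL

TREE_TYPES <- c("receptive", "vegetative", "non_ficus")
NON_FICUS <- "NON_FICUS"

.event_cols_mandatory <- c("event_id", "tree_id", "fig_species", "tree_type",
                           "date_start", "exposure_days", "count_pegoscapus")
.event_cols_optional <- c("n_traps", "count_tetrapus")

#' Validate a table of trapping events
#'
#' Checks the invariants of a trapping-event table: mandatory columns present,
#' tree types among \code{receptive}, \code{vegetative}, \code{non_ficus},
#' non-negative integer counts, strictly positive exposure, and the sentinel
#' rule that non-Ficus events carry fig species \code{"NON_FICUS"}.
#' Exposures outside the 1--6 day design range are flagged with a warning,
#' not an error.
#'
#' @param events data.frame of trapping events.
#' @return The validated data.frame (invisibly usable), with \code{n_traps}
#'   defaulted to 4 and \code{count_tetrapus} to \code{NA} when absent.
#' @export
validate_trapping_events <- function(events) {
  missing <- setdiff(.event_cols_mandatory, names(events))
  if (length(missing) > 0) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  if (!"n_traps" %in% names(events)) events$n_traps <- 4L
  if (!"count_tetrapus" %in% names(events)) events$count_tetrapus <- NA_integer_
  bad_type <- !events$tree_type %in% TREE_TYPES
  if (any(bad_type)) {
    stop("invalid tree_type in row(s): ",
         paste(which(bad_type), collapse = ", "))
  }
  events$exposure_days <- as.numeric(events$exposure_days)
  events$count_pegoscapus <- as.integer(events$count_pegoscapus)
  neg <- !is.na(events$count_pegoscapus) & events$count_pegoscapus < 0
  if (any(neg)) {
    stop("negative count_pegoscapus in row(s): ",
         paste(which(neg), collapse = ", "))
  }
  bad_exp <- !is.finite(events$exposure_days) | events$exposure_days <= 0
  if (any(bad_exp)) {
    stop("non-positive exposure_days in row(s): ",
         paste(which(bad_exp), collapse = ", "))
  }
  nf <- events$tree_type == "non_ficus"
  if (any(nf & events$fig_species != NON_FICUS)) {
    stop("non_ficus events must have fig_species '", NON_FICUS,
         "': row(s) ", paste(which(nf & events$fig_species != NON_FICUS),
                             collapse = ", "))
  }
  if (any(!nf & events$fig_species == NON_FICUS)) {
    stop("Ficus events may not use the ", NON_FICUS, " sentinel: row(s) ",
         paste(which(!nf & events$fig_species == NON_FICUS), collapse = ", "))
  }
  out_range <- events$exposure_days < 1 | events$exposure_days > 6
  if (any(out_range)) {
    warning(sum(out_range), " event(s) with exposure outside the 1-6 day ",
            "design range (row(s) ",
            paste(head(which(out_range), 10), collapse = ", "), ")")
  }
  events
}

#' Read trapping events from CSV
#'
#' One row per trapping event (a set of pooled sticky traps exposed at one
#' tree for \code{exposure_days} days). Validation is as in
#' \code{\link{validate_trapping_events}}; malformed rows are reported with
#' their row numbers.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @return data.frame of validated trapping events.
#' @export
read_trapping_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  events <- read.csv(path, stringsAsFactors = FALSE)
  validate_trapping_events(events)
}

#' Write trapping events to CSV
#'
#' @param events validated trapping-event data.frame.
#' @param path output path.
#' @export
write_trapping_events <- function(events, path) {
  write.csv(events, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Pollinators trapped per 24 h
#'
#' Normalizes each event's pooled Pegoscapus count to a per-24-hour capture
#' rate, count / exposure_days.
#'
#' @param events trapping-event data.frame (or any data.frame with
#'   \code{count_pegoscapus} and \code{exposure_days}).
#' @return numeric vector of rates per day.
#' @export
rate_per_24h <- function(events) {
  if (any(events$exposure_days <= 0)) stop("exposure_days must be positive")
  events$count_pegoscapus / events$exposure_days
}

#' Classify daily receptivity of one tree from syconium inspections
#'
#' A tree is receptive on an inspection date when living pollinators were seen
#' inside at least one sampled syconium, or when the number of syconia with
#' dead pollinators inside increased relative to the immediately preceding
#' inspection. The first inspection can only be called receptive through
#' living pollinators (there is no previous count to compare).
#'
#' @param inspections data.frame with columns \code{date} (sortable, unique),
#'   \code{n_sampled}, \code{n_with_living_pollinators},
#'   \code{n_with_dead_pollinators}, all for a single tree, ordered by date.
#' @return the input with a logical column \code{receptive} appended.
#' @export
classify_receptivity <- function(inspections) {
  d <- inspections$date
  if (anyDuplicated(d)) stop("inspection dates must be unique per tree")
  if (is.unsorted(order(d)) || any(order(d) != seq_along(d))) {
    stop("inspections must be sorted by date")
  }
  living <- inspections$n_with_living_pollinators
  dead <- inspections$n_with_dead_pollinators
  if (any(living > inspections$n_sampled | dead > inspections$n_sampled |
          living < 0 | dead < 0)) {
    stop("inspection counts must lie in [0, n_sampled]")
  }
  increased <- c(FALSE, diff(dead) > 0)
  inspections$receptive <- living >= 1 | increased
  inspections
}

#' Load the wasp-to-host association registry
#'
#' Returns the registry of which Urostigma fig species each Pegoscapus
#' pollinator species is routinely reared from. The shipped default
#' transcribes the published association table for the Panama Canal
#' community; \code{which = "current"} includes the recently observed
#' associations (P. insularis on two hosts, P. 'ex paraensis'), while
#' \code{which = "historical"} restricts to the associations known from
#' older surveys.
#'
#' @param which \code{"current"} (default) or \code{"historical"}.
#' @param path optional path to a registry CSV with columns
#'   \code{wasp_species}, \code{fig_species}, \code{shared}, \code{trend},
#'   \code{registry} (\code{both}/\code{current}/\code{historical}).
#' @return object of class \code{"host_registry"}: a named list mapping wasp
#'   species to character vectors of usual host fig species, with the raw
#'   table in attribute \code{"table"}.
#' @export
host_registry <- function(which = c("current", "historical"), path = NULL) {
  which <- match.arg(which)
  if (is.null(path)) {
    path <- system.file("extdata", "host_associations.csv", package = "figwasp")
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  keep <- tab$registry %in% c("both", which)
  tab <- tab[keep, , drop = FALSE]
  mapping <- split(tab$fig_species, tab$wasp_species)
  if (any(lengths(mapping) < 1)) stop("registry: wasp with no usual host")
  structure(mapping, class = "host_registry", table = tab)
}

#' Build a registry from an explicit wasp-to-fig mapping
#'
#' @param mapping named list: wasp species -> character vector of usual hosts.
#' @return \code{"host_registry"} object.
#' @export
make_registry <- function(mapping) {
  if (is.null(names(mapping)) || any(names(mapping) == "")) {
    stop("mapping must be a named list (wasp species names)")
  }
  if (any(lengths(mapping) < 1)) stop("every wasp must map to >= 1 fig species")
  structure(mapping, class = "host_registry")
}

#' Is a fig species a usual host of a wasp species?
#'
#' @param registry \code{"host_registry"} object.
#' @param wasp wasp species label(s).
#' @param fig fig species label(s), recycled against \code{wasp}.
#' @return logical vector; \code{NA} for wasp species absent from the registry
#'   (unknown, as distinct from a known non-association).
#' @export
is_usual_host <- function(registry, wasp, fig) {
  n <- max(length(wasp), length(fig))
  wasp <- rep_len(wasp, n)
  fig <- rep_len(fig, n)
  known <- wasp %in% names(registry)
  out <- rep(NA, n)
  out[known] <- mapply(function(w, f) f %in% registry[[w]],
                       wasp[known], fig[known], USE.NAMES = FALSE)
  out
}

#' Read a per-species trapping and barcoding summary table
#'
#' Reads a summary table with one row per fig species giving numbers of
#' sampled trees, trapping events and barcoded (identified) individuals for
#' the receptive and vegetative phases. The shipped fixture
#' \code{table2_trapping_summary.csv} transcribes the published field-effort
#' table for the Panama community.
#'
#' @param path CSV path; default loads the shipped fixture.
#' @return data.frame.
#' @export
read_trapping_summary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2_trapping_summary.csv",
                        package = "figwasp")
  }
  need <- c("fig_species", "trees_receptive", "trees_vegetative",
            "events_receptive", "events_vegetative",
            "identified_receptive", "identified_vegetative")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("summary table missing column(s): ", paste(missing, collapse = ", "))
  }
  tab
}
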