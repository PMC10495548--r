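# Shared fixtures built in code.

# small valid trapping-event table
make_events <- function(n = 6) {
  data.frame(
    event_id = sprintf("e%02d", seq_len(n)),
    tree_id = rep(c("t1", "t2"), length.out = n),
    fig_species = rep(c("F. bullenei", "F. citrifolia"), length.out = n),
    tree_type = rep(c("receptive", "vegetative"), length.out = n),
    date_start = rep(c("2021-01-01", "2021-01-02"), length.out = n),
    exposure_days = rep(c(1, 2, 3), length.out = n),
    n_traps = 4L,
    count_pegoscapus = seq_len(n),
    count_tetrapus = NA_integer_,
    stringsAsFactors = FALSE)
}

# random event table for round-trip tests
random_events <- function(n, seed) {
  set.seed(seed)
  types <- sample(c("receptive", "vegetative", "non_ficus"), n, replace = TRUE)
  data.frame(
    event_id = sprintf("e%03d", seq_len(n)),
    tree_id = sprintf("t%02d", sample(1:8, n, replace = TRUE)),
    fig_species = ifelse(types == "non_ficus", "NON_FICUS",
                         sample(c("F. a", "F. b", "F. c"), n, replace = TRUE)),
    tree_type = types,
    date_start = sample(c("2021-02-01", "2021-02-03", "2021-02-07"), n,
                        replace = TRUE),
    exposure_days = sample(1:6, n, replace = TRUE),
    n_traps = 4L,
    count_pegoscapus = rpois(n, 3),
    count_tetrapus = rpois(n, 0.2),
    stringsAsFactors = FALSE)
}

# deterministic ZIP sample with fixed coefficients
rzip <- function(n, lambda, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ifelse(runif(n) < p, 0L, rpois(n, lambda))
}

tree_type_levels <- c("non_ficus", "vegetative", "receptive")
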