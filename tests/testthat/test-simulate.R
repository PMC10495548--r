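test_that("trapping simulator is deterministic and honors degenerate settings", {
  cfg <- sim_config(n_fig_species = 3, trees_per_species = 1,
                    events_per_tree = c(receptive = 5, vegetative = 5),
                    n_nonficus_trees = 1, events_per_nonficus_tree = 2)
  a <- simulate_trapping(cfg, seed = 3)
  b <- simulate_trapping(cfg, seed = 3)
  expect_identical(a, b)
  c <- simulate_trapping(cfg, seed = 4)
  expect_false(identical(a$events$count_pegoscapus, c$events$count_pegoscapus))

  # all-structural-zero boundary
  cfg0 <- sim_config(p_zero = c(receptive = 1, vegetative = 1, non_ficus = 1),
                     n_fig_species = 3, trees_per_species = 1,
                     events_per_tree = c(receptive = 5, vegetative = 5))
  z <- simulate_trapping(cfg0, seed = 1)
  expect_true(all(z$events$count_pegoscapus == 0))

  # zero events requested -> empty table, no error
  e <- simulate_trapping(sim_config(n_fig_species = 0, n_nonficus_trees = 0),
                         seed = 1)
  expect_equal(nrow(e$events), 0)
})

test_that("sample mean rate converges to the conditional rate without noise", {
  # sigma = 0, p = 0: mean count/day must converge to exp(beta) (3 SE)
  beta <- log(2.5)
  cfg <- sim_config(n_fig_species = 1, trees_per_species = 1,
                    events_per_tree = c(receptive = 10000, vegetative = 0),
                    n_nonficus_trees = 0,
                    p_zero = c(receptive = 0, vegetative = 0, non_ficus = 0),
                    log_rate = c(receptive = beta, vegetative = 0,
                                 non_ficus = 0),
                    sigma_species = 0, sigma_date = 0)
  sim <- simulate_trapping(cfg, seed = 10)
  ev <- sim$events
  rate <- sum(ev$count_pegoscapus) / sum(ev$exposure_days)
  se <- sqrt(sum(ev$count_pegoscapus)) / sum(ev$exposure_days)
  expect_lt(abs(rate - exp(beta)), 3 * se)
})

test_that("simulated zero fraction matches the closed form at sigma = 0", {
  p <- 0.4
  lam <- 1.7
  cfg <- sim_config(n_fig_species = 2, trees_per_species = 1,
                    events_per_tree = c(receptive = 4000, vegetative = 0),
                    n_nonficus_trees = 0,
                    p_zero = c(receptive = p, vegetative = 0, non_ficus = 0),
                    log_rate = c(receptive = log(lam), vegetative = 0,
                                 non_ficus = 0),
                    sigma_species = 0, sigma_date = 0)
  sim <- simulate_trapping(cfg, seed = 2)
  ev <- sim$events
  expected <- mean(p + (1 - p) * exp(-lam * ev$exposure_days))
  obs <- mean(ev$count_pegoscapus == 0)
  se <- sqrt(expected * (1 - expected) / nrow(ev))
  expect_lt(abs(obs - expected), 4 * se)
})

test_that("barcode sampler respects specificity probabilities", {
  cfg <- sim_config(n_fig_species = 4, trees_per_species = 2,
                    events_per_tree = c(receptive = 10, vegetative = 40),
                    n_nonficus_trees = 0, s_receptive = 1, s_vegetative = 0.5,
                    barcode_per_tree_phase = 125)
  reg <- synthetic_registry(4)
  sim <- simulate_trapping(cfg, seed = 6)
  bar <- simulate_barcodes(sim$events, cfg, reg, seed = 6)
  usual <- is_usual_host(reg, bar$true_species, bar$host_fig_species)

  # boundary: every receptive-tree individual is a usual-host species
  expect_true(all(usual[bar$host_tree_type == "receptive"]))

  # s = 0.5 stratum fraction within binomial 99% bounds
  v <- usual[bar$host_tree_type == "vegetative"]
  expect_gt(length(v), 150)
  bounds <- qbinom(c(0.005, 0.995), length(v), 0.5) / length(v)
  expect_gte(mean(v), bounds[1])
  expect_lte(mean(v), bounds[2])

  # empty event list -> empty barcode table
  empty <- simulate_barcodes(sim$events[0, ], cfg, reg, seed = 1)
  expect_equal(nrow(empty), 0)
})

test_that("full parameter record allows reconstruction of event means", {
  cfg <- sim_config(n_fig_species = 3, trees_per_species = 1,
                    events_per_tree = c(receptive = 20, vegetative = 20),
                    n_nonficus_trees = 2, events_per_nonficus_tree = 5)
  sim <- simulate_trapping(cfg, seed = 9)
  ev <- sim$events
  tr <- sim$truth
  bs <- ifelse(ev$fig_species == "NON_FICUS", 0, tr$b_species[ev$fig_species])
  lam <- exp(cfg$log_rate[ev$tree_type] + bs + tr$b_date[ev$date_start] +
             log(ev$exposure_days))
  expect_equal(unname(lam), tr$lambda, tolerance = 1e-12)
  expect_equal(tr$mu, (1 - tr$p_zero) * tr$lambda, tolerance = 1e-12)
})
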