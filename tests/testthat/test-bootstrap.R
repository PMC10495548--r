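test_that("percentile interval uses inverse-ECDF quantiles", {
  expect_equal(percentile_ci(rep(3.5, 10)), c(low = 3.5, high = 3.5))
  expect_equal(percentile_ci(1:200, 0.95), c(low = 5, high = 195))
  # agreement with the type-1 sample quantile definition
  set.seed(161)
  for (i in 1:10) {
    x <- rexp(sample(20:300, 1))
    ci <- percentile_ci(x, 0.9)
    expect_equal(unname(ci), unname(quantile(x, c(0.05, 0.95), type = 1)))
  }
  # zero-heavy replicate vectors hit a zero lower bound
  x <- c(rep(0, 120), rexp(80))
  expect_equal(percentile_ci(x)[["low"]], 0)
  expect_error(percentile_ci(numeric(0)), "empty")
  expect_error(percentile_ci(1), "at least 2")
})

test_that("count bootstrap resamples events within strata", {
  ev <- make_events(6)
  ev1 <- ev[1, , drop = FALSE]
  b1 <- bootstrap_counts(ev1, B = 1, seed = 1)
  expect_equal(unname(b1$reps[1, 1]),
               ev1$count_pegoscapus / ev1$exposure_days)

  # identical events -> every replicate identical
  ev_id <- ev
  ev_id$count_pegoscapus <- 4L
  ev_id$exposure_days <- 2
  ev_id$fig_species <- "F. bullenei"
  ev_id$tree_type <- "receptive"
  bid <- bootstrap_counts(ev_id, B = 50, seed = 2)
  expect_true(all(bid$reps == 2))

  expect_error(bootstrap_counts(ev, B = 0), "B must be")
})

test_that("bootstrap replicate means track observed stratum rates", {
  set.seed(171)
  ev <- random_events(120, seed = 18)
  b <- bootstrap_counts(ev, B = 1000, seed = 3)
  for (si in seq_along(b$observed)) {
    reps <- b$reps[, si]
    se <- sd(reps)
    if (se > 0) {
      expect_lt(abs(mean(reps) - b$observed[si]), 3 * se)
    }
  }
})

test_that("proportion bootstrap compositions are multinomial resamples", {
  bar <- data.frame(
    individual_id = sprintf("i%02d", 1:20),
    host_fig_species = "F. a", host_tree_type = "receptive",
    assigned_species = rep(c("w1", "w2"), each = 10),
    stringsAsFactors = FALSE)
  b <- bootstrap_proportions(bar, B = 2000, seed = 4)
  # all compositions sum to one
  sums <- apply(b$reps, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # 50/50 stratum of 20: replicate proportions follow Binomial(20, 0.5)/20
  counts20 <- round(b$reps[, 1, "w1"] * 20)
  obs <- table(factor(counts20, levels = 0:20))
  expected <- dbinom(0:20, 20, 0.5) * 2000
  keep <- expected > 5
  chisq <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  p <- pchisq(chisq, sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)

  # single-species stratum is always 1
  bar1 <- bar
  bar1$assigned_species <- "w1"
  b1 <- bootstrap_proportions(bar1, B = 10, seed = 5)
  expect_true(all(b1$reps[, 1, "w1"] == 1))
})

test_that("combining streams multiplies within matched categories", {
  reg <- make_registry(list(w1 = "F. a", w2 = "F. b"))
  ev <- data.frame(event_id = "e1", tree_id = "t1", fig_species = "F. a",
                   tree_type = "receptive", date_start = "d1",
                   exposure_days = 1, n_traps = 4L, count_pegoscapus = 10L,
                   count_tetrapus = NA_integer_, stringsAsFactors = FALSE)
  bar <- data.frame(individual_id = "i1", host_fig_species = "F. a",
                    host_tree_type = "receptive", assigned_species = "w1",
                    stringsAsFactors = FALSE)
  cb <- bootstrap_counts(ev, B = 5, seed = 1)
  pb <- bootstrap_proportions(bar, B = 5, seed = 2)
  est <- combine_bootstrap(cb, pb, reg)
  ru <- est[est$wasp_species == "w1" & est$category == "receptive_usual", ]
  expect_equal(ru$point, 10)
  expect_equal(c(ru$ci_low, ru$ci_high), c(10, 10))
  # w1 never observed in an "other" stratum: no support, marked inestimable
  ro <- est[est$wasp_species == "w1" & est$category == "receptive_other", ]
  expect_false(ro$estimable)

  expect_error(combine_bootstrap(cb, bootstrap_proportions(bar, B = 4,
                                                           seed = 2), reg),
               "replicate counts differ")
})

test_that("combined replicates equal a brute-force triple sum", {
  # 3 wasps x 4 figs x 2 phases on fixed small replicate sets
  wasps <- c("w1", "w2", "w3")
  figs <- paste0("F.", 1:4)
  reg <- make_registry(list(w1 = figs[1], w2 = figs[2], w3 = figs[3:4]))
  cfg <- sim_config(n_fig_species = 4, trees_per_species = 1,
                    events_per_tree = c(receptive = 6, vegetative = 6),
                    n_nonficus_trees = 0)
  sim <- simulate_trapping(cfg, seed = 31)
  ev <- sim$events
  ev$fig_species <- figs[match(ev$fig_species,
                               sort(unique(ev$fig_species)))]
  set.seed(32)
  bar <- data.frame(
    individual_id = sprintf("i%03d", 1:160),
    host_fig_species = sample(figs, 160, TRUE),
    host_tree_type = sample(c("receptive", "vegetative"), 160, TRUE),
    assigned_species = sample(wasps, 160, TRUE), stringsAsFactors = FALSE)
  B <- 7
  cb <- bootstrap_counts(ev, B = B, seed = 41)
  pb <- bootstrap_proportions(bar, B = B, seed = 42)
  est <- combine_bootstrap(cb, pb, reg)
  reps <- attr(est, "replicates")
  for (w in wasps) {
    for (phase in c("receptive", "vegetative")) {
      for (usual in c(TRUE, FALSE)) {
        cat_name <- paste(phase, if (usual) "usual" else "other", sep = "_")
        brute <- numeric(B)
        for (b in seq_len(B)) {
          acc <- 0
          for (f in figs) {
            if (isTRUE(is_usual_host(reg, w, f)) != usual) next
            ck <- paste(f, phase, sep = "||")
            if (!ck %in% colnames(cb$reps)) next
            si <- which(pb$strata$fig_species == f &
                        pb$strata$tree_type == phase)
            if (length(si) == 0) next
            acc <- acc + cb$reps[b, ck] * pb$reps[b, si, w]
          }
          brute[b] <- acc
        }
        expect_equal(unname(reps[[cat_name]][, w]), brute, tolerance = 1e-12)
      }
    }
  }
})

test_that("usual plus other categories conserve total phase abundance", {
  cfg <- sim_config(n_nonficus_trees = 0)
  reg <- synthetic_registry(cfg$n_fig_species)
  sim <- simulate_trapping(cfg, seed = 51)
  bar <- simulate_barcodes(sim$events, cfg, reg, seed = 51)
  B <- 20
  cb <- bootstrap_counts(sim$events, B = B, seed = 52)
  pb <- bootstrap_proportions(bar, B = B, seed = 53)
  est <- combine_bootstrap(cb, pb, reg)
  reps <- attr(est, "replicates")
  for (phase in c("receptive", "vegetative")) {
    tot_wasp <- reps[[paste0(phase, "_usual")]] +
      reps[[paste0(phase, "_other")]]
    # summed over wasps: equals the summed stratum rates of that phase
    idx <- pb$strata$tree_type == phase
    expected <- numeric(B)
    for (si in which(idx)) {
      ck <- paste(pb$strata$fig_species[si], phase, sep = "||")
      expected <- expected + cb$reps[, ck]
    }
    expect_equal(unname(rowSums(tot_wasp)), expected, tolerance = 1e-10)
  }
})

test_that("the whole bootstrap stage is deterministic given a seed", {
  cfg <- sim_config(n_nonficus_trees = 0, n_fig_species = 3,
                    events_per_tree = c(receptive = 8, vegetative = 8))
  reg <- synthetic_registry(3)
  sim <- simulate_trapping(cfg, seed = 61)
  bar <- simulate_barcodes(sim$events, cfg, reg, seed = 61)
  a <- abundance_bootstrap(sim$events, bar, reg, B = 25, seed = 7)
  b <- abundance_bootstrap(sim$events, bar, reg, B = 25, seed = 7)
  expect_identical(a, b)
  c <- abundance_bootstrap(sim$events, bar, reg, B = 25, seed = 8)
  expect_false(identical(a$ci_high, c$ci_high))
})
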