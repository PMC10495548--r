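# moderate synthetic design shared across stage tests
.stage_sim <- function(seed = 301) {
  cfg <- sim_config(n_fig_species = 4, trees_per_species = 2,
                    events_per_tree = c(receptive = 8, vegetative = 20),
                    n_nonficus_trees = 6, events_per_nonficus_tree = 6)
  reg <- synthetic_registry(4)
  sim <- simulate_trapping(cfg, seed = seed)
  bar <- simulate_barcodes(sim$events, cfg, reg, seed = seed)
  list(cfg = cfg, reg = reg, sim = sim, bar = bar)
}

test_that("stage 1 ranks the ladder and reports tree-type contrasts", {
  s <- .stage_sim()
  rep1 <- run_stage1_treetype(s$sim$events,
                              ladder = c("zipm_nodate", "zip_glm", "pois_glm"))
  expect_equal(rep1$status, "ok")
  expect_true(all(c("model", "AIC", "dAIC") %in% names(rep1$aic)))
  expect_equal(rep1$aic$dAIC[1], 0)
  expect_equal(nrow(rep1$contrasts_cond), 3)
  # the zero-inflation-aware models beat the plain Poisson on ZIP data
  expect_true(rep1$aic$model[1] != "pois_glm")
  mr <- marginal_rates(rep1$fits[[rep1$best]])
  expect_equal(sort(mr$tree_type), sort(tree_type_levels))
  expect_true(all(mr$marginal >= 0))
})

test_that("stage 1 degenerates gracefully with a single tree type", {
  s <- .stage_sim()
  ev <- s$sim$events
  ev <- ev[ev$tree_type == "vegetative", ]
  rep1 <- run_stage1_treetype(ev, ladder = c("zip_glm", "pois_glm"))
  expect_equal(rep1$status, "ok")
  expect_equal(nrow(rep1$contrasts_cond), 0)
  expect_length(rep1$wald, 0)
})

test_that("stage 1 reports are deterministic", {
  s <- .stage_sim()
  a <- run_stage1_treetype(s$sim$events, ladder = c("zip_glm", "pois_glm"))
  b <- run_stage1_treetype(s$sim$events, ladder = c("zip_glm", "pois_glm"))
  expect_identical(a$aic, b$aic)
  expect_identical(a$contrasts_cond, b$contrasts_cond)
})

test_that("focal-species selection requires both phases with multi-capture events", {
  ev <- rbind(
    data.frame(event_id = c("a1", "a2"), tree_id = "t1",
               fig_species = "F. good", tree_type = c("receptive", "vegetative"),
               date_start = "d1", exposure_days = 2, n_traps = 4L,
               count_pegoscapus = c(5L, 3L), count_tetrapus = NA_integer_),
    # only single captures in the vegetative phase: excluded
    data.frame(event_id = c("b1", "b2"), tree_id = "t2",
               fig_species = "F. single", tree_type = c("receptive", "vegetative"),
               date_start = "d1", exposure_days = 2, n_traps = 4L,
               count_pegoscapus = c(4L, 1L), count_tetrapus = NA_integer_),
    # missing the receptive phase entirely: excluded
    data.frame(event_id = "c1", tree_id = "t3",
               fig_species = "F. vegonly", tree_type = "vegetative",
               date_start = "d1", exposure_days = 2, n_traps = 4L,
               count_pegoscapus = 7L, count_tetrapus = NA_integer_))
  expect_equal(select_focal_species(ev), "F. good")
})

test_that("stage 2 per-species intervals match direct fits", {
  s <- .stage_sim()
  out <- run_stage2_perspecies(s$sim$events)
  expect_true(length(out$species) >= 1)
  f <- out$species[1]
  sub <- rbind(s$sim$events[s$sim$events$fig_species == f, ],
               s$sim$events[s$sim$events$tree_type == "non_ficus", ])
  sub$tree_type <- factor(sub$tree_type, levels = tree_type_levels)
  direct <- fit_zip_glm(count_pegoscapus ~ tree_type, ~tree_type, sub,
                        offset = log(sub$exposure_days))
  tk <- tukey_pairwise(direct, "tree_type", "cond")
  ci <- out$ci[out$ci$fig_species == f & out$ci$part == "cond", ]
  m <- match(tk$contrast, ci$contrast)
  expect_equal(ci$estimate[m], tk$estimate, tolerance = 1e-8)
  expect_equal(ci$lower[m], tk$lower, tolerance = 1e-6)

  # empty selection: empty report, no error
  ev_nf <- s$sim$events[s$sim$events$tree_type == "non_ficus", ]
  empty <- run_stage2_perspecies(ev_nf)
  expect_length(empty$species, 0)
  expect_equal(nrow(empty$ci), 0)
})

test_that("stage 3 builds usual-host indicators through the registry", {
  reg <- host_registry("current")
  bar <- data.frame(
    individual_id = c("i1", "i2", "i3", "i4"),
    host_fig_species = c("F. bullenei", "F. popenoei", "F. bullenei",
                         "F. citrifolia"),
    host_tree_type = c("receptive", "receptive", "vegetative", "vegetative"),
    assigned_species = c("P. gemellus A", "P. gemellus A", "P. tonduzi",
                         "P. tonduzi"),
    stringsAsFactors = FALSE)
  out <- run_stage3_specificity(bar, reg)
  # shared-host pollinator counts as usual on both of its hosts
  d <- out$data
  expect_equal(d$success[1:2], c(1L, 1L))
  expect_equal(d$success[3:4], c(0L, 1L))
})

test_that("stage 3 detects a specificity difference between phases", {
  s <- .stage_sim()
  out <- run_stage3_specificity(s$bar, s$reg)
  expect_equal(out$lrt_tree_type$df, 1)
  expect_lt(out$lrt_tree_type$p, 0.05)
  expect_gt(out$ci$estimate, 0)      # receptive above vegetative
  expect_gt(out$p_usual[["receptive"]], out$p_usual[["vegetative"]])
  expect_equal(out$lrt_host$df,
               nlevels(out$data$host_fig_species) - 1)
})

test_that("stage 4 emits the category-by-species interval grid", {
  s <- .stage_sim()
  out <- run_stage4_bootstrap(s$sim$events, s$bar, s$reg, B = 50, seed = 5)
  expect_equal(dim(out$grid), c(4, 4))
  expect_true(all(rownames(out$grid) == c("receptive_usual", "receptive_other",
                                          "vegetative_usual",
                                          "vegetative_other")))
  expect_warning(run_stage4_bootstrap(s$sim$events, s$bar, s$reg, B = 1,
                                      seed = 5), "degenerate")
  # qualitative ordering: receptive usual dominates the other categories
  est <- out$estimates
  for (w in unique(est$wasp_species)) {
    ru <- est[est$wasp_species == w & est$category == "receptive_usual", ]
    vo <- est[est$wasp_species == w & est$category == "vegetative_other", ]
    if (ru$estimable && vo$estimable) {
      expect_gt(ru$point, vo$point)
    }
  }
})
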