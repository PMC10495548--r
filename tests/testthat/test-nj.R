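# path-length matrix of a tree from its newick string, via ape
.tree_dists <- function(nwk, labels) {
  tr <- ape::read.tree(text = nwk)
  as.matrix(ape::cophenetic.phylo(tr))[labels, labels]
}

test_that("neighbor joining recovers additive four-taxon metrics exactly", {
  skip_if_not_installed("ape")
  # ((a:2,b:3):3,(c:4,d:4)) as an additive distance matrix
  dm <- matrix(c(0, 5, 9, 9,
                 5, 0, 10, 10,
                 9, 10, 0, 8,
                 9, 10, 8, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  nwk <- neighbor_joining(dm)
  expect_equal(.tree_dists(nwk, letters[1:4]), dm, tolerance = 1e-12)
})

test_that("star-tree input yields zero internal branches", {
  dm <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dm) <- 0
  nwk <- neighbor_joining(dm)
  skip_if_not_installed("ape")
  tr <- ape::read.tree(text = nwk)
  internal <- tr$edge.length[tr$edge[, 2] > ape::Ntip(tr)]
  expect_true(all(abs(internal) < 1e-12))
})

test_that("path lengths reproduce random additive 8-taxon matrices", {
  skip_if_not_installed("ape")
  set.seed(17)
  for (rep in 1:5) {
    # random topology + branch lengths -> additive matrix, via ape
    tr <- ape::rtree(8, br = function(n) runif(n, 0.5, 3))
    dm <- as.matrix(ape::cophenetic.phylo(tr))
    labs <- rownames(dm)
    nwk <- neighbor_joining(dm)
    expect_lt(max(abs(.tree_dists(nwk, labs) - dm)), 1e-9)

    # topology stable under tiny jitter of the distances
    jit <- dm + matrix(runif(64, 0, 1e-7), 8, 8)
    jit <- (jit + t(jit)) / 2
    diag(jit) <- 0
    nwk_j <- neighbor_joining(jit)
    d0 <- ape::dist.topo(ape::unroot(ape::read.tree(text = nwk)),
                         ape::unroot(ape::read.tree(text = nwk_j)))
    expect_equal(as.numeric(d0), 0)
  }
})

test_that("degenerate inputs are rejected", {
  dm <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(dm), "at least 3")
  dm3 <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(dm3), "symmetric")
})

test_that("assignment follows the strict 2% nearest-reference rule", {
  cfg <- sim_config(n_fig_species = 4, d_inter = 0.10, d_intra = 0.005)
  sp <- paste0("sp", 1:4)
  out <- simulate_sequences(sp, cfg, seed = 19, queries_for = sp[1])
  refs <- out$references

  # query identical to a reference: that species at divergence 0
  asg <- assign_species(c(q1 = refs[["sp2"]]), refs)
  expect_equal(asg$assigned_species, "sp2")
  expect_equal(asg$divergence_to_closest, 0)

  # query far from every reference: new sp. with the closest noted
  # (same seed: the first four references are identical, the fifth species
  # supplies a query ~10% diverged from all of them)
  far <- simulate_sequences(c(sp, "ghost"), cfg, seed = 19,
                            queries_for = "ghost")
  asg2 <- assign_species(c(q2 = far$queries[[1]]), refs)
  expect_equal(asg2$assigned_species, "new sp.")
  expect_true(asg2$closest_reference %in% sp)
  expect_gt(asg2$divergence_to_closest, 0.02)

  # pseudogene flag requires all three frames to contain internal stops
  allstop <- strrep("TTAA", 126)
  asg4 <- assign_species(c(q4 = substr(allstop, 1, 503)), refs)
  expect_true(asg4$pseudogene_flag)
  expect_true(is.na(asg4$assigned_species))

  # short overlap -> unassigned with reason
  shortq <- paste0(substr(refs[["sp1"]], 1, 100), strrep("N", 403))
  asg5 <- assign_species(c(q5 = shortq), refs, min_overlap = 300)
  expect_true(is.na(asg5$assigned_species))
  expect_match(asg5$reason, "overlap")
})

test_that("assignment is invariant to input order and exact on synthetic cohorts", {
  cfg <- sim_config(n_fig_species = 5, d_inter = 0.10, d_intra = 0.005)
  sp <- paste0("sp", 1:5)
  truth <- rep(sp, times = 8)
  out <- simulate_sequences(sp, cfg, seed = 29, queries_for = truth)
  asg <- assign_species(out$queries, out$references)
  expect_equal(asg$assigned_species, truth)
  expect_true(all(asg$divergence_to_closest < 0.02))

  # permute queries and references: same assignments per individual
  qperm <- out$queries[rev(seq_along(out$queries))]
  rperm <- out$references[c(3, 1, 5, 2, 4)]
  asg2 <- assign_species(qperm, rperm)
  m <- match(asg$individual_id, asg2$individual_id)
  expect_equal(asg2$assigned_species[m], asg$assigned_species)

  # an audit NJ tree in newick form is attached
  expect_true(is.character(attr(asg, "tree")))
})
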