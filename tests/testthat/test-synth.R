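test_that("simulated phylogenies are ultrametric pure-birth trees", {
  tr2 <- simulate_phylogeny(2, seed = 1)
  expect_equal(ape::Ntip(tr2), 2)
  expect_equal(tr2$Nnode, 1)

  tr <- simulate_phylogeny(50, seed = 3)
  d <- stats::cophenetic(tr)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  depths <- ape::node.depth.edgelength(tr)[seq_len(50)]
  expect_lt(diff(range(depths)), 1e-9)
  expect_true(all(tr$edge.length > 0))

  expect_identical(ape::write.tree(simulate_phylogeny(50, seed = 7)),
                   ape::write.tree(simulate_phylogeny(50, seed = 7)))
  expect_error(simulate_phylogeny(1), "n_taxa")
})

test_that("trait evolution is Brownian: degenerate rate, determinism,
           and covariance decaying with phylogenetic distance", {
  tr <- simulate_phylogeny(30, seed = 2)
  expect_true(all(evolve_trait(tr, trait_sigma = 0, seed = 1) == 0))
  expect_identical(evolve_trait(tr, 1, seed = 5), evolve_trait(tr, 1, seed = 5))
  expect_error(evolve_trait(tr, -1), "trait_sigma")

  # Monte-Carlo: the closest tip pair has smaller mean |trait difference|
  # than the most distant pair (holds for any conservatism level)
  d <- stats::cophenetic(tr)
  d2 <- d; d2[upper.tri(d2, diag = TRUE)] <- NA
  close_pair <- which(d2 == min(d2, na.rm = TRUE), arr.ind = TRUE)[1, ]
  far_pair <- which(d2 == max(d2, na.rm = TRUE), arr.ind = TRUE)[1, ]
  diffs <- vapply(seq_len(200), function(i) {
    x <- evolve_trait(tr, 1, seed = 1000 + i, conservatism = 1)
    c(abs(x[close_pair[1]] - x[close_pair[2]]),
      abs(x[far_pair[1]] - x[far_pair[2]]))
  }, numeric(2))
  expect_lt(mean(diffs[1, ]), mean(diffs[2, ]))
})

test_that("community simulation respects depth, determinism, and the
           degenerate-selection reduction", {
  tr <- simulate_phylogeny(30, seed = 4)
  traits <- evolve_trait(tr, 1, seed = 5)
  cfg <- scenario_config("undominated", n_taxa = 30, n_samples = 8,
                         depth = 2000, seed = 6)
  sim <- simulate_community(cfg, tr, traits)
  expect_true(all(colSums(sim$counts) == 2000))
  expect_true(all(sim$counts >= 0))
  expect_identical(sim$counts, simulate_community(cfg, tr, traits)$counts)
  expect_equal(nrow(sim$metadata), 8)

  # selection_strength = 0 with full migration reduces exactly to the
  # undominated scenario (same weights, same draws)
  cfg_sel <- scenario_config("homogeneous_selection", n_taxa = 30,
                             n_samples = 8, depth = 2000,
                             selection_strength = 0, migration_rate = 1,
                             env_optimum = 0, seed = 6)
  expect_identical(simulate_community(cfg_sel, tr, traits)$counts, sim$counts)

  expect_error(simulate_community(cfg, tr, traits[1:10]), "cover")
})

test_that("undominated abundances converge to the shared pool at large depth", {
  tr <- simulate_phylogeny(25, seed = 9)
  traits <- evolve_trait(tr, 1, seed = 9)
  cfg <- scenario_config("undominated", n_taxa = 25, n_samples = 4,
                         depth = 1e6, seed = 10)
  sim <- simulate_community(cfg, tr, traits)
  rel <- sweep(sim$counts, 2, colSums(sim$counts), "/")
  # all samples share one pool, so columns must agree to sampling error
  expect_lt(max(abs(rel - rowMeans(rel))), 0.01)
})

test_that("scenario config validates its invariants", {
  expect_error(scenario_config("undominated", n_taxa = 1), "n_taxa")
  expect_error(scenario_config("undominated", n_samples = 1), "n_samples")
  expect_error(scenario_config("undominated", depth = 0), "depth")
  expect_error(scenario_config("dispersal_limitation", migration_rate = 0.5),
               "migration_rate <= 0.05")
  expect_error(scenario_config("homogenizing_dispersal", migration_rate = 0.5),
               "migration_rate >= 0.9")
  expect_error(scenario_config("undominated", migration_rate = 2), "\\[0, 1\\]")
})

test_that("correlated count simulation validates inputs, is deterministic,
           and carries the true basis correlations", {
  bc <- diag(6)
  bc[1, 2] <- bc[2, 1] <- 0.8
  cc <- simulate_correlated_counts(6, 30, bc, depth = 1000, seed = 3)
  expect_true(all(colSums(cc) == 1000))
  expect_identical(attr(cc, "basis_corr"), bc)
  expect_identical(cc, simulate_correlated_counts(6, 30, bc, depth = 1000,
                                                  seed = 3))
  bad <- matrix(0.99, 3, 3); diag(bad) <- 1
  bad[1, 2] <- bad[2, 1] <- -0.99
  expect_error(simulate_correlated_counts(3, 10, bad), "positive-definite")
  asym <- diag(3); asym[1, 2] <- 0.5
  expect_error(simulate_correlated_counts(3, 10, asym), "symmetric")
})

test_that("study simulation is reproducible and group-structured", {
  st <- suppressWarnings(simulate_study(seed = 11, n_taxa = 60,
                                        n_samples = 12, n_groups = 4,
                                        depth = 1000))
  expect_equal(dim(st$counts), c(60, 12))
  expect_equal(length(unique(st$metadata$group)), 4)
  st2 <- suppressWarnings(simulate_study(seed = 11, n_taxa = 60,
                                         n_samples = 12, n_groups = 4,
                                         depth = 1000))
  expect_identical(st$counts, st2$counts)
  expect_identical(ape::write.tree(st$tree), ape::write.tree(st2$tree))
})
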