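test_that("topology identities hold exactly on any network", {
  ts <- topology_summary(533, 10088, 5350, 4738)
  expect_equal(ts$avgK_paper, 10088 / 533)
  expect_equal(ts$graph_density, 2 * 10088 / (533 * 532))
  expect_equal(ts$pos_neg_ratio, 5350 / 4738)
  expect_equal(ts$mean_degree, 2 * ts$avgK_paper)
  expect_error(topology_summary(5, 4, 1, 1), "must equal")

  for (s in 1:4) {
    g <- random_signed_graph(20, 40, seed = s)
    rep <- topology_report(g)
    expect_equal(rep$n_positive + rep$n_negative, rep$n_edges)
    expect_equal(rep$graph_density,
                 2 * rep$n_edges / (rep$n_nodes * (rep$n_nodes - 1)))
    expect_equal(rep$avgK_paper, rep$n_edges / rep$n_nodes)
  }
})

test_that("triangle graph has closed-form topology", {
  g <- igraph::make_full_graph(3)
  igraph::V(g)$name <- c("a", "b", "c")
  rep <- topology_report(g)
  expect_equal(rep$avg_path_distance, 1)
  expect_equal(rep$avg_clustering, 1)
  expect_equal(rep$graph_density, 1)
})

test_that("module detection recovers disconnected cliques (Q = 0.5) and
           planted partitions", {
  mods <- detect_modules(two_cliques())
  expect_equal(mods$n_modules, 2)
  expect_equal(mods$modularity, 0.5)
  expect_equal(mods$n_modules_ge5, 2)

  gk <- igraph::make_full_graph(6)
  igraph::V(gk)$name <- paste0("n", 1:6)
  expect_lt(abs(detect_modules(gk)$modularity), 0.1)

  skip_if_not_installed("mclust")
  ari <- vapply(1:10, function(s) {
    set.seed(s)
    g <- igraph::sample_sbm(60, pref.matrix = matrix(c(0.5, 0.02, 0.02, 0.5), 2),
                            block.sizes = c(30, 30))
    igraph::V(g)$name <- paste0("n", 1:60)
    memb <- detect_modules(g, seed = s)$membership
    mclust::adjustedRandIndex(memb, rep(1:2, each = 30))
  }, numeric(1))
  expect_gte(mean(ari >= 0.9), 0.9)
})

test_that("z and c node roles hit closed forms and the threshold grid", {
  # node with all links inside its module: c = 0; equal split over m
  # modules: c = 1 - 1/m
  g <- igraph::graph_from_literal(a - b, a - c, a - d, b - c)
  memb <- c(a = 1, b = 2, c = 3, d = 1)
  roles <- zc_scores(g, memb)
  # a has degree 3 split over modules {2:b, 3:c, 1:d} -> one link each
  expect_equal(roles$c[roles$taxon == "a"], 1 - 1 / 3)
  # d's single link goes to a (module 1, its own) -> c = 0
  expect_equal(roles$c[roles$taxon == "d"], 0)

  expect_equal(unname(vapply(list(c(3, 0.7), c(3, 0.5), c(1, 0.7), c(1, 0.5)),
    function(p) {
      ifelse(p[1] > 2.5 & p[2] > 0.6, "network hub",
      ifelse(p[1] > 2.5, "module hub",
      ifelse(p[2] > 0.6, "connector", "peripheral")))
    }, character(1))),
    c("network hub", "module hub", "connector", "peripheral"))

  # classification is exhaustive and boundary values fall to the lower role
  gg <- two_cliques()
  mods <- detect_modules(gg)
  r <- zc_scores(gg, mods)
  expect_true(all(r$category %in% c("network hub", "module hub",
                                    "connector", "peripheral")))
  expect_true(all(r$c >= 0 & r$c <= 1 - 1 / mods$n_modules + 1e-12))
})

test_that("natural connectivity matches spectra and never decreases when
           an edge is added", {
  k4 <- igraph::make_full_graph(4)
  expect_equal(natural_connectivity(k4), log((exp(3) + 3 * exp(-1)) / 4),
               tolerance = 1e-9)
  empty <- igraph::make_empty_graph(5, directed = FALSE)
  expect_equal(natural_connectivity(empty), 0)
  expect_error(natural_connectivity(igraph::make_empty_graph(0)), "empty")

  for (s in 1:5) {
    set.seed(s)
    g <- igraph::sample_gnp(10, 0.3)
    nc1 <- natural_connectivity(g)
    # brute-force eigensolve agreement
    lam <- eigen(igraph::as_adjacency_matrix(g, sparse = FALSE),
                 symmetric = TRUE, only.values = TRUE)$values
    expect_equal(nc1, log(mean(exp(lam))), tolerance = 1e-9)
    miss <- which(igraph::as_adjacency_matrix(g, sparse = FALSE) == 0,
                  arr.ind = TRUE)
    miss <- miss[miss[, 1] < miss[, 2], , drop = FALSE]
    if (nrow(miss)) {
      e <- miss[sample(nrow(miss), 1), ]
      g2 <- igraph::add_edges(g, e)
      expect_gte(natural_connectivity(g2), nc1 - 1e-12)
    }
  }
})

test_that("robustness curves collapse the star at step one and follow
           betweenness order", {
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:5))
  rob <- robustness_curve(star)
  expect_equal(nrow(rob$curve), 7)
  expect_equal(rob$curve$removed_node[2], "hub")
  expect_equal(rob$curve$natural_connectivity[2], 0, tolerance = 1e-9)
  expect_equal(rob$curve$natural_connectivity[7], 0)

  p4 <- igraph::graph_from_literal(a - b, b - c, c - d)
  rb <- robustness_curve(p4)
  expect_setequal(rb$curve$removed_node[2:3], c("b", "c"))

  # removing edges cannot increase the robustness AUC
  for (s in 1:3) {
    g <- random_signed_graph(15, 40, seed = 100 + s)
    auc1 <- robustness_curve(g)$auc
    set.seed(s)
    g2 <- igraph::delete_edges(g, sample(igraph::E(g), 8))
    expect_gte(auc1, robustness_curve(g2)$auc - 1e-9)
  }
})

test_that("cohesion signs are structural and a planted positive block
           raises positive cohesion", {
  set.seed(9)
  for (s in 1:4) {
    tab <- matrix(rpois(30 * 20, 10), 30, 20,
                  dimnames = list(paste0("t", 1:30), paste0("s", 1:20)))
    res <- suppressWarnings(cohesion(tab, n_null_iter = 30, seed = s))
    expect_true(all(res$cohesion$pos >= 0))
    expect_true(all(res$cohesion$neg <= 0))
    expect_true(all(abs(res$cohesion$pos) <=
                    max(abs(res$connectedness$pos)) + 1e-12))
  }

  # paired comparison: correlated block vs independent taxa
  diffs <- vapply(1:6, function(s) {
    bc <- diag(12)
    bc[1:4, 1:4] <- 0.8; diag(bc) <- 1
    corr_tab <- simulate_correlated_counts(12, 40, bc, depth = 3000, seed = s)
    ind_tab <- simulate_correlated_counts(12, 40, diag(12), depth = 3000,
                                          seed = s)
    mean(cohesion(corr_tab, 50, seed = s)$cohesion$pos) -
      mean(cohesion(ind_tab, 50, seed = s)$cohesion$pos)
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.5)

  t2 <- c(2L, 4L, 6L, 8L, 3L, 5L)
  cst <- rbind(rep(10L, 6), t2, 10L - t2)
  dimnames(cst) <- list(paste0("t", 1:3), paste0("s", 1:6))
  expect_warning(cohesion(cst, 10, seed = 1), "constant")
})
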