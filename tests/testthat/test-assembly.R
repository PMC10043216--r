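test_that("top-taxa filter ranks by relative abundance with id tie-breaks", {
  tab <- matrix(c(10L, 5L, 5L, 1L, 1L), ncol = 1,
                dimnames = list(c("t5", "t3", "t2", "t4", "t1"), "s1"))
  expect_identical(rownames(filter_top_taxa(tab, 3)), c("t5", "t3", "t2"))
  expect_identical(filter_top_taxa(tab, 5), tab)
  expect_identical(rownames(filter_top_taxa(tab, 1)), "t5")
  expect_warning(out <- filter_top_taxa(tab, 10), "exceeds")
  expect_identical(out, tab)
})

test_that("niche values are abundance-weighted environmental means", {
  tab <- matrix(c(1L, 3L,   # taxon t1: a=(1,3) over env (2,6) -> 5
                  0L, 2L,   # taxon t2 only in s2 -> 6
                  0L, 0L),  # zero-total taxon excluded
                nrow = 3, byrow = TRUE,
                dimnames = list(paste0("t", 1:3), c("s1", "s2")))
  md <- data.frame(sample_id = c("s1", "s2"), group = c("a", "a"),
                   env = c(2, 6))
  nv <- niche_values(tab, md)
  expect_equal(unname(nv["t1", "env"]), 5)
  expect_equal(unname(nv["t2", "env"]), 6)
  expect_false("t3" %in% rownames(nv))

  # uniform abundance -> arithmetic mean
  u <- matrix(2L, 1, 2, dimnames = list("t1", c("s1", "s2")))
  expect_equal(unname(niche_values(u, md)["t1", "env"]), 4)
})

test_that("mantel correlogram detects conserved-trait signal in the
           shortest distance class", {
  hits <- vapply(1:15, function(i) {
    tr <- simulate_phylogeny(60, seed = 400 + i)
    x <- evolve_trait(tr, 1, seed = 500 + i)
    mc <- mantel_correlogram(stats::cophenetic(tr), dist(x),
                             n_classes = 6, n_perm = 99, seed = 600 + i)
    mc$r[1] > 0 && !is.na(mc$p[1]) && mc$p[1] <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.6)

  # trait independent of the tree: shortest class not systematically positive
  tr <- simulate_phylogeny(60, seed = 3)
  set.seed(4)
  mc0 <- mantel_correlogram(stats::cophenetic(tr), dist(rnorm(60)),
                            n_classes = 6, n_perm = 99, seed = 5)
  expect_true(is.na(mc0$p[1]) || mc0$p[1] > 0.01 || abs(mc0$r[1]) < 0.1)
})

test_that("beta-MNTD matches hand values and the picante oracle exactly", {
  # A={t1}, B={t2} on a two-tip tree with d = 2: 0.5*(2+2)/... = 2
  tab <- matrix(c(3L, 0L, 0L, 5L), 2,
                dimnames = list(c("t1", "t2"), c("A", "B")))
  expect_equal(unname(beta_mntd(tab, two_tip_tree())["A", "B"]), 2)

  # identical samples -> 0
  same <- matrix(c(3L, 1L, 3L, 1L), 2,
                 dimnames = list(c("t1", "t2"), c("A", "B")))
  expect_equal(unname(beta_mntd(same, two_tip_tree())["A", "B"]), 0)

  skip_if_not_installed("picante")
  for (s in 1:5) {
    set.seed(s)
    tr <- simulate_phylogeny(10, seed = s)
    m <- matrix(rpois(40, 2), 10, 4,
                dimnames = list(tr$tip.label, paste0("s", 1:4)))
    m[, colSums(m) == 0] <- 1L
    mine <- beta_mntd(m, tr)
    orac <- as.matrix(picante::comdistnt(t(m), stats::cophenetic(tr),
                                         abundance.weighted = TRUE))
    expect_equal(mine, orac[rownames(mine), colnames(mine)],
                 tolerance = 1e-12, ignore_attr = TRUE)
    # unweighted variant against an explicit double-loop oracle
    unw <- beta_mntd(m, tr, weighted = FALSE)
    d <- stats::cophenetic(tr)[rownames(m), rownames(m)]
    for (a in 1:3) for (b in (a + 1):4) {
      A <- which(m[, a] > 0); B <- which(m[, b] > 0)
      mins_a <- vapply(A, function(i) min(d[i, B]), numeric(1))
      mins_b <- vapply(B, function(j) min(d[j, A]), numeric(1))
      expect_equal(unname(unw[a, b]), 0.5 * (mean(mins_a) + mean(mins_b)),
                   tolerance = 1e-12)
    }
  }
})

test_that("beta-NTI flags a degenerate null on a star phylogeny", {
  star <- ape::read.tree(text = "(t1:1,t2:1,t3:1,t4:1);")
  tab <- matrix(c(5L, 1L, 0L, 0L,
                  0L, 0L, 4L, 2L), 4,
                dimnames = list(paste0("t", 1:4), c("A", "B")))
  expect_warning(z <- beta_nti(tab, star, n_reps = 19, seed = 1),
                 "degenerate")
  expect_true(is.na(z["A", "B"]))
})

test_that("RC-bray is bounded, symmetric, and zero-diagonal", {
  set.seed(6)
  tab <- matrix(rpois(60, 4), 10, 6,
                dimnames = list(paste0("t", 1:10), paste0("s", 1:6)))
  tab[tab < 0] <- 0L
  storage.mode(tab) <- "integer"
  rc <- rc_bray(tab, n_reps = 49, seed = 2)
  expect_true(all(rc >= -1 & rc <= 1))
  expect_true(isSymmetric(rc))
  expect_true(all(diag(rc) == 0))
  one <- matrix(c(3L, 0L, 4L, 0L), 2,
                dimnames = list(c("t1", "t2"), c("a", "b")))
  expect_error(rc_bray(one[1, , drop = FALSE], 19), "degenerate")
})

test_that("process classification follows the two-step threshold rule", {
  expect_equal(classify_processes(2.5, 0), "HeS")
  expect_equal(classify_processes(-2.5, 0), "HoS")
  expect_equal(classify_processes(0, 0.99), "DL")
  expect_equal(classify_processes(0, -0.99), "HD")
  expect_equal(classify_processes(0, 0), "UD")
  # beta-NTI takes precedence over RC
  expect_equal(classify_processes(-2.0001, 1), "HoS")
  # boundary values are not deterministic signals
  expect_equal(classify_processes(2, 0), "UD")
  expect_true(is.na(classify_processes(NA, 0.5)))
  # totality over a grid: every finite pair gets exactly one label
  grid <- expand.grid(z = seq(-4, 4, by = 0.5), rc = seq(-1, 1, by = 0.25))
  lab <- classify_processes(grid$z, grid$rc)
  expect_true(all(lab %in% c("HeS", "HoS", "DL", "HD", "UD")))
})

test_that("assembly summaries give per-group fractions that sum to one", {
  pairs <- data.frame(sample_a = c("s1", "s1", "s3", "s3"),
                      sample_b = c("s2", "s2", "s4", "s4"),
                      beta_nti = 0, rc_bray = 0,
                      process = c("HoS", "HoS", "DL", "UD"))
  md <- data.frame(sample_id = paste0("s", 1:4),
                   group = c("g1", "g1", "g2", "g2"))
  s <- assembly_summary(pairs, md)
  expect_equal(s$HoS[s$group == "g1"], 1)
  expect_equal(s$DL[s$group == "g2"], 0.5)
  expect_equal(rowSums(s[, c("HeS", "HoS", "DL", "HD", "UD")]), c(1, 1),
               ignore_attr = TRUE)
  # invariant to pair order
  s2 <- assembly_summary(pairs[4:1, ], md)
  expect_equal(s[order(s$group), ], s2[order(s2$group), ], ignore_attr = TRUE)
  # all-pairs scope gives a single row
  expect_equal(nrow(assembly_summary(pairs, md, scope = "all")), 1)
})

test_that("NST is 100% when observation matches the null and is invariant
           to relabelling", {
  # construct a table whose observed dissimilarity equals a null draw by
  # making observation and null statistically exchangeable: undominated
  # sampling from the table's own metacommunity
  st <- suppressWarnings(simulate_study(seed = 21, n_taxa = 80,
                                        n_samples = 8, n_groups = 1,
                                        depth = 5000,
                                        scenario = "undominated"))
  res <- nst(st$counts, rep("g", 8), n_reps = 49, seed = 3)
  expect_gt(res$nst, 70)
  expect_lte(res$nst, 100 + 1e-9)

  perm <- sample(8)
  res2 <- nst(st$counts[, perm], rep("g", 8), n_reps = 49, seed = 3)
  expect_equal(res$nst, res2$nst, tolerance = 1e-9)

  expect_error(nst(st$counts, c("a", rep("b", 7)), 49), "< 2 samples")
})
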