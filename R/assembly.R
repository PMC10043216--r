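#' Keep the most abundant taxa
#'
#' Retains the `n_top` taxa with the highest total relative abundance
#' (summed over samples after closing each sample to 1). Ties are broken by
#' taxon id so the filter is deterministic.
#'
#' @param table Count table.
#' @param n_top Number of taxa to keep (>= 1).
#' @return Filtered count table, rows in the original order.
#' @export
filter_top_taxa <- function(table, n_top) {
  validate_count_table(table, require_integer = FALSE)
  if (n_top < 1) stop("n_top must be >= 1")
  if (n_top > nrow(table)) {
    warning("n_top (", n_top, ") exceeds available taxa (", nrow(table),
            "); keeping all")
    n_top <- nrow(table)
  }
  score <- rowSums(rel_abund(table))
  ord <- order(-score, rownames(table))
  keep <- sort(ord[seq_len(n_top)])
  table[keep, , drop = FALSE]
}

#' Abundance-weighted niche values per taxon
#'
#' For each taxon and environmental variable, the abundance-weighted mean of
#' the variable over samples: `niche_iv = sum_s a_is e_vs / sum_s a_is`. The
#' Euclidean distances between rows of the result are the niche distances
#' used in the phylogenetic-signal test.
#'
#' @param table Count table.
#' @param metadata Data frame with `sample_id` and numeric environmental
#'   columns.
#' @param env_vars Names of the environmental columns; defaults to every
#'   numeric column other than `sample_id`/`group`.
#' @return Numeric matrix (taxa x variables); taxa with zero total abundance
#'   are excluded.
#' @export
niche_values <- function(table, metadata, env_vars = NULL) {
  validate_count_table(table, require_integer = FALSE)
  if (!all(colnames(table) %in% metadata$sample_id)) {
    stop("metadata does not cover all samples")
  }
  md <- metadata[match(colnames(table), metadata$sample_id), , drop = FALSE]
  if (is.null(env_vars)) {
    env_vars <- setdiff(names(md)[vapply(md, is.numeric, logical(1))],
                        c("sample_id", "group"))
  }
  if (!length(env_vars)) stop("no numeric environmental variables found")
  ev <- as.matrix(md[, env_vars, drop = FALSE])
  if (anyNA(ev)) stop("environmental variables contain missing values")
  tot <- rowSums(table)
  keep <- tot > 0
  niche <- (table[keep, , drop = FALSE] %*% ev) / tot[keep]
  colnames(niche) <- env_vars
  niche
}

#' Mantel correlogram of niche distance against phylogenetic distance
#'
#' Tests for phylogenetic signal in niche values: significant positive
#' Mantel correlation within the shortest phylogenetic-distance classes
#' indicates that ecologically similar taxa are close relatives, the
#' premise of the beta-NTI null model. Distance classes are equal-width;
#' p-values carry vegan's progressive (Holm) multiple-test correction.
#'
#' @param phylo_dist Cophenetic distances between taxa (`dist` or matrix).
#' @param niche_dist Niche (e.g. Euclidean) distances between the same taxa.
#' @param n_classes Number of distance classes (>= 2).
#' @param n_perm Permutations per class (default 999).
#' @param seed Integer seed.
#' @return Data frame with `class_index` (class midpoint), `n_dist` (pairs in
#'   class), `r` (Mantel correlation, positive = similar niches within the
#'   class), `p`, `p_corrected`. Empty classes are `NA`.
#' @export
mantel_correlogram <- function(phylo_dist, niche_dist, n_classes = 10,
                               n_perm = 999, seed = 1) {
  dp <- stats::as.dist(phylo_dist)
  dn <- stats::as.dist(niche_dist)
  if (attr(dp, "Size") != attr(dn, "Size")) {
    stop("phylo_dist and niche_dist cover different numbers of taxa")
  }
  if (n_classes < 2) stop("n_classes must be >= 2")
  breaks <- seq(min(dp), max(dp), length.out = n_classes + 1)
  fit <- with_seed(seed, vegan::mantel.correlog(
    D.eco = dn, D.geo = dp, break.pts = breaks, cutoff = FALSE,
    nperm = n_perm, mult = "holm", progressive = TRUE))
  res <- as.data.frame(fit$mantel.res)
  data.frame(class_index = res[["class.index"]],
             n_dist = res[["n.dist"]],
             r = res[["Mantel.cor"]],
             p = res[["Pr(Mantel)"]],
             p_corrected = res[["Pr(corrected)"]])
}

# beta-MNTD on a relative-abundance matrix given a taxon distance matrix.
# For each sample pair, the abundance-weighted mean distance from each taxon
# to its nearest neighbour in the other sample (shared taxa contribute 0).
bmntd_core <- function(relab, d, weighted = TRUE) {
  n <- ncol(relab)
  idx <- lapply(seq_len(n), function(s) which(relab[, s] > 0))
  out <- matrix(0, n, n, dimnames = list(colnames(relab), colnames(relab)))
  for (a in seq_len(n - 1)) {
    A <- idx[[a]]
    for (b in seq(a + 1, n)) {
      B <- idx[[b]]
      dAB <- d[A, B, drop = FALSE]
      min_a <- apply(dAB, 1, min)   # nearest taxon in B for each taxon of A
      min_b <- apply(dAB, 2, min)
      if (weighted) {
        v <- 0.5 * (sum(relab[A, a] * min_a) + sum(relab[B, b] * min_b))
      } else {
        v <- 0.5 * (mean(min_a) + mean(min_b))
      }
      out[a, b] <- out[b, a] <- v
    }
  }
  out
}

#' Between-sample mean nearest taxon distance (beta-MNTD)
#'
#' For samples A and B,
#' `betaMNTD(A, B) = 0.5 * (sum_{i in A} f_iA min_{j in B} d_ij +
#'  sum_{j in B} f_jB min_{i in A} d_ij)`,
#' with `f` the within-sample relative abundances and `d` the cophenetic
#' distance; a taxon present in both samples has nearest-neighbour
#' distance 0.
#'
#' @param table Count table; all taxa must be tips of `tree`.
#' @param tree Rooted phylogeny with branch lengths.
#' @param weighted Abundance-weight the means (default `TRUE`); otherwise
#'   presences are weighted equally.
#' @return Symmetric matrix of beta-MNTD values (tree branch-length units).
#' @export
beta_mntd <- function(table, tree, weighted = TRUE) {
  validate_count_table(table, require_integer = FALSE)
  check_tree_coverage(table, tree)
  if (ncol(table) < 2) stop("need >= 2 samples")
  d <- stats::cophenetic(tree)[rownames(table), rownames(table)]
  bmntd_core(rel_abund(table), d, weighted = weighted)
}

#' Beta nearest taxon index (beta-NTI)
#'
#' Standardised effect size of the observed beta-MNTD against a null model
#' that shuffles taxon labels across the tips present in the table
#' (randomising phylogenetic relationships while preserving each sample's
#' abundance structure):
#' `betaNTI = (obs - mean(null)) / sd(null)` per sample pair.
#' `betaNTI < -2` indicates homogeneous selection, `> +2` heterogeneous
#' selection; `|betaNTI| <= 2` leaves the pair to the stochastic classes.
#'
#' @param table Count table; taxa must be on `tree`.
#' @param tree Rooted phylogeny.
#' @param n_reps Null-model replicates (>= 2; 999 for production runs, fewer
#'   for quick checks).
#' @param seed Integer seed.
#' @param weighted Abundance weighting, as in [beta_mntd()].
#' @return Symmetric matrix of z-scores with attribute `"beta_mntd_obs"`
#'   (the observed beta-MNTD matrix). Pairs with a degenerate null
#'   (`sd = 0`) are `NA` with a warning.
#' @export
beta_nti <- function(table, tree, n_reps = 999, seed = 1, weighted = TRUE) {
  validate_count_table(table, require_integer = FALSE)
  check_tree_coverage(table, tree)
  if (n_reps < 2) stop("n_reps must be >= 2")
  taxa <- rownames(table)
  d <- stats::cophenetic(tree)[taxa, taxa]
  relab <- rel_abund(table)
  obs <- bmntd_core(relab, d, weighted = weighted)
  p <- nrow(table)
  n <- ncol(table)
  sum_null <- matrix(0, n, n)
  sumsq_null <- matrix(0, n, n)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      perm <- sample.int(p)
      bn <- bmntd_core(relab, d[perm, perm], weighted = weighted)
      sum_null <- sum_null + bn
      sumsq_null <- sumsq_null + bn^2
    }
  })
  mean_null <- sum_null / n_reps
  var_null <- pmax(sumsq_null / n_reps - mean_null^2, 0) * n_reps / (n_reps - 1)
  sd_null <- sqrt(var_null)
  z <- (obs - mean_null) / sd_null
  degen <- sd_null == 0
  diag(degen) <- FALSE
  if (any(degen)) {
    warning(sum(degen) / 2, " pair(s) with degenerate null (sd = 0); ",
            "beta-NTI undefined for them")
    z[degen] <- NA_real_
  }
  diag(z) <- 0
  dimnames(z) <- dimnames(obs)
  attr(z, "beta_mntd_obs") <- obs
  z
}

# Null community draws preserving each sample's richness and total
# abundance: occurrences drawn with probability proportional to
# metacommunity occupancy, then the remaining individuals distributed among
# the drawn taxa with probability proportional to metacommunity relative
# abundance. Each sample's RNG stream is keyed to its id (not its column
# position), so results are invariant to sample order. Returns one
# taxa x n_reps matrix per sample.
null_community_draws <- function(table, n_reps, seed) {
  p <- nrow(table)
  occ <- rowSums(table > 0)
  meta <- rowSums(table)
  if (sum(occ > 0) < 2) stop("degenerate metacommunity (single taxon)")
  meta <- meta / sum(meta)
  rich <- colSums(table > 0)
  depth <- colSums(table)
  seeds <- split_seed(seed, ncol(table))[rank(colnames(table))]
  lapply(seq_len(ncol(table)), function(s) {
    with_seed(seeds[s], {
      reps <- matrix(0L, p, n_reps)
      for (r in seq_len(n_reps)) {
        drawn <- sample.int(p, rich[s], prob = occ)
        v <- integer(p)
        v[drawn] <- 1L
        extra <- depth[s] - rich[s]
        if (extra > 0) {
          pr <- meta[drawn]
          v[drawn] <- v[drawn] +
            stats::rmultinom(1, extra, pr / sum(pr))[, 1]
        }
        reps[, r] <- v
      }
      reps
    })
  })
}

#' Bray-Curtis-based Raup-Crick metric (RC-bray)
#'
#' For each sample pair, compares the observed Bray-Curtis dissimilarity to
#' a null distribution generated by probabilistically reassembling both
#' samples while preserving their observed richness and total abundance
#' (occurrence probability proportional to metacommunity occupancy,
#' individual allocation proportional to metacommunity relative abundance):
#' `RC = 2 * (#{null < obs} + 0.5 * #{null = obs}) / n_reps - 1`, in
#' `[-1, 1]`. `RC > 0.95` indicates dispersal limitation, `< -0.95`
#' homogenizing dispersal for pairs not already assigned by beta-NTI.
#'
#' @param table Integer count table.
#' @param n_reps Null replicates (>= 2; default 999).
#' @param seed Integer seed.
#' @return Symmetric matrix of RC values in `[-1, 1]`, zero diagonal.
#' @export
rc_bray <- function(table, n_reps = 999, seed = 1) {
  validate_count_table(table)
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (ncol(table) < 2) stop("need >= 2 samples")
  obs <- as.matrix(bray_curtis(table))
  nulls <- null_community_draws(table, n_reps, seed)
  n <- ncol(table)
  rc <- matrix(0, n, n, dimnames = dimnames(obs))
  eps <- 1e-12
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      X <- nulls[[a]]
      Y <- nulls[[b]]
      bc_null <- colSums(abs(X - Y)) / colSums(X + Y)
      o <- obs[a, b]
      stat <- (sum(bc_null < o - eps) + 0.5 * sum(abs(bc_null - o) <= eps)) /
        n_reps
      rc[a, b] <- rc[b, a] <- 2 * stat - 1
    }
  }
  rc
}

#' Classify sample pairs into the five assembly processes
#'
#' Two-step rule: deterministic signal first
#' (`betaNTI > +t` = heterogeneous selection HeS, `< -t` = homogeneous
#' selection HoS), then Raup-Crick partitions the remaining stochastic pairs
#' (`RC > rc_t` = dispersal limitation DL, `< -rc_t` = homogenizing
#' dispersal HD, otherwise undominated UD). Missing beta-NTI yields `NA`.
#'
#' @param beta_nti Numeric vector or matrix of beta-NTI values.
#' @param rc_bray Matching RC-bray values.
#' @param nti_threshold Deterministic threshold `t` (default 2).
#' @param rc_threshold Raup-Crick threshold (default 0.95).
#' @return Character vector/matrix of labels in
#'   `{"HeS", "HoS", "DL", "HD", "UD"}` (or `NA`).
#' @export
classify_processes <- function(beta_nti, rc_bray, nti_threshold = 2,
                               rc_threshold = 0.95) {
  if (length(beta_nti) != length(rc_bray)) {
    stop("beta_nti and rc_bray must have matching pair sets")
  }
  out <- ifelse(is.na(beta_nti), NA_character_,
         ifelse(beta_nti > nti_threshold, "HeS",
         ifelse(beta_nti < -nti_threshold, "HoS",
         ifelse(is.na(rc_bray), NA_character_,
         ifelse(rc_bray > rc_threshold, "DL",
         ifelse(rc_bray < -rc_threshold, "HD", "UD"))))))
  if (is.matrix(beta_nti)) {
    out <- matrix(out, nrow(beta_nti), dimnames = dimnames(beta_nti))
  }
  out
}

#' Build the per-pair assembly table
#'
#' Combines beta-NTI and RC-bray matrices into one row per unordered sample
#' pair with the assembly-process label.
#'
#' @param beta_nti z-score matrix from [beta_nti()].
#' @param rc RC matrix from [rc_bray()].
#' @inheritParams classify_processes
#' @return Data frame: `sample_a`, `sample_b`, `beta_mntd_obs` (if carried
#'   on `beta_nti`), `beta_nti`, `rc_bray`, `process`.
#' @export
pair_assembly <- function(beta_nti, rc, nti_threshold = 2,
                          rc_threshold = 0.95) {
  stopifnot(is.matrix(beta_nti), is.matrix(rc),
            all(dim(beta_nti) == dim(rc)))
  ids <- colnames(beta_nti)
  pairs <- which(upper.tri(beta_nti), arr.ind = TRUE)
  obs <- attr(beta_nti, "beta_mntd_obs")
  df <- data.frame(
    sample_a = ids[pairs[, 1]],
    sample_b = ids[pairs[, 2]],
    beta_nti = beta_nti[pairs],
    rc_bray = rc[pairs],
    stringsAsFactors = FALSE)
  if (!is.null(obs)) df$beta_mntd_obs <- obs[pairs]
  df$process <- classify_processes(df$beta_nti, df$rc_bray,
                                   nti_threshold, rc_threshold)
  df
}

#' Per-group fractions of assembly processes
#'
#' @param pairs Data frame from [pair_assembly()].
#' @param metadata Data frame with `sample_id` and `group`.
#' @param scope `"within"` (default): only pairs whose two samples share a
#'   group, summarised per group; `"all"`: every pair, one overall row.
#' @return Data frame with `group`, one column per process (fractions
#'   summing to 1 per row), and `n_pairs`. Groups with no pairs are omitted
#'   with a warning.
#' @export
assembly_summary <- function(pairs, metadata, scope = c("within", "all")) {
  scope <- match.arg(scope)
  procs <- c("HeS", "HoS", "DL", "HD", "UD")
  grp <- stats::setNames(metadata$group, metadata$sample_id)
  pairs <- pairs[!is.na(pairs$process), , drop = FALSE]
  if (scope == "within") {
    ga <- grp[pairs$sample_a]
    gb <- grp[pairs$sample_b]
    pairs <- pairs[!is.na(ga) & !is.na(gb) & ga == gb, , drop = FALSE]
    key <- grp[pairs$sample_a]
    groups <- unique(metadata$group)
    missing <- setdiff(groups, unique(key))
    if (length(missing)) {
      warning("group(s) without within-group pairs omitted: ",
              paste(missing, collapse = ", "))
    }
  } else {
    key <- rep("all", nrow(pairs))
  }
  if (!nrow(pairs)) stop("no classified pairs to summarise")
  out <- do.call(rbind, lapply(split(pairs$process, key), function(pr) {
    tab <- table(factor(pr, levels = procs))
    as.data.frame(c(as.list(tab / length(pr)), n_pairs = length(pr)))
  }))
  data.frame(group = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Normalized stochasticity ratio (NST)
#'
#' For each within-group sample pair, the observed dissimilarity `D` is
#' compared with the mean dissimilarity `E` of null communities assembled
#' under the richness- and abundance-preserving null of [rc_bray()]. The
#' per-pair stochasticity ratio is `ST = (1 - E) / (1 - D)` when `D <= E`
#' (communities more similar than the null, the selection side) and
#' `ST = E / D` otherwise, so `ST = 1` when observation matches the null
#' and `ST -> 0` under strong determinism. The group NST is the mean ST
#' rescaled to percent: 100% = fully stochastic, with 50% as the
#' conventional stochastic/deterministic boundary.
#'
#' @param table Integer count table.
#' @param groups Group label per sample.
#' @param n_reps Null replicates (default 999).
#' @param metric `"bray-curtis"` (abundance-based) or `"jaccard"`
#'   (presence/absence).
#' @param seed Integer seed.
#' @return Data frame with `group`, `nst` (percent), `n_pairs`. Non-finite
#'   pairs are skipped with a warning.
#' @export
nst <- function(table, groups, n_reps = 999,
                metric = c("bray-curtis", "jaccard"), seed = 1) {
  metric <- match.arg(metric)
  validate_count_table(table)
  groups <- as.character(groups)
  if (length(groups) != ncol(table)) stop("groups length must match samples")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("group(s) with < 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  dfun <- function(x, y) {
    if (metric == "jaccard") {
      a <- x > 0; b <- y > 0
      1 - sum(a & b) / sum(a | b)
    } else {
      sum(abs(x - y)) / sum(x + y)
    }
  }
  obs <- if (metric == "jaccard") as.matrix(jaccard(table)) else
    as.matrix(bray_curtis(table))
  nulls <- null_community_draws(table, n_reps, seed)
  res <- lapply(unique(groups), function(g) {
    cols <- which(groups == g)
    st <- c()
    for (ia in seq_along(cols)[-length(cols)]) {
      for (ib in seq(ia + 1, length(cols))) {
        a <- cols[ia]; b <- cols[ib]
        X <- nulls[[a]]; Y <- nulls[[b]]
        e_null <- if (metric == "jaccard") {
          mean(vapply(seq_len(n_reps),
                      function(r) dfun(X[, r], Y[, r]), numeric(1)))
        } else {
          mean(colSums(abs(X - Y)) / colSums(X + Y))
        }
        d <- obs[a, b]
        v <- if (d <= e_null) (1 - e_null) / (1 - d) else e_null / d
        st <- c(st, v)
      }
    }
    bad <- !is.finite(st)
    if (any(bad)) {
      warning("group ", g, ": skipping ", sum(bad), " non-finite pair(s)")
      st <- st[!bad]
    }
    data.frame(group = g, nst = 100 * mean(st), n_pairs = length(st),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
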