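#' Rarefy a count table to even depth
#'
#' Random subsampling without replacement (hypergeometric draw, via
#' [vegan::rrarefy()]) of each sample to `depth` reads. Samples whose total
#' falls below `depth` are excluded with a warning; taxa left with all-zero
#' rows are dropped when `drop_empty = TRUE` and listed in the
#' `"dropped_taxa"` attribute.
#'
#' @param table Count table (taxa x samples).
#' @param depth Target reads per sample.
#' @param seed Integer seed.
#' @param drop_empty Drop taxa that become all-zero (default `TRUE`).
#' @return Rarefied integer count table; every retained column sums to
#'   `depth`.
#' @export
rarefy <- function(table, depth, seed = 1, drop_empty = TRUE) {
  validate_count_table(table)
  totals <- colSums(table)
  keep <- totals >= depth
  if (!any(keep)) stop("no sample reaches depth ", depth)
  if (any(!keep)) {
    warning("excluding ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(colnames(table)[!keep], collapse = ", "))
  }
  table <- table[, keep, drop = FALSE]
  out <- with_seed(seed, t(vegan::rrarefy(t(table), depth)))
  storage.mode(out) <- "integer"
  if (drop_empty) {
    empty <- rowSums(out) == 0
    attr(out, "dropped_taxa") <- rownames(out)[empty]
    out <- out[!empty, , drop = FALSE]
  }
  out
}

#' Per-sample alpha diversity
#'
#' Shannon entropy in nats (`-sum p log p`), Gini-Simpson index
#' (`1 - sum p^2`), classic Chao1 richness
#' (`S_obs + F1^2 / (2 F2)`, or `S_obs + F1 (F1 - 1) / 2` when no
#' doubletons), and observed richness. Samples with zero total are reported
#' as `NA`.
#'
#' @param table Integer count table (Chao1 needs singleton/doubleton counts).
#' @param base Logarithm base for Shannon (default `exp(1)`, i.e. nats).
#' @return Data frame with one row per sample: `sample_id`, `shannon`,
#'   `simpson`, `chao1`, `observed`.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  validate_count_table(table)
  res <- lapply(seq_len(ncol(table)), function(s) {
    x <- table[, s]
    tot <- sum(x)
    if (tot == 0) {
      return(data.frame(shannon = NA_real_, simpson = NA_real_,
                        chao1 = NA_real_, observed = NA_real_))
    }
    p <- x[x > 0] / tot
    sobs <- sum(x > 0)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    chao1 <- if (f2 > 0) sobs + f1^2 / (2 * f2) else sobs + f1 * (f1 - 1) / 2
    data.frame(shannon = -sum(p * log(p, base = base)),
               simpson = 1 - sum(p^2),
               chao1 = chao1, observed = sobs)
  })
  cbind(data.frame(sample_id = colnames(table), stringsAsFactors = FALSE),
        do.call(rbind, res))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum |x - y| / sum (x + y)` over taxa, computed with
#' [vegan::vegdist()].
#'
#' @param table Count table (taxa x samples), >= 2 samples.
#' @return A `dist` object over samples, values in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  validate_count_table(table, require_integer = FALSE)
  if (ncol(table) < 2) stop("need >= 2 samples")
  if (any(colSums(table) == 0)) {
    stop("all-zero sample(s): dissimilarity undefined")
  }
  vegan::vegdist(t(table), method = "bray")
}

#' Jaccard dissimilarity on presence/absence
#'
#' `1 - |A intersect B| / |A union B|` over the taxon sets of each sample
#' pair, computed with [vegan::vegdist()] on binarised data.
#'
#' @inheritParams bray_curtis
#' @return A `dist` object over samples, values in `[0, 1]`.
#' @export
jaccard <- function(table) {
  validate_count_table(table, require_integer = FALSE)
  if (ncol(table) < 2) stop("need >= 2 samples")
  if (any(colSums(table) == 0)) {
    stop("all-zero sample(s): dissimilarity undefined")
  }
  vegan::vegdist(t(table), method = "jaccard", binary = TRUE)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Anderson's pseudo-F on a dissimilarity matrix with a permutation p-value,
#' computed with [vegan::adonis2()]:
#' `p = (#{F_perm >= F_obs} + 1) / (n_perm + 1)`.
#'
#' @param dist A `dist` object or square dissimilarity matrix over samples.
#' @param groups Group labels, one per sample (>= 2 groups, each of size
#'   >= 2).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List with `f` (pseudo-F), `p` (permutation p-value), `n_perm`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = 1) {
  d <- stats::as.dist(dist)
  groups <- as.factor(groups)
  n <- attr(d, "Size")
  if (length(groups) != n) stop("groups length must match dist size")
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups")
  if (any(table(droplevels(groups)) < 2)) stop("every group needs >= 2 samples")
  fit <- with_seed(seed, vegan::adonis2(d ~ g,
                                        data = data.frame(g = groups),
                                        permutations = n_perm))
  list(f = fit$F[1], p = fit$`Pr(>F)`[1], n_perm = n_perm)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the lower triangles with a permutation p-value
#' ([vegan::mantel()]).
#'
#' @param dist_a,dist_b `dist` objects (or square matrices) over the same
#'   samples.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List with `r` (Mantel correlation), `p`, `n_perm`.
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 999, seed = 1) {
  da <- stats::as.dist(dist_a)
  db <- stats::as.dist(dist_b)
  if (attr(da, "Size") != attr(db, "Size")) {
    stop("distance matrices have different sizes")
  }
  fit <- with_seed(seed, vegan::mantel(da, db, permutations = n_perm))
  list(r = fit$statistic, p = fit$signif, n_perm = n_perm)
}

#' Shared and unique taxon counts across groups (Venn partition)
#'
#' A taxon is "present" in a group when it has a nonzero count in at least
#' one of the group's samples. Returns the size of every exclusive region of
#' the k-group Venn partition (`2^k - 1` regions), named by the group
#' combination (`"A"`, `"A&B"`, ...).
#'
#' @param table Count table.
#' @param groups Group label per sample.
#' @return Named integer vector of region sizes plus attribute
#'   `"group_totals"` (taxa present per group).
#' @export
group_taxon_sets <- function(table, groups) {
  validate_count_table(table, require_integer = FALSE)
  groups <- as.character(groups)
  if (length(groups) != ncol(table)) stop("groups length must match samples")
  glev <- unique(groups)
  if (any(!nzchar(glev))) stop("empty group label")
  pres <- vapply(glev, function(g) {
    cols <- which(groups == g)
    if (!length(cols)) stop("empty group: ", g)
    rowSums(table[, cols, drop = FALSE] > 0) > 0
  }, logical(nrow(table)))
  k <- length(glev)
  combos <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(glev, m, simplify = FALSE)
  }), recursive = FALSE)
  counts <- vapply(combos, function(cmb) {
    inside <- rowSums(pres[, cmb, drop = FALSE]) == length(cmb)
    outside <- if (length(cmb) == k) TRUE else
      rowSums(pres[, setdiff(glev, cmb), drop = FALSE]) == 0
    sum(inside & outside)
  }, integer(1))
  names(counts) <- vapply(combos, paste, character(1), collapse = "&")
  attr(counts, "group_totals") <- colSums(pres)
  counts
}
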