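#' Prevalence filter
#'
#' Retains taxa observed (count > 0) in strictly more than `min_fraction` of
#' the samples — "more than" is a strict inequality, so a taxon present in
#' exactly that fraction is dropped.
#'
#' @param table Count table.
#' @param min_fraction Prevalence cutoff in `(0, 1)` (e.g. 0.2 for bacteria,
#'   0.3 for fungi).
#' @return Filtered count table.
#' @export
prevalence_filter <- function(table, min_fraction) {
  validate_count_table(table, require_integer = FALSE)
  if (min_fraction <= 0 || min_fraction >= 1) {
    stop("min_fraction must be in (0, 1)")
  }
  prev <- rowMeans(table > 0)
  keep <- prev > min_fraction
  if (!any(keep)) stop("no taxa pass the prevalence filter")
  table[keep, , drop = FALSE]
}

# Solve the SparCC basis-variance system for the pairs marked in M
# (M = 1 for included pairs, 0 diagonal and excluded pairs):
#   sum_{j in M_i} t_ij = |M_i| * omega_i + sum_{j in M_i} omega_j
sparcc_basis <- function(tmat, M) {
  A <- diag(rowSums(M)) + M
  b <- rowSums(M * tmat)
  omega <- tryCatch(solve(A, b),
                    error = function(e) stop("singular basis-variance system"))
  omega
}

sparcc_rho <- function(tmat, omega) {
  denom <- 2 * sqrt(outer(omega, omega))
  rho <- (outer(omega, omega, "+") - tmat) / denom
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  rho
}

#' SparCC correlation inference on compositional counts
#'
#' Estimates basis (absolute-abundance) correlations from relative count
#' data under SparCC's sparsity assumption. Fractions default to the
#' deterministic pseudocount-1 estimate
#' `x_is = (c_is + 1) / (depth_s + p)`; setting `n_inner_iter > 1` instead
#' averages over Dirichlet posterior draws of the fractions (the original
#' stochastic variant). From the log-ratio variances
#' `t_ij = Var_s[log(x_is / x_js)]` the basis variances `omega` solve the
#' linear system implied by sparsity (`sum_{j != i} rho_ij ~ 0`):
#' `sum_{j != i} t_ij = (p - 2) omega_i + sum_j omega_j`, and
#' `rho_ij = (omega_i + omega_j - t_ij) / (2 sqrt(omega_i omega_j))`,
#' clamped to `[-1, 1]`. Strongly correlated pairs violate sparsity, so up
#' to `n_exclusion_rounds` rounds remove the strongest-|rho| pair from the
#' system and re-solve, stopping early once the strongest remaining
#' candidate has `|rho| <= exclusion_threshold`.
#'
#' @param table Integer count table with >= 4 taxa and >= 5 samples.
#' @param n_inner_iter Dirichlet resampling iterations (1 = deterministic
#'   pseudocount estimate, the default).
#' @param n_exclusion_rounds Maximum exclusion-refinement rounds (default
#'   10).
#' @param exclusion_threshold |rho| below which no further pairs are
#'   excluded (default 0.1).
#' @param seed Integer seed (only consumed when `n_inner_iter > 1`).
#' @return Symmetric correlation matrix with unit diagonal. Taxa whose
#'   solved basis variance is non-positive have their correlations set to
#'   `NA` with a warning.
#' @export
sparcc_correlations <- function(table, n_inner_iter = 1,
                                n_exclusion_rounds = 10,
                                exclusion_threshold = 0.1, seed = 1) {
  validate_count_table(table)
  p <- nrow(table)
  if (p < 4) stop("SparCC needs >= 4 taxa")
  if (ncol(table) < 5) stop("SparCC needs >= 5 samples")

  logfrac <- function(counts) {
    f <- sweep(counts + 1, 2, colSums(counts + 1), "/")
    log(f)
  }
  if (n_inner_iter <= 1) {
    lf_list <- list(logfrac(table))
  } else {
    lf_list <- with_seed(seed, lapply(seq_len(n_inner_iter), function(i) {
      f <- apply(table + 1, 2, function(a) {
        g <- stats::rgamma(length(a), shape = a)
        g / sum(g)
      })
      log(f)
    }))
  }

  estimate_one <- function(lf) {
    v <- apply(lf, 1, stats::var)
    cv <- stats::cov(t(lf))
    tmat <- outer(v, v, "+") - 2 * cv       # t_ij = Var(log x_i / x_j)
    M <- matrix(1, p, p) - diag(p)
    omega <- sparcc_basis(tmat, M)
    rho <- sparcc_rho(tmat, omega)
    for (round in seq_len(n_exclusion_rounds)) {
      cand <- abs(rho) * M
      cand[!is.finite(cand)] <- 0
      diag(cand) <- 0
      mx <- max(cand)
      if (mx <= exclusion_threshold) break
      ij <- which(cand == mx, arr.ind = TRUE)[1, ]
      M[ij[1], ij[2]] <- M[ij[2], ij[1]] <- 0
      if (any(rowSums(M) < 2)) break        # keep the system well-posed
      omega <- sparcc_basis(tmat, M)
      rho <- sparcc_rho(tmat, omega)
    }
    list(rho = rho, omega = omega, tmat = tmat)
  }

  ests <- lapply(lf_list, estimate_one)
  rho <- Reduce(`+`, lapply(ests, `[[`, "rho")) / length(ests)
  omega <- Reduce(`+`, lapply(ests, `[[`, "omega")) / length(ests)
  rho <- (rho + t(rho)) / 2
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  bad <- omega <= 0
  if (any(bad)) {
    warning(sum(bad), " taxon/taxa with non-positive basis variance; ",
            "their correlations set to NA: ",
            paste(rownames(table)[bad], collapse = ", "))
    rho[bad, ] <- NA_real_
    rho[, bad] <- NA_real_
    diag(rho) <- 1
  }
  dimnames(rho) <- list(rownames(table), rownames(table))
  rho
}

#' Permutation p-values for SparCC correlations
#'
#' Null model: each taxon's counts are permuted independently across
#' samples, destroying all inter-taxon association while preserving each
#' taxon's abundance distribution; SparCC is recomputed per permutation.
#' Two-sided `p = (#{|rho_null| >= |rho_obs|} + 1) / (n_perm + 1)`.
#'
#' @param table Integer count table.
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed.
#' @param ... Passed to [sparcc_correlations()].
#' @return List with `rho` (observed correlations) and `p` (symmetric
#'   p-value matrix, diagonal `NA`).
#' @export
sparcc_pvalues <- function(table, n_perm = 100, seed = 1, ...) {
  validate_count_table(table)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (n_perm < 19) {
    warning("n_perm = ", n_perm, " cannot resolve p <= 0.05; ",
            "minimum attainable p is ", signif(1 / (n_perm + 1), 3))
  }
  obs <- sparcc_correlations(table, ...)
  exceed <- matrix(0, nrow(table), nrow(table))
  perm_seeds <- split_seed(seed, n_perm)
  for (k in seq_len(n_perm)) {
    tab_k <- with_seed(perm_seeds[k], {
      t(apply(table, 1, sample))
    })
    dimnames(tab_k) <- dimnames(table)
    rho_k <- suppressWarnings(sparcc_correlations(tab_k, ...))
    exceed <- exceed + (abs(rho_k) >= abs(obs))
  }
  pmat <- (exceed + 1) / (n_perm + 1)
  pmat[is.na(obs)] <- NA_real_
  diag(pmat) <- NA_real_
  dimnames(pmat) <- dimnames(obs)
  list(rho = obs, p = pmat)
}

#' Build a signed co-occurrence network from correlations
#'
#' Keeps an edge between two taxa iff `|rho| >= r_threshold` and
#' `p <= p_threshold`; edge weight is the signed correlation.
#'
#' @param corr Symmetric correlation matrix.
#' @param pvals Symmetric p-value matrix (or `NULL` to threshold on
#'   correlation only).
#' @param r_threshold Minimum absolute correlation (default 0.3).
#' @param p_threshold Maximum p-value (default 0.05).
#' @param keep_isolated Keep nodes without any qualifying edge (default
#'   `FALSE`).
#' @return An undirected [igraph] graph with edge attributes `weight`
#'   (signed rho) and `sign`.
#' @export
build_network <- function(corr, pvals = NULL, r_threshold = 0.3,
                          p_threshold = 0.05, keep_isolated = FALSE) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (r_threshold < 0) stop("r_threshold must be >= 0")
  if (p_threshold < 0 || p_threshold > 1) stop("p_threshold must be in [0, 1]")
  ids <- rownames(corr) %||% paste0("t", seq_len(nrow(corr)))
  keep <- abs(corr) >= r_threshold
  if (!is.null(pvals)) keep <- keep & (pvals <= p_threshold)
  keep[is.na(keep)] <- FALSE
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = nrow(corr), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, rbind(idx[, 1], idx[, 2]))
    igraph::E(g)$weight <- corr[idx]
    igraph::E(g)$sign <- ifelse(corr[idx] >= 0, 1L, -1L)
  }
  if (!keep_isolated) {
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  }
  g
}
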