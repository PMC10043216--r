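#' Topology identities from node/edge counts
#'
#' The degree/density/sign-ratio fields of a topology report depend only on
#' the node, edge, and sign counts. `avgK` is reported under two
#' conventions: `avgK_paper = E / N` (the convention used in many published
#' network tables) and `mean_degree = 2E / N` (the graph-theoretic mean
#' degree); the two differ by a factor of 2.
#'
#' @param n_nodes,n_edges,n_positive,n_negative Integer counts;
#'   `n_positive + n_negative` must equal `n_edges`.
#' @return Named list: `n_nodes`, `n_edges`, `n_positive`, `n_negative`,
#'   `pos_neg_ratio`, `avgK_paper`, `mean_degree`, `graph_density`.
#' @export
topology_summary <- function(n_nodes, n_edges, n_positive, n_negative) {
  if (n_positive + n_negative != n_edges) {
    stop("n_positive + n_negative must equal n_edges")
  }
  list(n_nodes = n_nodes, n_edges = n_edges,
       n_positive = n_positive, n_negative = n_negative,
       pos_neg_ratio = if (n_negative > 0) n_positive / n_negative else NA_real_,
       avgK_paper = if (n_nodes > 0) n_edges / n_nodes else NA_real_,
       mean_degree = if (n_nodes > 0) 2 * n_edges / n_nodes else NA_real_,
       graph_density = if (n_nodes > 1)
         2 * n_edges / (n_nodes * (n_nodes - 1)) else NA_real_)
}

#' Topological properties of a signed network
#'
#' Computes the standard co-occurrence-network table: node/edge/sign counts
#' and their identities (via [topology_summary()]), average path distance GD
#' (mean unweighted shortest-path length over connected node pairs), average
#' clustering coefficient avgCC (mean local clustering on the unsigned
#' graph; nodes with degree < 2 contribute 0), and — when `modules` is
#' supplied — modularity Q and the number of modules with >= 5 nodes.
#'
#' @param network An [igraph] graph with a `sign` edge attribute (edges
#'   without one count as positive).
#' @param modules Optional result of [detect_modules()].
#' @return Named list (class `"topology_report"`).
#' @export
topology_report <- function(network, modules = NULL) {
  stopifnot(inherits(network, "igraph"))
  N <- igraph::vcount(network)
  E <- igraph::ecount(network)
  if (N == 0) {
    warning("empty network: reporting zeros")
    rep0 <- topology_summary(0, 0, 0, 0)
    return(structure(c(rep0, list(avg_path_distance = NA_real_,
                                  avg_clustering = NA_real_,
                                  n_modules_ge5 = 0L, modularity = NA_real_)),
                     class = "topology_report"))
  }
  sgn <- igraph::E(network)$sign %||% rep(1L, E)
  base <- topology_summary(N, E, sum(sgn > 0), sum(sgn < 0))
  gd <- if (E > 0) igraph::mean_distance(network, weights = NA, directed = FALSE,
                                         unconnected = TRUE) else NA_real_
  cc <- igraph::transitivity(network, type = "local", isolates = "zero")
  structure(c(base, list(
    avg_path_distance = gd,
    avg_clustering = if (N > 0) mean(cc) else NA_real_,
    n_modules_ge5 = if (!is.null(modules)) modules$n_modules_ge5 else NA_integer_,
    modularity = if (!is.null(modules)) modules$modularity else NA_real_)),
    class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("Topology report\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm,
                if (is.numeric(v) && !is.na(v)) format(round(v, 4)) else v))
  }
  invisible(x)
}

#' Detect network modules and modularity
#'
#' Community detection on the unsigned graph (edge weights `|rho|`), greedy
#' modularity optimisation by default or multi-level Louvain. Returns
#' Newman's modularity `Q = sum_m (e_mm - a_m^2)` for the chosen partition
#' and the count of modules with at least 5 nodes (the convention of
#' published topology tables).
#'
#' @param network An [igraph] graph; a `weight` edge attribute, if present,
#'   is used as `|weight|`.
#' @param method `"greedy"` (default) or `"louvain"`.
#' @param seed Integer seed (Louvain is stochastic; greedy is
#'   deterministic).
#' @return List with `membership` (named integer vector), `modularity`,
#'   `n_modules`, `n_modules_ge5`.
#' @export
detect_modules <- function(network, method = c("greedy", "louvain"),
                           seed = 1) {
  stopifnot(inherits(network, "igraph"))
  method <- match.arg(method)
  if (igraph::vcount(network) == 0) {
    return(list(membership = integer(0), modularity = NA_real_,
                n_modules = 0L, n_modules_ge5 = 0L))
  }
  w <- igraph::E(network)$weight
  w <- if (is.null(w)) NULL else abs(w)
  g <- network
  if (!is.null(w)) igraph::E(g)$weight <- w
  cl <- with_seed(seed, switch(method,
    greedy = igraph::cluster_fast_greedy(g, weights = w),
    louvain = igraph::cluster_louvain(g, weights = w)))
  memb <- igraph::membership(cl)
  sizes <- table(memb)
  list(membership = memb,
       modularity = igraph::modularity(g, memb, weights = w),
       n_modules = length(sizes),
       n_modules_ge5 = sum(sizes >= 5))
}

#' Within-module degree (z) and participation coefficient (c) node roles
#'
#' `z_i` standardises node i's within-module degree against the nodes of its
#' own module; `c_i = 1 - sum_m (k_im / k_i)^2` measures how evenly i's
#' links spread over modules. Degrees are unweighted. Classification uses
#' the conventional keystone thresholds: z > 2.5 & c > 0.6 network hub,
#' z > 2.5 & c < 0.6 module hub, z < 2.5 & c > 0.6 connector, otherwise
#' peripheral (exact boundary values fall to the lower category, matching
#' the strict inequalities). Modules with zero degree spread (sd = 0) give
#' z = 0 for their nodes.
#'
#' @param network An [igraph] graph.
#' @param modules Result of [detect_modules()] (or a named membership
#'   vector).
#' @param z_threshold,c_threshold Role thresholds (defaults 2.5 and 0.6).
#' @return Data frame: `taxon`, `module`, `degree`, `z`, `c`, `category`.
#' @export
zc_scores <- function(network, modules, z_threshold = 2.5,
                      c_threshold = 0.6) {
  stopifnot(inherits(network, "igraph"))
  memb <- if (is.list(modules)) modules$membership else modules
  nodes <- igraph::V(network)$name %||% as.character(seq_len(igraph::vcount(network)))
  if (!all(nodes %in% names(memb))) stop("every node needs a module assignment")
  memb <- memb[nodes]
  adj <- igraph::as_adjacency_matrix(network, sparse = FALSE)
  adj <- (adj != 0) * 1
  k <- rowSums(adj)
  mods <- sort(unique(memb))
  # k_im: links of node i into module m
  kim <- vapply(mods, function(m) rowSums(adj[, memb == m, drop = FALSE]),
                numeric(length(nodes)))
  kin <- kim[cbind(seq_along(nodes), match(memb, mods))]
  z <- numeric(length(nodes))
  for (m in mods) {
    sel <- memb == m
    mu <- mean(kin[sel])
    sdv <- stats::sd(kin[sel])
    z[sel] <- if (is.na(sdv) || sdv == 0) 0 else (kin[sel] - mu) / sdv
  }
  cpart <- ifelse(k > 0, 1 - rowSums((kim / pmax(k, 1))^2), 0)
  category <- ifelse(z > z_threshold & cpart > c_threshold, "network hub",
              ifelse(z > z_threshold, "module hub",
              ifelse(cpart > c_threshold, "connector", "peripheral")))
  data.frame(taxon = nodes, module = as.integer(memb), degree = k,
             z = z, c = cpart, category = category,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Natural connectivity of a graph
#'
#' `ln[(1/N) sum_i exp(lambda_i)]` over the eigenvalues of the unsigned,
#' unweighted adjacency matrix — the log of the average closed-walk
#' generating function, a spectral robustness measure. Computed with an
#' overflow-safe log-sum-exp; non-negative for any simple graph (Jensen,
#' since the eigenvalues sum to 0).
#'
#' @param network An [igraph] graph (or a square adjacency matrix).
#' @return Scalar natural connectivity (nats).
#' @export
natural_connectivity <- function(network) {
  adj <- if (inherits(network, "igraph")) {
    igraph::as_adjacency_matrix(network, sparse = FALSE)
  } else as.matrix(network)
  if (nrow(adj) == 0) stop("natural connectivity undefined for an empty graph")
  adj <- (adj != 0) * 1
  lam <- eigen(adj, symmetric = TRUE, only.values = TRUE)$values
  m <- max(lam)
  m + log(mean(exp(lam - m)))
}

#' Robustness under targeted node removal
#'
#' Betweenness centrality is computed once on the full (unsigned,
#' unweighted) network; nodes are then removed one at a time in descending
#' betweenness (ties broken by node name) and natural connectivity is
#' recorded after each removal, giving an `n_nodes + 1`-point curve from the
#' intact graph down to the empty graph (natural connectivity 0). The
#' trapezoidal area under the curve over the removed fraction summarises
#' robustness as one scalar.
#'
#' @param network An [igraph] graph with >= 1 node.
#' @param recompute Recompute betweenness after every removal instead of
#'   using the initial static ranking (default `FALSE`).
#' @return List with `curve` (data frame: `step`, `removed_fraction`,
#'   `natural_connectivity`, `removed_node`) and `auc`.
#' @export
robustness_curve <- function(network, recompute = FALSE) {
  stopifnot(inherits(network, "igraph"))
  N <- igraph::vcount(network)
  if (N < 1) stop("network must have >= 1 node")
  if (is.null(igraph::V(network)$name)) {
    igraph::V(network)$name <- as.character(seq_len(N))
  }
  g <- network
  nc <- numeric(N + 1)
  removed <- character(N)
  nc[1] <- natural_connectivity(g)
  if (!recompute) {
    btw <- igraph::betweenness(g, weights = NA)
    order_names <- igraph::V(g)$name[order(-btw, igraph::V(g)$name)]
  }
  for (step in seq_len(N)) {
    target <- if (recompute) {
      b <- igraph::betweenness(g, weights = NA)
      igraph::V(g)$name[order(-b, igraph::V(g)$name)][1]
    } else order_names[step]
    g <- igraph::delete_vertices(g, target)
    removed[step] <- target
    nc[step + 1] <- if (igraph::vcount(g) > 0) natural_connectivity(g) else 0
  }
  frac <- seq(0, N) / N
  curve <- data.frame(step = seq(0, N), removed_fraction = frac,
                      natural_connectivity = nc,
                      removed_node = c(NA_character_, removed),
                      stringsAsFactors = FALSE)
  auc <- sum(diff(frac) * (utils::head(nc, -1) + utils::tail(nc, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Community cohesion
#'
#' Quantifies sample-level connectivity from null-corrected pairwise taxon
#' correlations. Counts are closed to relative abundances; observed Pearson
#' correlations `r_ij` across samples are corrected by subtracting their
#' expectation under a null that independently shuffles each taxon's
#' abundances across samples (`n_null_iter` iterations). Each taxon's
#' positive (negative) connectedness is the mean of its positive (negative)
#' corrected correlations; sample cohesion is the abundance-weighted sum
#' `cohesion_s = sum_i a_is * connectedness_i`, split by sign, so
#' `cohesion+ >= 0` and `cohesion- <= 0` by construction.
#'
#' @param table Count table.
#' @param n_null_iter Null shuffling iterations (default 200).
#' @param seed Integer seed.
#' @return List with `connectedness` (data frame: `taxon`, `pos`, `neg`) and
#'   `cohesion` (data frame: `sample_id`, `pos`, `neg`). Constant
#'   (zero-variance) taxa are excluded with a warning.
#' @export
cohesion <- function(table, n_null_iter = 200, seed = 1) {
  validate_count_table(table, require_integer = FALSE)
  if (n_null_iter < 1) stop("n_null_iter must be >= 1")
  if (ncol(table) < 3) stop("cohesion needs >= 3 samples")
  ra <- rel_abund(table)
  keep <- apply(ra, 1, stats::var) > 0
  if (any(!keep)) {
    warning("excluding ", sum(!keep), " constant taxon/taxa: ",
            paste(rownames(ra)[!keep], collapse = ", "))
    ra <- ra[keep, , drop = FALSE]
  }
  p <- nrow(ra)
  if (p < 2) stop("need >= 2 non-constant taxa")
  robs <- stats::cor(t(ra))
  rnull <- matrix(0, p, p)
  with_seed(seed, {
    for (it in seq_len(n_null_iter)) {
      shuf <- t(apply(ra, 1, sample))
      rnull <- rnull + stats::cor(t(shuf))
    }
  })
  rhat <- robs - rnull / n_null_iter
  diag(rhat) <- NA
  conn_pos <- apply(rhat, 1, function(r) {
    r <- r[!is.na(r) & r > 0]
    if (length(r)) mean(r) else 0
  })
  conn_neg <- apply(rhat, 1, function(r) {
    r <- r[!is.na(r) & r < 0]
    if (length(r)) mean(r) else 0
  })
  coh_pos <- colSums(ra * conn_pos)
  coh_neg <- colSums(ra * conn_neg)
  list(connectedness = data.frame(taxon = rownames(ra), pos = conn_pos,
                                  neg = conn_neg, row.names = NULL,
                                  stringsAsFactors = FALSE),
       cohesion = data.frame(sample_id = colnames(ra), pos = coh_pos,
                             neg = coh_neg, row.names = NULL,
                             stringsAsFactors = FALSE))
}
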