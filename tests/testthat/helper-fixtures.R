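# Small fixtures shared across test files; everything is built in code.

toy_table <- function() {
  m <- matrix(c(2L, 0L, 1L,
                1L, 1L, 0L,
                0L, 3L, 2L,
                4L, 2L, 5L),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("t", 1:4), paste0("s", 1:3)))
  m
}

two_tip_tree <- function() ape::read.tree(text = "(t1:1,t2:1);")

# Signed correlation matrix with a known qualifying edge set.
toy_corr <- function() {
  m <- diag(4)
  m[1, 2] <- m[2, 1] <- 0.9
  m[3, 4] <- m[4, 3] <- -0.5
  m[1, 3] <- m[3, 1] <- 0.1
  dimnames(m) <- list(paste0("t", 1:4), paste0("t", 1:4))
  m
}

# Two disconnected 5-cliques, a classic closed-form modularity case.
two_cliques <- function() {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  igraph::V(g)$name <- paste0("n", 1:10)
  igraph::E(g)$weight <- 1
  igraph::E(g)$sign <- 1L
  g
}

random_signed_graph <- function(n, m, seed, n_pos = NULL) {
  set.seed(seed)
  g <- igraph::sample_gnm(n, m)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  if (is.null(n_pos)) n_pos <- rbinom(1, m, 0.6)
  sgn <- sample(rep(c(1L, -1L), c(n_pos, m - n_pos)))
  igraph::E(g)$weight <- sgn * runif(m, 0.3, 1)
  igraph::E(g)$sign <- sgn
  g
}
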