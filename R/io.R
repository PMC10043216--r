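#' Read a taxa-by-samples count table from TSV
#'
#' Expects taxon ids in the first column and sample ids in the header row;
#' the orientation follows the amplicon convention (taxa as rows). Duplicate
#' ids, negative values, and non-integer cells are rejected.
#'
#' @param path Path to a tab-separated file.
#' @return Integer matrix (taxa x samples) with dimnames.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2) stop("parse error in ", path,
                         ": need a taxon-id column plus >= 1 sample column")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate taxon id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop("parse error in ", path, ": non-numeric values in column '",
         names(df)[bad + 1], "'")
  }
  rownames(m) <- ids
  validate_count_table(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count table as TSV
#'
#' @param table Count table (taxa x samples).
#' @param path Output path.
#' @param id_column Name of the taxon-id column (default `"taxon_id"`).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, id_column = "taxon_id") {
  validate_count_table(table)
  df <- data.frame(rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table from a BIOM file
#'
#' Optional reader for the BIOM interchange format; requires the
#' `biomformat` package. TSV remains the canonical format.
#'
#' @param path Path to a BIOM file.
#' @return Integer matrix (taxa x samples).
#' @export
read_count_table_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("the 'biomformat' package is required to read BIOM files")
  }
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  validate_count_table(m)
  storage.mode(m) <- "integer"
  m
}

#' Read sample metadata from TSV
#'
#' @param path Path to a tab-separated file with a `sample_id` column and a
#'   group column; remaining numeric columns are treated as environmental
#'   variables.
#' @param group_column Name of the group column (default `"group"`).
#' @return Data frame with at least `sample_id` and `group`.
#' @export
read_metadata <- function(path, group_column = "group") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (!"sample_id" %in% names(df)) stop("metadata needs a 'sample_id' column")
  if (!group_column %in% names(df)) {
    stop("metadata needs a '", group_column, "' column")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  if (any(!nzchar(df[[group_column]]))) stop("empty group label(s) in metadata")
  names(df)[names(df) == group_column] <- "group"
  df
}

#' Read a rooted phylogeny from a Newick file
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object with branch lengths.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("parse error: '", path, "' is not valid Newick")
  }
  if (is.null(tree$edge.length)) {
    stop("tree in '", path, "' has no branch lengths")
  }
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  tree
}

#' Check that a tree covers the taxa of a count table
#'
#' @param table Count table.
#' @param tree Phylogeny.
#' @return Invisibly `TRUE`; errors listing missing taxa otherwise.
#' @keywords internal
check_tree_coverage <- function(table, tree) {
  missing <- setdiff(rownames(table), tree$tip.label)
  if (length(missing)) {
    stop("taxa absent from the tree: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  }
  invisible(TRUE)
}

#' Write a signed network to disk
#'
#' `edgelist-tsv` writes a four-column table (`from`, `to`, `weight`,
#' `sign`); `graphml` delegates to [igraph::write_graph()] and carries any
#' node attributes present (module id, role category).
#'
#' @param network An [igraph] graph with edge attributes `weight` and `sign`.
#' @param path Output path.
#' @param format `"edgelist-tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("edgelist-tsv", "graphml")) {
  if (!inherits(network, "igraph")) stop("network must be an igraph graph")
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(network, names = TRUE)
    w <- igraph::E(network)$weight %||% rep(1, igraph::ecount(network))
    df <- data.frame(from = el[, 1], to = el[, 2], weight = w,
                     sign = ifelse(w >= 0, 1L, -1L),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a signed network from an edge-list TSV
#'
#' @param path Path written by [write_network()] with format
#'   `"edgelist-tsv"`.
#' @return An igraph graph with `weight` and `sign` edge attributes.
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("from", "to", "weight")
  if (!all(need %in% names(df))) {
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(df[, c("from", "to")], directed = FALSE)
  igraph::E(g)$weight <- df$weight
  igraph::E(g)$sign <- ifelse(df$weight >= 0, 1L, -1L)
  g
}
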