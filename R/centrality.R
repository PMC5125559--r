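#' Subgraph centrality
#'
#' The subgraph centrality of a node u counts the closed walks starting and
#' ending at u, weighting walks of length k by 1/k!; it equals the u-th
#' diagonal entry of the matrix exponential of the adjacency matrix and is
#' computed here from the spectrum, SC(u) = sum_j (v_ju)^2 exp(lambda_j).
#' The computation is done per connected component with a dense symmetric
#' eigendecomposition; isolated nodes get exactly 1. Components larger than
#' `dense_limit` nodes fall back to the truncated closed-walk series
#' sum_{k<=60} (A^k)_uu / k! with a warning, to bound memory on
#' interactome-scale graphs.
#'
#' @param graph An [interactome()].
#' @param dense_limit Largest component size handled by dense
#'   eigendecomposition (default 3000).
#' @return A tibble with columns `protein_id` and `sc` (`sc >= 1`).
#' @export
#' @examples
#' g <- interactome(tibble::tibble(protein1 = "a", protein2 = "b"))
#' subgraph_centrality(g) # both nodes: cosh(1)
subgraph_centrality <- function(graph, dense_limit = 3000) {
  stopifnot(inherits(graph, "interactome"))
  n <- length(graph$nodes)
  if (n == 0) return(tibble(protein_id = character(), sc = numeric()))
  ig <- as_igraph(graph)
  comp <- igraph::components(ig)
  sc <- setNames(rep(1.0, n), graph$nodes)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    if (length(members) == 1) next # isolated node: exp(0) = 1
    sub <- igraph::induced_subgraph(ig, members)
    A <- as.matrix(igraph::as_adjacency_matrix(sub, sparse = TRUE))
    if (nrow(A) <= dense_limit) {
      es <- eigen(A, symmetric = TRUE)
      vals <- as.vector((es$vectors^2) %*% exp(es$values))
    } else {
      warn(sprintf("component of %d nodes exceeds dense_limit; using truncated series", nrow(A)))
      vals <- closed_walk_series(A, k_max = 60)
    }
    sc[igraph::V(sub)$name] <- vals
  }
  tibble(protein_id = graph$nodes, sc = unname(sc[graph$nodes]))
}

# truncated closed-walk series sum_k diag(A^k)/k!
closed_walk_series <- function(A, k_max = 60) {
  term <- diag(nrow(A))
  acc <- rep(1.0, nrow(A))
  for (k in seq_len(k_max)) {
    term <- (A %*% term) / k
    acc <- acc + diag(term)
  }
  acc
}

#' Betweenness centrality
#'
#' The fraction of shortest paths between other node pairs that pass through
#' each node, with endpoint-excluding normalization 2/((n-1)(n-2)) so values
#' lie in [0, 1]. Pairs in different components contribute 0. Graphs with
#' fewer than three nodes have no intermediate routing, so all values are 0.
#'
#' @param graph An [interactome()].
#' @return A tibble with columns `protein_id` and `bc` in `[0, 1]`.
#' @export
betweenness_centrality <- function(graph) {
  stopifnot(inherits(graph, "interactome"))
  n <- length(graph$nodes)
  if (n == 0) return(tibble(protein_id = character(), bc = numeric()))
  if (n < 3) return(tibble(protein_id = graph$nodes, bc = rep(0.0, n)))
  bc <- igraph::betweenness(as_igraph(graph), directed = FALSE, normalized = TRUE)
  tibble(protein_id = graph$nodes, bc = unname(bc[graph$nodes]))
}

#' Centrality table for every protein in a graph
#'
#' @param graph An [interactome()].
#' @inheritParams subgraph_centrality
#' @return A tibble of class `dti_centrality` with columns
#'   `protein_id`, `sc`, `bc`.
#' @export
centrality_table <- function(graph, dense_limit = 3000) {
  out <- left_join(
    subgraph_centrality(graph, dense_limit = dense_limit),
    betweenness_centrality(graph),
    by = "protein_id"
  )
  class(out) <- c("dti_centrality", class(out))
  out
}

#' Prioritize drug targets from centrality records
#'
#' Implements the bottleneck heuristic: keep proteins whose subgraph
#' centrality strictly exceeds `sc_min`, sort by betweenness centrality
#' descending, and truncate to the top `k`. Ties are broken by `sc`
#' descending, then `protein_id` ascending, so output order is deterministic.
#'
#' @param records A data frame with columns `protein_id`, `sc`, `bc`.
#' @param sc_min Strict lower bound on subgraph centrality (default `1e23`,
#'   the threshold used for the MRSA COL interactome).
#' @param k Maximum shortlist length (default 10).
#' @return A tibble of class `dti_shortlist`, ordered by `bc` descending.
#' @export
prioritize_targets <- function(records, sc_min = 1e23, k = 10) {
  stopifnot(sc_min > 0, k >= 0)
  records <- as_tibble(records)
  stopifnot(all(c("protein_id", "sc", "bc") %in% names(records)))
  out <- filter(records, .data$sc > sc_min)
  out <- arrange(out, desc(.data$bc), desc(.data$sc), .data$protein_id)
  out <- slice_head(out, n = k)
  class(out) <- c("dti_shortlist", class(out))
  out
}

#' Write a target shortlist as TSV
#'
#' Columns `protein_id`, `sc` (scientific notation, 3 significant digits) and
#' `bc` (4 decimals), matching the conventional presentation of centrality
#' tables.
#'
#' @param shortlist A tibble from [prioritize_targets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shortlist <- function(shortlist, path) {
  df <- tibble(
    protein_id = shortlist$protein_id,
    sc = sprintf("%.2E", shortlist$sc),
    bc = sprintf("%.4f", shortlist$bc)
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @export
autoplot.dti_centrality <- function(object, sc_min = NULL, ...) {
  p <- ggplot(object, aes(x = .data$sc, y = .data$bc)) +
    geom_point(alpha = 0.6) +
    scale_x_log10() +
    labs(
      x = "subgraph centrality (log scale)",
      y = "betweenness centrality",
      title = "Interactome centrality map"
    ) +
    theme_minimal()
  p
}
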