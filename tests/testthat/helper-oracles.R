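# Independent oracles used to check the centrality implementations.

# adjacency matrix of an interactome, in node order
adjacency_of <- function(graph) {
  n <- length(graph$nodes)
  A <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    A[e$protein1[i], e$protein2[i]] <- 1
    A[e$protein2[i], e$protein1[i]] <- 1
  }
  A
}

# truncated closed-walk series sum_k diag(A^k)/k! (independent of the
# eigendecomposition route used by the package)
oracle_subgraph_centrality <- function(graph, k_max = 60) {
  A <- adjacency_of(graph)
  term <- diag(nrow(A))
  acc <- rep(1.0, nrow(A))
  for (k in seq_len(k_max)) {
    term <- (A %*% term) / k
    acc <- acc + diag(term)
  }
  setNames(acc, graph$nodes)
}

# exhaustive shortest-path enumeration betweenness (endpoint-excluding,
# normalized by 2/((n-1)(n-2))); practical for n <= 7
oracle_betweenness <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  if (n < 3) return(setNames(rep(0, n), nodes))
  A <- adjacency_of(graph)
  all_paths <- function(s, t) {
    found <- list()
    walk <- function(path) {
      v <- path[[length(path)]]
      if (v == t) { found[[length(found) + 1L]] <<- path; return(invisible()) }
      for (w in which(A[v, ] == 1)) {
        if (!w %in% path) walk(c(path, w))
      }
    }
    walk(s)
    found
  }
  bc <- setNames(rep(0, n), nodes)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
        bc[v] <- bc[v] + through / sigma
      }
    }
  }
  bc * 2 / ((n - 1) * (n - 2))
}
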