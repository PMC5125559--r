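#' Protein-protein interaction graphs
#'
#' An `interactome` is a simple undirected graph over protein identifiers:
#' no self-loops, no duplicate edges, every edge endpoint present in the node
#' set. Edges may carry an optional confidence score (STRING-style, 0-1000).
#'
#' @param edges A data frame with character columns `protein1`, `protein2` and
#'   an optional numeric `score`.
#' @param nodes Optional character vector of node identifiers; defaults to the
#'   identifiers appearing in `edges`. Extra identifiers become isolated nodes.
#' @return An object of class `interactome`.
#' @export
#' @examples
#' g <- interactome(tibble::tibble(protein1 = c("a", "b"), protein2 = c("b", "c")))
#' g
interactome <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  if (nrow(edges) == 0 && !all(c("protein1", "protein2") %in% names(edges))) {
    edges <- tibble(protein1 = character(), protein2 = character())
  }
  stopifnot(all(c("protein1", "protein2") %in% names(edges)))
  if (!"score" %in% names(edges)) edges$score <- NA_real_
  edges <- mutate(edges,
    a = pmin(.data$protein1, .data$protein2),
    b = pmax(.data$protein1, .data$protein2)
  )
  edges <- filter(edges, .data$a != .data$b)
  edges <- edges[!duplicated(edges[c("a", "b")]), , drop = FALSE]
  edges <- tibble(protein1 = edges$a, protein2 = edges$b, score = edges$score)
  nodes <- sort(unique(c(nodes, edges$protein1, edges$protein2)))
  structure(list(nodes = nodes, edges = edges), class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome: %d nodes, %d edges>\n", length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
as_tibble.interactome <- function(x, ...) x$edges

# internal: igraph view of an interactome (vertex order = x$nodes)
as_igraph <- function(x) {
  igraph::graph_from_data_frame(
    x$edges[c("protein1", "protein2")],
    directed = FALSE,
    vertices = data.frame(name = x$nodes)
  )
}

#' Parse a STRING-style protein links file
#'
#' Reads whitespace-separated `protein1 protein2 combined_score` edge lists
#' (the STRING `protein.links` dialect). A single header line starting with
#' `protein1` is skipped. Self-loops are dropped, duplicate and reversed
#' duplicate edges collapse to one, and edges scoring below `min_score` are
#' excluded (the retention rule is `score >= min_score`).
#'
#' @param path Path to the edge-list file.
#' @param min_score Minimum combined score to retain an edge (default 0,
#'   i.e. no thresholding).
#' @return An [interactome()].
#' @export
parse_string_links <- function(path, min_score = 0) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(interactome(tibble(protein1 = character(), protein2 = character())))
  if (grepl("^\\s*protein1\\b", lines[[1]])) lines <- lines[-1]
  if (length(lines) == 0) return(interactome(tibble(protein1 = character(), protein2 = character())))
  parts <- strsplit(trimws(lines), "\\s+")
  nfield <- lengths(parts)
  bad <- which(nfield < 2)
  if (length(bad) > 0) {
    abort(sprintf("malformed edge line %d: %s", bad[[1]], lines[[bad[[1]]]]))
  }
  score <- map_dbl(parts, function(p) {
    if (length(p) >= 3) suppressWarnings(as.numeric(p[[3]])) else NA_real_
  })
  badscore <- which(lengths(parts) >= 3 & is.na(score))
  if (length(badscore) > 0) {
    abort(sprintf("malformed score on line %d: %s", badscore[[1]], lines[[badscore[[1]]]]))
  }
  edges <- tibble(
    protein1 = map_chr(parts, 1),
    protein2 = map_chr(parts, 2),
    score = score
  )
  keep <- is.na(edges$score) | edges$score >= min_score
  interactome(edges[keep, , drop = FALSE])
}

#' Restrict a graph to a set of nodes
#'
#' Returns the induced subgraph on the intersection of the graph's nodes with
#' `keep`; edges losing either endpoint are dropped. Used to restrict a STRING
#' interactome to reviewed (Swiss-Prot) proteins.
#'
#' @param graph An [interactome()].
#' @param keep Character vector of node identifiers to retain.
#' @return An [interactome()].
#' @export
restrict_to_nodes <- function(graph, keep) {
  stopifnot(inherits(graph, "interactome"))
  nodes <- intersect(graph$nodes, keep)
  edges <- filter(graph$edges, .data$protein1 %in% nodes & .data$protein2 %in% nodes)
  interactome(edges, nodes = nodes)
}

#' Write an interactome as a STRING-style links file
#'
#' @param graph An [interactome()].
#' @param path Output path.
#' @param score Default score written when an edge has none.
#' @return `path`, invisibly.
#' @export
write_string_links <- function(graph, path, score = 999) {
  stopifnot(inherits(graph, "interactome"))
  e <- graph$edges
  s <- ifelse(is.na(e$score), score, e$score)
  lines <- c(
    "protein1 protein2 combined_score",
    sprintf("%s %s %d", e$protein1, e$protein2, as.integer(s))
  )
  writeLines(lines, path)
  invisible(path)
}
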