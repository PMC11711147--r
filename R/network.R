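#' Build a PPI graph from a scored edge list
#'
#' Self-loops are dropped, duplicate edges (in either orientation) are
#' collapsed keeping the maximum combined score, and only edges with a
#' score strictly greater than `score_cutoff` are retained. Nodes without a
#' surviving edge do not appear in the graph.
#'
#' @param edges Data.frame `node_a, node_b, combined_score` (see
#'   [read_ppi_table()]).
#' @param score_cutoff Strict lower bound on the combined score. Default 0.4.
#' @return An undirected simple `igraph` graph with edge attribute
#'   `combined_score`.
#' @export
build_graph <- function(edges, score_cutoff = 0.4) {
  e <- edges[edges$node_a != edges$node_b, , drop = FALSE]
  kept <- numeric(0)
  if (nrow(e)) {
    a <- pmin(e$node_a, e$node_b)
    b <- pmax(e$node_a, e$node_b)
    score <- tapply(e$combined_score, paste(a, b, sep = "\r"), max)
    kept <- score[score > score_cutoff]
  }
  if (!length(kept))
    return(igraph::make_empty_graph(0, directed = FALSE))
  pairs <- do.call(rbind, strsplit(names(kept), "\r", fixed = TRUE))
  igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2],
               combined_score = as.numeric(kept), stringsAsFactors = FALSE),
    directed = FALSE)
}

#' MCODE vertex weights
#'
#' The weight of a vertex v is k * d, where k is the highest k-core number
#' found in the subgraph induced by v's closed neighborhood N[v], and d is
#' the density (2E / (n(n-1))) of that highest k-core. Vertices with no
#' neighbors get weight 0.
#'
#' @param graph An undirected simple `igraph` graph.
#' @return A named numeric vector of weights (one per vertex).
#' @export
mcode_vertex_weights <- function(graph) {
  vnames <- igraph::V(graph)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(igraph::vcount(graph)))
  w <- stats::setNames(numeric(igraph::vcount(graph)), vnames)
  if (igraph::vcount(graph) == 0) return(w)
  adj <- igraph::adjacent_vertices(graph, igraph::V(graph))
  for (i in seq_along(w)) {
    nb <- c(i, as.integer(adj[[i]]))
    if (length(nb) < 2) next
    sub <- igraph::induced_subgraph(graph, nb)
    core <- igraph::coreness(sub)
    k <- max(core)
    if (k == 0) next
    core_vs <- which(core == k)
    core_sub <- igraph::induced_subgraph(sub, core_vs)
    nc <- igraph::vcount(core_sub)
    dens <- if (nc < 2) 0 else
      2 * igraph::ecount(core_sub) / (nc * (nc - 1))
    w[i] <- k * dens
  }
  w
}

#' MCODE complex detection
#'
#' Seeds at the highest-weight unvisited vertex and grows the complex
#' outward in breadth-first order, admitting an unvisited neighbor whenever
#' its weight is at least `seed_weight * (1 - vwp)` (vertex weight
#' percentage). Each vertex joins at most one complex. Haircut
#' post-processing replaces each complex by its 2-core (removing
#' singly-connected members); a complex whose 2-core is empty — the minimal
#' single-edge complex — is kept as grown. Complexes with fewer than two
#' members are discarded. Results are ranked by score = 2E/(n-1)
#' descending, ties broken by size (descending) then seed id.
#'
#' @param graph An undirected simple `igraph` graph.
#' @param weights Vertex weights from [mcode_vertex_weights()]; computed if
#'   missing.
#' @param vwp Vertex weight percentage in [0, 1). Default 0.2.
#' @param haircut Apply haircut post-processing. Default TRUE.
#' @return A list of clusters, each a list with `seed`, `members` (sorted),
#'   `n`, `edge_count`, `density`, `score`; ordered by rank.
#' @export
mcode_find_clusters <- function(graph, weights = NULL, vwp = 0.2,
                                haircut = TRUE) {
  stopifnot(vwp >= 0, vwp < 1)
  if (igraph::vcount(graph) == 0) return(list())
  if (is.null(weights)) weights <- mcode_vertex_weights(graph)
  vnames <- names(weights)
  # deterministic seed order: weight desc, name asc
  order_idx <- order(-weights, vnames)
  visited <- stats::setNames(rep(FALSE, length(weights)), vnames)
  adj <- igraph::adjacent_vertices(graph, igraph::V(graph))
  clusters <- list()
  for (s in order_idx) {
    if (visited[s]) next
    threshold <- weights[s] * (1 - vwp)
    members <- s
    visited[s] <- TRUE
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nbs <- as.integer(adj[[v]])
      nbs <- nbs[order(vnames[nbs])]
      for (u in nbs) {
        if (!visited[u] && weights[u] >= threshold) {
          visited[u] <- TRUE
          members <- c(members, u)
          queue <- c(queue, u)
        }
      }
    }
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(graph, members)
    if (haircut) {
      core <- igraph::coreness(sub)
      keep <- which(core >= 2)
      if (length(keep) >= 2) {
        sub <- igraph::induced_subgraph(sub, keep)
        members <- members[keep]
      }
      # empty 2-core: keep the grown complex (minimal K2 case)
    }
    n <- length(members)
    E <- igraph::ecount(sub)
    if (n < 2 || E == 0) next
    clusters[[length(clusters) + 1L]] <- list(
      seed = vnames[s],
      members = sort(vnames[members]),
      n = n, edge_count = E,
      density = 2 * E / (n * (n - 1)),
      score = cluster_score(n, E))
  }
  ord <- order(-vapply(clusters, `[[`, numeric(1), "score"),
               -vapply(clusters, `[[`, numeric(1), "n"),
               vapply(clusters, `[[`, character(1), "seed"))
  clusters[ord]
}

#' MCODE cluster score
#'
#' The score of a complex with n nodes and E internal edges is its density
#' times its size: (2E / (n(n-1))) * n = 2E / (n - 1).
#'
#' @param n Number of nodes (>= 2).
#' @param E Number of internal edges (0 <= E <= n(n-1)/2).
#' @return The score 2E/(n-1).
#' @export
cluster_score <- function(n, E) {
  if (n < 2) stop("a cluster needs at least 2 nodes")
  if (E < 0 || E > n * (n - 1) / 2) stop("impossible edge count")
  2 * E / (n - 1)
}

#' Flatten MCODE clusters to a table
#'
#' @param clusters Result of [mcode_find_clusters()].
#' @return A data.frame `rank, seed, n, edge_count, density, score, members`
#'   (members semicolon-joined).
#' @export
clusters_table <- function(clusters) {
  if (!length(clusters))
    return(data.frame(rank = integer(), seed = character(), n = integer(),
                      edge_count = integer(), density = numeric(),
                      score = numeric(), members = character(),
                      stringsAsFactors = FALSE))
  data.frame(rank = seq_along(clusters),
             seed = vapply(clusters, `[[`, character(1), "seed"),
             n = vapply(clusters, function(x) as.integer(x$n), integer(1)),
             edge_count = vapply(clusters, function(x)
               as.integer(x$edge_count), integer(1)),
             density = vapply(clusters, `[[`, numeric(1), "density"),
             score = vapply(clusters, `[[`, numeric(1), "score"),
             members = vapply(clusters, function(x)
               paste(x$members, collapse = ";"), character(1)),
             stringsAsFactors = FALSE)
}
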