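# Co-occurrence networks over taxa: correlation-threshold edges, greedy
# modularity modules, stress centrality.

#' Build a co-occurrence network from an OTU table
#'
#' Taxa are optionally aggregated to order level, filtered to those present in
#' at least `min_prevalence` sites, converted to relative abundances, and
#' correlated pairwise across sites; an edge joins two taxa when the absolute
#' correlation reaches the threshold. Constant (zero-variance) taxa are
#' excluded and reported.
#'
#' @param table an [otu_table()].
#' @param min_prevalence minimum number of sites a taxon must occur in
#'   (default 7).
#' @param threshold minimum `|r|` for an edge (default 0.8; the threshold is a
#'   fixed design parameter, configurable).
#' @param method `"pearson"` or `"spearman"`.
#' @param level `"order"` (sum counts by taxonomy order before correlating) or
#'   `"otu"`.
#' @param sites optional logical/character selector restricting the sites used.
#' @return object of class `cooccurrence_network`: list with `nodes`,
#'   `edges` (data.frame `from`, `to`, `r`, `sign`), `graph` (igraph object),
#'   `excluded` (constant taxa), and the filter settings.
#' @export
build_network <- function(table, min_prevalence = 7, threshold = 0.8,
                          method = c("pearson", "spearman"),
                          level = c("order", "otu"), sites = NULL) {
  method <- match.arg(method)
  level <- match.arg(level)
  cnt <- table$counts
  if (!is.null(sites)) {
    if (is.character(sites)) sites <- rownames(cnt) %in% sites
    cnt <- cnt[sites, , drop = FALSE]
  }
  if (nrow(cnt) < 4) stop("need at least four sites to correlate")
  if (level == "order") {
    ord <- table$taxonomy$order[match(colnames(cnt), table$taxonomy$otu)]
    cnt <- t(rowsum(t(cnt), group = ord))
  }
  keep <- colSums(cnt > 0) >= min_prevalence
  cnt <- cnt[, keep, drop = FALSE]
  if (ncol(cnt) < 2) stop("prevalence filter left fewer than two taxa")
  rel <- cnt / rowSums(cnt)
  constant <- apply(rel, 2, stats::sd) == 0
  excluded <- colnames(rel)[constant]
  if (length(excluded))
    message("excluding constant taxa: ", paste(excluded, collapse = ", "))
  rel <- rel[, !constant, drop = FALSE]
  cm <- stats::cor(rel, method = method)
  ut <- which(upper.tri(cm) & abs(cm) >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = colnames(rel)[ut[, 1]],
                      to = colnames(rel)[ut[, 2]],
                      r = cm[ut],
                      sign = ifelse(cm[ut] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE,
                                     vertices = data.frame(name = colnames(rel)))
  structure(list(nodes = colnames(rel), edges = edges, graph = g,
                 excluded = excluded, threshold = threshold, method = method,
                 min_prevalence = min_prevalence, level = level),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network: %d nodes, %d edges (|%s r| >= %g)\n",
              length(x$nodes), nrow(x$edges), x$method, x$threshold))
  invisible(x)
}

#' Build a network directly from an edge list (toy graphs, import)
#' @param edges data.frame with columns `from`, `to` (and optionally `r`).
#' @param nodes optional node names (isolated nodes allowed).
#' @return a `cooccurrence_network`.
#' @export
network_from_edges <- function(edges, nodes = NULL) {
  if (is.null(edges$r)) edges$r <- rep(1, nrow(edges))
  edges$sign <- ifelse(edges$r >= 0, "positive", "negative")
  nodes <- union(nodes, union(edges$from, edges$to))
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(nodes = nodes, edges = edges, graph = g,
                 excluded = character(0), threshold = NA_real_,
                 method = "fixed", min_prevalence = NA_integer_,
                 level = "custom"),
            class = "cooccurrence_network")
}

#' Greedy modularity module detection
#'
#' Agglomerative modularity maximization on the unsigned edge set: starting
#' from singleton communities, repeatedly merge the connected pair of
#' communities with the largest modularity gain until no merge improves Q.
#' Ties break toward the lexicographically first community pair, so the
#' partition is deterministic.
#'
#' @param network a [build_network()] result (at least one edge).
#' @return list with `membership` (named integer vector), `Q` (modularity of
#'   the partition), `n_modules`.
#' @export
#' @examples
#' net <- gen_toy_network("two_cliques")
#' greedy_modules(net)$Q # 0.5
greedy_modules <- function(network) {
  g <- network$graph
  m <- igraph::ecount(g)
  if (m == 0) stop("empty graph: no edges to cluster")
  comm <- seq_len(igraph::vcount(g))
  q <- igraph::modularity(g, comm)
  repeat {
    # candidate merges: community pairs joined by at least one edge
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    pairs <- unique(t(apply(cbind(comm[ends[, 1]], comm[ends[, 2]]), 1,
                            function(z) sort(z))))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (!nrow(pairs)) break
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    gains <- apply(pairs, 1, function(pr) {
      trial <- comm
      trial[trial == pr[2]] <- pr[1]
      igraph::modularity(g, trial) - q
    })
    best <- which.max(gains)
    if (gains[best] <= 1e-12) break
    comm[comm == pairs[best, 2]] <- pairs[best, 1]
    q <- q + gains[best]
  }
  membership <- as.integer(factor(comm))
  names(membership) <- igraph::V(g)$name
  list(membership = membership, Q = igraph::modularity(g, membership),
       n_modules = length(unique(membership)))
}

#' Stress centrality
#'
#' The number of shortest paths between all unordered pairs of other nodes
#' that pass through the node of interest as an interior vertex: a node is
#' more central when more short paths run through it. Unweighted shortest
#' paths; all shortest paths between a pair are counted. Computed from
#' breadth-first shortest-path counts via the identity
#' `sigma_st(x) = sigma_sx * sigma_xt` whenever `d(s,x) + d(x,t) = d(s,t)`.
#'
#' @param network a [build_network()] result.
#' @param node node name, or `NULL` for all nodes.
#' @return named integer vector of stress centralities.
#' @export
#' @examples
#' stress_centrality(gen_toy_network("star")) # center 3, leaves 0
stress_centrality <- function(network, node = NULL) {
  g <- network$graph
  vn <- igraph::V(g)$name
  if (!is.null(node) && !all(node %in% vn))
    stop("unknown node: ", paste(setdiff(node, vn), collapse = ", "))
  nv <- igraph::vcount(g)
  d <- igraph::distances(g)
  # sigma[s, v]: number of shortest s-v paths, by BFS in distance order
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  sigma <- matrix(0, nv, nv)
  for (s in seq_len(nv)) {
    sigma[s, s] <- 1
    ds <- d[s, ]
    for (dist in sort(unique(ds[is.finite(ds) & ds > 0]))) {
      for (v in which(ds == dist)) {
        pred <- which(adj[, v] & ds == dist - 1)
        sigma[s, v] <- sum(sigma[s, pred])
      }
    }
  }
  cs <- integer(nv)
  for (x in seq_len(nv)) {
    tot <- 0
    for (s in seq_len(nv - 1)) {
      if (s == x) next
      for (t in seq((s + 1), nv)) {
        if (t == x || t == s) next
        if (is.finite(d[s, t]) && is.finite(d[s, x]) && is.finite(d[x, t]) &&
            d[s, x] + d[x, t] == d[s, t])
          tot <- tot + sigma[s, x] * sigma[x, t]
      }
    }
    cs[x] <- as.integer(tot)
  }
  names(cs) <- vn
  if (is.null(node)) cs else cs[node]
}

#' Export a network as tabular text and GraphML
#' @param network a [build_network()] result.
#' @param prefix output path prefix; writes `<prefix>_edges.tsv`,
#'   `<prefix>_nodes.tsv` (module + centrality per node) and
#'   `<prefix>.graphml`.
#' @param header optional provenance comment lines for the TSVs.
#' @return invisibly, the file paths.
#' @export
export_network <- function(network, prefix, header = character(0)) {
  has_edges <- nrow(network$edges) > 0
  mods <- if (has_edges) greedy_modules(network)
  cent <- stress_centrality(network)
  nodes <- data.frame(node = network$nodes,
                      module = if (has_edges) mods$membership[network$nodes]
                               else NA_integer_,
                      stress_centrality = cent[network$nodes])
  paths <- paste0(prefix, c("_edges.tsv", "_nodes.tsv", ".graphml"))
  write_tsv_with_header(network$edges, paths[1], header)
  write_tsv_with_header(nodes, paths[2], header)
  igraph::write_graph(network$graph, paths[3], format = "graphml")
  invisible(paths)
}
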