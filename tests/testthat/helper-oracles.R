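# Independent oracles used against the package implementation.

# brute-force one-component PLS1 by NIPALS iteration (independent of the
# package's closed-form weight computation)
pls1_nipals_oracle <- function(X, y, max_iter = 500, tol = 1e-12) {
  yc <- y - mean(y)
  u <- yc
  w <- rep(1 / sqrt(ncol(X)), ncol(X))
  for (i in seq_len(max_iter)) {
    w_new <- as.vector(t(X) %*% u)
    w_new <- w_new / sqrt(sum(w_new^2))
    t_new <- as.vector(X %*% w_new)
    q <- sum(yc * t_new) / sum(t_new^2)
    u_new <- yc * q
    if (sqrt(sum((w_new - w)^2)) < tol) {
      w <- w_new
      break
    }
    w <- w_new; u <- u_new
  }
  t_scores <- as.vector(X %*% w)
  list(w = w, t = t_scores)
}

# 5-node star pathway whose betweenness is known in closed form
star5 <- local({
  edges <- data.frame(from = "hub", to = c("a", "b", "c", "d"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  structure(list(id = "star", name = "5-node star", graph = g,
                 nodes = igraph::V(g)$name, connected = TRUE,
                 decoy = FALSE), class = "pathway_graph")
})

# exact hypergeometric upper tail by exhaustive enumeration of all draws
# (universe <= 15 elements)
hyper_upper_tail_enum <- function(background, pathway_nodes, n_draw, k_min) {
  draws <- utils::combn(length(background), n_draw)
  in_path <- background %in% pathway_nodes
  hits <- apply(draws, 2, function(ix) sum(in_path[ix]))
  mean(hits >= k_min)
}

# betweenness of a graph by brute-force shortest-path counting
betweenness_brute <- function(edges, nodes) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  paths_through <- stats::setNames(numeric(length(nodes)), nodes)
  for (s in seq_along(nodes)) {
    for (t in seq_along(nodes)) {
      if (s >= t) next
      sp <- igraph::all_shortest_paths(g, from = nodes[s],
                                       to = nodes[t])$res
      if (!length(sp)) next
      for (v in nodes) {
        frac <- mean(vapply(sp, function(p) {
          nm <- names(unclass(p))
          v %in% nm[-c(1, length(nm))]
        }, logical(1)))
        paths_through[v] <- paths_through[v] + frac
      }
    }
  }
  paths_through
}
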