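# Independent oracles and random-network builders for the test suite.
# The betweenness oracle enumerates every shortest path explicitly (DFS over
# the BFS distance gradient); the closeness oracle recomputes r/D from an
# igraph all-pairs distance matrix. Neither shares code with the package's
# Brandes / BFS implementations.

fixture <- function(name) system.file("extdata", name, package = "netpharm")

oracle_adj <- function(net) {
  ids <- net$nodes$id
  adj <- lapply(ids, function(v)
    unique(c(net$edges$to[net$edges$from == v],
             net$edges$from[net$edges$to == v])))
  names(adj) <- ids
  adj
}

oracle_bfs_dist <- function(adj, s) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[s] <- 0
  q <- s
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (w in adj[[v]]) if (is.infinite(d[w])) {
      d[w] <- d[v] + 1
      q <- c(q, w)
    }
  }
  d
}

# raw betweenness (unordered pairs, endpoints excluded) by exhaustive
# shortest-path enumeration
oracle_betweenness <- function(net) {
  ids <- net$nodes$id
  n <- length(ids)
  bc <- stats::setNames(numeric(n), ids)
  if (n < 3) return(bc)
  adj <- oracle_adj(net)
  for (i in seq_len(n - 1)) {
    s <- ids[i]
    d <- oracle_bfs_dist(adj, s)
    for (j in (i + 1):n) {
      t <- ids[j]
      if (is.infinite(d[t])) next
      paths <- list()
      walk <- function(v, acc) {
        if (v == t) {
          paths[[length(paths) + 1L]] <<- acc
          return(invisible())
        }
        for (w in adj[[v]])
          if (d[w] == d[v] + 1 && d[w] <= d[t]) walk(w, c(acc, w))
      }
      walk(s, s)
      np <- length(paths)
      for (p in paths)
        for (v in setdiff(p, c(s, t))) bc[v] <- bc[v] + 1 / np
    }
  }
  bc
}

# closeness r/D from an igraph distance matrix
oracle_closeness <- function(net) {
  g <- as_igraph(net)
  D <- igraph::distances(g)
  out <- apply(D, 1, function(row) {
    row <- row[is.finite(row) & row > 0]
    if (length(row) == 0) 0 else length(row) / sum(row)
  })
  stats::setNames(as.numeric(out), net$nodes$id)
}

# random typed network: G(n, p) with random node classes
random_typed_network <- function(n, p, classes = c("compound", "target",
                                                   "pathway"),
                                 keep_isolates = FALSE) {
  ids <- sprintf("n%03d", seq_len(n))
  cls <- sample(classes, n, replace = TRUE)
  from <- character(0); to <- character(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (stats::runif(1) < p) {
        from <- c(from, ids[i]); to <- c(to, ids[j])
      }
  }
  nodes <- data.frame(id = ids, class = cls, stringsAsFactors = FALSE)
  if (!keep_isolates) {
    used <- unique(c(from, to))
    nodes <- nodes[nodes$id %in% used, , drop = FALSE]
  }
  typed_network(nodes, data.frame(from = from, to = to,
                                  stringsAsFactors = FALSE))
}

# small builders for hand-made networks
net_from_edges <- function(..., classes) {
  e <- list(...)
  from <- vapply(e, `[[`, "", 1L)
  to <- vapply(e, `[[`, "", 2L)
  ids <- unique(c(from, to, names(classes)))
  cls <- classes[ids]
  cls[is.na(cls)] <- "target"
  typed_network(data.frame(id = ids, class = unname(cls),
                           stringsAsFactors = FALSE),
                data.frame(from = from, to = to, stringsAsFactors = FALSE))
}

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
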