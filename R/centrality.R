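#' @title Native centrality computations
#' @description Degree, betweenness and closeness centrality computed from
#'   scratch on [typed_network()] objects. Betweenness follows Brandes'
#'   single-source accumulation over BFS shortest-path DAGs and is reported
#'   in raw unordered-pair units (endpoints excluded); closeness uses the
#'   within-component form \eqn{r/D} -- the number of reachable nodes over
#'   their total distance -- which is the convention of Cytoscape's
#'   NetworkAnalyzer and lies in \eqn{[0, 1]} (isolated nodes score 0).
#'   These are the quantities the key-target and important-pathway screens
#'   consume.
#' @name centrality
NULL

# adjacency list of integer neighbour indices, nodes in net$nodes order
adjacency_list <- function(net) {
  n <- nrow(net$nodes)
  idx <- stats::setNames(seq_len(n), net$nodes$id)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(net$edges) > 0L) {
    f <- idx[net$edges$from]
    t <- idx[net$edges$to]
    for (k in seq_along(f)) {
      adj[[f[k]]] <- c(adj[[f[k]]], t[k])
      adj[[t[k]]] <- c(adj[[t[k]]], f[k])
    }
  }
  adj
}

#' Degree centrality
#'
#' @param net a [typed_network()].
#' @return named integer vector: number of incident edges per node.
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "typed_network"))
  deg <- stats::setNames(integer(nrow(net$nodes)), net$nodes$id)
  if (nrow(net$edges) > 0L) {
    tab <- table(c(net$edges$from, net$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Betweenness centrality (Brandes' algorithm)
#'
#' For each node v, the sum over unordered pairs of distinct other nodes
#' (s, t) of the fraction of shortest s-t paths passing through v. Pairs
#' with no connecting path contribute nothing. Normalization divides by
#' (n-1)(n-2)/2, the number of pairs a node could lie between.
#'
#' @param net a [typed_network()].
#' @param normalized divide by \code{(n-1)(n-2)/2}? Default \code{FALSE}
#'   (raw pair-count units).
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(net, normalized = FALSE) {
  stopifnot(inherits(net, "typed_network"))
  n <- nrow(net$nodes)
  adj <- adjacency_list(net)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    order_visited <- integer(0)
    pred <- vector("list", n)
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    queue <- integer(n); queue[1L] <- s
    qh <- 1L; qt <- 1L
    while (qh <= qt) {
      v <- queue[qh]; qh <- qh + 1L
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          qt <- qt + 1L; queue[qt] <- w
          dist[w] <- dist[v] + 1L
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          pred[[w]] <- c(pred[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in pred[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2  # each unordered pair was accumulated from both endpoints
  if (normalized) {
    denom <- (n - 1) * (n - 2) / 2
    bc <- if (denom > 0) bc / denom else bc * 0
  }
  stats::setNames(bc, net$nodes$id)
}

#' Closeness centrality (within-component r/D form)
#'
#' For a node v reaching r other nodes at total shortest-path distance D,
#' closeness is r/D (0 if nothing is reachable). This is the reciprocal of
#' the mean distance to reachable nodes, so a node adjacent to everything
#' it can reach scores 1.
#'
#' @param net a [typed_network()].
#' @return named numeric vector in \eqn{[0, 1]}.
#' @export
closeness_centrality <- function(net) {
  stopifnot(inherits(net, "typed_network"))
  n <- nrow(net$nodes)
  adj <- adjacency_list(net)
  cc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); dist[s] <- 0L
    queue <- integer(n); queue[1L] <- s
    qh <- 1L; qt <- 1L
    while (qh <= qt) {
      v <- queue[qh]; qh <- qh + 1L
      for (w in adj[[v]]) if (dist[w] < 0L) {
        qt <- qt + 1L; queue[qt] <- w
        dist[w] <- dist[v] + 1L
      }
    }
    reach <- dist > 0L
    total <- sum(dist[reach])
    cc[s] <- if (total > 0) sum(reach) / total else 0
  }
  stats::setNames(cc, net$nodes$id)
}

#' Full per-node centrality table
#'
#' Computes all three centralities on the whole heterogeneous network (class
#' filtering happens only at screening time, mirroring centralities being
#' computed "in the CTN" / "in the TPN" as wholes).
#'
#' @param net a [typed_network()].
#' @return data.frame with columns \code{node}, \code{class}, \code{degree},
#'   \code{betweenness} (raw), \code{betweenness_norm}, \code{closeness}.
#' @export
centrality_table <- function(net) {
  n <- nrow(net$nodes)
  raw <- betweenness_centrality(net, normalized = FALSE)
  denom <- (n - 1) * (n - 2) / 2
  data.frame(node = net$nodes$id,
             class = net$nodes$class,
             degree = as.integer(degree_centrality(net)),
             betweenness = as.numeric(raw),
             betweenness_norm = if (denom > 0) as.numeric(raw) / denom
                                else numeric(n),
             closeness = as.numeric(closeness_centrality(net)),
             stringsAsFactors = FALSE)
}

#' Mean of a centrality metric over one node class
#'
#' The screening criteria compare each candidate against the average of all
#' nodes of its class ("larger than the average value of all involved
#' targets").
#'
#' @param table a [centrality_table()] data.frame.
#' @param metric column name, e.g. \code{"betweenness"}.
#' @param node_class \code{"compound"}, \code{"target"} or \code{"pathway"}.
#' @return the arithmetic mean (numeric scalar).
#' @export
class_mean <- function(table, metric, node_class) {
  stopifnot(metric %in% names(table))
  vals <- table[[metric]][table$class == node_class]
  if (length(vals) == 0L)
    stop("no nodes of class '", node_class, "' in centrality table")
  mean(vals)
}
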