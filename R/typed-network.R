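#' Typed (heterogeneous) network container
#'
#' An undirected, unweighted graph whose nodes carry one of three classes:
#' \code{"compound"}, \code{"target"} or \code{"pathway"}. This is the
#' container used for the compound-target network (CTN), the target-pathway
#' network (TPN) and the combined compound-target-pathway network (CTPN).
#'
#' Invariants enforced at construction: node ids unique, classes drawn from
#' the three-class vocabulary, no self-loops, no duplicate (unordered) edges,
#' every edge endpoint present among the nodes, and -- when \code{allowed} is
#' given -- every edge connecting one of the allowed class pairs.
#'
#' @param nodes data.frame with columns \code{id} (character, unique) and
#'   \code{class} (one of \code{"compound"}, \code{"target"},
#'   \code{"pathway"}).
#' @param edges data.frame with columns \code{from} and \code{to} (node ids),
#'   or \code{NULL} for an edgeless network.
#' @param allowed optional character vector of permitted class pairs in
#'   canonical order, e.g. \code{"compound-target"}. \code{NULL} permits any
#'   pair.
#' @return An object of class \code{typed_network}: a list with elements
#'   \code{nodes} and \code{edges}.
#' @examples
#' net <- typed_network(
#'   nodes = data.frame(id = c("CAA", "P35354"),
#'                      class = c("compound", "target")),
#'   edges = data.frame(from = "CAA", to = "P35354")
#' )
#' summarize_network(net)
#' @export
typed_network <- function(nodes, edges = NULL, allowed = NULL) {
  stopifnot(is.data.frame(nodes), all(c("id", "class") %in% names(nodes)))
  nodes <- data.frame(id = as.character(nodes$id),
                      class = as.character(nodes$class),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  bad <- setdiff(unique(nodes$class), node_classes())
  if (length(bad))
    stop("unknown node class(es): ", paste(bad, collapse = ", "))

  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        stringsAsFactors = FALSE)
    if (any(edges$from == edges$to))
      stop("self-loop(s) not allowed: ",
           paste(unique(edges$from[edges$from == edges$to]), collapse = ", "))
    missing_ep <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
    if (length(missing_ep))
      stop("edge endpoint(s) not in node set: ",
           paste(missing_ep, collapse = ", "))
    key <- edge_key(edges$from, edges$to)
    if (anyDuplicated(key))
      stop("duplicate edge(s): ", paste(unique(key[duplicated(key)]),
                                        collapse = ", "))
  }

  net <- structure(list(nodes = nodes, edges = edges),
                   class = "typed_network")
  if (!is.null(allowed)) {
    pairs <- edge_class_pairs(net)
    bad <- setdiff(unique(pairs), allowed)
    if (length(bad))
      stop("edge class pair(s) not allowed here: ",
           paste(bad, collapse = ", "))
  }
  net
}

node_classes <- function() c("compound", "target", "pathway")

# canonical unordered-edge key
edge_key <- function(from, to) {
  paste(pmin(from, to), pmax(from, to), sep = "\r")
}

#' @export
print.typed_network <- function(x, ...) {
  s <- summarize_network(x)
  cat(sprintf(
    "typed_network: %d nodes (%d compounds, %d targets, %d pathways), %d edges\n",
    s$n_nodes, s$n_compounds, s$n_targets, s$n_pathways, s$n_edges))
  invisible(x)
}

# per-edge class pair label, canonical order compound < target < pathway
edge_class_pairs <- function(net) {
  if (nrow(net$edges) == 0L) return(character(0))
  cls <- stats::setNames(net$nodes$class, net$nodes$id)
  a <- cls[net$edges$from]
  b <- cls[net$edges$to]
  ord <- match(a, node_classes()) <= match(b, node_classes())
  paste(ifelse(ord, a, b), ifelse(ord, b, a), sep = "-")
}

#' Convert a typed network to an igraph graph
#'
#' The node class is carried as the \code{class} vertex attribute. Used for
#' GraphML serialization and for independent cross-checks; all centrality
#' computations in this package are native (see [centrality_table()]).
#'
#' @param net a [typed_network()].
#' @return an \code{igraph} graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "typed_network"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(net$nodes),
                            name = net$nodes$id, class = net$nodes$class)
  if (nrow(net$edges) > 0L)
    g <- igraph::add_edges(g, rbind(net$edges$from, net$edges$to))
  g
}

#' Write a typed network to disk
#'
#' Supported formats:
#' \describe{
#'   \item{\code{"sif"}}{Cytoscape simple-interaction format; one line per
#'     edge, the interaction label being the canonical class pair (e.g.
#'     \code{compound-target}). Isolated nodes, if any, are written as bare
#'     single-field lines.}
#'   \item{\code{"graphml"}}{GraphML via igraph; node classes stored in the
#'     \code{class} attribute. Round-trips through [read_network()].}
#'   \item{\code{"edge-csv"}}{CSV with columns \code{source, source_class,
#'     target, target_class}; round-trips through [read_network()] for
#'     networks without isolated nodes.}
#' }
#'
#' @param net a [typed_network()].
#' @param path output file path.
#' @param format one of \code{"sif"}, \code{"graphml"}, \code{"edge-csv"}.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(net, path, format = c("sif", "graphml", "edge-csv")) {
  stopifnot(inherits(net, "typed_network"))
  if (length(format) != 1L || !format %in% c("sif", "graphml", "edge-csv"))
    stop("unknown network format: ", paste(format, collapse = ", "))
  if (format == "sif") {
    labels <- edge_class_pairs(net)
    lines <- character(0)
    if (nrow(net$edges) > 0L)
      lines <- paste(net$edges$from, labels, net$edges$to, sep = "\t")
    iso <- setdiff(net$nodes$id, c(net$edges$from, net$edges$to))
    writeLines(c(lines, iso), path)
  } else if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    cls <- stats::setNames(net$nodes$class, net$nodes$id)
    out <- data.frame(source = net$edges$from,
                      source_class = unname(cls[net$edges$from]),
                      target = net$edges$to,
                      target_class = unname(cls[net$edges$to]),
                      stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Read a typed network written by [write_network()]
#'
#' @param path file path.
#' @param format \code{"graphml"} or \code{"edge-csv"} (SIF is write-only
#'   here, as the interaction label does not carry the node classes of
#'   isolated nodes).
#' @return a [typed_network()].
#' @export
read_network <- function(path, format = c("graphml", "edge-csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(id = igraph::V(g)$name,
                        class = igraph::V(g)$class,
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g, names = TRUE)
    edges <- data.frame(from = el[, 1], to = el[, 2],
                        stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    need <- c("source", "source_class", "target", "target_class")
    if (!all(need %in% names(df)))
      stop("edge-csv must have columns: ", paste(need, collapse = ", "))
    ids <- c(df$source, df$target)
    cls <- c(df$source_class, df$target_class)
    keep <- !duplicated(ids)
    nodes <- data.frame(id = ids[keep], class = cls[keep],
                        stringsAsFactors = FALSE)
    edges <- data.frame(from = df$source, to = df$target,
                        stringsAsFactors = FALSE)
  }
  typed_network(nodes, edges)
}
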