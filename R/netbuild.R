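#' @title Construction of the CTN, TPN and CTPN
#' @description Builders that assemble the compound-target network (CTN)
#'   from interaction edges, the target-pathway network (TPN) from pathway
#'   memberships restricted to the CTN's targets, and the combined
#'   compound-target-pathway network (CTPN) induced by a set of selected
#'   pathways. Nodes without any surviving edge are dropped, never kept
#'   isolated.
#' @name netbuild
NULL

#' Build the compound-target network
#'
#' Nodes are all compounds and targets mentioned by at least one edge;
#' compounds whose every interaction was filtered away simply do not appear.
#'
#' @param edges deduplicated interaction-edge data.frame
#'   (see [interaction_edges()]).
#' @return a [typed_network()] whose edges connect compounds to targets only.
#' @export
build_ctn <- function(edges) {
  key <- paste(edges$compound_abbrev, edges$uniprot_ac, sep = "\r")
  if (anyDuplicated(key))
    stop("edges must be deduplicated on (compound, target) before build_ctn")
  compounds <- unique(edges$compound_abbrev)
  targets <- unique(edges$uniprot_ac)
  nodes <- data.frame(id = c(compounds, targets),
                      class = rep(c("compound", "target"),
                                  c(length(compounds), length(targets))),
                      stringsAsFactors = FALSE)
  typed_network(nodes,
                data.frame(from = edges$compound_abbrev,
                           to = edges$uniprot_ac, stringsAsFactors = FALSE),
                allowed = "compound-target")
}

#' Build the target-pathway network
#'
#' Only memberships whose target appears in \code{target_whitelist}
#' (normally the target nodes of the CTN) contribute; targets with no
#' pathway membership, and pathways left memberless, are absent.
#'
#' @param members pathway-membership data.frame from [read_pathway_table()]
#'   (columns \code{uniprot_ac, pathway_id}, optionally
#'   \code{pathway_name}).
#' @param target_whitelist character vector of admissible accessions.
#' @return a [typed_network()] whose edges connect targets to pathways only.
#' @export
build_tpn <- function(members, target_whitelist) {
  keep <- members[members$uniprot_ac %in% target_whitelist, , drop = FALSE]
  if (nrow(keep) == 0L)
    return(typed_network(data.frame(id = character(0),
                                    class = character(0))))
  targets <- unique(keep$uniprot_ac)
  pathways <- unique(keep$pathway_id)
  nodes <- data.frame(id = c(targets, pathways),
                      class = rep(c("target", "pathway"),
                                  c(length(targets), length(pathways))),
                      stringsAsFactors = FALSE)
  typed_network(nodes,
                data.frame(from = keep$uniprot_ac, to = keep$pathway_id,
                           stringsAsFactors = FALSE),
                allowed = "target-pathway")
}

#' Build the compound-target-pathway network
#'
#' Keeps the selected pathways, the targets linked to them in the TPN, the
#' compounds linked to those targets in the CTN, and the induced
#' compound-target and target-pathway edges. No compound-pathway or
#' pathway-pathway edges exist by construction.
#'
#' @param ctn the compound-target network.
#' @param tpn the target-pathway network.
#' @param selected_pathways character vector of pathway ids; must all be
#'   pathway nodes of \code{tpn}.
#' @return a [typed_network()].
#' @export
build_ctpn <- function(ctn, tpn, selected_pathways) {
  tpn_pathways <- tpn$nodes$id[tpn$nodes$class == "pathway"]
  missing <- setdiff(selected_pathways, tpn_pathways)
  if (length(missing))
    stop("selected pathway(s) absent from TPN: ",
         paste(missing, collapse = ", "))
  if (length(selected_pathways) == 0L)
    return(typed_network(data.frame(id = character(0),
                                    class = character(0))))
  tp <- tpn$edges
  # orient target-pathway edges as (target, pathway)
  cls <- stats::setNames(tpn$nodes$class, tpn$nodes$id)
  flip <- cls[tp$from] == "pathway"
  tp[flip, c("from", "to")] <- tp[flip, c("to", "from")]
  tp <- tp[tp$to %in% selected_pathways, , drop = FALSE]
  kept_targets <- unique(tp$from)

  ct <- ctn$edges
  cls_c <- stats::setNames(ctn$nodes$class, ctn$nodes$id)
  flip <- cls_c[ct$from] == "target"
  ct[flip, c("from", "to")] <- ct[flip, c("to", "from")]
  ct <- ct[ct$to %in% kept_targets, , drop = FALSE]
  kept_compounds <- unique(ct$from)

  nodes <- data.frame(
    id = c(kept_compounds, kept_targets, unique(tp$to)),
    class = rep(c("compound", "target", "pathway"),
                c(length(kept_compounds), length(kept_targets),
                  length(unique(tp$to)))),
    stringsAsFactors = FALSE)
  typed_network(nodes, rbind(ct, tp),
                allowed = c("compound-target", "target-pathway"))
}

#' Summarize a typed network
#'
#' @param net a [typed_network()].
#' @return an object of class \code{network_summary}: a list with
#'   \code{n_nodes}, \code{n_compounds}, \code{n_targets}, \code{n_pathways}
#'   and \code{n_edges}.
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "typed_network"))
  tab <- table(factor(net$nodes$class, levels = node_classes()))
  structure(list(n_nodes = nrow(net$nodes),
                 n_compounds = unname(tab[["compound"]]),
                 n_targets = unname(tab[["target"]]),
                 n_pathways = unname(tab[["pathway"]]),
                 n_edges = nrow(net$edges)),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("%d nodes (%d compounds, %d targets, %d pathways), %d edges\n",
              x$n_nodes, x$n_compounds, x$n_targets, x$n_pathways,
              x$n_edges))
  invisible(x)
}
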