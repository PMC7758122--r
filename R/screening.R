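#' @title Key-target and important-pathway screening
#' @description The two centrality-based screening cascades. Targets are
#'   "important" when their degree ranks in the top k (default ten, ties at
#'   the boundary value included) of all targets in the CTN and both their
#'   betweenness and closeness exceed the target-class means. Pathways are
#'   "important" when their degree strictly exceeds a cutoff (default 6) and
#'   their betweenness exceeds the pathway-class mean, they are not on a
#'   blocklist of non-specific catch-all maps, and their closeness exceeds
#'   the pathway-class mean. All mean comparisons are strict.
#' @name screening
NULL

#' Screening criteria for key targets
#'
#' @param top_k_degree keep targets whose degree ranks in the top k
#'   (ties at the k-th value included). Default 10.
#' @param require_betweenness_above_mean require betweenness strictly above
#'   the target-class mean. Default \code{TRUE}.
#' @param require_closeness_above_mean require closeness strictly above the
#'   target-class mean. Default \code{TRUE}.
#' @return a \code{target_criteria} list.
#' @export
target_criteria <- function(top_k_degree = 10L,
                            require_betweenness_above_mean = TRUE,
                            require_closeness_above_mean = TRUE) {
  stopifnot(top_k_degree >= 1L)
  structure(list(top_k_degree = as.integer(top_k_degree),
                 require_betweenness_above_mean =
                   isTRUE(require_betweenness_above_mean),
                 require_closeness_above_mean =
                   isTRUE(require_closeness_above_mean)),
            class = "target_criteria")
}

#' Screening criteria for important pathways
#'
#' @param min_degree_exclusive pathways must have degree strictly greater
#'   than this. Default 6.
#' @param require_betweenness_above_mean require betweenness strictly above
#'   the pathway-class mean. Default \code{TRUE}.
#' @param require_closeness_above_mean require closeness strictly above the
#'   pathway-class mean. Default \code{TRUE}.
#' @param nonspecific_blocklist pathway names or ids (matched
#'   case-insensitively against both) excluded as not representing a
#'   specific biological process. Defaults to
#'   [default_nonspecific_pathways()].
#' @return a \code{pathway_criteria} list.
#' @export
pathway_criteria <- function(min_degree_exclusive = 6L,
                             require_betweenness_above_mean = TRUE,
                             require_closeness_above_mean = TRUE,
                             nonspecific_blocklist =
                               default_nonspecific_pathways()) {
  stopifnot(min_degree_exclusive >= 0L)
  structure(list(min_degree_exclusive = as.integer(min_degree_exclusive),
                 require_betweenness_above_mean =
                   isTRUE(require_betweenness_above_mean),
                 require_closeness_above_mean =
                   isTRUE(require_closeness_above_mean),
                 nonspecific_blocklist =
                   as.character(nonspecific_blocklist)),
            class = "pathway_criteria")
}

#' Default blocklist of non-specific catch-all pathways
#'
#' Large aggregate KEGG maps that describe no single biological process and
#' therefore carry no mechanistic signal in a pathway screen.
#'
#' @return character vector of pathway names.
#' @export
default_nonspecific_pathways <- function() {
  c("metabolic pathways",
    "pathways in cancer",
    "neuroactive ligand-receptor interaction",
    "microRNAs in cancer")
}

order_selection <- function(tab) {
  tab[order(-tab$degree, -tab$betweenness, tab$node), , drop = FALSE]
}

#' Screen key targets in a compound-target network
#'
#' @param table a [centrality_table()] computed on a CTN.
#' @param criteria a [target_criteria()].
#' @return a \code{screening_result}: list with \code{selected} (ordered
#'   character vector of target ids), \code{audit} (one row per target-class
#'   node with each criterion's pass/fail), and \code{thresholds} (the
#'   top-k degree boundary and the class means actually used). Ordering is
#'   degree desc, betweenness desc, node id asc.
#' @export
screen_key_targets <- function(table, criteria = target_criteria()) {
  stopifnot(inherits(criteria, "target_criteria"))
  tt <- table[table$class == "target", , drop = FALSE]
  if (nrow(tt) == 0L) stop("no target-class nodes to screen")
  sorted_deg <- sort(tt$degree, decreasing = TRUE)
  kth <- sorted_deg[min(criteria$top_k_degree, length(sorted_deg))]
  mean_b <- class_mean(table, "betweenness", "target")
  mean_c <- class_mean(table, "closeness", "target")

  audit <- data.frame(node = tt$node, degree = tt$degree,
                      betweenness = tt$betweenness,
                      closeness = tt$closeness,
                      in_top_k = tt$degree >= kth,
                      betweenness_above_mean = tt$betweenness > mean_b,
                      closeness_above_mean = tt$closeness > mean_c,
                      stringsAsFactors = FALSE)
  pass <- audit$in_top_k
  if (criteria$require_betweenness_above_mean)
    pass <- pass & audit$betweenness_above_mean
  if (criteria$require_closeness_above_mean)
    pass <- pass & audit$closeness_above_mean
  audit$selected <- pass
  audit <- order_selection(audit)
  rownames(audit) <- NULL
  structure(list(selected = audit$node[audit$selected],
                 audit = audit,
                 thresholds = list(degree_boundary = kth,
                                   mean_betweenness = mean_b,
                                   mean_closeness = mean_c)),
            class = "screening_result")
}

#' Screen important pathways in a target-pathway network
#'
#' The cascade runs degree, then betweenness, then the non-specific
#' blocklist, then closeness; the audit records the first stage at which
#' each pathway was removed (\code{NA} for the selected ones). Because the
#' criteria are conjunctive, the selected set does not depend on the
#' cascade order, only the recorded removal reasons do.
#'
#' @param table a [centrality_table()] computed on a TPN.
#' @param criteria a [pathway_criteria()].
#' @param pathway_names optional named character vector mapping pathway
#'   node ids to display names, used for blocklist matching (ids are always
#'   matched too).
#' @return a \code{screening_result} (see [screen_key_targets()]); the audit
#'   carries a \code{stage_removed} column with values among
#'   \code{"degree"}, \code{"betweenness"}, \code{"nonspecific"},
#'   \code{"closeness"}, \code{NA}.
#' @export
screen_important_pathways <- function(table,
                                      criteria = pathway_criteria(),
                                      pathway_names = NULL) {
  stopifnot(inherits(criteria, "pathway_criteria"))
  pt <- table[table$class == "pathway", , drop = FALSE]
  if (nrow(pt) == 0L) stop("no pathway-class nodes to screen")
  mean_b <- class_mean(table, "betweenness", "pathway")
  mean_c <- class_mean(table, "closeness", "pathway")
  block <- tolower(criteria$nonspecific_blocklist)
  names_of <- function(id) {
    nm <- if (!is.null(pathway_names)) unname(pathway_names[id]) else NA
    tolower(c(id, nm[!is.na(nm)]))
  }
  blocked <- vapply(pt$node,
                    function(id) any(names_of(id) %in% block), logical(1))

  stage <- rep(NA_character_, nrow(pt))
  fail_deg <- !(pt$degree > criteria$min_degree_exclusive)
  stage[fail_deg] <- "degree"
  fail_b <- criteria$require_betweenness_above_mean &
    !(pt$betweenness > mean_b)
  stage[is.na(stage) & fail_b] <- "betweenness"
  stage[is.na(stage) & blocked] <- "nonspecific"
  fail_c <- criteria$require_closeness_above_mean &
    !(pt$closeness > mean_c)
  stage[is.na(stage) & fail_c] <- "closeness"

  audit <- data.frame(node = pt$node, degree = pt$degree,
                      betweenness = pt$betweenness,
                      closeness = pt$closeness,
                      blocked = blocked,
                      stage_removed = stage,
                      selected = is.na(stage),
                      stringsAsFactors = FALSE)
  audit <- order_selection(audit)
  rownames(audit) <- NULL
  structure(list(selected = audit$node[audit$selected],
                 audit = audit,
                 thresholds = list(
                   min_degree_exclusive = criteria$min_degree_exclusive,
                   mean_betweenness = mean_b,
                   mean_closeness = mean_c)),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("screening_result: %d of %d candidates selected\n",
              length(x$selected), nrow(x$audit)))
  if (length(x$selected))
    cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Vocabulary of the seven cross-talk pathways
#'
#' The four key inflammation-related pathways plus the three bridging
#' pathways of the cross-talk figure.
#'
#' @return character vector of seven pathway names.
#' @export
crosstalk_pathways <- function() {
  c("estrogen signaling pathway",
    "PI3K-AKT signaling pathway",
    "cGMP-PKG signaling pathway",
    "calcium signaling pathway",
    "cAMP signaling pathway",
    "MAPK signaling pathway",
    "NF-kB signaling pathway")
}

#' Load a curated pathway cross-talk edge list
#'
#' Expected columns: \code{from_pathway, to_pathway, connector,
#' is_feedback}. Edges are directed (regulator to regulated), labelled by
#' the mediating molecule(s), with feedback regulations flagged. Pathway
#' names are validated against the seven-pathway vocabulary; unknown names
#' are a hard error.
#'
#' @param path CSV file path; the packaged fixture is
#'   \code{fig4_crosstalk.csv}.
#' @param vocabulary permitted pathway names
#'   (default [crosstalk_pathways()]).
#' @return data.frame with character columns \code{from_pathway,
#'   to_pathway, connector} and logical \code{is_feedback}.
#' @export
load_crosstalk <- function(path, vocabulary = crosstalk_pathways()) {
  df <- read_table_raw(path)
  need <- c("from_pathway", "to_pathway", "connector", "is_feedback")
  if (!all(need %in% names(df)))
    stop("cross-talk table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L)
    return(data.frame(from_pathway = character(0),
                      to_pathway = character(0), connector = character(0),
                      is_feedback = logical(0), stringsAsFactors = FALSE))
  from <- blank_to_na(df$from_pathway)
  to <- blank_to_na(df$to_pathway)
  unknown <- setdiff(unique(c(from, to)), vocabulary)
  if (length(unknown))
    stop("unknown cross-talk pathway name(s): ",
         paste(unknown, collapse = "; "))
  if (any(from == to)) stop("cross-talk edges must connect distinct pathways")
  data.frame(from_pathway = from, to_pathway = to,
             connector = blank_to_na(df$connector),
             is_feedback = toupper(trimws(df$is_feedback)) %in%
               c("TRUE", "T", "1", "YES"),
             stringsAsFactors = FALSE)
}

#' Validate the NF-kB hub property of a cross-talk network
#'
#' Checks that every pathway in the vocabulary other than the NF-kB
#' signaling pathway has at least one edge into it -- the structural
#' signature of NF-kB acting as the common effector of the
#' inflammation-related cross-talk network.
#'
#' @param edges data.frame from [load_crosstalk()].
#' @param hub the hub pathway name (default \code{"NF-kB signaling
#'   pathway"}).
#' @param vocabulary pathway vocabulary (default [crosstalk_pathways()]).
#' @return \code{TRUE} invisibly; errors naming the offending pathways
#'   otherwise.
#' @export
validate_crosstalk <- function(edges, hub = "NF-kB signaling pathway",
                               vocabulary = crosstalk_pathways()) {
  others <- setdiff(vocabulary, hub)
  has_edge <- vapply(others, function(p)
    any(edges$from_pathway == p & edges$to_pathway == hub), logical(1))
  if (!all(has_edge))
    stop("pathway(s) without an edge into ", hub, ": ",
         paste(others[!has_edge], collapse = "; "))
  invisible(TRUE)
}

#' Write a cross-talk edge list as a directed SIF file
#'
#' The interaction label is \code{"regulates"} or, for feedback edges,
#' \code{"feedback"}.
#'
#' @param edges data.frame from [load_crosstalk()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_crosstalk_sif <- function(edges, path) {
  label <- ifelse(edges$is_feedback, "feedback", "regulates")
  writeLines(paste(edges$from_pathway, label, edges$to_pathway, sep = "\t"),
             path)
  invisible(path)
}
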