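#' @title Seeded synthetic compound-target-pathway data
#' @description A generator for tripartite compound-to-target-to-pathway
#'   data with the statistical structure the screening pipeline assumes: a
#'   bipartite compound-target layer with a few planted hub targets whose
#'   connection probability is inflated over the background, a
#'   heavy-tailed pathway-size layer drawn from a Dirichlet-multinomial
#'   (a few large pathways, many small ones), and docking energies from a
#'   two-component Gaussian mixture of strong binders versus non-binders
#'   straddling the -8.18 kcal/mol threshold. Every run is reproducible
#'   from a single seed and ships a ledger of the planted structure for
#'   exact bookkeeping checks.
#' @name synthetic-data
NULL

#' Configuration for the synthetic generator
#'
#' Defaults state a world at the scale of the motivating study: 13
#' compounds, tens of targets of which a handful are genuine multi-compound
#' hubs, and a pathway layer where only a few pathways exceed the
#' degree-6 screening cutoff.
#'
#' @param n_compounds,n_targets,n_pathways layer sizes.
#' @param edge_prob_ct background compound-target edge probability in
#'   \eqn{[0, 1]}.
#' @param hub_targets number of planted hub targets.
#' @param hub_boost multiplicative inflation of the hub edge probability
#'   (>= 1; capped at probability 1).
#' @param membership_concentration Dirichlet concentration for pathway
#'   sizes (> 0); small values give heavy-tailed sizes.
#' @param memberships_total total number of target-pathway memberships to
#'   allocate across pathways (default \code{3 * n_targets}).
#' @param active_energy_mean,active_energy_sd Gaussian parameters
#'   (kcal/mol) for true binders. Defaults -9.5 / 0.8.
#' @param inactive_energy_mean,inactive_energy_sd Gaussian parameters for
#'   non-binders. Defaults -6.8 / 1.0.
#' @param seed integer seed; all randomness flows from it.
#' @return a \code{generator_config} list.
#' @export
generator_config <- function(n_compounds = 13L, n_targets = 50L,
                             n_pathways = 30L, edge_prob_ct = 0.08,
                             hub_targets = 5L, hub_boost = 5,
                             membership_concentration = 0.3,
                             memberships_total = 3L * n_targets,
                             active_energy_mean = -9.5,
                             active_energy_sd = 0.8,
                             inactive_energy_mean = -6.8,
                             inactive_energy_sd = 1.0,
                             seed = 1L) {
  stopifnot(n_compounds >= 0, n_targets >= 0, n_pathways >= 0,
            edge_prob_ct >= 0, edge_prob_ct <= 1,
            hub_targets >= 0, hub_boost >= 1,
            membership_concentration > 0, memberships_total >= 0,
            active_energy_sd > 0, inactive_energy_sd > 0)
  if (hub_targets > n_targets)
    stop("infeasible config: hub_targets (", hub_targets,
         ") exceeds n_targets (", n_targets, ")")
  structure(list(n_compounds = as.integer(n_compounds),
                 n_targets = as.integer(n_targets),
                 n_pathways = as.integer(n_pathways),
                 edge_prob_ct = edge_prob_ct,
                 hub_targets = as.integer(hub_targets),
                 hub_boost = hub_boost,
                 membership_concentration = membership_concentration,
                 memberships_total = as.integer(memberships_total),
                 active_energy_mean = active_energy_mean,
                 active_energy_sd = active_energy_sd,
                 inactive_energy_mean = inactive_energy_mean,
                 inactive_energy_sd = inactive_energy_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

synthetic_compound_ids <- function(n) sprintf("C%02d", seq_len(n))
synthetic_target_ids <- function(n) sprintf("P%05d", seq_len(n))
synthetic_pathway_ids <- function(n) sprintf("hsa%05d", 90000L + seq_len(n))

#' Generate a synthetic tripartite dataset
#'
#' Compound-target edges are independent Bernoulli draws at the background
#' probability, except for planted hub targets whose probability is
#' inflated by \code{hub_boost}. Pathway sizes are drawn once from a
#' Dirichlet-multinomial (capped at \code{n_targets}) and filled by
#' sampling member targets without replacement. The returned ledger
#' records the planted hubs, the realized per-pathway sizes and exact edge
#' counts, so downstream network summaries can be checked against the
#' generator's own bookkeeping.
#'
#' @param config a [generator_config()].
#' @return list with elements \code{compounds} (a compound table),
#'   \code{edges} (interaction edges, evidence \code{"database"}),
#'   \code{memberships} (a pathway-membership table) and \code{ledger}
#'   (list: \code{hub_targets}, \code{pathway_sizes} named integer vector,
#'   \code{n_ct_edges}, \code{n_tp_edges}, \code{connected_compounds},
#'   \code{connected_targets}, \code{targets_in_pathways}).
#' @export
generate_tripartite <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  comp_ids <- synthetic_compound_ids(config$n_compounds)
  targ_ids <- synthetic_target_ids(config$n_targets)
  path_ids <- synthetic_pathway_ids(config$n_pathways)

  hubs <- if (config$hub_targets > 0L)
    sort(sample(targ_ids, config$hub_targets)) else character(0)
  p_target <- ifelse(targ_ids %in% hubs,
                     pmin(1, config$edge_prob_ct * config$hub_boost),
                     config$edge_prob_ct)

  edge_from <- character(0); edge_to <- character(0)
  if (config$n_compounds > 0L && config$n_targets > 0L) {
    draw <- matrix(stats::runif(config$n_compounds * config$n_targets),
                   nrow = config$n_compounds)
    hit <- draw < matrix(p_target, nrow = config$n_compounds,
                         ncol = config$n_targets, byrow = TRUE)
    idx <- which(hit, arr.ind = TRUE)
    edge_from <- comp_ids[idx[, 1L]]
    edge_to <- targ_ids[idx[, 2L]]
  }
  ord <- order(edge_from, edge_to)
  edges <- interaction_edges(edge_from[ord], edge_to[ord],
                             "database", "synthetic")

  sizes <- integer(0)
  mem_ac <- character(0); mem_path <- character(0)
  if (config$n_pathways > 0L && config$n_targets > 0L &&
      config$memberships_total > 0L) {
    w <- stats::rgamma(config$n_pathways,
                       shape = config$membership_concentration, rate = 1)
    if (sum(w) == 0) w <- rep(1, config$n_pathways)
    sizes <- as.integer(stats::rmultinom(1L, config$memberships_total,
                                         w / sum(w)))
    sizes <- pmin(sizes, config$n_targets)
    for (j in seq_len(config$n_pathways)) {
      if (sizes[j] == 0L) next
      members <- sort(sample(targ_ids, sizes[j]))
      mem_ac <- c(mem_ac, members)
      mem_path <- c(mem_path, rep(path_ids[j], sizes[j]))
    }
  } else {
    sizes <- integer(config$n_pathways)
  }
  memberships <- data.frame(
    uniprot_ac = mem_ac, pathway_id = mem_path,
    pathway_name = if (length(mem_path)) paste("synthetic pathway", mem_path)
                   else character(0),
    stringsAsFactors = FALSE)

  compounds <- data.frame(
    abbrev = comp_ids,
    name = paste("synthetic compound", comp_ids),
    cas = NA_character_,
    pubchem_cid = seq_len(config$n_compounds),
    mw = round(stats::runif(config$n_compounds, 150, 600), 2),
    content_mg_per_ml = round(stats::rexp(config$n_compounds, rate = 0.5), 2),
    metabolite_of = NA_character_,
    stringsAsFactors = FALSE)

  ledger <- list(
    hub_targets = hubs,
    pathway_sizes = stats::setNames(sizes, path_ids),
    n_ct_edges = nrow(edges),
    n_tp_edges = length(mem_ac),
    connected_compounds = length(unique(edges$compound_abbrev)),
    connected_targets = length(unique(edges$uniprot_ac)),
    targets_in_pathways = length(unique(mem_ac)))

  list(compounds = compounds, edges = edges, memberships = memberships,
       ledger = ledger)
}

#' Generate a synthetic docking table
#'
#' Every docked pair draws its binding energy from one of two Gaussians:
#' the active component for pairs listed in \code{true_binders}, the
#' inactive component otherwise.
#'
#' @param config a [generator_config()]; supplies the mixture parameters
#'   and the seed.
#' @param true_binders data.frame with columns \code{compound_abbrev} and
#'   \code{uniprot_ac} marking the genuinely binding pairs (may be empty).
#' @param pairs data.frame of pairs to dock (same columns); default all
#'   \code{n_compounds x n_targets} combinations from the config.
#' @return docking-record data.frame as from [read_docking_table()].
#' @export
generate_docking_table <- function(config = generator_config(),
                                   true_binders,
                                   pairs = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(pairs)) {
    pairs <- expand.grid(
      compound_abbrev = synthetic_compound_ids(config$n_compounds),
      uniprot_ac = synthetic_target_ids(config$n_targets),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  if (nrow(pairs) == 0L)
    return(data.frame(compound_abbrev = character(0),
                      target_name = character(0), uniprot_ac = character(0),
                      binding_energy = numeric(0), stringsAsFactors = FALSE))
  set.seed(config$seed)
  binder_key <- if (nrow(true_binders) > 0L)
    paste(true_binders$compound_abbrev, true_binders$uniprot_ac, sep = "\r")
  else character(0)
  is_binder <- paste(pairs$compound_abbrev, pairs$uniprot_ac,
                     sep = "\r") %in% binder_key
  energy <- ifelse(
    is_binder,
    stats::rnorm(nrow(pairs), config$active_energy_mean,
                 config$active_energy_sd),
    stats::rnorm(nrow(pairs), config$inactive_energy_mean,
                 config$inactive_energy_sd))
  data.frame(compound_abbrev = pairs$compound_abbrev,
             target_name = paste("synthetic target", pairs$uniprot_ac),
             uniprot_ac = pairs$uniprot_ac,
             binding_energy = round(energy, 4),
             stringsAsFactors = FALSE)
}
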