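#' @title One-call pipeline
#' @description Orchestrates the full inference chain: docking-score
#'   filtering, integration with database-evidenced interactions, CTN
#'   construction, centrality computation, key-target screening and --
#'   when a pathway-membership table is supplied -- TPN construction,
#'   important-pathway screening and the induced CTPN. The run is
#'   deterministic given its inputs and produces a machine-readable report.
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' Every tunable of the method surfaces here with its conventional value:
#' the inhibition-constant cutoff (1 micromolar), the docking temperature
#' (298 K), the top-ten degree rule for targets, the strict degree > 6
#' rule for pathways, and the non-specific pathway blocklist.
#'
#' @return a named list of defaults; unknown keys in a user config are
#'   rejected by [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(docking = NULL,          # docking CSV path
       known_edges = NULL,      # known compound-target edge CSV path
       pathways = NULL,         # target-pathway membership CSV path
       selected_pathways = NULL,# pathway ids for the CTPN (default: screened)
       ki = 1e-6,
       temperature = DEFAULT_TEMPERATURE_K,
       pin_energy = NULL,
       comparison = "<",
       top_k_degree = 10L,
       pathway_min_degree = 6L,
       nonspecific_blocklist = default_nonspecific_pathways(),
       out_dir = NULL)
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config))
      yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, config)
}

#' Run the full network-pharmacology pipeline
#'
#' Stages: read docking table, derive the energy threshold from the Ki
#' cutoff, filter, integrate with known edges, build the CTN, compute
#' centralities, screen key targets; then, if a pathway table is given,
#' build the TPN against the CTN's targets, screen important pathways and
#' build the CTPN from the selected (or user-supplied) pathways. Missing
#' optional inputs skip the affected stages, which are logged as skipped.
#'
#' @param config a named list, or a path to a YAML/JSON file, with keys as
#'   in [default_pipeline_config()]. At least one of \code{docking} or
#'   \code{known_edges} must be given.
#' @param quiet suppress stage logging. Default \code{TRUE}.
#' @return a \code{run_report} list: \code{threshold_energy},
#'   \code{integration}, \code{ctn_summary}, \code{tpn_summary},
#'   \code{ctpn_summary}, \code{key_targets}, \code{important_pathways},
#'   \code{networks} (the built [typed_network()] objects),
#'   \code{centrality} (the CTN and TPN tables), \code{skipped},
#'   \code{config} echo and package \code{version}. If
#'   \code{config$out_dir} is set, the report (JSON), the centrality
#'   tables (CSV) and the networks (SIF + GraphML) are written there.
#' @examples
#' report <- run_pipeline(list(
#'   docking = system.file("extdata", "table2_docking.csv",
#'                         package = "netpharm")))
#' report$integration$n_docking   # 19
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  cfg <- read_pipeline_config(config)
  log_stage <- function(...) if (!quiet) message("[netpharm] ", ...)
  if (is.null(cfg$docking) && is.null(cfg$known_edges))
    stop("config must provide 'docking' and/or 'known_edges'")

  spec <- threshold_spec(ki_molar = cfg$ki, temperature_k = cfg$temperature,
                         pin_energy = cfg$pin_energy,
                         comparison = cfg$comparison)
  log_stage(sprintf("threshold: %.4f kcal/mol (Ki %g mol/L, %g K)",
                    spec$derived_energy, spec$ki_molar, spec$temperature_k))
  skipped <- character(0)

  docked <- if (!is.null(cfg$docking)) {
    log_stage("dock_screen: ", cfg$docking)
    filter_docking(read_docking_table(cfg$docking), spec)
  } else {
    skipped <- c(skipped, "dock_screen")
    interaction_edges(character(0), character(0), "docking")
  }
  known <- if (!is.null(cfg$known_edges)) {
    log_stage("known edges: ", cfg$known_edges)
    read_known_edges(cfg$known_edges)
  } else {
    skipped <- c(skipped, "known_edges")
    interaction_edges(character(0), character(0), "database")
  }

  integ <- integrate_targets(known, docked)
  log_stage(sprintf("integration: %d targets (%d known, %d docking)",
                    integ$report$n_union, integ$report$n_known,
                    integ$report$n_docking))

  ctn <- build_ctn(integ$edges)
  ctn_tab <- centrality_table(ctn)
  key_targets <- screen_key_targets(
    ctn_tab, target_criteria(top_k_degree = cfg$top_k_degree))
  log_stage(sprintf("CTN: %d nodes, %d edges; %d key targets",
                    nrow(ctn$nodes), nrow(ctn$edges),
                    length(key_targets$selected)))

  tpn <- NULL; tpn_tab <- NULL; pathways_res <- NULL; ctpn <- NULL
  if (!is.null(cfg$pathways)) {
    members <- read_pathway_table(cfg$pathways)
    whitelist <- ctn$nodes$id[ctn$nodes$class == "target"]
    tpn <- build_tpn(members, whitelist)
    if (nrow(tpn$nodes) > 0L) {
      tpn_tab <- centrality_table(tpn)
      name_map <- stats::setNames(members$pathway_name, members$pathway_id)
      name_map <- name_map[!duplicated(names(name_map))]
      pathways_res <- screen_important_pathways(
        tpn_tab,
        pathway_criteria(min_degree_exclusive = cfg$pathway_min_degree,
                         nonspecific_blocklist = cfg$nonspecific_blocklist),
        pathway_names = name_map)
      selected <- if (!is.null(cfg$selected_pathways))
        cfg$selected_pathways else pathways_res$selected
      ctpn <- build_ctpn(ctn, tpn, selected)
      log_stage(sprintf("TPN: %d nodes; %d important pathways; CTPN: %d nodes",
                        nrow(tpn$nodes), length(pathways_res$selected),
                        nrow(ctpn$nodes)))
    } else {
      skipped <- c(skipped, "pathway_screen", "ctpn")
    }
  } else {
    skipped <- c(skipped, "tpn", "pathway_screen", "ctpn")
  }

  report <- structure(list(
    threshold_energy = spec$derived_energy,
    integration = integ$report,
    ctn_summary = summarize_network(ctn),
    tpn_summary = if (!is.null(tpn)) summarize_network(tpn),
    ctpn_summary = if (!is.null(ctpn)) summarize_network(ctpn),
    key_targets = key_targets,
    important_pathways = pathways_res,
    networks = list(ctn = ctn, tpn = tpn, ctpn = ctpn),
    centrality = list(ctn = ctn_tab, tpn = tpn_tab),
    skipped = skipped,
    config = cfg[setdiff(names(cfg), "out_dir")],
    version = as.character(utils::packageVersion("netpharm"))
  ), class = "run_report")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(cfg$out_dir, "report.json"))
    utils::write.csv(ctn_tab, file.path(cfg$out_dir, "ctn_centrality.csv"),
                     row.names = FALSE)
    write_network(ctn, file.path(cfg$out_dir, "ctn.sif"), "sif")
    write_network(ctn, file.path(cfg$out_dir, "ctn.graphml"), "graphml")
    if (!is.null(tpn_tab)) {
      utils::write.csv(tpn_tab, file.path(cfg$out_dir, "tpn_centrality.csv"),
                       row.names = FALSE)
      write_network(tpn, file.path(cfg$out_dir, "tpn.graphml"), "graphml")
    }
    if (!is.null(ctpn))
      write_network(ctpn, file.path(cfg$out_dir, "ctpn.graphml"), "graphml")
  }
  report
}

#' Serialize a pipeline report to JSON
#'
#' Networks are written as node/edge tables so the JSON is self-contained;
#' serialization is deterministic (fixed key order, full precision) so two
#' identical runs give byte-identical files.
#'
#' @param report a \code{run_report} from [run_pipeline()].
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  strip <- function(x) {
    if (inherits(x, "typed_network"))
      return(list(nodes = x$nodes, edges = x$edges))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Re-load a serialized pipeline report
#'
#' @param path JSON path written by [write_report()].
#' @return the report as plain nested lists / data.frames.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @export
print.run_report <- function(x, ...) {
  cat("netpharm run report\n")
  cat(sprintf("  threshold: %.4f kcal/mol\n", x$threshold_energy))
  print(x$integration)
  cat("  CTN: "); print(x$ctn_summary)
  if (!is.null(x$tpn_summary)) { cat("  TPN: "); print(x$tpn_summary) }
  if (!is.null(x$ctpn_summary)) { cat("  CTPN: "); print(x$ctpn_summary) }
  cat(sprintf("  key targets: %s\n",
              paste(x$key_targets$selected, collapse = ", ")))
  if (!is.null(x$important_pathways))
    cat(sprintf("  important pathways: %s\n",
                paste(x$important_pathways$selected, collapse = ", ")))
  invisible(x)
}
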