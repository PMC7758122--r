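#' @title Docking-score thresholding via the Ki / binding-energy relation
#' @description The docking filter regards a protein as a target of a
#'   compound when the predicted binding free energy falls below the energy
#'   equivalent of an inhibition-constant cutoff, \eqn{\Delta G = RT \ln
#'   K_i}. At the conventional cutoff \eqn{K_i = 1\,\mu M} and room
#'   temperature this is the familiar \eqn{-8.18} kcal/mol.
#' @name dock-screen
NULL

# gas constant, kcal mol^-1 K^-1
GAS_CONSTANT_KCAL <- 1.987204e-3

# Default docking temperature (K). 298 K, not 298.15 K: only 298 K makes
# RT*ln(1e-6) round to the conventional -8.18 kcal/mol at 2 d.p.
DEFAULT_TEMPERATURE_K <- 298

#' Convert an inhibition constant to a binding free energy
#'
#' \eqn{\Delta G = R T \ln K_i} with \eqn{R = 1.987204 \times 10^{-3}}
#' kcal mol\eqn{^{-1}} K\eqn{^{-1}}. Sub-molar constants give negative
#' energies; \eqn{K_i = 1} mol/L gives exactly 0.
#'
#' @param ki_molar inhibition constant, mol/L (positive).
#' @param temperature_k temperature in kelvin (positive; default 298).
#' @return binding free energy in kcal/mol.
#' @examples
#' ki_to_binding_energy(1e-6)   # -8.18 at 2 d.p.
#' @export
ki_to_binding_energy <- function(ki_molar,
                                 temperature_k = DEFAULT_TEMPERATURE_K) {
  if (any(!is.finite(ki_molar)) || any(ki_molar <= 0))
    stop("ki_molar must be positive and finite")
  if (any(!is.finite(temperature_k)) || any(temperature_k <= 0))
    stop("temperature_k must be positive and finite")
  GAS_CONSTANT_KCAL * temperature_k * log(ki_molar)
}

#' Convert a binding free energy to an inhibition constant
#'
#' Exact inverse of [ki_to_binding_energy()]: \eqn{K_i =
#' \exp(\Delta G / RT)}.
#'
#' @param energy binding free energy, kcal/mol.
#' @param temperature_k temperature in kelvin (positive; default 298).
#' @return inhibition constant in mol/L.
#' @export
binding_energy_to_ki <- function(energy,
                                 temperature_k = DEFAULT_TEMPERATURE_K) {
  if (any(!is.finite(temperature_k)) || any(temperature_k <= 0))
    stop("temperature_k must be positive and finite")
  exp(energy / (GAS_CONSTANT_KCAL * temperature_k))
}

#' Docking acceptance threshold
#'
#' Bundles the inhibition-constant cutoff, the temperature and the derived
#' energy threshold. By default the energy is recomputed from \code{ki_molar}
#' so its thermodynamic provenance stays testable; \code{pin_energy} instead
#' pins a literal printed value (e.g. \code{-8.18}).
#'
#' @param ki_molar inhibition-constant cutoff in mol/L (default 1e-6,
#'   i.e. 1 micromolar).
#' @param temperature_k kelvin (default 298).
#' @param pin_energy optional literal energy threshold in kcal/mol that
#'   overrides the derived value.
#' @param comparison \code{"<"} (default; strictly lower energies pass,
#'   matching "lower than") or \code{"<="}.
#' @return an object of class \code{threshold_spec} with elements
#'   \code{ki_molar}, \code{temperature_k}, \code{derived_energy},
#'   \code{comparison}.
#' @examples
#' threshold_spec()$derived_energy   # about -8.18
#' @export
threshold_spec <- function(ki_molar = 1e-6,
                           temperature_k = DEFAULT_TEMPERATURE_K,
                           pin_energy = NULL,
                           comparison = c("<", "<=")) {
  comparison <- match.arg(comparison)
  energy <- if (is.null(pin_energy))
    ki_to_binding_energy(ki_molar, temperature_k)
  else as.numeric(pin_energy)
  structure(list(ki_molar = ki_molar, temperature_k = temperature_k,
                 derived_energy = energy, comparison = comparison),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("docking threshold: Ki = %g mol/L at %g K -> energy %s %.4f kcal/mol\n",
              x$ki_molar, x$temperature_k, x$comparison, x$derived_energy))
  invisible(x)
}

#' Filter docking records by binding-energy threshold
#'
#' Keeps records whose binding energy passes the threshold (strictly below
#' it by default; more negative = stronger binding) and emits them as
#' docking-evidenced interaction edges, input order preserved.
#'
#' @param records data.frame from [read_docking_table()].
#' @param spec a [threshold_spec()].
#' @return interaction-edge data.frame with \code{evidence = "docking"}
#'   and \code{source_label = "docking"}.
#' @examples
#' dock <- read_docking_table(
#'   system.file("extdata", "table2_docking.csv", package = "netpharm"))
#' hits <- filter_docking(dock, threshold_spec())
#' length(unique(hits$uniprot_ac))   # 19 docking-evidenced targets
#' @export
filter_docking <- function(records, spec = threshold_spec()) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (nrow(records) == 0L)
    return(interaction_edges(character(0), character(0), "docking"))
  pass <- if (spec$comparison == "<")
    records$binding_energy < spec$derived_energy
  else records$binding_energy <= spec$derived_energy
  kept <- records[pass, , drop = FALSE]
  interaction_edges(kept$compound_abbrev, kept$uniprot_ac,
                    "docking", "docking")
}

#' Integrate database- and docking-evidenced interaction edges
#'
#' Unions the two edge lists and deduplicates on (compound, target). When a
#' pair is supported by both evidence kinds the merged edge keeps
#' \code{evidence = "database"} and concatenates the source labels. The
#' accompanying report counts unique targets (accessions), not edges, and
#' satisfies the inclusion-exclusion identity
#' \code{n_union = n_known + n_docking - n_overlap}.
#'
#' @param known database-evidenced interaction edges (deduplicated).
#' @param docked docking-evidenced interaction edges (deduplicated).
#' @return list with elements \code{edges} (the integrated edge data.frame)
#'   and \code{report} (class \code{integration_report}: \code{n_known},
#'   \code{n_docking}, \code{n_union}, \code{n_overlap}).
#' @export
integrate_targets <- function(known, docked) {
  all_edges <- rbind(known[names(known)], docked[names(known)])
  edges <- dedup_edges(all_edges)
  t_known <- unique(known$uniprot_ac)
  t_dock <- unique(docked$uniprot_ac)
  report <- structure(list(
    n_known = length(t_known),
    n_docking = length(t_dock),
    n_union = length(union(t_known, t_dock)),
    n_overlap = length(intersect(t_known, t_dock))
  ), class = "integration_report")
  stopifnot(report$n_union == report$n_known + report$n_docking -
              report$n_overlap)
  list(edges = edges, report = report)
}

#' @export
print.integration_report <- function(x, ...) {
  cat(sprintf("targets: %d known, %d docking, %d overlap -> %d integrated\n",
              x$n_known, x$n_docking, x$n_overlap, x$n_union))
  invisible(x)
}
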