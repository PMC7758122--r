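#' @title Tabular readers for compound, docking, interaction and pathway data
#' @description Readers for the four CSV inputs of the pipeline. All readers
#'   accept comma- (default) or tab-delimited UTF-8 text with a header row;
#'   \code{"NA"} and the empty string both map to an absent value.
#' @name tabular-readers
NULL

# UniProt accession grammar (release format, 6- and 10-character forms)
uniprot_regex <- function() {
  paste0("^([OPQ][0-9][A-Z0-9]{3}[0-9]",
         "|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$")
}

is_uniprot_ac <- function(x) grepl(uniprot_regex(), x)

# KEGG human pathway identifier
is_kegg_id <- function(x) grepl("^hsa[0-9]+$", x)

blank_to_na <- function(x) {
  x <- trimws(x)
  x[x == "" | x == "NA"] <- NA_character_
  x
}

parse_num <- function(x, what, rows) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop("malformed numeric ", what, " in row(s) ",
         paste(rows[bad], collapse = ", "), ": ",
         paste(x[bad], collapse = ", "))
  out
}

read_table_raw <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = TRUE,
                  fileEncoding = "UTF-8")
}

#' Read a compound table
#'
#' Expected columns: \code{abbrev, name, cas, pubchem_cid, mw,
#' content_mg_per_ml, metabolite_of}. \code{abbrev} must be unique;
#' \code{metabolite_of}, when present, must name another row's abbreviation;
#' molecular weight must be a positive number. Row order is preserved.
#'
#' The packaged fixture \code{table1_compounds.csv} transcribes the thirteen
#' RDNI ingredients and metabolites (nine quantified ingredients plus four
#' metabolites).
#'
#' @param path CSV file path.
#' @param sep field delimiter; \code{","} (default) or \code{"\t"} for
#'   tab-delimited transcriptions of printed tables.
#' @return data.frame with one row per compound, character columns
#'   \code{abbrev, name, cas, metabolite_of}, numeric \code{mw,
#'   content_mg_per_ml} and integer \code{pubchem_cid}; absent cells are
#'   \code{NA}.
#' @examples
#' path <- system.file("extdata", "table1_compounds.csv", package = "netpharm")
#' compounds <- read_compound_table(path)
#' nrow(compounds)                         # 13
#' sum(!is.na(compounds$metabolite_of))    # 4
#' @export
read_compound_table <- function(path, sep = ",") {
  df <- read_table_raw(path, sep)
  need <- c("abbrev", "name", "cas", "pubchem_cid", "mw",
            "content_mg_per_ml", "metabolite_of")
  if (!all(need %in% names(df)))
    stop("compound table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) {
    out <- data.frame(abbrev = character(0), name = character(0),
                      cas = character(0), pubchem_cid = integer(0),
                      mw = numeric(0), content_mg_per_ml = numeric(0),
                      metabolite_of = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  rows <- seq_len(nrow(df)) + 1L  # file row numbers (header is row 1)
  abbrev <- blank_to_na(df$abbrev)
  if (anyNA(abbrev)) stop("missing abbrev in row(s) ",
                          paste(rows[is.na(abbrev)], collapse = ", "))
  if (anyDuplicated(abbrev))
    stop("duplicate compound abbrev: ",
         paste(unique(abbrev[duplicated(abbrev)]), collapse = ", "))
  mw <- parse_num(blank_to_na(df$mw), "mw", rows)
  if (any(is.na(mw) | mw <= 0))
    stop("mw must be a positive number; offending row(s): ",
         paste(rows[is.na(mw) | mw <= 0], collapse = ", "))
  cid <- parse_num(blank_to_na(df$pubchem_cid), "pubchem_cid", rows)
  if (any(!is.na(cid) & cid <= 0))
    stop("pubchem_cid must be positive; offending row(s): ",
         paste(rows[!is.na(cid) & cid <= 0], collapse = ", "))
  content <- parse_num(blank_to_na(df$content_mg_per_ml),
                       "content_mg_per_ml", rows)
  if (any(!is.na(content) & content < 0))
    stop("content_mg_per_ml must be non-negative; offending row(s): ",
         paste(rows[!is.na(content) & content < 0], collapse = ", "))
  parent <- blank_to_na(df$metabolite_of)
  unresolved <- setdiff(parent[!is.na(parent)], abbrev)
  if (length(unresolved))
    stop("metabolite_of refers to unknown abbrev: ",
         paste(unresolved, collapse = ", "))
  data.frame(abbrev = abbrev, name = blank_to_na(df$name),
             cas = blank_to_na(df$cas), pubchem_cid = as.integer(cid),
             mw = mw, content_mg_per_ml = content, metabolite_of = parent,
             stringsAsFactors = FALSE)
}

#' Read a molecular-docking results table
#'
#' Expected columns: \code{compound_abbrev, target_name, uniprot_ac,
#' binding_energy}. The compound column may be blank on continuation rows,
#' in which case the last seen compound label is carried down -- the dialect
#' of printed docking tables that list each compound once per block. The
#' packaged fixture \code{table2_docking.csv} transcribes the 38 accepted
#' docking records of the RDNI study.
#'
#' @inheritParams read_compound_table
#' @return data.frame with character \code{compound_abbrev, target_name,
#'   uniprot_ac} and numeric \code{binding_energy} (kcal/mol), one row per
#'   record, input order preserved.
#' @examples
#' path <- system.file("extdata", "table2_docking.csv", package = "netpharm")
#' dock <- read_docking_table(path)
#' nrow(dock)                 # 38
#' min(dock$binding_energy)   # -11.82
#' @export
read_docking_table <- function(path, sep = ",") {
  df <- read_table_raw(path, sep)
  need <- c("compound_abbrev", "target_name", "uniprot_ac", "binding_energy")
  if (!all(need %in% names(df)))
    stop("docking table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L)
    return(data.frame(compound_abbrev = character(0),
                      target_name = character(0), uniprot_ac = character(0),
                      binding_energy = numeric(0), stringsAsFactors = FALSE))
  rows <- seq_len(nrow(df)) + 1L
  comp <- blank_to_na(df$compound_abbrev)
  if (is.na(comp[1L]))
    stop("first docking row has no compound label (row 2)")
  for (i in seq_along(comp))            # carry the block label down
    if (is.na(comp[i])) comp[i] <- comp[i - 1L]
  ac <- blank_to_na(df$uniprot_ac)
  bad <- which(is.na(ac) | !is_uniprot_ac(ac))
  if (length(bad))
    stop("invalid UniProt accession in row(s) ",
         paste(rows[bad], collapse = ", "), ": ",
         paste(ac[bad], collapse = ", "))
  energy <- parse_num(blank_to_na(df$binding_energy), "binding_energy", rows)
  if (anyNA(energy))
    stop("missing binding_energy in row(s) ",
         paste(rows[is.na(energy)], collapse = ", "))
  key <- paste(comp, ac)
  if (anyDuplicated(key))
    stop("duplicate (compound, accession) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  data.frame(compound_abbrev = comp, target_name = blank_to_na(df$target_name),
             uniprot_ac = ac, binding_energy = energy,
             stringsAsFactors = FALSE)
}

#' Read a known compound-target edge list
#'
#' Expected columns: \code{compound_abbrev, uniprot_ac, source_label}
#' (\code{source_label} optional; e.g. a database name). Edges are
#' deduplicated on (compound, accession) with source labels concatenated.
#'
#' @inheritParams read_compound_table
#' @return an interaction-edge data.frame (see [interaction_edges()]) with
#'   \code{evidence = "database"}.
#' @export
read_known_edges <- function(path, sep = ",") {
  df <- read_table_raw(path, sep)
  need <- c("compound_abbrev", "uniprot_ac")
  if (!all(need %in% names(df)))
    stop("known-edge table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L)
    return(interaction_edges(character(0), character(0), "database",
                             character(0)))
  rows <- seq_len(nrow(df)) + 1L
  ac <- blank_to_na(df$uniprot_ac)
  bad <- which(is.na(ac) | !is_uniprot_ac(ac))
  if (length(bad))
    stop("invalid UniProt accession in row(s) ",
         paste(rows[bad], collapse = ", "))
  lab <- if ("source_label" %in% names(df)) blank_to_na(df$source_label)
         else rep(NA_character_, nrow(df))
  lab[is.na(lab)] <- "database"
  e <- interaction_edges(blank_to_na(df$compound_abbrev), ac,
                         "database", lab)
  dedup_edges(e)
}

#' Read a target-pathway membership table
#'
#' Expected columns: \code{uniprot_ac, pathway_id, pathway_name}
#' (\code{pathway_name} optional). Pathway ids must match the KEGG human
#' map pattern \code{hsaNNNNN}; (accession, pathway) pairs must be unique.
#'
#' @inheritParams read_compound_table
#' @return data.frame with character columns \code{uniprot_ac, pathway_id,
#'   pathway_name}.
#' @export
read_pathway_table <- function(path, sep = ",") {
  df <- read_table_raw(path, sep)
  need <- c("uniprot_ac", "pathway_id")
  if (!all(need %in% names(df)))
    stop("pathway table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L)
    return(data.frame(uniprot_ac = character(0), pathway_id = character(0),
                      pathway_name = character(0), stringsAsFactors = FALSE))
  rows <- seq_len(nrow(df)) + 1L
  ac <- blank_to_na(df$uniprot_ac)
  bad <- which(is.na(ac) | !is_uniprot_ac(ac))
  if (length(bad))
    stop("invalid UniProt accession in row(s) ",
         paste(rows[bad], collapse = ", "))
  pid <- blank_to_na(df$pathway_id)
  bad <- which(is.na(pid) | !is_kegg_id(pid))
  if (length(bad))
    stop("invalid KEGG pathway id (expected hsaNNNNN) in row(s) ",
         paste(rows[bad], collapse = ", "))
  key <- paste(ac, pid)
  if (anyDuplicated(key))
    stop("duplicate (accession, pathway) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  nm <- if ("pathway_name" %in% names(df)) blank_to_na(df$pathway_name)
        else rep(NA_character_, nrow(df))
  data.frame(uniprot_ac = ac, pathway_id = pid, pathway_name = nm,
             stringsAsFactors = FALSE)
}

#' Construct an interaction-edge data.frame
#'
#' The common currency between the docking filter, the multi-source
#' integrator and the network builders: one row per evidenced
#' compound-target link.
#'
#' @param compound_abbrev character vector of compound keys.
#' @param uniprot_ac character vector of UniProt accessions.
#' @param evidence \code{"database"} or \code{"docking"} (recycled).
#' @param source_label free-text provenance label (recycled).
#' @return data.frame with columns \code{compound_abbrev, uniprot_ac,
#'   evidence, source_label}.
#' @export
interaction_edges <- function(compound_abbrev, uniprot_ac,
                              evidence = "database",
                              source_label = evidence) {
  n <- length(compound_abbrev)
  stopifnot(length(uniprot_ac) == n)
  evidence <- rep_len(as.character(evidence), n)
  bad <- setdiff(unique(evidence), c("database", "docking"))
  if (length(bad) && n > 0L)
    stop("evidence must be 'database' or 'docking', got: ",
         paste(bad, collapse = ", "))
  data.frame(compound_abbrev = as.character(compound_abbrev),
             uniprot_ac = as.character(uniprot_ac),
             evidence = evidence,
             source_label = rep_len(as.character(source_label), n),
             stringsAsFactors = FALSE)
}

# deduplicate interaction edges on (compound, target); labels concatenated,
# evidence "database" wins over "docking" when both support a pair
dedup_edges <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  key <- paste(edges$compound_abbrev, edges$uniprot_ac, sep = "\r")
  if (!anyDuplicated(key)) return(edges)
  idx <- split(seq_len(nrow(edges)), factor(key, levels = unique(key)))
  out <- lapply(idx, function(i) {
    ev <- if (any(edges$evidence[i] == "database")) "database" else "docking"
    data.frame(compound_abbrev = edges$compound_abbrev[i[1L]],
               uniprot_ac = edges$uniprot_ac[i[1L]],
               evidence = ev,
               source_label = paste(unique(edges$source_label[i]),
                                    collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
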