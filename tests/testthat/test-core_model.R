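test_that("compound table fixture parses with metadata intact", {
  comp <- read_compound_table(fixture("table1_compounds.csv"))
  expect_equal(nrow(comp), 13L)
  expect_equal(sum(!is.na(comp$metabolite_of)), 4L)
  # order preserved: quantified ingredients first, metabolites last
  expect_equal(comp$abbrev[1:4], c("5CQA", "CGA", "4CQA", "CAA"))
  expect_equal(comp$metabolite_of[comp$abbrev == "Gep"], "Gen")
  expect_equal(comp$metabolite_of[comp$abbrev %in% c("FA", "DFA", "HCA")],
               rep("CAA", 3))
  # "NA" cells map to absent: DFA has no CAS, metabolites no content
  expect_true(is.na(comp$cas[comp$abbrev == "DFA"]))
  expect_true(all(is.na(comp$content_mg_per_ml[!is.na(comp$metabolite_of)])))
  expect_true(all(comp$mw > 0))
  expect_equal(comp$pubchem_cid[comp$abbrev == "CAA"], 689043L)
})

test_that("compound table invariants are enforced", {
  hdr <- "abbrev,name,cas,pubchem_cid,mw,content_mg_per_ml,metabolite_of"
  expect_equal(nrow(read_compound_table(write_tmp_csv(hdr))), 0L)
  expect_error(
    read_compound_table(write_tmp_csv(c(hdr,
      "CAA,Caffeic acid,NA,1,180.15,NA,NA",
      "CAA,Caffeic acid again,NA,2,180.15,NA,NA"))),
    "duplicate compound abbrev.*CAA")
  expect_error(
    read_compound_table(write_tmp_csv(c(hdr,
      "CAA,Caffeic acid,NA,1,not-a-number,NA,NA"))),
    "malformed numeric mw.*row.* 2")
  expect_error(
    read_compound_table(write_tmp_csv(c(hdr,
      "CAA,Caffeic acid,NA,1,-5,NA,NA"))),
    "mw must be a positive number")
  expect_error(
    read_compound_table(write_tmp_csv(c(hdr,
      "FA,Ferulic acid,NA,1,194.18,NA,CAA"))),
    "metabolite_of refers to unknown abbrev: CAA")
})

test_that("docking table fixture parses with carried-down compound labels", {
  dock <- read_docking_table(fixture("table2_docking.csv"))
  expect_equal(nrow(dock), 38L)
  expect_equal(length(unique(dock$compound_abbrev)), 8L)
  # continuation rows inherit the block label
  expect_equal(dock$compound_abbrev[1:5], rep("4CQA", 5))
  expect_equal(sum(dock$compound_abbrev == "IsoA"), 9L)
  expect_equal(min(dock$binding_energy), -11.82)
  expect_equal(dock$uniprot_ac[which.min(dock$binding_energy)], "P14555")
  expect_true(all(grepl("^[OPQ][0-9][A-Z0-9]{3}[0-9]$", dock$uniprot_ac)))
})

test_that("docking table rejects malformed rows; single row round-trips", {
  hdr <- "compound_abbrev,target_name,uniprot_ac,binding_energy"
  one <- read_docking_table(write_tmp_csv(c(hdr, "CAA,PTGS2,P35354,-8.5")))
  expect_equal(one$compound_abbrev, "CAA")
  expect_equal(one$binding_energy, -8.5)
  expect_error(
    read_docking_table(write_tmp_csv(c(hdr, "CAA,PTGS2,NOTANAC,-8.5"))),
    "invalid UniProt accession")
  expect_error(
    read_docking_table(write_tmp_csv(c(hdr, "CAA,PTGS2,P35354,strong"))),
    "malformed numeric binding_energy")
  expect_error(
    read_docking_table(write_tmp_csv(c(hdr, ",PTGS2,P35354,-8.5"))),
    "no compound label")
})

test_that("typed_network enforces its invariants", {
  nodes <- data.frame(id = c("a", "b"), class = c("compound", "target"))
  expect_error(typed_network(nodes, data.frame(from = "a", to = "a")),
               "self-loop")
  expect_error(typed_network(nodes, data.frame(from = "a", to = "c")),
               "endpoint.*c")
  expect_error(typed_network(nodes,
                             data.frame(from = c("a", "b"), to = c("b", "a"))),
               "duplicate edge")
  expect_error(typed_network(data.frame(id = c("a", "a"),
                                        class = c("target", "target"))),
               "duplicate node")
  expect_error(typed_network(data.frame(id = "a", class = "gene")),
               "unknown node class")
  expect_error(typed_network(nodes, data.frame(from = "a", to = "b"),
                             allowed = "target-pathway"),
               "not allowed")
})

test_that("SIF export writes one labelled line per edge", {
  net <- net_from_edges(c("CAA", "P35354"),
                        classes = c(CAA = "compound", P35354 = "target"))
  f <- tempfile(fileext = ".sif")
  write_network(net, f, "sif")
  expect_equal(readLines(f), "CAA\tcompound-target\tP35354")
  expect_error(write_network(net, f, "gexf"), "unknown network format")
})

test_that("graphml and edge-csv round-trip randomized networks exactly", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(5:200, 1)
    net <- random_typed_network(n, p = min(1, 3 / n))
    if (nrow(net$edges) == 0) next
    for (fmt in c("graphml", "edge-csv")) {
      f <- tempfile(fileext = paste0(".", fmt))
      write_network(net, f, fmt)
      back <- read_network(f, fmt)
      expect_setequal(paste(back$nodes$id, back$nodes$class),
                      paste(net$nodes$id, net$nodes$class))
      expect_setequal(paste(pmin(back$edges$from, back$edges$to),
                            pmax(back$edges$from, back$edges$to)),
                      paste(pmin(net$edges$from, net$edges$to),
                            pmax(net$edges$from, net$edges$to)))
    }
  }
})

test_that("edge-csv has a header plus one row per edge", {
  net <- random_typed_network(30, 0.15)
  f <- tempfile(fileext = ".csv")
  write_network(net, f, "edge-csv")
  expect_equal(length(readLines(f)), nrow(net$edges) + 1L)
})

test_that("known-edge and pathway readers validate accessions and ids", {
  ke <- read_known_edges(write_tmp_csv(c(
    "compound_abbrev,uniprot_ac,source_label",
    "CAA,P35354,TCMSP", "CAA,P35354,BindingDB", "FA,P29474,PubChem")))
  expect_equal(nrow(ke), 2L)  # deduplicated, labels concatenated
  expect_equal(ke$source_label[1], "TCMSP;BindingDB")
  expect_true(all(ke$evidence == "database"))
  expect_error(read_known_edges(write_tmp_csv(c(
    "compound_abbrev,uniprot_ac", "CAA,xyz"))), "invalid UniProt")

  pw <- read_pathway_table(write_tmp_csv(c(
    "uniprot_ac,pathway_id,pathway_name",
    "P35354,hsa04915,estrogen signaling pathway")))
  expect_equal(pw$pathway_id, "hsa04915")
  expect_error(read_pathway_table(write_tmp_csv(c(
    "uniprot_ac,pathway_id", "P35354,map04915"))), "invalid KEGG")
  expect_error(read_pathway_table(write_tmp_csv(c(
    "uniprot_ac,pathway_id", "P35354,hsa04915", "P35354,hsa04915"))),
    "duplicate")
})
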