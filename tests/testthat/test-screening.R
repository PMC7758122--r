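make_table <- function(node, class, degree, betweenness, closeness) {
  data.frame(node = node, class = class, degree = degree,
             betweenness = betweenness,
             betweenness_norm = betweenness,
             closeness = closeness, stringsAsFactors = FALSE)
}

test_that("single-target screening is empty under strict mean comparison", {
  tab <- make_table(c("P00001", "C1"), c("target", "compound"),
                    c(3, 3), c(1, 0), c(0.5, 0.4))
  res <- screen_key_targets(tab)
  expect_equal(res$selected, character(0))
  expect_equal(nrow(res$audit), 1L)
  expect_true(res$audit$in_top_k)
  expect_false(res$audit$betweenness_above_mean)
})

test_that("toy target screen keeps the hub above both means", {
  tab <- make_table(
    c("T1", "T2", "T3", "T4", "C1"),
    c(rep("target", 4), "compound"),
    c(5, 4, 1, 1, 7),
    c(10, 8, 0, 0, 20),
    c(0.8, 0.7, 0.2, 0.2, 0.9))
  res <- screen_key_targets(tab, target_criteria(top_k_degree = 2))
  # degree boundary is the 2nd largest value (4); T1 and T2 audited in,
  # both above the class means -> both selected, hub first
  expect_equal(res$thresholds$degree_boundary, 4)
  expect_equal(sum(res$audit$in_top_k), 2L)
  expect_equal(res$selected, c("T1", "T2"))
  expect_equal(res$audit$node, c("T1", "T2", "T3", "T4"))
  expect_error(screen_key_targets(tab[tab$class == "compound", ]),
               "no target-class nodes")
})

test_that("top-k tie inclusion is insensitive to row order", {
  set.seed(21)
  tab <- make_table(sprintf("T%02d", 1:15), "target",
                    c(9, 9, 7, 7, 7, 7, 5, 4, 3, 3, 2, 2, 1, 1, 1),
                    stats::runif(15, 0, 5), stats::runif(15))
  base <- screen_key_targets(tab, target_criteria(top_k_degree = 5))
  # k-th value is 7: all four ties included
  expect_true(all(tab$node[tab$degree >= 7] %in%
                    base$audit$node[base$audit$in_top_k]))
  for (rep in 1:5) {
    perm <- tab[sample(nrow(tab)), ]
    res <- screen_key_targets(perm, target_criteria(top_k_degree = 5))
    expect_identical(res$selected, base$selected)
    expect_identical(res$audit, base$audit)
  }
})

test_that("enlarging top_k never removes a selected target", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(8:30, 1)
    tab <- make_table(sprintf("T%02d", 1:n), "target",
                      sample(1:10, n, replace = TRUE),
                      stats::runif(n, 0, 5), stats::runif(n))
    prev <- character(0)
    for (k in c(2, 5, 10, 20)) {
      sel <- screen_key_targets(tab, target_criteria(top_k_degree = k))$selected
      expect_true(all(prev %in% sel))
      prev <- sel
    }
  }
})

test_that("pathway cascade applies degree, betweenness, blocklist, closeness", {
  tab <- make_table(
    c(sprintf("hsa%05d", 1:6), "T1"),
    c(rep("pathway", 6), "target"),
    degree = c(10, 9, 8, 7, 6, 2, 4),
    betweenness = c(50, 40, 35, 1, 60, 0, 5),
    closeness = c(0.9, 0.8, 0.1, 0.9, 0.9, 0.1, 0.5))
  names_map <- stats::setNames(
    c("estrogen signaling pathway", "metabolic pathways",
      "PI3K-AKT signaling pathway", "calcium signaling pathway",
      "pathways in cancer", "nitrogen metabolism"),
    sprintf("hsa%05d", 1:6))
  res <- screen_important_pathways(tab, pathway_criteria(),
                                   pathway_names = names_map)
  audit <- res$audit
  stage <- stats::setNames(audit$stage_removed, audit$node)
  expect_equal(res$selected, "hsa00001")
  expect_equal(stage[["hsa00005"]], "degree")      # degree 6 is not > 6
  expect_equal(stage[["hsa00006"]], "degree")
  expect_equal(stage[["hsa00004"]], "betweenness")
  expect_equal(stage[["hsa00002"]], "nonspecific") # blocklisted by name
  expect_equal(stage[["hsa00003"]], "closeness")
  expect_true(is.na(stage[["hsa00001"]]))
  expect_error(screen_important_pathways(tab[tab$class == "target", ]),
               "no pathway-class nodes")
})

test_that("a blocklisted pathway passing every numeric test is still removed", {
  tab <- make_table(c("hsa00001", "hsa00002", "hsa00003"), "pathway",
                    c(10, 9, 2), c(50, 40, 0), c(0.9, 0.8, 0.1))
  res <- screen_important_pathways(
    tab, pathway_criteria(nonspecific_blocklist = "hsa00001"))
  expect_equal(res$selected, "hsa00002")
  expect_equal(res$audit$stage_removed[res$audit$node == "hsa00001"],
               "nonspecific")
})

test_that("raising the degree cutoff never adds a pathway", {
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    tab <- make_table(sprintf("hsa%05d", 1:n), "pathway",
                      sample(1:15, n, replace = TRUE),
                      stats::runif(n, 0, 10), stats::runif(n))
    prev <- NULL
    for (cutoff in c(2, 4, 6, 9)) {
      sel <- screen_important_pathways(
        tab, pathway_criteria(min_degree_exclusive = cutoff))$selected
      if (!is.null(prev)) expect_true(all(sel %in% prev))
      prev <- sel
    }
  }
})

test_that("a 12-candidate pathway table narrows to 6 important pathways", {
  # planted: 12 pathways pass degree > 6 and betweenness > mean; of those,
  # 4 are blocklisted catch-all maps and 2 have low closeness -> 6 remain
  high <- make_table(sprintf("hsa%05d", 1:12), "pathway",
                     degree = rep(10, 12),
                     betweenness = rep(30, 12),
                     closeness = c(rep(0.9, 10), 0.05, 0.05))
  low <- make_table(sprintf("hsa%05d", 13:42), "pathway",
                    degree = rep(2, 30), betweenness = rep(0.1, 30),
                    closeness = rep(0.4, 30))
  tab <- rbind(high, low)
  names_map <- stats::setNames(
    c("metabolic pathways", "pathways in cancer",
      "neuroactive ligand-receptor interaction", "microRNAs in cancer",
      sprintf("specific pathway %d", 5:42)),
    sprintf("hsa%05d", 1:42))
  res <- screen_important_pathways(tab, pathway_criteria(),
                                   pathway_names = names_map)
  expect_equal(length(res$selected), 6L)
  expect_equal(sum(res$audit$stage_removed == "nonspecific", na.rm = TRUE),
               4L)
  expect_equal(sum(res$audit$stage_removed == "closeness", na.rm = TRUE), 2L)
})

test_that("cross-talk fixture loads, validates, and exports", {
  ct <- load_crosstalk(fixture("fig4_crosstalk.csv"))
  expect_true(nrow(ct) >= 7)
  expect_true(validate_crosstalk(ct))
  expect_true(any(ct$is_feedback))
  f <- tempfile(fileext = ".sif")
  write_crosstalk_sif(ct, f)
  lines <- readLines(f)
  expect_equal(length(lines), nrow(ct))
  expect_true(any(grepl("\tfeedback\t", lines)))

  bad <- write_tmp_csv(c("from_pathway,to_pathway,connector,is_feedback",
                         "estrogen signaling pathway,WNT pathway,x,FALSE"))
  expect_error(load_crosstalk(bad), "unknown cross-talk pathway")

  empty <- write_tmp_csv("from_pathway,to_pathway,connector,is_feedback")
  ct0 <- load_crosstalk(empty)
  expect_equal(nrow(ct0), 0L)
  expect_error(validate_crosstalk(ct0), "without an edge")
})

test_that("selections are identical under raw and normalized betweenness", {
  set.seed(55)
  gen <- generate_tripartite(generator_config(seed = 55))
  ctn <- build_ctn(gen$edges)
  tab <- centrality_table(ctn)
  tab_norm <- tab
  tab_norm$betweenness <- tab$betweenness_norm
  expect_identical(screen_key_targets(tab)$selected,
                   screen_key_targets(tab_norm)$selected)
})
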