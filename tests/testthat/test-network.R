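write_edge_file <- function(df, dialect = c("node", "protein")) {
  dialect <- match.arg(dialect)
  if (dialect == "protein") names(df)[1:2] <- c("protein1", "protein2")
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("edge loading canonicalizes orientations and applies the score cutoff", {
  df <- data.frame(node1 = c("b", "a", "c", "d", "e"),
                   node2 = c("a", "b", "c", "e", "d"),
                   combined_score = c(700, 650, 900, 399, 400))
  e <- load_edges(write_edge_file(df), min_score = 400)
  # both orientations of a-b collapse to one edge at the max score;
  # the c-c self loop goes; 399 is dropped and 400 kept
  expect_equal(nrow(e), 2)
  expect_identical(e$node1, c("a", "d"))
  expect_equal(e$combined_score[e$node1 == "a"], 700)
  expect_equal(e$combined_score[e$node1 == "d"], 400)
})

test_that("both STRING header dialects parse identically", {
  df <- data.frame(node1 = c("x", "y"), node2 = c("y", "z"),
                   combined_score = c(500, 800))
  e1 <- load_edges(write_edge_file(df, "node"))
  e2 <- load_edges(write_edge_file(df, "protein"))
  expect_identical(e1, e2)
})

test_that("malformed edge rows are reported with their line numbers", {
  df <- data.frame(node1 = c("a", "b"), node2 = c("b", "c"),
                   combined_score = c(500, 1500))
  expect_error(load_edges(write_edge_file(df)), "line 2")
})

test_that("edge filtering matches a brute-force scan on a toy table", {
  set.seed(31)
  df <- random_edge_table(letters[1:8], 20, seed = 31)
  e <- load_edges(write_edge_file(df), min_score = 400)
  seen <- character(0)
  for (i in seq_len(nrow(df))) {
    a <- min(df$node1[i], df$node2[i]); b <- max(df$node1[i], df$node2[i])
    if (a != b) {
      best <- max(df$combined_score[(pmin(df$node1, df$node2) == a) &
                                      (pmax(df$node1, df$node2) == b)])
      if (best >= 400) seen <- unique(c(seen, paste(a, b)))
    }
  }
  expect_setequal(paste(e$node1, e$node2), seen)
})

test_that("subnetwork build drops orphans and reports coverage", {
  edges <- data.frame(node1 = "a", node2 = "b", combined_score = 900L)
  net <- build_subnetwork(c("a", "b", "c"), edges)
  expect_setequal(net$nodes$gene_id, c("a", "b"))
  expect_equal(attr(net, "coverage"), 2 / 3)
  expect_warning(build_subnetwork(c("x", "y"), edges), "empty")
  expect_error(build_subnetwork(character(0), edges), "empty")
})

test_that("induced subgraphs match brute-force construction on random instances", {
  set.seed(32)
  genes <- sprintf("n%02d", 1:40)
  for (rep in 1:8) {
    edges <- tcensemble:::canonicalize_edges(random_edge_table(genes, 100, seed = rep))
    cand <- sample(genes, 30)
    net <- suppressWarnings(build_subnetwork(cand, edges))
    expect_identical(net$nodes$gene_id, brute_subnetwork_nodes(cand, edges))
    expect_true(all(net$edges$node1 %in% cand & net$edges$node2 %in% cand))
    # no orphans: every node appears in at least one edge
    expect_true(all(net$nodes$gene_id %in% c(net$edges$node1, net$edges$node2)))
  }
})

test_that("temporal annotation applies the first-DE and direction rules", {
  edges <- data.frame(node1 = c("a", "a", "b"), node2 = c("b", "c", "c"),
                      combined_score = 800L)
  net <- build_subnetwork(c("a", "b", "c"), edges, experiment = "SB")
  lfc <- data.frame(gene_id = c("a", "b", "c"),
                    lfc_3h = c(0.3, -0.2, -0.8),
                    lfc_6h = c(0.6, 0.1, -1.2),
                    lfc_9h = c(0.9, 0.3, -1.5))
  ann <- annotate_first_de(net, lfc, lambda = 0.5)
  n <- ann$nodes
  expect_equal(n$first_de_timepoint[n$gene_id == "a"], 6)
  expect_identical(unlist(n[n$gene_id == "a", c("dir_3h", "dir_6h", "dir_9h")],
                          use.names = FALSE), c("none", "up", "up"))
  expect_true(is.na(n$first_de_timepoint[n$gene_id == "b"]))
  expect_equal(n$first_de_timepoint[n$gene_id == "c"], 3)
  expect_identical(unlist(n[n$gene_id == "c", c("dir_3h", "dir_6h", "dir_9h")],
                          use.names = FALSE), c("down", "down", "down"))
  expect_error(annotate_first_de(net, lfc[1:2, ], 0.5), "missing")
})

test_that("merging is additive on disjoint inputs and idempotent on identical ones", {
  e1 <- data.frame(node1 = "a", node2 = "b", combined_score = 700L)
  e2 <- data.frame(node1 = "x", node2 = "y", combined_score = 600L)
  n1 <- build_subnetwork(c("a", "b"), e1, "SB")
  n2 <- build_subnetwork(c("x", "y"), e2, "SU")
  m <- merge_networks(n1, n2)
  expect_equal(nrow(m$nodes), 4)
  expect_setequal(m$nodes$experiment, c("SB", "SU"))
  same <- merge_networks(n1, build_subnetwork(c("a", "b"), e1, "SU"))
  expect_true(all(same$nodes$experiment == "both"))
  expect_equal(nrow(same$edges), 1)
})

test_that("merge is commutative up to ordering and resolves scores by maximum", {
  ea <- data.frame(node1 = c("a", "b"), node2 = c("b", "c"),
                   combined_score = c(500L, 700L))
  eb <- data.frame(node1 = c("a", "c"), node2 = c("b", "d"),
                   combined_score = c(900L, 800L))
  na <- build_subnetwork(c("a", "b", "c"), ea, "SB")
  nb <- build_subnetwork(c("a", "b", "c", "d"), eb, "SU")
  ab <- merge_networks(na, nb)
  ba <- merge_networks(nb, na)
  expect_identical(ab$edges, ba$edges)
  expect_setequal(ab$nodes$gene_id, ba$nodes$gene_id)
  expect_equal(ab$edges$combined_score[ab$edges$node1 == "a"], 900)
})

test_that("crosstalk extraction keeps shared targets plus direct neighbors only", {
  edges <- data.frame(node1 = c("s", "a"), node2 = c("a", "b"),
                      combined_score = 800L)
  net <- build_subnetwork(c("s", "a", "b"), edges, "SB")
  cross <- extract_crosstalk(net, "s")
  expect_setequal(cross$nodes$gene_id, c("s", "a"))
  expect_equal(nrow(cross$edges), 1)
  expect_true(cross$nodes$shared_target[cross$nodes$gene_id == "s"])
  expect_warning(out <- extract_crosstalk(net, character(0)), "empty")
  expect_equal(nrow(out$nodes), 0)
})

test_that("crosstalk matches brute-force neighborhood scans and is idempotent", {
  set.seed(33)
  genes <- sprintf("n%02d", 1:30)
  for (rep in 1:8) {
    edges <- tcensemble:::canonicalize_edges(random_edge_table(genes, 70, seed = rep + 50))
    net <- suppressWarnings(build_subnetwork(genes, edges, "SB"))
    shared <- sample(net$nodes$gene_id, min(4, nrow(net$nodes)))
    cross <- extract_crosstalk(net, shared)
    expect_identical(cross$nodes$gene_id,
                     brute_crosstalk_nodes(net$edges, shared))
    # subset of the input and stable under re-extraction
    expect_true(all(cross$nodes$gene_id %in% net$nodes$gene_id))
    again <- extract_crosstalk(cross, intersect(shared, cross$nodes$gene_id))
    expect_identical(again$nodes$gene_id, cross$nodes$gene_id)
    expect_identical(again$edges, cross$edges)
    # every non-shared survivor touches a shared target
    for (g in setdiff(cross$nodes$gene_id, shared)) {
      touching <- cross$edges$node1 == g | cross$edges$node2 == g
      partners <- unique(c(cross$edges$node1[touching], cross$edges$node2[touching]))
      expect_true(any(partners %in% shared))
    }
  }
})

test_that("direction concordance follows the max-|LFC| sign rule", {
  expect_equal(classify_direction(c(0.6, 1.2, 1.5), c(0.9, 1.4, 2.0)), "synergistic")
  expect_equal(classify_direction(c(-0.6, -1.2, -1.5), c(0.9, 1.4, 2.0)), "antagonistic")
  expect_equal(classify_direction(c(0.9, 0.4, 0.2), c(0.0, 0.3, 0.5), 0.5, 0.7),
               "indeterminate")
})

test_that("graphml export is deterministic", {
  edges <- data.frame(node1 = c("a", "b"), node2 = c("b", "c"),
                      combined_score = c(500L, 700L))
  net <- build_subnetwork(c("a", "b", "c"), edges, "SB")
  lfc <- data.frame(gene_id = c("a", "b", "c"), lfc_3h = c(1, -1, 0.2),
                    lfc_6h = 0, lfc_9h = 0)
  net <- annotate_first_de(net, lfc, 0.5)
  p1 <- withr::local_tempfile(fileext = ".graphml")
  p2 <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, p1)
  write_graphml(net, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_true(file.exists(paste0(p1, ".nodes.tsv")))
})
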