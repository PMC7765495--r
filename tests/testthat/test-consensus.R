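test_that("positive-control anchoring reproduces the documented thresholds", {
  tab <- data.frame(gene_id = "CTRL", lfc_3h = -0.58, lfc_6h = -1.24,
                    lfc_9h = -1.54)
  expect_equal(as.numeric(calibrate_lfc_threshold(tab, "CTRL")), 0.5)
  tab2 <- data.frame(gene_id = "CTRL", lfc_3h = 0.74, lfc_6h = 1.2, lfc_9h = 2.0)
  lam <- calibrate_lfc_threshold(tab2, "CTRL")
  expect_equal(as.numeric(lam), 0.7)
  expect_equal(attr(lam, "timepoint"), 3)
})

test_that("anchoring fails loudly on absent or flat controls", {
  tab <- data.frame(gene_id = "CTRL", lfc_3h = 0, lfc_6h = 0, lfc_9h = 0)
  expect_error(calibrate_lfc_threshold(tab, "CTRL"), "flat")
  expect_error(calibrate_lfc_threshold(tab, "OTHER"), "absent")
  # below-noise early point is skipped, not used
  tab3 <- data.frame(gene_id = "CTRL", lfc_3h = 0.05, lfc_6h = 0.93, lfc_9h = 1.5)
  expect_equal(as.numeric(calibrate_lfc_threshold(tab3, "CTRL")), 0.9)
  expect_equal(as.numeric(calibrate_lfc_threshold(tab3, "CTRL",
                                                  rule = "min_significant")), 0.9)
})

test_that("gates are inclusive at lambda and exclusive at alpha", {
  genes <- c("g1", "g2")
  res <- list(t1 = fake_result("t1", genes, c(0.04, 0.04)))
  res$t1$p_adj <- res$t1$p_raw  # gate directly on these values
  lfc <- data.frame(gene_id = genes, lfc_3h = c(0.49, 0.50),
                    lfc_6h = 0, lfc_9h = 0)
  sets <- apply_gates(res, lfc, consensus_config(alpha = 0.05, lambda = 0.5))
  expect_false("g1" %in% sets$t1)
  expect_true("g2" %in% sets$t1)
})

test_that("gates match a brute-force double-filter scan on random tables", {
  set.seed(21)
  for (rep in 1:8) {
    genes <- sprintf("g%03d", 1:100)
    res <- lapply(setNames(nm = c("a", "b", "c", "d")), function(nm) {
      fake_result(nm, genes, runif(100))
    })
    lfc <- data.frame(gene_id = genes, lfc_3h = rnorm(100, 0, 0.6),
                      lfc_6h = rnorm(100, 0, 0.6), lfc_9h = rnorm(100, 0, 0.6))
    cfg <- consensus_config(alpha = runif(1, 0.01, 0.3),
                            lambda = runif(1, 0, 1))
    expect_identical(apply_gates(res, lfc, cfg),
                     brute_gates(res, lfc, cfg$alpha, cfg$lambda))
  }
})

test_that("mismatched gene universes are rejected with the difference listed", {
  res <- list(a = fake_result("a", c("g1", "g2"), c(0.1, 0.2)),
              b = fake_result("b", c("g1", "g3"), c(0.1, 0.2)))
  lfc <- data.frame(gene_id = c("g1", "g2"), lfc_3h = 0, lfc_6h = 0, lfc_9h = 0)
  expect_error(apply_gates(res, lfc, consensus_config()), "g3")
})

test_that("voting matches membership enumeration", {
  sets <- list(A = c("g1", "g2", "g3"), B = c("g1", "g2"),
               C = c("g1", "g3"), D = "g4")
  v <- consensus_vote(sets, 3)
  expect_identical(v$gene_id, "g1")
  expect_identical(v$supporting_tools, "A;B;C")
  expect_identical(consensus_vote(list(A = character(0), B = character(0)), 1)$gene_id,
                   character(0))
  expect_setequal(consensus_vote(sets, 1)$gene_id, unique(unlist(sets)))
  expect_error(consensus_vote(sets, 5), "exceeds")
})

test_that("overlap regions partition the union", {
  expect_equal(sum(overlap_summary(list(A = "a", B = "b"))$count), 2)
  ident <- overlap_summary(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(ident$count[ident$region == "A;B"], 2)
  expect_equal(sum(ident$count), 2)
  set.seed(22)
  for (rep in 1:8) {
    genes <- sprintf("g%02d", 1:50)
    sets <- lapply(setNames(nm = c("A", "B", "C", "D")), function(nm) {
      sample(genes, rpois(1, 15))
    })
    ov <- overlap_summary(sets)
    expect_equal(sum(ov$count), length(unique(unlist(sets))))
    brute <- brute_overlap(sets)
    for (k in names(brute)) {
      expect_equal(ov$count[ov$region == k], brute[[k]],
                   info = paste("region", k))
    }
  }
})

test_that("vote and gate monotonicity hold on random inputs", {
  set.seed(23)
  genes <- sprintf("g%03d", 1:80)
  res <- lapply(setNames(nm = c("a", "b", "c", "d")), function(nm) {
    fake_result(nm, genes, runif(80))
  })
  lfc <- data.frame(gene_id = genes, lfc_3h = rnorm(80, 0, 0.7),
                    lfc_6h = rnorm(80, 0, 0.7), lfc_9h = rnorm(80, 0, 0.7))
  sets <- apply_gates(res, lfc, consensus_config(alpha = 0.2, lambda = 0.4))
  prev <- NULL
  for (k in 1:4) {
    cur <- consensus_vote(sets, k)$gene_id
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  # relaxing either gate only grows each tool set
  tight <- apply_gates(res, lfc, consensus_config(alpha = 0.05, lambda = 0.6))
  loose_a <- apply_gates(res, lfc, consensus_config(alpha = 0.2, lambda = 0.6))
  loose_l <- apply_gates(res, lfc, consensus_config(alpha = 0.05, lambda = 0.3))
  for (nm in names(tight)) {
    expect_true(all(tight[[nm]] %in% loose_a[[nm]]))
    expect_true(all(tight[[nm]] %in% loose_l[[nm]]))
  }
})

test_that("consensus calls carry ordered annotation columns", {
  genes <- c("g1", "g2", "g3")
  res <- lapply(setNames(nm = c("a", "b", "c", "d")), function(nm) {
    fake_result(nm, genes, c(0.001, 0.002, 0.5))
  })
  lfc <- data.frame(gene_id = genes, lfc_3h = c(0.3, -0.9, 0.1),
                    lfc_6h = c(0.8, -1.6, 0.2), lfc_9h = c(1.2, -2.0, 0.1))
  calls <- consensus_calls(res, lfc, consensus_config(alpha = 0.05, lambda = 0.5))
  expect_identical(calls$gene_id, c("g2", "g1"))  # sorted by max |lfc| desc
  expect_identical(calls$direction_3h, c("down", "none"))
  expect_equal(calls$first_de_timepoint, c(3, 6))
  expect_equal(calls$n_tools, c(4L, 4L))
})
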