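# Fixture builders and independent brute-force oracles shared across the
# suite. Oracles deliberately use naive enumeration, never the package's
# own code paths.

# tiny deterministic experiment: two arms + optional untreated anchors
toy_sheet <- function(n_reps = 3, timepoints = c(3, 6, 9), treatment = "SB",
                      anchors = TRUE) {
  sheet <- expand.grid(replicate = seq_len(n_reps), timepoint_h = timepoints,
                       treatment = c(treatment, "DMSO"),
                       stringsAsFactors = FALSE)
  if (anchors) {
    sheet <- rbind(sheet,
                   expand.grid(replicate = seq_len(n_reps), timepoint_h = 0,
                               treatment = "untreated", stringsAsFactors = FALSE))
  }
  sheet$sample_id <- sprintf("%s_%gh_r%d", sheet$treatment, sheet$timepoint_h,
                             sheet$replicate)
  sheet[, c("sample_id", "treatment", "timepoint_h", "replicate")]
}

# counts with given per-(treatment, timepoint) mean per gene; means is a
# function(treatment, timepoint) -> vector of gene means
toy_counts <- function(sheet, n_genes, means, phi = 0.05, seed = 1) {
  set.seed(seed)
  counts <- matrix(0L, n_genes, nrow(sheet),
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   sheet$sample_id))
  for (s in seq_len(nrow(sheet))) {
    mu <- means(sheet$treatment[s], sheet$timepoint_h[s])
    counts[, s] <- if (phi == 0) rpois(n_genes, mu)
                   else rnbinom(n_genes, mu = mu, size = 1 / phi)
  }
  counts
}

random_edge_table <- function(genes, n_edges, seed = 1, score_min = 0,
                              score_max = 1000) {
  set.seed(seed)
  data.frame(node1 = sample(genes, n_edges, replace = TRUE),
             node2 = sample(genes, n_edges, replace = TRUE),
             combined_score = sample(score_min:score_max, n_edges, replace = TRUE),
             stringsAsFactors = FALSE)
}

# ---- brute-force oracles ----

brute_gates <- function(results, lfc_table, alpha, lambda, use_adjusted = TRUE) {
  lapply(results, function(r) {
    keep <- character(0)
    for (g in r$gene_id) {
      p <- if (use_adjusted) r$p_adj[r$gene_id == g] else r$p_raw[r$gene_id == g]
      row <- lfc_table[lfc_table$gene_id == g, grep("^lfc_", names(lfc_table))]
      if (p < alpha && max(abs(as.numeric(row))) >= lambda) keep <- c(keep, g)
    }
    sort(keep)
  })
}

brute_vote <- function(sets, k) {
  genes <- sort(unique(unlist(sets)))
  genes[vapply(genes, function(g) {
    sum(vapply(sets, function(s) g %in% s, TRUE)) >= k
  }, TRUE)]
}

brute_overlap <- function(sets) {
  genes <- unique(unlist(sets))
  out <- list()
  for (g in genes) {
    memb <- names(sets)[vapply(sets, function(s) g %in% s, TRUE)]
    key <- paste(memb, collapse = ";")
    out[[key]] <- (out[[key]] %||% 0L) + 1L
  }
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

brute_subnetwork_nodes <- function(candidates, edges) {
  nodes <- character(0)
  for (i in seq_len(nrow(edges))) {
    a <- edges$node1[i]; b <- edges$node2[i]
    if (a %in% candidates && b %in% candidates && a != b) nodes <- c(nodes, a, b)
  }
  sort(unique(nodes))
}

brute_crosstalk_nodes <- function(edges, shared) {
  keep <- intersect(shared, unique(c(edges$node1, edges$node2)))
  nb <- character(0)
  for (i in seq_len(nrow(edges))) {
    a <- edges$node1[i]; b <- edges$node2[i]
    if (a %in% keep) nb <- c(nb, b)
    if (b %in% keep) nb <- c(nb, a)
  }
  sort(unique(c(keep, setdiff(nb, keep))))
}

# fake detector result table with given p-values
fake_result <- function(name, gene_ids, p) {
  r <- data.frame(gene_id = gene_ids, statistic = 0, p_raw = p,
                  stringsAsFactors = FALSE)
  r$p_adj <- p.adjust(p, "BH")
  r$detector_name <- name
  r
}
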