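# Candidate interaction subnetworks over a STRING-style edge table:
# induced subgraph construction with orphan removal, temporal first-DE
# annotation, merging of two experiments' networks, crosstalk
# extraction around shared targets, and direction-concordance
# classification. Networks are kept as plain node/edge tables (class
# `annotated_network`) for deterministic merging and export; igraph
# backs the GraphML writer and any graph algorithms.

annotated_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "annotated_network")
}

empty_network <- function() {
  annotated_network(
    data.frame(gene_id = character(0), experiment = character(0),
               stringsAsFactors = FALSE),
    data.frame(node1 = character(0), node2 = character(0),
               combined_score = integer(0), stringsAsFactors = FALSE))
}

#' @export
print.annotated_network <- function(x, ...) {
  cat(sprintf("annotated_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# canonical undirected form: node1 < node2, no self loops, duplicates
# collapsed keeping the maximum score
canonicalize_edges <- function(edges) {
  a <- pmin(edges$node1, edges$node2)
  b <- pmax(edges$node1, edges$node2)
  e <- data.frame(node1 = a, node2 = b,
                  combined_score = edges$combined_score,
                  stringsAsFactors = FALSE)
  e <- e[e$node1 != e$node2, , drop = FALSE]
  if (nrow(e)) {
    key <- paste(e$node1, e$node2, sep = "\r")
    mx <- tapply(e$combined_score, key, max)
    e <- e[!duplicated(key), , drop = FALSE]
    e$combined_score <- as.integer(mx[paste(e$node1, e$node2, sep = "\r")])
    e <- e[order(e$node1, e$node2), , drop = FALSE]
  }
  rownames(e) <- NULL
  e
}

#' Load a STRING-dialect interaction edge table
#'
#' Accepts TSV with columns `node1`/`node2` or `protein1`/`protein2`
#' plus `combined_score` (STRING convention, integer 0-1000). Edges are
#' made canonical (undirected, no self-loops, duplicates collapsed to
#' the maximum score) and filtered at `min_score` (inclusive; 400 is
#' STRING's medium-confidence default).
#'
#' @param path TSV file path.
#' @param min_score minimum combined score kept (default 400).
#' @return data.frame with `node1`, `node2`, `combined_score`.
#' @export
load_edges <- function(path, min_score = 400) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  n1 <- intersect(c("node1", "protein1"), names(df))[1L]
  n2 <- intersect(c("node2", "protein2"), names(df))[1L]
  if (is.na(n1) || is.na(n2) || !"combined_score" %in% names(df)) {
    stopf("edge table needs node1/protein1, node2/protein2 and combined_score columns")
  }
  sc <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(!is.finite(sc) | sc < 0 | sc > 1000 |
                 !nzchar(df[[n1]]) | !nzchar(df[[n2]]))
  if (length(bad)) {
    stopf("malformed edge rows (data line %s)",
          paste(utils::head(bad, 10L), collapse = ", "))
  }
  e <- data.frame(node1 = as.character(df[[n1]]),
                  node2 = as.character(df[[n2]]),
                  combined_score = as.integer(round(sc)),
                  stringsAsFactors = FALSE)
  e <- canonicalize_edges(e)
  e <- e[e$combined_score >= min_score, , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Build the induced candidate subnetwork
#'
#' Induces the subgraph of the edge table on the candidate genes and
#' removes degree-0 (orphan) nodes. The fraction of candidates retained
#' is attached as attribute `coverage`.
#'
#' @param candidates character vector of consensus candidate gene ids.
#' @param edges canonical edge table (see [load_edges()]).
#' @param experiment experiment label stored on every node (e.g. "SB").
#' @return an `annotated_network`.
#' @export
build_subnetwork <- function(candidates, edges, experiment = NA_character_) {
  if (!length(candidates)) stopf("candidate set is empty")
  candidates <- unique(candidates)
  e <- edges[edges$node1 %in% candidates & edges$node2 %in% candidates, ,
             drop = FALSE]
  rownames(e) <- NULL
  connected <- sort(unique(c(e$node1, e$node2)))
  if (!length(connected)) warnf("no candidate pair is connected: empty network")
  nodes <- data.frame(gene_id = connected,
                      experiment = rep(experiment, length(connected)),
                      stringsAsFactors = FALSE)
  net <- annotated_network(nodes, e)
  attr(net, "coverage") <- length(connected) / length(candidates)
  net
}

#' Annotate nodes with temporal expression dynamics
#'
#' Each node gets `first_de_timepoint` (earliest t with |LFC| >= lambda,
#' `NA` if never), per-timepoint direction segments (`up`/`down` where
#' |LFC| >= lambda, else `none`) and `max_abs_lfc`.
#'
#' @param net an `annotated_network`.
#' @param lfc_table [lfc_vs_control()] table covering every node.
#' @param lambda the experiment's |LFC| threshold.
#' @return the annotated network.
#' @export
annotate_first_de <- function(net, lfc_table, lambda) {
  idx <- match(net$nodes$gene_id, lfc_table$gene_id)
  if (anyNA(idx)) {
    stopf("nodes missing from LFC table: %s",
          paste(net$nodes$gene_id[is.na(idx)], collapse = ", "))
  }
  m <- lfc_matrix(lfc_table)[idx, , drop = FALSE]
  tps <- lfc_timepoints(lfc_table)
  net$nodes$first_de_timepoint <- apply(m, 1L, function(v) {
    hit <- which(abs(v) >= lambda)
    if (length(hit)) tps[hit[1L]] else NA_real_
  })
  for (j in seq_along(tps)) {
    v <- m[, j]
    net$nodes[[sprintf("dir_%gh", tps[j])]] <-
      ifelse(abs(v) >= lambda, ifelse(v > 0, "up", "down"), "none")
  }
  net$nodes$max_abs_lfc <- apply(abs(m), 1L, max)
  net
}

#' Merge two experiments' annotated networks
#'
#' Node union and edge union; nodes present in both networks are tagged
#' `experiment = "both"` and carry both experiments' temporal
#' annotations via suffixed columns. Conflicting edge scores resolve to
#' the maximum.
#'
#' @param net_a,net_b `annotated_network` objects (e.g. SB and SU).
#' @return merged `annotated_network`.
#' @export
merge_networks <- function(net_a, net_b) {
  na <- net_a$nodes; nb <- net_b$nodes
  suff_a <- if (nrow(na) && !is.na(na$experiment[1L])) paste0(".", na$experiment[1L]) else ".a"
  suff_b <- if (nrow(nb) && !is.na(nb$experiment[1L])) paste0(".", nb$experiment[1L]) else ".b"
  if (identical(suff_a, suff_b)) suff_b <- paste0(suff_b, "2")
  merged <- merge(na, nb, by = "gene_id", all = TRUE,
                  suffixes = c(suff_a, suff_b), sort = TRUE)
  in_a <- merged$gene_id %in% na$gene_id
  in_b <- merged$gene_id %in% nb$gene_id
  exp_a <- merged[[paste0("experiment", suff_a)]]
  exp_b <- merged[[paste0("experiment", suff_b)]]
  merged$experiment <- ifelse(in_a & in_b, "both",
                              ifelse(in_a, as.character(exp_a),
                                     as.character(exp_b)))
  merged[[paste0("experiment", suff_a)]] <- NULL
  merged[[paste0("experiment", suff_b)]] <- NULL
  edges <- canonicalize_edges(rbind(net_a$edges, net_b$edges))
  annotated_network(merged, edges)
}

#' Extract the crosstalk subnetwork around shared targets
#'
#' Induces the merged network on the shared targets plus their direct
#' neighbors (depth 1, "adjacent nodes"). Every retained non-shared
#' node is adjacent to at least one shared target; shared targets
#' missing from the network are skipped with a message.
#'
#' @param merged merged `annotated_network`.
#' @param shared_targets gene ids called in both experiments.
#' @return crosstalk `annotated_network`; shared targets are flagged in
#'   a logical node column `shared_target`.
#' @export
extract_crosstalk <- function(merged, shared_targets) {
  shared <- intersect(unique(shared_targets), merged$nodes$gene_id)
  skipped <- setdiff(unique(shared_targets), shared)
  if (length(skipped)) {
    message("shared targets absent from merged network, skipped: ",
            paste(skipped, collapse = ", "))
  }
  if (!length(shared)) {
    warnf("no shared targets present: empty crosstalk network")
    return(empty_network())
  }
  e <- merged$edges
  touch <- e$node1 %in% shared | e$node2 %in% shared
  neighbors <- setdiff(unique(c(e$node1[touch], e$node2[touch])), shared)
  keep <- c(shared, neighbors)
  sub_e <- e[e$node1 %in% keep & e$node2 %in% keep, , drop = FALSE]
  rownames(sub_e) <- NULL
  nodes <- merged$nodes[merged$nodes$gene_id %in% keep, , drop = FALSE]
  nodes <- nodes[order(nodes$gene_id), , drop = FALSE]
  nodes$shared_target <- nodes$gene_id %in% shared
  rownames(nodes) <- NULL
  annotated_network(nodes, sub_e)
}

#' Classify direction concordance of a common target
#'
#' Compares the sign of the log2 fold change at the timepoint of maximum
#' |LFC| in each experiment: equal signs are `synergistic`, opposite
#' `antagonistic`; if either experiment's maximum |LFC| stays below its
#' threshold the call is `indeterminate`.
#'
#' @param lfc_a,lfc_b the gene's LFC profile in each experiment (numeric
#'   vectors over timepoints).
#' @param lambda_a,lambda_b the experiments' |LFC| thresholds.
#' @return one of `"synergistic"`, `"antagonistic"`, `"indeterminate"`.
#' @export
classify_direction <- function(lfc_a, lfc_b, lambda_a = 0.5, lambda_b = 0.7) {
  sa <- lfc_a[which.max(abs(lfc_a))]
  sb <- lfc_b[which.max(abs(lfc_b))]
  if (abs(sa) < lambda_a || abs(sb) < lambda_b) return("indeterminate")
  if (sign(sa) == sign(sb)) "synergistic" else "antagonistic"
}

#' Convert an annotated network to igraph
#' @param net an `annotated_network`.
#' @return an undirected [igraph::graph] with all node/edge attributes.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = net$nodes[order(net$nodes$gene_id), , drop = FALSE])
}

#' Write an annotated network as GraphML (plus node/edge TSVs)
#'
#' Node and edge ordering is made canonical first, so identical inputs
#' produce byte-identical GraphML.
#'
#' @param net an `annotated_network`.
#' @param path output GraphML path; sibling `<path>.nodes.tsv` and
#'   `<path>.edges.tsv` are written alongside.
#' @export
write_graphml <- function(net, path) {
  net$edges <- canonicalize_edges(net$edges)
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  utils::write.table(net$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(net$edges, paste0(path, ".edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
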