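# Consensus calling: per-tool significance + fold-change gates with a
# positive-control-anchored threshold, an at-least-k-tools vote, and
# overlap bookkeeping between the per-tool candidate sets.

#' Consensus configuration
#'
#' @param alpha per-tool p-value gate (the emulated study used 0.05 for
#'   the TGF-beta/SB arm and 0.01 for the FGF/SU arm).
#' @param lambda absolute log2 fold-change gate (0.5 for SB, 0.7 for SU
#'   in the emulated study).
#' @param k_min_tools minimum number of supporting detectors (default 3
#'   of 4).
#' @param use_adjusted gate on BH-adjusted p-values (default) or raw.
#' @param control_gene optional positive-control gene id used by
#'   [calibrate_lfc_threshold()].
#' @return a `consensus_config` list.
#' @export
consensus_config <- function(alpha = 0.05, lambda = 0.5, k_min_tools = 3L,
                             use_adjusted = TRUE, control_gene = NULL) {
  if (!is_number(alpha) || alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  if (!is_number(lambda) || lambda < 0) stopf("lambda must be >= 0")
  if (!is_count(k_min_tools) || k_min_tools > 4L) stopf("k_min_tools must be an integer in 1..4")
  structure(list(alpha = alpha, lambda = lambda,
                 k_min_tools = as.integer(k_min_tools),
                 use_adjusted = isTRUE(use_adjusted),
                 control_gene = control_gene),
            class = "consensus_config")
}

#' Anchor the fold-change threshold on a positive-control gene
#'
#' Rule: take the control gene's |LFC| at its earliest supra-noise
#' timepoint (first t with |LFC| > 0.1) and round it down to one
#' decimal. Applied to a well-behaved known target this yields a
#' threshold that the control itself clears at every responsive
#' timepoint. The rule is an explicit, auditable interpretation of
#' "threshold chosen based on a positive control"; `rule =
#' "min_significant"` instead floors the minimum |LFC| over all
#' supra-noise timepoints (identical for monotone profiles).
#'
#' @param lfc_table an [lfc_vs_control()] table (or any data.frame with
#'   `gene_id` and `lfc_*` columns).
#' @param control_gene positive-control gene id.
#' @param noise_floor |LFC| below this is treated as noise (default 0.1).
#' @param rule `"earliest"` (default) or `"min_significant"`.
#' @return the threshold `lambda`, with attributes `control_gene`,
#'   `timepoint` and `rule` recording provenance.
#' @examples
#' tab <- data.frame(gene_id = "NANOG", lfc_3h = -0.58, lfc_6h = -1.24,
#'                   lfc_9h = -1.54)
#' calibrate_lfc_threshold(tab, "NANOG")  # 0.5
#' @export
calibrate_lfc_threshold <- function(lfc_table, control_gene,
                                    noise_floor = 0.1,
                                    rule = c("earliest", "min_significant")) {
  rule <- match.arg(rule)
  i <- match(control_gene, lfc_table$gene_id)
  if (is.na(i)) stopf("control gene %s absent from the LFC table; supply lambda manually", control_gene)
  prof <- abs(lfc_matrix(lfc_table)[i, ])
  if (max(prof) < noise_floor) {
    stopf("control gene %s is flat (max |LFC| %.3g < %.3g); supply lambda manually",
          control_gene, max(prof), noise_floor)
  }
  supra <- which(prof > noise_floor)
  tp <- lfc_timepoints(lfc_table)
  val <- switch(rule,
                earliest = prof[supra[1L]],
                min_significant = min(prof[supra]))
  lambda <- floor(val * 10) / 10
  structure(lambda, control_gene = control_gene,
            timepoint = tp[supra[1L]], rule = rule)
}

#' Apply the per-tool significance and fold-change gates
#'
#' A gene enters a tool's candidate set iff its gate p-value (adjusted
#' or raw, per config) is below `alpha` AND its maximum |LFC| over
#' timepoints is at least `lambda` (inclusive).
#'
#' @param results named list of detector result data.frames covering the
#'   same gene universe.
#' @param lfc_table [lfc_vs_control()] table over that universe.
#' @param config a [consensus_config()].
#' @return named list of character vectors (candidate gene ids per tool).
#' @export
apply_gates <- function(results, lfc_table, config) {
  genes <- sort(results[[1L]]$gene_id)
  for (r in results) {
    if (!setequal(r$gene_id, genes)) {
      d <- union(setdiff(r$gene_id, genes), setdiff(genes, r$gene_id))
      stopf("detector gene universes differ; symmetric difference: %s",
            paste(utils::head(d, 20L), collapse = ", "))
    }
  }
  if (!setequal(lfc_table$gene_id, genes)) {
    d <- union(setdiff(lfc_table$gene_id, genes), setdiff(genes, lfc_table$gene_id))
    stopf("LFC table gene universe differs; symmetric difference: %s",
          paste(utils::head(d, 20L), collapse = ", "))
  }
  max_abs <- apply(abs(lfc_matrix(lfc_table)), 1L, max)
  pass_lfc <- lfc_table$gene_id[max_abs >= config$lambda]
  lapply(results, function(r) {
    p <- if (config$use_adjusted) r$p_adj else r$p_raw
    sort(intersect(r$gene_id[p < config$alpha], pass_lfc))
  })
}

#' Consensus vote over per-tool candidate sets
#'
#' @param sets named list of candidate gene-id vectors (1-4 tools).
#' @param k_min_tools keep genes present in at least this many sets.
#' @return data.frame with `gene_id`, `n_tools` and `supporting_tools`
#'   (semicolon-joined), one row per consensus gene.
#' @export
consensus_vote <- function(sets, k_min_tools = 3L) {
  if (!length(sets)) stopf("no candidate sets given")
  if (k_min_tools > length(sets)) {
    stopf("k_min_tools (%d) exceeds the number of sets (%d)", k_min_tools, length(sets))
  }
  if (is.null(names(sets))) names(sets) <- paste0("tool", seq_along(sets))
  genes <- sort(unique(unlist(sets)))
  if (!length(genes)) {
    return(data.frame(gene_id = character(0), n_tools = integer(0),
                      supporting_tools = character(0), stringsAsFactors = FALSE))
  }
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  member <- matrix(member, nrow = length(genes),
                   dimnames = list(genes, names(sets)))
  n_tools <- rowSums(member)
  keep <- n_tools >= k_min_tools
  data.frame(
    gene_id = genes[keep],
    n_tools = as.integer(n_tools[keep]),
    supporting_tools = apply(member[keep, , drop = FALSE], 1L,
                             function(m) paste(names(sets)[m], collapse = ";")),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Exclusive overlap regions of up to four candidate sets
#'
#' @param sets named list of candidate gene-id vectors.
#' @return data.frame with one row per non-empty tool combination
#'   (`region`, semicolon-joined tool names) and the count of genes
#'   falling exactly in that region; counts sum to the union size.
#' @export
overlap_summary <- function(sets) {
  if (length(sets) > 4L) stopf("at most four sets supported")
  if (is.null(names(sets))) names(sets) <- paste0("tool", seq_along(sets))
  genes <- sort(unique(unlist(sets)))
  key <- vapply(genes, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, TRUE)], collapse = ";")
  }, "")
  combos <- unlist(lapply(seq_along(sets), function(k) {
    utils::combn(names(sets), k, paste, collapse = ";")
  }))
  counts <- vapply(combos, function(cb) sum(key == cb), 0L)
  data.frame(region = combos, count = as.integer(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full consensus call table
#'
#' Combines [apply_gates()] and [consensus_vote()] and annotates each
#' consensus gene with its maximum |LFC|, per-timepoint direction
#' (up/down/none at |LFC| >= lambda) and first-DE timepoint (earliest t
#' with |LFC| >= lambda). Rows are ordered by descending support, then
#' descending max |LFC|, then gene id.
#'
#' @inheritParams apply_gates
#' @return data.frame of consensus calls.
#' @export
consensus_calls <- function(results, lfc_table, config) {
  sets <- apply_gates(results, lfc_table, config)
  votes <- consensus_vote(sets, config$k_min_tools)
  m <- lfc_matrix(lfc_table)
  tps <- lfc_timepoints(lfc_table)
  idx <- match(votes$gene_id, lfc_table$gene_id)
  votes$max_abs_lfc <- if (nrow(votes)) apply(abs(m[idx, , drop = FALSE]), 1L, max) else numeric(0)
  for (j in seq_along(tps)) {
    v <- m[idx, j]
    votes[[sprintf("direction_%gh", tps[j])]] <-
      ifelse(abs(v) >= config$lambda, ifelse(v > 0, "up", "down"), "none")
  }
  votes$first_de_timepoint <- vapply(seq_len(nrow(votes)), function(i) {
    hit <- which(abs(m[idx[i], ]) >= config$lambda)
    if (length(hit)) tps[hit[1L]] else NA_real_
  }, 0)
  ord <- order(-votes$n_tools, -votes$max_abs_lfc, votes$gene_id)
  votes <- votes[ord, , drop = FALSE]
  rownames(votes) <- NULL
  attr(votes, "tool_sets") <- sets
  votes
}
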