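# Count-matrix ingestion and the expression-level preprocessing used by
# every detector: CPM normalization, the >= 1 CPM expression pre-filter,
# and per-timepoint log2 fold changes against the time-matched solvent
# control.

VALID_TREATMENTS <- c("SB", "SU", "DMSO", "untreated")

#' Validate a count matrix
#'
#' @param counts numeric matrix, genes x samples, with unique rownames
#'   (gene ids) and colnames (sample ids); entries must be non-negative
#'   integers.
#' @return the matrix, invisibly, in integer storage.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) stopf("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("counts must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stopf("duplicate gene ids: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) stopf("duplicate sample ids")
  if (anyNA(counts)) stopf("counts contain missing values")
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (any(counts != floor(counts))) stopf("counts must be integers")
  storage.mode(counts) <- "integer"
  invisible(counts)
}

#' Read a gene x sample count matrix from TSV
#'
#' Expects a header line; the first column holds gene ids, remaining
#' columns integer counts per sample.
#'
#' @param path TSV file path.
#' @return validated integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("count file needs a gene id column plus samples")
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stopf("count columns must be numeric")
  rownames(m) <- genes
  validate_counts(m)
  m
}

#' Write a count matrix to TSV (first column `gene_id`)
#' @param counts gene x sample matrix.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' Required columns: `sample_id`, `treatment` (one of SB, SU, DMSO,
#' untreated), `timepoint_h`, `replicate`.
#'
#' @param path TSV file path.
#' @param counts optional count matrix; if given, the sample sets must
#'   match exactly.
#' @return data.frame sample sheet.
#' @export
read_sample_sheet <- function(path, counts = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df, counts)
  df
}

#' Validate a sample sheet (optionally against a count matrix)
#' @param sheet data.frame with sample_id, treatment, timepoint_h, replicate.
#' @param counts optional count matrix whose colnames must equal the
#'   sheet's sample set.
#' @return the sheet, invisibly.
#' @export
validate_sample_sheet <- function(sheet, counts = NULL) {
  need <- c("sample_id", "treatment", "timepoint_h", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stopf("sample sheet lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stopf("duplicate sample ids in sheet")
  bad <- setdiff(unique(sheet$treatment), VALID_TREATMENTS)
  if (length(bad)) {
    stopf("unknown treatment labels: %s (expected %s)",
          paste(bad, collapse = ", "), paste(VALID_TREATMENTS, collapse = ", "))
  }
  if (!is.numeric(sheet$timepoint_h)) stopf("timepoint_h must be numeric")
  if (!is.null(counts)) {
    only_counts <- setdiff(colnames(counts), sheet$sample_id)
    only_sheet <- setdiff(sheet$sample_id, colnames(counts))
    if (length(only_counts) || length(only_sheet)) {
      stopf("sample sets differ: in counts only [%s]; in sheet only [%s]",
            paste(only_counts, collapse = ", "),
            paste(only_sheet, collapse = ", "))
    }
  }
  invisible(sheet)
}

#' Write a sample sheet to TSV
#' @param sheet data.frame sample sheet.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Counts per million
#'
#' `cpm[g, s] = counts[g, s] / lib_size[s] * 1e6`, with library sizes
#' taken as column sums unless supplied; every column of the result sums
#' to exactly 1e6.
#'
#' @param counts gene x sample count matrix.
#' @param lib_sizes optional per-sample library sizes (default column sums).
#' @return numeric matrix of CPM values.
#' @export
cpm <- function(counts, lib_sizes = NULL) {
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) {
    stopf("zero/negative library size for sample(s): %s",
          paste(colnames(counts)[lib_sizes <= 0], collapse = ", "))
  }
  sweep(counts, 2L, lib_sizes, "/") * 1e6
}

#' Expression pre-filter: keep genes at or above a CPM floor
#'
#' Retains genes whose mean CPM across the selected samples is at least
#' `min_cpm` (inclusive); `scope = "any"` / `"all"` instead require at
#' least one / every sample to reach the floor. Gene order is preserved.
#'
#' @param counts gene x sample count matrix.
#' @param samples sample ids defining the experiment over which the
#'   filter is computed (default: all columns).
#' @param min_cpm CPM floor (default 1).
#' @param scope `"mean"` (default), `"any"` or `"all"`.
#' @return the filtered count matrix (all samples, filtered genes).
#' @export
filter_low_expression <- function(counts, samples = colnames(counts),
                                  min_cpm = 1, scope = c("mean", "any", "all")) {
  scope <- match.arg(scope)
  if (!is_number(min_cpm) || min_cpm < 0) stopf("min_cpm must be >= 0")
  missing_s <- setdiff(samples, colnames(counts))
  if (length(missing_s)) stopf("samples not in counts: %s", paste(missing_s, collapse = ", "))
  x <- cpm(counts[, samples, drop = FALSE], lib_sizes = colSums(counts)[samples])
  keep <- switch(scope,
                 mean = rowMeans(x) >= min_cpm,
                 any = apply(x, 1L, max) >= min_cpm,
                 all = apply(x, 1L, min) >= min_cpm)
  if (!any(keep)) warnf("expression filter removed every gene")
  counts[keep, , drop = FALSE]
}

#' Per-timepoint log2 fold change against the time-matched solvent control
#'
#' For each nonzero timepoint `t`,
#' `lfc[g, t] = log2((mean CPM treated at t + pc) / (mean CPM DMSO at t + pc))`
#' with means over replicates and a pseudocount `pc` keeping ratios
#' finite for silent genes.
#'
#' @param counts gene x sample count matrix.
#' @param sheet sample sheet covering the counts' samples.
#' @param treatment treated arm label (`"SB"` or `"SU"`).
#' @param pseudocount CPM pseudocount added to both means (default 0.5).
#' @param control control arm label (default `"DMSO"`).
#' @return data.frame with `gene_id` and one `lfc_<t>h` column per
#'   treated timepoint; attribute `timepoints` lists them.
#' @export
lfc_vs_control <- function(counts, sheet, treatment, pseudocount = 0.5,
                           control = "DMSO") {
  validate_sample_sheet(sheet)
  if (!treatment %in% sheet$treatment) stopf("no samples with treatment %s", treatment)
  x <- cpm(counts)
  tps <- sort(unique(sheet$timepoint_h[sheet$treatment == treatment]))
  out <- data.frame(gene_id = rownames(counts), stringsAsFactors = FALSE)
  for (t in tps) {
    trt <- sheet$sample_id[sheet$treatment == treatment & sheet$timepoint_h == t]
    ctl <- sheet$sample_id[sheet$treatment == control & sheet$timepoint_h == t]
    if (!length(ctl)) stopf("no time-matched %s control at %g h", control, t)
    m_trt <- rowMeans(x[, trt, drop = FALSE])
    m_ctl <- rowMeans(x[, ctl, drop = FALSE])
    out[[sprintf("lfc_%gh", t)]] <- log2((m_trt + pseudocount) / (m_ctl + pseudocount))
  }
  attr(out, "timepoints") <- tps
  out
}

# internal: lfc matrix (genes x timepoints) from an lfc table
lfc_matrix <- function(lfc_table) {
  cols <- grep("^lfc_", names(lfc_table), value = TRUE)
  m <- as.matrix(lfc_table[, cols, drop = FALSE])
  rownames(m) <- lfc_table$gene_id
  m
}

lfc_timepoints <- function(lfc_table) {
  cols <- grep("^lfc_", names(lfc_table), value = TRUE)
  as.numeric(sub("^lfc_", "", sub("h$", "", cols)))
}

#' Write an LFC table with signed values plus magnitude/direction columns
#'
#' @param lfc_table result of [lfc_vs_control()].
#' @param path output TSV path.
#' @export
write_lfc_table <- function(lfc_table, path) {
  m <- lfc_matrix(lfc_table)
  out <- lfc_table
  for (j in colnames(m)) {
    t <- sub("^lfc_", "", j)
    out[[paste0("abs_", t)]] <- abs(m[, j])
    out[[paste0("direction_", t)]] <- ifelse(m[, j] > 0, "up",
                                             ifelse(m[, j] < 0, "down", "none"))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
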