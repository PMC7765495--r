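# Gene-wise NB dispersion by pooled method of moments on common-scale
# counts, shrunk toward the experiment-wide common value. Every
# count-based test in the package plugs these in.

# counts rescaled so every sample has the mean library size; on this
# scale Var(y) ~ a * mu + phi * mu^2 with a = mean(libbar / lib).
common_scale <- function(counts, lib_sizes = colSums(counts)) {
  f <- mean(lib_sizes) / lib_sizes
  list(y = sweep(counts, 2L, f, "*"), a = f)
}

#' Estimate gene-wise NB dispersions with shrinkage
#'
#' Raw dispersions come from a pooled method of moments across all
#' replicate groups (same treatment and timepoint): per group the excess
#' of the sample variance over the Poisson expectation is attributed to
#' `phi * mean^2`, residual degrees of freedom are pooled, and negative
#' estimates are clamped at zero. Each gene's estimate is then shrunk
#' toward the common dispersion (the same moment ratio pooled over all
#' genes) with weight `df / (df + prior_df)`.
#'
#' @param counts gene x sample count matrix.
#' @param sheet sample sheet; groups are `(treatment, timepoint_h)`
#'   combinations with at least two replicates.
#' @param prior_df prior degrees of freedom of the common-dispersion
#'   shrinkage target (default 30).
#' @return data.frame with `gene_id`, `phi_raw`, `phi_shrunk` and the
#'   scalar `common_phi` (attribute and column).
#' @export
estimate_dispersions <- function(counts, sheet, prior_df = 30) {
  validate_sample_sheet(sheet, counts)
  sheet <- sheet[match(colnames(counts), sheet$sample_id), ]
  grp <- interaction(sheet$treatment, sheet$timepoint_h, drop = TRUE)
  sizes <- table(grp)
  if (all(sizes < 2L)) stopf("no replicate group has >= 2 samples")
  cs <- common_scale(counts)
  num <- den <- rep(0, nrow(counts))
  df_tot <- 0
  for (g in names(sizes)[sizes >= 2L]) {
    i <- which(grp == g)
    yg <- cs$y[, i, drop = FALSE]
    n_g <- length(i)
    m <- rowMeans(yg)
    v <- rowSums((yg - m)^2) / (n_g - 1L)
    a <- mean(cs$a[i])
    dfg <- n_g - 1L
    # E[v] = a mu + phi mu^2 and E[m^2 - v/n] = mu^2, so this ratio is a
    # first-order unbiased method-of-moments estimate of phi
    num <- num + dfg * (v - a * m)
    den <- den + dfg * pmax(m^2 - v / n_g, 0)
    df_tot <- df_tot + dfg
  }
  phi_raw <- pmax(0, ifelse(den > 0, num / den, 0))
  # common dispersion: the same moment ratio pooled over all genes, far
  # more stable than a location summary of the noisy per-gene values
  common_phi <- max(0, sum(num) / sum(den))
  w <- df_tot / (df_tot + prior_df)
  phi_shrunk <- w * phi_raw + (1 - w) * common_phi
  out <- data.frame(gene_id = rownames(counts), phi_raw = phi_raw,
                    phi_shrunk = phi_shrunk, common_phi = common_phi,
                    stringsAsFactors = FALSE)
  attr(out, "common_phi") <- common_phi
  out
}
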