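# Four independent per-gene time-course DE detectors sharing one output
# contract: a data.frame with gene_id, statistic, p_raw, p_adj and
# detector_name. They emulate the statistical idioms of the classic
# time-course tool ensemble (per-timepoint NB tests, impulse-model NB
# LRT, spline moderated F, two-stage polynomial screen) and are
# implemented from first principles on top of shared dispersion
# estimates.

DETECTOR_NAMES <- c("pairwise_nb", "impulse_lrt", "spline_f", "poly_twostage")

detector_result <- function(name, gene_ids, statistic, p_raw, extra = NULL) {
  out <- data.frame(gene_id = gene_ids, statistic = statistic,
                    p_raw = pmin(1, pmax(0, p_raw)),
                    stringsAsFactors = FALSE)
  out$p_adj <- adjust_pvalues(out$p_raw)
  out$detector_name <- name
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

# Samples entering the time-course models: the treated arm at its
# timepoints plus a control condition made of time-matched DMSO samples
# and (if present) the untreated anchors at the earliest timepoint,
# which provide the shared t = 0 baseline. Late untreated anchors are
# solvent-effect QC samples and stay out of the contrasts.
tc_design <- function(sheet, treatment, control = "DMSO",
                      include_anchors = TRUE) {
  validate_sample_sheet(sheet)
  if (!treatment %in% sheet$treatment) stopf("no samples with treatment %s", treatment)
  trt <- sheet[sheet$treatment == treatment, ]
  ctl <- sheet[sheet$treatment == control & sheet$timepoint_h %in% trt$timepoint_h, ]
  if (!nrow(ctl)) stopf("no %s control samples matching the treated timepoints", control)
  des <- rbind(
    data.frame(sample_id = ctl$sample_id, time = ctl$timepoint_h,
               condition = "control", stringsAsFactors = FALSE),
    data.frame(sample_id = trt$sample_id, time = trt$timepoint_h,
               condition = "treated", stringsAsFactors = FALSE))
  if (include_anchors && "untreated" %in% sheet$treatment) {
    anc <- sheet[sheet$treatment == "untreated", ]
    t0 <- min(sheet$timepoint_h)
    anc <- anc[anc$timepoint_h == t0 & t0 < min(trt$timepoint_h), ]
    if (nrow(anc)) {
      des <- rbind(data.frame(sample_id = anc$sample_id, time = anc$timepoint_h,
                              condition = "control", stringsAsFactors = FALSE), des)
    }
  }
  des
}

#' Per-timepoint negative-binomial Wald tests
#'
#' At each treated timepoint the treated and time-matched control group
#' means (on common-scale counts) are compared by a Wald z statistic for
#' the log-mean difference, with the variance evaluated at the pooled
#' mean (score-type, better calibrated near the null) using the shrunk
#' gene-wise dispersion. The per-timepoint p-values come from disjoint
#' sample sets and are therefore independent; the gene-level p is the
#' exact distribution of their minimum, `1 - (1 - min p)^T`
#' (`combine = "min_exact"`, uniform under the null), or the
#' conservative Bonferroni `min(1, T * min p)`.
#'
#' @param counts gene x sample count matrix.
#' @param sheet sample sheet.
#' @param treatment treated arm label.
#' @param dispersions result of [estimate_dispersions()] on (a superset
#'   of) these genes.
#' @param combine how per-timepoint p-values are combined.
#' @param pseudocount count-scale pseudocount stabilizing log ratios.
#' @param control control arm label.
#' @return detector result data.frame; `statistic` is the largest
#'   absolute z across timepoints.
#' @export
detect_pairwise_nb <- function(counts, sheet, treatment, dispersions,
                               combine = c("min_exact", "bonferroni"),
                               pseudocount = 0.5, control = "DMSO") {
  combine <- match.arg(combine)
  validate_sample_sheet(sheet)
  phi <- dispersions$phi_shrunk[match(rownames(counts), dispersions$gene_id)]
  if (anyNA(phi)) stopf("dispersions missing for some genes")
  tps <- sort(unique(sheet$timepoint_h[sheet$treatment == treatment]))
  if (!length(tps)) stopf("no samples with treatment %s", treatment)
  cs <- common_scale(counts)
  pmat <- zmat <- matrix(NA_real_, nrow(counts), length(tps))
  for (j in seq_along(tps)) {
    t <- tps[j]
    i1 <- which(colnames(counts) %in%
                  sheet$sample_id[sheet$treatment == treatment & sheet$timepoint_h == t])
    i2 <- which(colnames(counts) %in%
                  sheet$sample_id[sheet$treatment == control & sheet$timepoint_h == t])
    if (!length(i1) || !length(i2)) stopf("missing group at %g h", t)
    n1 <- length(i1); n2 <- length(i2)
    m1 <- rowMeans(cs$y[, i1, drop = FALSE])
    m2 <- rowMeans(cs$y[, i2, drop = FALSE])
    a1 <- mean(cs$a[i1]); a2 <- mean(cs$a[i2])
    m0 <- (n1 * m1 + n2 * m2) / (n1 + n2) + pseudocount
    lr <- log((m1 + pseudocount) / (m2 + pseudocount))
    se2 <- a1 / (n1 * m0) + phi / n1 + a2 / (n2 * m0) + phi / n2
    z <- lr / sqrt(se2)
    zmat[, j] <- z
    pmat[, j] <- 2 * stats::pnorm(-abs(z))
  }
  pmin_t <- apply(pmat, 1L, min)
  p_raw <- switch(combine,
                  min_exact = 1 - (1 - pmin_t)^length(tps),
                  bonferroni = pmin(1, pmin_t * length(tps)))
  detector_result("pairwise_nb", rownames(counts),
                  apply(abs(zmat), 1L, max), p_raw)
}

#' Impulse-model negative-binomial likelihood-ratio detector
#'
#' Fits, per gene, a shared impulse mean curve (null) against separate
#' treated/control curves (alternative) by NB maximum likelihood with
#' plug-in shrunk dispersions; see [fit_impulse_nb()] for the test.
#' Genes whose optimization fails outright are reported with p = 1.
#'
#' @inheritParams detect_pairwise_nb
#' @param include_anchors use untreated baseline anchors as control
#'   t = 0 samples (default TRUE).
#' @return detector result data.frame; `statistic` is the LRT statistic.
#' @export
detect_impulse <- function(counts, sheet, treatment, dispersions,
                           control = "DMSO", include_anchors = TRUE) {
  des <- tc_design(sheet, treatment, control, include_anchors)
  y <- counts[, des$sample_id, drop = FALSE]
  sf <- colSums(counts)[des$sample_id] / 1e6
  phi <- dispersions$phi_shrunk[match(rownames(counts), dispersions$gene_id)]
  if (anyNA(phi)) stopf("dispersions missing for some genes")
  stat <- p <- numeric(nrow(y))
  for (g in seq_len(nrow(y))) {
    fit <- tryCatch(
      fit_impulse_nb(y[g, ], des$time, des$condition, sf, phi[g]),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$stat)) {
      stat[g] <- NA_real_; p[g] <- 1
    } else {
      stat[g] <- fit$stat; p[g] <- fit$p_value
    }
  }
  detector_result("impulse_lrt", rownames(counts), stat, p)
}

# RSS of every response column for one design matrix, via the QR
# projection; returns rank as attribute.
design_rss <- function(X, Y) {
  qrX <- qr(X)
  r <- qrX$rank
  Q <- qr.Q(qrX)[, seq_len(r), drop = FALSE]
  rss <- colSums((Y - Q %*% crossprod(Q, Y))^2)
  attr(rss, "rank") <- r
  rss
}

# Invert the trigamma function by Newton iteration (monotone decreasing
# on (0, Inf)); used to moment-match the prior df of the variance prior.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

#' Empirical-Bayes shrinkage of residual variances
#'
#' Moment-matches a scaled inverse chi-square prior to the observed
#' log-variances (the classic moderated-statistics recipe) and returns
#' posterior variances `(df0 * s0^2 + df * s2) / (df0 + df)`.
#'
#' @param s2 per-gene residual variances.
#' @param df residual degrees of freedom (scalar).
#' @return list with `var_post`, `var_prior` (`s0^2`) and `df_prior`.
#' @export
squeeze_var <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) return(list(var_post = s2, var_prior = 0, df_prior = Inf))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  if (sum(ok) < 2L) {
    df0 <- Inf
    s20 <- exp(mean(e))
  } else {
    evar <- stats::var(e) - trigamma(df / 2)
    if (evar > 0) {
      df0 <- 2 * trigamma_inverse(evar)
      s20 <- exp(mean(e) + digamma(df0 / 2) - log(df0 / 2))
    } else {
      df0 <- Inf
      s20 <- exp(mean(e))
    }
  }
  var_post <- if (is.infinite(df0)) rep(s20, length(s2))
              else (df0 * s20 + df * s2) / (df0 + df)
  list(var_post = var_post, var_prior = s20, df_prior = df0)
}

#' Natural-cubic-spline moderated F detector
#'
#' Models `log2(CPM + pc)` by a natural cubic spline basis in time with
#' condition main effect and condition-by-basis interactions, and tests
#' all condition-dependent coefficients jointly with an F statistic
#' whose denominator variance is shrunk across genes by [squeeze_var()]
#' (limma-style variance moderation).
#'
#' @inheritParams detect_impulse
#' @param df spline degrees of freedom; must be below the number of
#'   distinct timepoints.
#' @param pseudocount CPM pseudocount before the log transform.
#' @return detector result data.frame; `statistic` is the moderated F.
#' @export
detect_spline <- function(counts, sheet, treatment, df = 3,
                          pseudocount = 0.5, control = "DMSO",
                          include_anchors = TRUE) {
  des <- tc_design(sheet, treatment, control, include_anchors)
  n_tp <- length(unique(des$time))
  if (df >= n_tp) stopf("spline df (%d) must be below the number of distinct timepoints (%d)", df, n_tp)
  Y <- t(log2(cpm(counts)[, des$sample_id, drop = FALSE] + pseudocount))
  B <- splines::ns(des$time, df = df)
  cond <- factor(des$condition, levels = c("control", "treated"))
  X_full <- stats::model.matrix(~ cond * B)
  X_red <- stats::model.matrix(~ B)
  rss1 <- design_rss(X_full, Y)
  rss0 <- design_rss(X_red, Y)
  df1 <- attr(rss1, "rank") - attr(rss0, "rank")
  df2 <- nrow(Y) - attr(rss1, "rank")
  if (df1 < 1L || df2 < 1L) stopf("design leaves no degrees of freedom")
  s2 <- rss1 / df2
  sq <- squeeze_var(s2, df2)
  num <- pmax(0, rss0 - rss1) / df1
  fstat <- ifelse(num == 0, 0,
                  ifelse(sq$var_post > 0, num / sq$var_post, Inf))
  df_total <- df2 + ifelse(is.infinite(sq$df_prior), 1e6, sq$df_prior)
  p <- stats::pf(fstat, df1, df_total, lower.tail = FALSE)
  detector_result("spline_f", rownames(counts), fstat, p)
}

#' Two-stage polynomial regression detector
#'
#' Stage 1 tests the full polynomial-in-time by condition regression of
#' `log2(CPM + pc)` against the intercept-only model with a global F
#' test. Genes passing `alpha_stage1` (on the raw stage-1 p) proceed to
#' stage 2, a backward elimination of individual terms at
#' `stage2_alpha`, and are reported with the surviving term set. The
#' reported p-value is always the stage-1 p.
#'
#' @inheritParams detect_spline
#' @param degree polynomial degree (default 2); must be below the number
#'   of distinct timepoints.
#' @param alpha_stage1 gate for entering backward elimination.
#' @param stage2_alpha per-term elimination threshold.
#' @return detector result data.frame with an extra `terms` column
#'   (comma-separated surviving terms, `NA` for genes failing stage 1);
#'   `statistic` is the stage-1 F.
#' @export
detect_polynomial <- function(counts, sheet, treatment, degree = 2,
                              alpha_stage1 = 0.05, stage2_alpha = 0.05,
                              pseudocount = 0.5, control = "DMSO",
                              include_anchors = TRUE) {
  des <- tc_design(sheet, treatment, control, include_anchors)
  n_tp <- length(unique(des$time))
  if (degree >= n_tp) stopf("degree (%d) must be below the number of distinct timepoints (%d)", degree, n_tp)
  Y <- t(log2(cpm(counts)[, des$sample_id, drop = FALSE] + pseudocount))
  tt <- des$time
  cond <- as.integer(des$condition == "treated")
  terms <- list(cond = cond)
  for (d in seq_len(degree)) terms[[paste0("time", d)]] <- tt^d
  for (d in seq_len(degree)) terms[[paste0("cond:time", d)]] <- cond * tt^d
  X_full <- cbind(`(Intercept)` = 1, do.call(cbind, terms))
  colnames(X_full) <- c("(Intercept)", names(terms))
  rss1 <- design_rss(X_full, Y)
  r <- attr(rss1, "rank")
  if (r >= nrow(Y)) stopf("collinear/saturated design: no residual degrees of freedom")
  n <- nrow(Y)
  ybar <- colMeans(Y)
  rss0 <- colSums((Y - rep(1, n) %o% ybar)^2)
  df1 <- r - 1L
  df2 <- n - r
  num <- pmax(0, rss0 - rss1) / df1
  fstat <- ifelse(rss1 > 0, num / (rss1 / df2), ifelse(num == 0, 0, Inf))
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  sel <- rep(NA_character_, ncol(Y))
  for (g in which(p < alpha_stage1)) {
    sel[g] <- backward_eliminate(X_full, Y[, g], stage2_alpha)
  }
  detector_result("poly_twostage", rownames(counts), fstat, p,
                  extra = data.frame(terms = sel, stringsAsFactors = FALSE))
}

# drop the least significant term (largest t-test p above alpha) until
# all survivors clear alpha; the intercept is never dropped
backward_eliminate <- function(X, y, alpha) {
  keep <- colnames(X)
  repeat {
    fit <- stats::lm.fit(X[, keep, drop = FALSE], y)
    used <- keep[!is.na(fit$coefficients)]
    dfr <- length(y) - fit$rank
    if (dfr <= 0 || length(used) <= 1L) break
    XtXi <- tryCatch(chol2inv(chol(crossprod(X[, used, drop = FALSE]))),
                     error = function(e) NULL)
    if (is.null(XtXi)) break
    s2 <- sum(fit$residuals^2) / dfr
    se <- sqrt(pmax(diag(XtXi) * s2, 1e-300))
    tv <- fit$coefficients[used] / se
    pv <- 2 * stats::pt(-abs(tv), dfr)
    cand <- setdiff(used, "(Intercept)")
    if (!length(cand)) break
    worst <- cand[which.max(pv[cand])]
    if (pv[worst] <= alpha) break
    keep <- setdiff(used, worst)
    if (length(keep) <= 1L) break
  }
  paste(setdiff(keep, "(Intercept)"), collapse = ",")
}

#' Run all four detectors
#'
#' @inheritParams detect_pairwise_nb
#' @param dispersions optional precomputed [estimate_dispersions()]
#'   result; computed if missing.
#' @return named list of the four detector result data.frames.
#' @export
run_detectors <- function(counts, sheet, treatment, dispersions = NULL,
                          control = "DMSO") {
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts, sheet)
  list(
    pairwise_nb = detect_pairwise_nb(counts, sheet, treatment, dispersions,
                                     control = control),
    impulse_lrt = detect_impulse(counts, sheet, treatment, dispersions,
                                 control = control),
    spline_f = detect_spline(counts, sheet, treatment, control = control),
    poly_twostage = detect_polynomial(counts, sheet, treatment,
                                      control = control)
  )
}
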