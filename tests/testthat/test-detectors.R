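flat_disp <- function(counts, phi = 0.05) {
  d <- data.frame(gene_id = rownames(counts), phi_raw = phi, phi_shrunk = phi,
                  common_phi = phi, stringsAsFactors = FALSE)
  attr(d, "common_phi") <- phi
  d
}

test_that("copied treated/control columns give p = 1 in the pairwise test", {
  sheet <- toy_sheet(anchors = FALSE)
  counts <- toy_counts(sheet, 20, function(tr, tp) runif(20, 50, 500), seed = 1)
  # make every treated column an exact copy of the matching control column
  for (t in c(3, 6, 9)) for (r in 1:3) {
    counts[, sprintf("SB_%gh_r%d", t, r)] <- counts[, sprintf("DMSO_%gh_r%d", t, r)]
  }
  r <- detect_pairwise_nb(counts, sheet, "SB", flat_disp(counts))
  expect_true(all(r$p_raw == 1))
  expect_true(all(r$statistic == 0))
})

test_that("a strong persistent effect is detected with tiny p-values", {
  sheet <- toy_sheet(anchors = TRUE)
  base <- c(300, rep(200, 39))
  counts <- toy_counts(sheet, 40, function(tr, tp) {
    mu <- base
    if (tr == "SB") mu[1] <- mu[1] * 4  # |LFC| = 2 at every timepoint
    mu
  }, phi = 0.05, seed = 2)
  disp <- estimate_dispersions(counts, sheet)
  expect_lt(detect_pairwise_nb(counts, sheet, "SB", disp)$p_raw[1], 1e-3)
  expect_lt(detect_spline(counts, sheet, "SB")$p_raw[1], 1e-4)
  expect_lt(detect_polynomial(counts, sheet, "SB")$p_raw[1], 1e-3)
  expect_lt(detect_impulse(counts, sheet, "SB", disp)$p_raw[1], 1e-3)
})

test_that("symmetric tests are invariant to swapping the arm labels", {
  sheet <- toy_sheet(anchors = FALSE)
  counts <- toy_counts(sheet, 30, function(tr, tp) {
    mu <- seq(50, 400, length.out = 30)
    if (tr == "SB") mu * 2^seq(-0.5, 0.5, length.out = 30) else mu
  }, seed = 3)
  disp <- estimate_dispersions(counts, sheet)
  a <- detect_pairwise_nb(counts, sheet, "SB", disp, control = "DMSO")
  b <- detect_pairwise_nb(counts, sheet, "DMSO", disp, control = "SB")
  expect_equal(a$p_raw, b$p_raw, tolerance = 1e-10)
  a <- detect_spline(counts, sheet, "SB", df = 2, control = "DMSO")
  b <- detect_spline(counts, sheet, "DMSO", df = 2, control = "SB")
  expect_equal(a$p_raw, b$p_raw, tolerance = 1e-10)
  a <- detect_polynomial(counts, sheet, "SB", control = "DMSO")
  b <- detect_polynomial(counts, sheet, "DMSO", control = "SB")
  expect_equal(a$p_raw, b$p_raw, tolerance = 1e-10)
})

test_that("median detector p decreases as the true effect grows", {
  sheet <- toy_sheet(anchors = TRUE)
  # effect genes are a small library fraction so CPM composition stays flat
  lfcs <- c(rep(c(0.5, 1, 2), each = 25), rep(0, 425))
  counts <- toy_counts(sheet, 500, function(tr, tp) {
    mu <- c(rep(100, 75), rep(2000, 425))
    if (tr == "SB") mu * 2^lfcs else mu
  }, phi = 0.05, seed = 4)
  disp <- estimate_dispersions(counts, sheet)
  eff <- 1:75
  res <- list(detect_pairwise_nb(counts, sheet, "SB", disp),
              detect_spline(counts, sheet, "SB"),
              detect_polynomial(counts, sheet, "SB"),
              detect_impulse(counts, sheet, "SB", disp))
  for (r in res) {
    med <- tapply(r$p_raw[seq_len(75)], lfcs[eff], median)
    expect_true(all(diff(med) <= 0),
                info = paste("power ordering for", r$detector_name[1]))
  }
})

test_that("spline detector returns F = 0 for a zero-variance equal-arm gene", {
  sheet <- toy_sheet(anchors = TRUE)
  counts <- matrix(100L, 1, nrow(sheet),
                   dimnames = list("g1", sheet$sample_id))
  # equal library sizes, identical values: zero residual variance
  r <- detect_spline(counts, sheet, "SB")
  expect_equal(r$statistic, 0)
})

test_that("spline df must stay below the number of distinct timepoints", {
  sheet <- toy_sheet(anchors = FALSE)  # 3 distinct timepoints
  counts <- toy_counts(sheet, 5, function(tr, tp) rep(100, 5))
  expect_error(detect_spline(counts, sheet, "SB", df = 3), "distinct timepoints")
  expect_error(detect_polynomial(counts, sheet, "SB", degree = 3),
               "distinct timepoints")
})

test_that("flat genes fail polynomial stage 1; quadratic responders keep the interaction", {
  sheet <- toy_sheet(anchors = TRUE)
  counts <- toy_counts(sheet, 200, function(tr, tp) {
    mu <- rep(200, 200)
    # gene 1: transient quadratic response in the treated arm only; the
    # other 199 flat genes keep the library composition stable
    if (tr == "SB") mu[1] <- 200 * 2^(1.5 * (tp / 3) * (1 - tp / 12) * 2)
    mu
  }, phi = 0.01, seed = 5)
  r <- detect_polynomial(counts, sheet, "SB")
  expect_lt(r$p_raw[1], 0.01)
  expect_match(r$terms[1], "cond")
  expect_gt(median(r$p_raw[-1]), 0.2)

  # independent OLS oracle for the stage-1 F of gene 1
  des <- tcensemble:::tc_design(sheet, "SB")
  y <- log2(cpm(counts)[1, des$sample_id] + 0.5)
  d <- data.frame(y = y, t = des$time,
                  cond = as.integer(des$condition == "treated"))
  full <- lm(y ~ cond * poly(t, 2, raw = TRUE), data = d)
  f_oracle <- summary(full)$fstatistic[["value"]]
  expect_equal(r$statistic[1], f_oracle, tolerance = 1e-8)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  expect_error(adjust_pvalues(c(0.1, NA)), "NA")
  expect_error(adjust_pvalues(c(0.1, 1.2)), "\\[0, 1\\]")
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  expect_true(all(diff(sort(adjust_pvalues(p))) >= 0))
})

test_that("variance shrinkage agrees with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(8)
  # gene-wise variances drawn from a genuine scaled-inverse-chisq prior
  truevar <- 0.3 * 8 / rchisq(400, 8)
  s2 <- truevar * rchisq(400, 7) / 7
  mine <- squeeze_var(s2, df = 7)
  ref <- limma::squeezeVar(s2, df = 7)
  expect_equal(mine$df_prior, ref$df.prior, tolerance = 1e-6)
  expect_equal(mine$var_prior, ref$var.prior, tolerance = 1e-6)
  expect_equal(mine$var_post, ref$var.post, tolerance = 1e-9)
})

test_that("detector outputs satisfy the result contract", {
  sheet <- toy_sheet(anchors = TRUE)
  counts <- toy_counts(sheet, 15, function(tr, tp) runif(15, 50, 300), seed = 7)
  disp <- estimate_dispersions(counts, sheet)
  res <- run_detectors(counts, sheet, "SB", disp)
  expect_named(res, c("pairwise_nb", "impulse_lrt", "spline_f", "poly_twostage"))
  for (r in res) {
    expect_true(all(r$p_raw >= 0 & r$p_raw <= 1))
    expect_true(all(r$p_adj >= r$p_raw - 1e-12))
    expect_identical(r$gene_id, rownames(counts))
  }
})
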