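# Synthetic count generator emulating a short inhibitor time course:
# one treated arm and a time-matched solvent (DMSO) arm at each nonzero
# timepoint, in triplicate, plus untreated anchor samples at the first
# and last timepoints. Counts are negative-binomial with gene-wise
# dispersion; differentially expressed genes follow impulse-shaped
# (monotone or transient) log2 fold-change trajectories of known size.

#' Simulation configuration
#'
#' Defaults mirror the emulated experiment: triplicates at 3/6/9 h with
#' time-matched DMSO controls and untreated 0/9-h anchors, ~1e6 reads per
#' library with 10% lognormal jitter, lognormal baseline abundances,
#' gene-wise NB dispersion lognormal around 0.05, and true effect sizes
#' of 1-3 log2 units split between monotone-up, monotone-down and
#' transient trajectories.
#'
#' @param n_genes number of genes.
#' @param frac_de fraction of genes that are truly differentially
#'   expressed, in \[0, 1\].
#' @param timepoints_h ordered vector of timepoints (hours); the first is
#'   the untreated baseline.
#' @param n_reps replicates per arm and timepoint (>= 2).
#' @param lib_size expected total counts per sample.
#' @param lib_size_cv lognormal coefficient of variation of per-sample
#'   library sizes (0 disables jitter).
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of the
#'   (unnormalized) baseline abundance of each gene; only the shape
#'   matters, abundances are renormalized to sum to one.
#' @param phi_meanlog,phi_sdlog lognormal parameters of the gene-wise NB
#'   dispersion; `phi_sdlog = 0` gives every gene the same dispersion
#'   `exp(phi_meanlog)`.
#' @param effect_lfc_min,effect_lfc_max range of the true maximum
#'   absolute log2 fold change of DE genes (drawn uniformly).
#' @param trajectory_mix named fractions of the three trajectory shapes
#'   `monotone_up`, `monotone_down`, `transient`; must sum to 1.
#' @param treatment label of the treated arm (e.g. `"SB"` or `"SU"`).
#' @param dmso_shift optional solvent effect: log2 shift applied to every
#'   gene's DMSO mean relative to the untreated baseline (default 0).
#' @param seed integer RNG seed; identical configs give byte-identical
#'   output.
#' @return a validated `sim_config` object (a list).
#' @export
sim_config <- function(n_genes = 2000L,
                       frac_de = 0.1,
                       timepoints_h = c(0, 3, 6, 9),
                       n_reps = 3L,
                       lib_size = 1e6,
                       lib_size_cv = 0.1,
                       baseline_meanlog = 0,
                       baseline_sdlog = 1,
                       phi_meanlog = log(0.05),
                       phi_sdlog = 0.3,
                       effect_lfc_min = 1,
                       effect_lfc_max = 3,
                       trajectory_mix = c(monotone_up = 0.35,
                                          monotone_down = 0.35,
                                          transient = 0.3),
                       treatment = "SB",
                       dmso_shift = 0,
                       seed = 1L) {
  if (!is_count(n_genes)) stopf("n_genes must be a positive integer")
  if (!is_number(frac_de) || frac_de < 0 || frac_de > 1) {
    stopf("frac_de must lie in [0, 1]")
  }
  if (!is.numeric(timepoints_h) || length(timepoints_h) < 2L ||
      is.unsorted(timepoints_h, strictly = TRUE)) {
    stopf("timepoints_h must be strictly ascending with at least two entries")
  }
  if (!is_count(n_reps) || n_reps < 2L) stopf("n_reps must be an integer >= 2")
  if (!is_number(lib_size) || lib_size <= 0) stopf("lib_size must be positive")
  for (v in c(lib_size_cv, baseline_meanlog, baseline_sdlog, phi_meanlog,
              phi_sdlog, effect_lfc_min, effect_lfc_max, dmso_shift)) {
    if (!is_number(v)) stopf("distribution parameters must be finite numbers")
  }
  if (baseline_sdlog < 0 || phi_sdlog < 0 || lib_size_cv < 0) {
    stopf("scale parameters must be non-negative")
  }
  if (effect_lfc_min <= 0 || effect_lfc_max < effect_lfc_min) {
    stopf("effect LFC range must satisfy 0 < min <= max")
  }
  mix_names <- c("monotone_up", "monotone_down", "transient")
  if (!setequal(names(trajectory_mix), mix_names) ||
      any(trajectory_mix < 0) || abs(sum(trajectory_mix) - 1) > 1e-8) {
    stopf("trajectory_mix must be fractions over {%s} summing to 1",
          paste(mix_names, collapse = ", "))
  }
  structure(list(n_genes = as.integer(n_genes), frac_de = frac_de,
                 timepoints_h = timepoints_h, n_reps = as.integer(n_reps),
                 lib_size = lib_size, lib_size_cv = lib_size_cv,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 phi_meanlog = phi_meanlog, phi_sdlog = phi_sdlog,
                 effect_lfc_min = effect_lfc_min,
                 effect_lfc_max = effect_lfc_max,
                 trajectory_mix = trajectory_mix[mix_names],
                 treatment = treatment, dmso_shift = dmso_shift,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw negative-binomial counts with the mean/dispersion convention
#'
#' `Var = mean + dispersion * mean^2`; `dispersion = 0` degenerates to
#' Poisson.
#'
#' @param mean positive mean (scalar or vector recycled over `size`).
#' @param dispersion NB dispersion `phi >= 0`.
#' @param size number of draws.
#' @param seed optional seed set locally for reproducible draws.
#' @return integer vector of counts.
#' @export
sample_nb_counts <- function(mean, dispersion, size, seed = NULL) {
  if (any(!is.finite(mean)) || any(mean <= 0)) stopf("mean must be positive")
  if (!is_number(dispersion) || dispersion < 0) {
    stopf("dispersion must be a non-negative number")
  }
  if (!is_count(size)) stopf("size must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  if (dispersion == 0) stats::rpois(size, lambda = mean)
  else stats::rnbinom(size, mu = mean, size = 1 / dispersion)
}

# True LFC trajectory l(t) for one DE gene: built from an impulse-shaped
# pulse, anchored to 0 at t = 0 and rescaled so max |l(t)| over the
# observed window equals the drawn effect size. Monotone shapes put the
# offset beyond the window; transient shapes peak inside it.
make_trajectory <- function(shape, effect, timepoints) {
  rng <- range(timepoints)
  span <- diff(rng)
  if (shape == "transient") {
    t1 <- stats::runif(1, rng[1] + 0.15 * span, rng[1] + 0.45 * span)
    t2 <- stats::runif(1, rng[1] + 0.55 * span, rng[1] + 0.9 * span)
    sign_eff <- sample(c(-1, 1), 1L)
  } else {
    t1 <- stats::runif(1, rng[1] + 0.2 * span, rng[1] + 0.7 * span)
    t2 <- rng[2] + span  # offset beyond the window -> monotone within it
    sign_eff <- if (shape == "monotone_up") 1 else -1
  }
  beta <- stats::runif(1, 0.5, 1.5)
  raw <- function(t) sigmoid(beta * (t - t1)) * sigmoid(beta * (t2 - t))
  grid <- seq(rng[1], rng[2], length.out = 81L)
  vals <- raw(grid) - raw(rng[1])
  scale <- max(abs(vals))
  l <- function(t) sign_eff * effect * (raw(t) - raw(rng[1])) / scale
  list(fn = l, t1 = t1, t2 = t2, beta = beta, sign = sign_eff)
}

#' Simulate a complete time-course inhibition experiment
#'
#' @param config a [sim_config()].
#' @return list with `counts` (integer matrix, genes x samples),
#'   `sample_sheet` (data.frame: sample_id, treatment, timepoint_h,
#'   replicate) and `truth` (data.frame: gene_id, is_de, shape,
#'   true_max_lfc and true LFC at each nonzero timepoint).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) stopf("config must come from sim_config()")
  set.seed(config$seed)
  n <- config$n_genes
  tps <- config$timepoints_h
  t0 <- tps[1L]
  t_treat <- tps[-1L]
  gene_ids <- sprintf("g%04d", seq_len(n))

  # sample sheet: treated + DMSO at each nonzero timepoint, untreated
  # anchors at the first and last timepoint
  rep_idx <- seq_len(config$n_reps)
  sheet <- rbind(
    expand.grid(replicate = rep_idx, timepoint_h = c(t0, tps[length(tps)]),
                treatment = "untreated", stringsAsFactors = FALSE),
    expand.grid(replicate = rep_idx, timepoint_h = t_treat,
                treatment = "DMSO", stringsAsFactors = FALSE),
    expand.grid(replicate = rep_idx, timepoint_h = t_treat,
                treatment = config$treatment, stringsAsFactors = FALSE)
  )
  sheet$sample_id <- sprintf("%s_%gh_r%d", sheet$treatment,
                             sheet$timepoint_h, sheet$replicate)
  sheet <- sheet[, c("sample_id", "treatment", "timepoint_h", "replicate")]
  rownames(sheet) <- NULL

  # gene-level baselines and dispersions
  w <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  rel <- w / sum(w)
  phi <- if (config$phi_sdlog == 0) rep(exp(config$phi_meanlog), n)
         else stats::rlnorm(n, config$phi_meanlog, config$phi_sdlog)

  # ground truth
  n_de <- round(config$frac_de * n)
  de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)
  shapes <- character(n)
  effects <- numeric(n)
  lfc_true <- matrix(0, n, length(t_treat),
                     dimnames = list(gene_ids, sprintf("lfc_%gh", t_treat)))
  mix <- config$trajectory_mix
  for (g in de_idx) {
    shapes[g] <- sample(names(mix), 1L, prob = mix)
    effects[g] <- stats::runif(1, config$effect_lfc_min, config$effect_lfc_max)
    tr <- make_trajectory(shapes[g], effects[g], tps)
    lfc_true[g, ] <- tr$fn(t_treat)
  }

  # per-sample library sizes (lognormal jitter) and NB counts
  n_samp <- nrow(sheet)
  sdlog <- sqrt(log(1 + config$lib_size_cv^2))
  libs <- if (config$lib_size_cv == 0) rep(config$lib_size, n_samp)
          else stats::rlnorm(n_samp, log(config$lib_size) - sdlog^2 / 2, sdlog)
  counts <- matrix(0L, n, n_samp, dimnames = list(gene_ids, sheet$sample_id))
  for (s in seq_len(n_samp)) {
    fold <- rep(1, n)
    if (sheet$treatment[s] == "DMSO" && config$dmso_shift != 0) {
      fold <- rep(2^config$dmso_shift, n)
    } else if (sheet$treatment[s] == config$treatment) {
      ti <- match(sheet$timepoint_h[s], t_treat)
      fold <- 2^lfc_true[, ti]
      if (config$dmso_shift != 0) fold <- fold * 2^config$dmso_shift
    }
    mu <- pmax(rel * fold * libs[s], 1e-8)
    counts[, s] <- as.integer(stats::rnbinom(n, mu = mu, size = 1 / phi))
  }

  truth <- data.frame(gene_id = gene_ids,
                      is_de = seq_len(n) %in% de_idx,
                      shape = ifelse(shapes == "", NA, shapes),
                      true_max_lfc = ifelse(effects == 0, 0, effects),
                      phi = phi,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(lfc_true))
  rownames(truth) <- NULL
  list(counts = counts, sample_sheet = sheet, truth = truth)
}

#' Write a simulated experiment to TSV files
#'
#' Writes `counts.tsv` (first column `gene_id`), `samples.tsv` and
#' `truth.tsv` into `dir`.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "samples.tsv", "truth.tsv"))
  write_counts(sim$counts, paths[1L])
  write_sample_sheet(sim$sample_sheet, paths[2L])
  utils::write.table(sim$truth, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
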