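# Seeded synthetic-data generators. Each is a pure function of its
# parameters and seed (RNG state is restored on exit) and returns the
# dataset together with a ground-truth manifest, so planted-gene recovery is
# testable without external data.
#
# Defaults emulate the unbalanced T-lineage study design: four biological
# groups of 34 / 5 / 4 / 9 samples (patients, normal bone-marrow
# T-lymphocytes, thymocytes, cell lines) and a small panel of candidate
# normalizers among a larger set of assayed miRNAs.

default_cq_groups <- function() c(T_ALL = 34L, BM = 5L, thymocytes = 4L, cell_lines = 9L)

#' Simulate a replicate-level Cq dataset with planted stable genes
#'
#' Generates `Cq(g, s, rep) = baseline_g + shift_s + group_effect +
#' N(0, sigma_g) + N(0, sigma_tech)`: a per-gene baseline (abundance), a
#' per-sample loading/input shift common to all genes, a group effect for
#' differentially expressed genes, per-(gene, sample) biological noise and
#' per-replicate technical noise. Stable genes have small `stable_sd` and no
#' group effect; noisy genes have `noisy_sd`; DE genes additionally shift by
#' `-de_effect` Cq (i.e. `+de_effect` log2 overexpression) in the first
#' group. Deterministic per seed.
#'
#' @param n_samples_per_group named integer vector of group sizes (default
#'   34/5/4/9, the unbalanced T-lineage design).
#' @param n_stable,n_noisy,n_de gene counts per class (defaults 3, 7, 3: a
#'   trio of planted normalizers among a 10-gene candidate panel plus DE
#'   targets).
#' @param stable_sd,noisy_sd per-gene biological noise SD in Cq units
#'   (defaults 0.05 and 0.6).
#' @param de_effect log2 overexpression of DE genes in the first group
#'   (default 2).
#' @param shift_sd SD of per-sample shifts (default 0.8 Cq, typical
#'   input-amount variation).
#' @param replicate_sd technical replicate SD (default 0.15 Cq).
#' @param n_replicates technical replicates per well (default 3).
#' @param baseline_range uniform range for per-gene baseline Cq
#'   (default 20-27, the abundant-miRNA window).
#' @param seed non-negative integer seed.
#' @return list with `cq` (a [cq_table()]) and `truth` (list: gene classes,
#'   noise SDs, per-sample shifts, group effects, seed).
#' @export
simulate_cq_dataset <- function(n_samples_per_group = default_cq_groups(),
                                n_stable = 3L, n_noisy = 7L, n_de = 3L,
                                stable_sd = 0.05, noisy_sd = 0.6, de_effect = 2,
                                shift_sd = 0.8, replicate_sd = 0.15,
                                n_replicates = 3L,
                                baseline_range = c(20, 27), seed = 1L) {
  if (any(n_samples_per_group < 1L) || length(n_samples_per_group) < 1L) {
    stop_parameter("each group needs >= 1 sample")
  }
  if (n_stable < 0L || n_noisy < 0L || n_de < 0L || n_stable + n_noisy + n_de < 1L) {
    stop_parameter("gene counts must be non-negative with at least one gene")
  }
  if (min(stable_sd, noisy_sd, shift_sd, replicate_sd) < 0) {
    stop_parameter("noise SDs must be >= 0")
  }
  if (!is_count(n_replicates)) stop_parameter("n_replicates must be a positive integer")
  if (is.null(names(n_samples_per_group))) {
    names(n_samples_per_group) <- paste0("grp", seq_along(n_samples_per_group))
  }
  withr::local_seed(seed)

  genes <- c(
    if (n_stable > 0L) sprintf("stable_%02d", seq_len(n_stable)),
    if (n_noisy > 0L) sprintf("noisy_%02d", seq_len(n_noisy)),
    if (n_de > 0L) sprintf("de_%02d", seq_len(n_de))
  )
  gene_sd <- c(rep(stable_sd, n_stable), rep(noisy_sd, n_noisy), rep(noisy_sd, n_de))
  names(gene_sd) <- genes
  groups <- rep(names(n_samples_per_group), n_samples_per_group)
  n_samples <- length(groups)
  samples <- sprintf("sample_%03d", seq_len(n_samples))

  baseline <- setNames(runif(length(genes), baseline_range[1L], baseline_range[2L]), genes)
  shift <- setNames(rnorm(n_samples, 0, shift_sd), samples)
  # DE genes are overexpressed (lower Cq) in the first group.
  effect <- matrix(0, length(genes), n_samples, dimnames = list(genes, samples))
  de_genes <- genes[grepl("^de_", genes)]
  effect[de_genes, groups == names(n_samples_per_group)[1L]] <- -de_effect

  rows <- vector("list", length(genes) * n_samples)
  idx <- 0L
  for (g in genes) {
    bio <- rnorm(n_samples, 0, gene_sd[[g]])
    for (s in seq_len(n_samples)) {
      idx <- idx + 1L
      cqs <- baseline[[g]] + shift[[s]] + effect[g, s] + bio[s] +
        rnorm(n_replicates, 0, replicate_sd)
      rows[[idx]] <- data.frame(
        sample_id = samples[s], group = groups[s], target_id = g,
        replicate = seq_len(n_replicates), cq = cqs, row.names = NULL
      )
    }
  }
  truth <- list(
    stable_genes = genes[grepl("^stable_", genes)],
    noisy_genes = genes[grepl("^noisy_", genes)],
    de_genes = de_genes,
    gene_sd = as.list(gene_sd),
    de_effect_log2 = de_effect,
    shift_sd = shift_sd, replicate_sd = replicate_sd,
    baseline = as.list(baseline),
    sample_shift = as.list(shift),
    groups = as.list(setNames(groups, samples)),
    seed = seed
  )
  list(cq = cq_table(do.call(rbind, rows)), truth = truth)
}

#' Simulate a negative-binomial miRNA-seq count matrix
#'
#' Counts are drawn as `NB(mean = library size x relative abundance,
#' dispersion)`. Stable genes keep a constant relative abundance with low
#' dispersion; the remaining genes receive per-sample lognormal abundance
#' jitter (`jitter_sd` on the log2 scale) on top of the shared dispersion;
#' DE genes change by `de_log2fc` in the first group. Library sizes are
#' lognormal around `lib_size` with coefficient of variation `lib_cv`.
#'
#' @param n_samples_per_group named group sizes (default 34/5/4/9).
#' @param n_genes total genes (default 50).
#' @param n_stable planted stable genes (default 10, the candidate panel).
#' @param n_de differentially expressed genes (default 5).
#' @param de_log2fc group log2 fold change of DE genes (default 2).
#' @param jitter_sd log2-scale abundance jitter SD of non-stable genes
#'   (default 0.8).
#' @param dispersion NB dispersion of non-stable genes (default 0.1; stable
#'   genes use `dispersion / 10`).
#' @param lib_size,lib_cv mean library size and its CV (defaults 1e6, 0.3).
#' @param seed non-negative integer seed.
#' @return list with `counts` (a counts-scale [expression_matrix()]) and
#'   `truth`.
#' @export
simulate_count_dataset <- function(n_samples_per_group = default_cq_groups(),
                                   n_genes = 50L, n_stable = 10L, n_de = 5L,
                                   de_log2fc = 2, jitter_sd = 0.8,
                                   dispersion = 0.1,
                                   lib_size = 1e6, lib_cv = 0.3, seed = 1L) {
  if (dispersion < 0) stop_parameter("dispersion must be >= 0")
  if (n_stable + n_de > n_genes) stop_parameter("n_stable + n_de must be <= n_genes")
  if (is.null(names(n_samples_per_group))) {
    names(n_samples_per_group) <- paste0("grp", seq_along(n_samples_per_group))
  }
  withr::local_seed(seed)

  groups <- rep(names(n_samples_per_group), n_samples_per_group)
  n_samples <- length(groups)
  samples <- sprintf("sample_%03d", seq_len(n_samples))
  n_other <- n_genes - n_stable - n_de
  genes <- c(
    if (n_stable > 0L) sprintf("stable_%02d", seq_len(n_stable)),
    if (n_de > 0L) sprintf("de_%02d", seq_len(n_de)),
    if (n_other > 0L) sprintf("gene_%03d", seq_len(n_other))
  )
  # Base relative abundances: lognormal, spanning a realistic dynamic range.
  # DE targets are scaled down a decade: validated target miRNAs are rarely
  # among the library-dominating species, and keeping their library fraction
  # small limits CPM composition bias on the planted fold changes.
  base_ab <- setNames(rlnorm(n_genes, meanlog = log(1e-3), sdlog = 1.5), genes)
  base_ab[grepl("^de_", genes)] <- base_ab[grepl("^de_", genes)] * 0.1
  base_ab <- base_ab / sum(base_ab)
  libsize <- rlnorm(n_samples, meanlog = log(lib_size) - log(1 + lib_cv^2) / 2,
                    sdlog = sqrt(log(1 + lib_cv^2)))

  mu <- matrix(0, n_genes, n_samples, dimnames = list(genes, samples))
  is_stable <- grepl("^stable_", genes)
  is_de <- grepl("^de_", genes)
  for (s in seq_len(n_samples)) {
    ab <- base_ab
    jitter <- 2^rnorm(n_genes, 0, jitter_sd)
    jitter[is_stable] <- 1
    ab <- ab * jitter
    if (groups[s] == names(n_samples_per_group)[1L]) {
      ab[is_de] <- ab[is_de] * 2^de_log2fc
    }
    mu[, s] <- libsize[s] * ab / sum(ab)
  }
  size_par <- ifelse(is_stable,
                     if (dispersion > 0) 10 / dispersion else Inf,
                     if (dispersion > 0) 1 / dispersion else Inf)
  counts <- matrix(0, n_genes, n_samples, dimnames = list(genes, samples))
  for (g in seq_len(n_genes)) {
    counts[g, ] <- if (is.finite(size_par[g])) {
      rnbinom(n_samples, mu = mu[g, ], size = size_par[g])
    } else {
      stats::rpois(n_samples, mu[g, ])
    }
  }
  truth <- list(
    stable_genes = genes[is_stable], de_genes = genes[is_de],
    de_log2fc = de_log2fc, jitter_sd = jitter_sd, dispersion = dispersion,
    library_sizes = as.list(setNames(libsize, samples)),
    groups = as.list(setNames(groups, samples)), seed = seed
  )
  list(counts = expression_matrix(counts, scale = "counts", groups = groups),
       truth = truth)
}

#' Simulate a qPCR serial-dilution series
#'
#' `Cq(d) = intercept - log10(d) / log10(1 + E) + N(0, noise_sd)` at
#' `dilution_step`-fold dilutions, where `E` is the true per-cycle
#' amplification gain (`true_efficiency_pct / 100`). With 100% efficiency
#' and no noise the slope is exactly `-1/log10(2) = -3.3219`.
#'
#' @param true_efficiency_pct true efficiency in percent, in (50, 150].
#' @param intercept Cq of the undiluted sample (default 20).
#' @param n_levels number of dilution levels (default 6, i.e. 10^0..10^-5).
#' @param noise_sd Cq measurement noise SD (default 0).
#' @param dilution_step fold dilution per level (default 10).
#' @param seed non-negative integer seed.
#' @return data frame with columns `dilution`, `cq`, and the truth in
#'   `attr(, "truth")`.
#' @export
simulate_dilution_series <- function(true_efficiency_pct = 100, intercept = 20,
                                     n_levels = 6L, noise_sd = 0,
                                     dilution_step = 10, seed = 1L) {
  if (true_efficiency_pct <= 50 || true_efficiency_pct > 150) {
    stop_parameter("true_efficiency_pct must be in (50, 150]")
  }
  if (!is_count(n_levels) || n_levels < 3L) stop_parameter("n_levels must be >= 3")
  if (noise_sd < 0) stop_parameter("noise_sd must be >= 0")
  withr::local_seed(seed)
  e <- true_efficiency_pct / 100
  dilution <- dilution_step^-(seq_len(n_levels) - 1L)
  cq <- intercept - log10(dilution) / log10(1 + e) + rnorm(n_levels, 0, noise_sd)
  out <- data.frame(dilution = dilution, cq = cq)
  attr(out, "truth") <- list(true_efficiency_pct = true_efficiency_pct,
                             intercept = intercept, noise_sd = noise_sd,
                             seed = seed)
  out
}
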