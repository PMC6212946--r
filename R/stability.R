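# Four expression-stability estimators plus a comprehensive rank aggregate.
# All operate on a genes x samples matrix of log2-scale signals; Cq values
# are log2-scale by nature (one PCR cycle = one doubling) and are used as-is.

# Coerce the accepted containers to a plain matrix (+ groups), enforcing the
# scale each estimator needs and subsetting to complete cases.
stability_input <- function(m, need = c("log", "cq"), context = "stability") {
  need <- match.arg(need)
  groups <- NULL
  if (inherits(m, "cq_matrix")) {
    x <- m$cq
    groups <- m$groups
  } else if (inherits(m, "expression_matrix")) {
    if (m$scale != "log2") {
      stop_scale(sprintf("%s requires log2-scale signals; call to_log2() first", context))
    }
    if (need == "cq") {
      stop_scale(sprintf("%s requires raw Cq data (a cq_matrix)", context))
    }
    x <- m$values
    groups <- m$groups
  } else if (is.matrix(m) && is.numeric(m)) {
    x <- m
    if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  } else {
    stop_validation("input must be a cq_matrix, expression_matrix or numeric matrix")
  }
  x <- complete_case_columns(x, context)
  list(x = x, groups = groups)
}

# Residuals of the two-way additive model value = gene + sample + error,
# fitted by row/column mean centering.
two_way_residuals <- function(x) {
  sweep(sweep(x, 1L, rowMeans(x)), 2L, colMeans(x)) + mean(x)
}

#' NormFinder-style stability score
#'
#' Fits the two-way additive model `signal = gene effect + sample effect +
#' residual` by row/column mean centering. In the default ungrouped mode a
#' gene's score is the sample standard deviation (n-1 denominator) of its
#' residuals: genes that track the common sample-to-sample signal perfectly
#' score 0. With `groups` given, the score additionally penalises systematic
#' between-group deviation: `sqrt(mean intragroup residual variance +
#' variance of the gene's group-mean residuals)` — a simplified form of the
#' published model-based estimator. Lower = more stable.
#'
#' @param m [cq_table()]-derived `cq_matrix`, a log2-scale
#'   [expression_matrix()], or a plain numeric matrix (genes x samples).
#' @param groups optional per-sample labels enabling grouped mode; `NULL`
#'   (default) scores stability across all samples.
#' @return named numeric vector of per-gene scores (lower = more stable).
#' @references Andersen, Jensen & Orntoft (2004) Cancer Res 64:5245-5250.
#' @export
normfinder_stability <- function(m, groups = NULL) {
  inp <- stability_input(m, "log", "normfinder_stability")
  x <- inp$x
  if (is.null(groups)) groups <- inp$groups[colnames(x)]
  if (nrow(x) < 3L || ncol(x) < 3L) {
    stop_insufficient("normfinder_stability needs >= 3 genes and >= 3 samples")
  }
  r <- two_way_residuals(x)
  if (is.null(groups)) {
    return(apply(r, 1L, sd))
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(x)) stop_validation("groups must label every sample")
  apply(r, 1L, function(ri) {
    by_grp <- split(ri, groups)
    intra <- mean(vapply(by_grp, function(v) if (length(v) > 1L) var(v) else 0, 0))
    inter <- var(vapply(by_grp, mean, 0))
    if (is.na(inter)) inter <- 0  # single group degenerates to ungrouped form
    sqrt(intra + inter)
  })
}

# M value of each gene in x: mean over partners of the SD of per-sample
# pairwise Cq differences (= SD of log2 expression ratios at efficiency 2).
genorm_m_values <- function(x) {
  g <- nrow(x)
  v <- matrix(0, g, g)
  for (j in seq_len(g - 1L)) {
    for (k in (j + 1L):g) {
      v[j, k] <- v[k, j] <- sd(x[k, ] - x[j, ])
    }
  }
  setNames(rowSums(v) / (g - 1L), rownames(x))
}

#' geNorm M values with stepwise exclusion ranking
#'
#' The pairwise variation of genes j and k is the standard deviation across
#' samples of their per-sample signal difference; a gene's M value is the
#' mean pairwise variation with all other candidates. Co-regulated, stable
#' genes have low M. Ranking follows geNorm's iterative exclusion: the gene
#' with the highest M is removed and M values recomputed until two genes
#' remain; those two are ordered by their last-round M (classic geNorm
#' leaves them tied).
#'
#' @inheritParams normfinder_stability
#' @return list with `M` (full-panel M per gene), `ranking` (gene ids, most
#'   stable first), and `rank` (named integer vector, ties share the minimum
#'   rank), classed `genorm_result`.
#' @references Vandesompele et al. (2002) Genome Biol 3:research0034.
#' @export
genorm_m <- function(m) {
  inp <- stability_input(m, "log", "genorm_m")
  x <- inp$x
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop_insufficient("genorm_m needs >= 2 genes and >= 2 samples")
  }
  m_full <- genorm_m_values(x)
  remaining <- rownames(x)
  excluded <- character(0)
  while (length(remaining) > 2L) {
    mr <- genorm_m_values(x[remaining, , drop = FALSE])
    worst <- remaining[order(-mr, remaining)][1L]
    excluded <- c(worst, excluded)
    remaining <- setdiff(remaining, worst)
  }
  m_last <- genorm_m_values(x[remaining, , drop = FALSE])
  ranking <- c(remaining[order(m_last, remaining)], excluded)
  rank_v <- setNames(seq_along(ranking), ranking)
  if (m_last[ranking[1L]] == m_last[ranking[2L]]) rank_v[2L] <- 1L  # tied pair
  structure(list(M = m_full, ranking = ranking, rank = rank_v[rownames(x)]),
            class = "genorm_result")
}

#' BestKeeper descriptive statistics
#'
#' Operates on raw Cq values. Per gene: dispersion across samples (sample SD
#' by default, or BestKeeper's original mean absolute deviation from the
#' mean), the coefficient of variation CV% = 100 * SD / mean, and the Pearson
#' correlation with the BestKeeper index (the per-sample arithmetic mean Cq
#' over all candidates, i.e. the geometric mean of linear expression).
#' Candidates are ranked by ascending dispersion. Unlike the other three
#' estimators, BestKeeper is sensitive to per-sample loading shifts.
#'
#' @param m `cq_matrix` or plain numeric Cq matrix (targets x samples).
#' @param dispersion `"sd"` (default, RefFinder convention) or `"mad"`
#'   (mean absolute deviation, the original BestKeeper statistic).
#' @return data frame with columns `gene`, `sd`, `cv_pct`, `r_index`, `rank`.
#' @references Pfaffl et al. (2004) Biotechnol Lett 26:509-515.
#' @export
bestkeeper_stats <- function(m, dispersion = c("sd", "mad")) {
  dispersion <- match.arg(dispersion)
  inp <- stability_input(m, "cq", "bestkeeper_stats")
  x <- inp$x
  if (ncol(x) < 2L) stop_insufficient("bestkeeper_stats needs >= 2 samples")
  disp <- apply(x, 1L, function(v) {
    if (dispersion == "sd") sd1(v) else mean(abs(v - mean(v)))
  })
  cv <- 100 * disp / rowMeans(x)
  index <- colMeans(x)
  r <- apply(x, 1L, function(v) {
    if (sd(v) == 0 || sd(index) == 0) 1 else cor(v, index)
  })
  data.frame(gene = rownames(x), sd = disp, cv_pct = cv, r_index = r,
             rank = rank(disp, ties.method = "min"), row.names = NULL)
}

#' Comparative delta-Ct stability score
#'
#' For every ordered gene pair (g, h) the per-sample difference
#' `Cq_g - Cq_h` is formed; the pair's dispersion is its standard deviation
#' across samples, and a gene's score is the mean dispersion over all
#' partners. Identical to the geNorm M value computation on the full panel;
#' kept as an independent estimator because the two diverge once geNorm's
#' stepwise exclusion reranks genes.
#'
#' @inheritParams normfinder_stability
#' @return named numeric vector of per-gene scores (lower = more stable).
#' @references Silver et al. (2006) BMC Mol Biol 7:33.
#' @export
delta_ct_stability <- function(m) {
  inp <- stability_input(m, "log", "delta_ct_stability")
  x <- inp$x
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop_insufficient("delta_ct_stability needs >= 2 genes and >= 2 samples")
  }
  genorm_m_values(x)
}

#' Comprehensive geometric-mean-of-ranks stability score
#'
#' Aggregates the four per-method rankings into a single comprehensive score
#' per gene: the geometric mean of its four ranks (1 = most stable per
#' method; ties share the minimum rank). Genes are then ranked by ascending
#' comprehensive score, ties broken by gene name.
#'
#' @param normfinder named per-gene scores from [normfinder_stability()].
#' @param genorm a [genorm_m()] result (its stepwise ranking is used).
#' @param bestkeeper a [bestkeeper_stats()] data frame.
#' @param delta_ct named per-gene scores from [delta_ct_stability()].
#' @return a `stability_result` data frame: per-method scores and ranks,
#'   `comp_score` and `comp_rank`, ordered by `comp_rank`.
#' @export
comprehensive_rank <- function(normfinder, genorm, bestkeeper, delta_ct) {
  genes <- sort(names(normfinder))
  bk_sd <- setNames(bestkeeper$sd, bestkeeper$gene)
  if (!setequal(genes, names(genorm$M)) || !setequal(genes, bestkeeper$gene) ||
      !setequal(genes, names(delta_ct))) {
    stop_consistency("the four methods must be computed on the same gene set")
  }
  rk <- cbind(
    normfinder = rank(normfinder[genes], ties.method = "min"),
    genorm = genorm$rank[genes],
    bestkeeper = rank(bk_sd[genes], ties.method = "min"),
    delta_ct = rank(delta_ct[genes], ties.method = "min")
  )
  comp <- apply(rk, 1L, geometric_mean)
  out <- data.frame(
    gene = genes,
    normfinder = unname(normfinder[genes]),
    genorm_m = unname(genorm$M[genes]),
    bestkeeper_sd = unname(bk_sd[genes]),
    bestkeeper_cv = setNames(bestkeeper$cv_pct, bestkeeper$gene)[genes],
    bestkeeper_r = setNames(bestkeeper$r_index, bestkeeper$gene)[genes],
    delta_ct = unname(delta_ct[genes]),
    rank_normfinder = rk[, "normfinder"],
    rank_genorm = rk[, "genorm"],
    rank_bestkeeper = rk[, "bestkeeper"],
    rank_delta_ct = rk[, "delta_ct"],
    comp_score = comp,
    row.names = NULL
  )
  out$comp_rank <- order(order(out$comp_score, out$gene))
  out <- out[order(out$comp_rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("stability_result", "data.frame")
  out
}

#' Run all four stability estimators and the comprehensive ranking
#'
#' Convenience wrapper around [normfinder_stability()], [genorm_m()],
#' [bestkeeper_stats()], [delta_ct_stability()] and [comprehensive_rank()].
#' BestKeeper needs raw Cq dispersion, so the input must be Cq-scale.
#'
#' @param m `cq_matrix` or plain numeric Cq matrix (targets x samples).
#' @param groups optional per-sample labels for NormFinder's grouped mode.
#' @param dispersion BestKeeper dispersion statistic, see [bestkeeper_stats()].
#' @return a `stability_result` data frame, see [comprehensive_rank()].
#' @export
stability_analysis <- function(m, groups = NULL, dispersion = c("sd", "mad")) {
  comprehensive_rank(
    normfinder = normfinder_stability(m, groups = groups),
    genorm = genorm_m(m),
    bestkeeper = bestkeeper_stats(m, dispersion = dispersion),
    delta_ct = delta_ct_stability(m)
  )
}

#' Top-k agreement between the four stability rankings
#'
#' Extracts each method's k most stable genes (rank order, gene-name
#' tie-break) and tabulates every Venn region over the four sets: how many
#' genes fall in each membership pattern. The region counts partition the
#' union of the four sets.
#'
#' @param result a `stability_result` from [stability_analysis()] /
#'   [comprehensive_rank()].
#' @param k set size (default 5); must be between 1 and the number of genes.
#' @return list with `sets` (named list of 4 character vectors), `venn`
#'   (data frame of membership pattern counts) and `four_way` (genes in all
#'   four top-k sets).
#' @export
top_k_overlap <- function(result, k = 5L) {
  stopifnot(inherits(result, "stability_result"))
  if (!is_count(k)) stop_parameter("k must be a positive integer")
  if (k > nrow(result)) stop_parameter("k exceeds the number of genes")
  methods <- c("normfinder", "genorm", "bestkeeper", "delta_ct")
  sets <- lapply(methods, function(mth) {
    r <- result[[paste0("rank_", mth)]]
    result$gene[order(r, result$gene)][seq_len(k)]
  })
  names(sets) <- methods
  union_genes <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) union_genes %in% s, logical(length(union_genes)))
  if (length(union_genes) == 1L) membership <- matrix(membership, nrow = 1L,
                                                      dimnames = list(NULL, methods))
  pattern <- apply(membership, 1L, function(b) paste(as.integer(b), collapse = ""))
  venn <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(venn) <- c("pattern", "count")
  list(sets = sets, venn = venn,
       four_way = union_genes[rowSums(membership) == 4L])
}
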