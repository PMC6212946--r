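# Standard-curve efficiency analysis, multi-reference delta-delta-Ct
# relative quantification, and group-uniformity screening.

#' Amplification efficiency from a standard-curve slope
#'
#' For a serial dilution, the slope of Cq against log10(input amount)
#' determines the per-cycle amplification gain:
#' `E% = (10^(-1/slope) - 1) * 100`. Perfect doubling gives slope
#' `-1/log10(2) = -3.3219` and 100% efficiency; assays are conventionally
#' accepted in the 90-110% window.
#'
#' @param slope standard-curve slope in Cq per log10 dilution; must be < 0.
#' @return list with `raw` (exact efficiency, %) and `reported` (rounded to
#'   the nearest integer, the conventional reporting precision).
#' @export
efficiency_from_slope <- function(slope) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) || slope >= 0) {
    stop_parameter("slope must be a finite negative number")
  }
  raw <- (10^(-1 / slope) - 1) * 100
  list(raw = raw, reported = round(raw))
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of mean Cq on log10(dilution factor) over a serial
#' dilution series, yielding the slope, intercept, R-squared and the
#' amplification efficiency via [efficiency_from_slope()].
#'
#' @param dilution positive dilution factors (1 = undiluted), or a data
#'   frame with columns `dilution` and `cq`.
#' @param cq mean Cq at each dilution (ignored when a data frame is given).
#' @return a `standard_curve` list: `slope`, `intercept`, `r2`,
#'   `efficiency_pct` (raw), `efficiency_reported` (integer), `n_points`.
#' @export
fit_standard_curve <- function(dilution, cq = NULL) {
  if (is.data.frame(dilution)) {
    cq <- dilution$cq
    dilution <- dilution$dilution
  }
  if (!is.numeric(dilution) || !is.numeric(cq) || length(dilution) != length(cq)) {
    stop_parameter("dilution and cq must be numeric vectors of equal length")
  }
  if (any(!is.finite(dilution)) || any(dilution <= 0)) {
    stop_parameter("dilution factors must be positive")
  }
  if (length(unique(dilution)) < 3L) {
    stop_insufficient("a standard curve needs >= 3 distinct dilution levels")
  }
  fit <- lm(cq ~ log10(dilution))
  slope <- unname(coef(fit)[2L])
  eff <- efficiency_from_slope(slope)
  sst <- sum((cq - mean(cq))^2)
  structure(list(
    slope = slope,
    intercept = unname(coef(fit)[1L]),
    # direct SSE/SST form: summary.lm warns on noiseless (exact) series
    r2 = 1 - sum(stats::residuals(fit)^2) / sst,
    efficiency_pct = eff$raw,
    efficiency_reported = eff$reported,
    n_points = length(cq)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> slope %.4f, R2 %.4f, efficiency %.1f%% (reported %d%%), n = %d\n",
              x$slope, x$r2, x$efficiency_pct, x$efficiency_reported, x$n_points))
  invisible(x)
}

#' Multi-reference delta-delta-Ct relative quantification
#'
#' Normalizes each target against the arithmetic mean Cq of the reference
#' genes (the geometric mean of their linear expression — the standard
#' multi-reference convention): per sample, `dCq = Cq_target - mean(Cq_refs)`.
#' For each target and each non-calibrator group,
#' `ddCq = mean dCq(group) - mean dCq(calibrator)`, the relative quantity is
#' `RQ = 2^(-ddCq)` under the efficiency-2 model, and `log2FC = -ddCq`.
#' Group differences in dCq are tested with a 2-tailed Student's t-test
#' (equal variance by default; `var_equal = FALSE` for Welch). Per-sample
#' relative expression `2^-(dCq - mean dCq(calibrator))` is returned for
#' plotting.
#'
#' @param m a `cq_matrix` from [collapse_replicates()].
#' @param targets target gene ids.
#' @param refs reference gene ids; must be measured in every sample.
#' @param calibrator_group group label serving as calibrator (e.g. the
#'   healthy controls).
#' @param var_equal use the classical equal-variance t-test (default `TRUE`).
#' @return a `rel_quant_result` list: `summary` (one row per target x test
#'   group: `ddcq`, `rq`, `log2fc`, `p_value`, group mean dCq) and
#'   `per_sample` (per target and sample: `dcq`, `rel_expr`, `group`).
#' @export
relative_quantification <- function(m, targets, refs, calibrator_group,
                                    var_equal = TRUE) {
  stopifnot(inherits(m, "cq_matrix"))
  x <- m$cq
  groups <- m$groups[colnames(x)]
  if (length(refs) == 0L) stop_parameter("refs must be non-empty")
  missing_genes <- setdiff(c(targets, refs), rownames(x))
  if (length(missing_genes) > 0L) {
    stop_consistency(sprintf("gene(s) not in the Cq matrix: %s",
                             paste(missing_genes, collapse = ", ")))
  }
  if (anyNA(x[refs, , drop = FALSE])) {
    stop_consistency("every reference must be measured in every sample")
  }
  if (!calibrator_group %in% groups) {
    stop_parameter(sprintf("calibrator group '%s' not present", calibrator_group))
  }
  ref_agg <- colMeans(x[refs, , drop = FALSE])
  cal <- which(groups == calibrator_group)
  test_groups <- setdiff(unique(groups), calibrator_group)

  per_sample <- do.call(rbind, lapply(targets, function(tg) {
    dcq <- x[tg, ] - ref_agg
    data.frame(target = tg, sample_id = colnames(x), group = unname(groups),
               dcq = unname(dcq),
               rel_expr = 2^-(unname(dcq) - mean(dcq[cal], na.rm = TRUE)),
               row.names = NULL)
  }))

  summary_df <- do.call(rbind, lapply(targets, function(tg) {
    dcq <- x[tg, ] - ref_agg
    dcq_cal <- dcq[cal]
    do.call(rbind, lapply(test_groups, function(tgroup) {
      dcq_test <- dcq[groups == tgroup]
      ddcq <- mean(dcq_test, na.rm = TRUE) - mean(dcq_cal, na.rm = TRUE)
      p <- NA_real_
      if (length(dcq_test) < 2L || length(dcq_cal) < 2L) {
        warning(sprintf("group with < 2 samples: t-test skipped for %s vs %s",
                        tg, tgroup), call. = FALSE)
      } else if (sd(dcq_test) == 0 && sd(dcq_cal) == 0) {
        p <- 1  # both groups constant: no evidence of a difference
      } else {
        p <- t.test(dcq_test, dcq_cal, var.equal = var_equal)$p.value
      }
      data.frame(target = tg, group = tgroup,
                 calibrator = calibrator_group,
                 mean_dcq_test = mean(dcq_test, na.rm = TRUE),
                 mean_dcq_calibrator = mean(dcq_cal, na.rm = TRUE),
                 ddcq = ddcq, rq = 2^-ddcq, log2fc = -ddcq, p_value = p,
                 row.names = NULL)
    }))
  }))
  structure(list(summary = summary_df, per_sample = per_sample),
            class = "rel_quant_result")
}

#' @export
print.rel_quant_result <- function(x, ...) {
  cat("<rel_quant_result>\n")
  print(x$summary)
  invisible(x)
}

#' Group-uniformity screen of candidate normalizers
#'
#' A good normalizer shows no systematic Cq difference between biological
#' groups (material types). Per gene, mean Cq values are compared across
#' groups with a one-way ANOVA; p-values are adjusted across genes by
#' Benjamini-Hochberg. Genes with zero variance everywhere (F undefined) are
#' reported with p = 1 and flagged `degenerate`.
#'
#' @param m a `cq_matrix`.
#' @param groups optional per-sample labels (defaults to the matrix's own).
#' @return data frame: per gene, `mean_<group>` / `sd_<group>` columns,
#'   `p_value`, `p_adj`, `degenerate`.
#' @export
group_uniformity_test <- function(m, groups = NULL) {
  stopifnot(inherits(m, "cq_matrix"))
  x <- m$cq
  if (is.null(groups)) groups <- m$groups[colnames(x)]
  groups <- as.character(groups)
  sizes <- table(groups)
  if (sum(sizes >= 2L) < 2L) {
    stop_insufficient("need >= 2 groups with >= 2 samples each")
  }
  grp_levels <- names(sizes)
  rows <- lapply(rownames(x), function(g) {
    v <- x[g, ]
    ok <- !is.na(v)
    means <- vapply(grp_levels, function(l) mean(v[ok & groups == l]), 0)
    sds <- vapply(grp_levels, function(l) sd1(v[ok & groups == l]), 0)
    if (var(v[ok]) < 1e-20) {
      # no variance anywhere: F is 0/0; report p = 1 by convention and flag
      p <- 1
      degenerate <- TRUE
    } else {
      fit <- anova(lm(v[ok] ~ factor(groups[ok])))
      p <- fit[["Pr(>F)"]][1L]
      degenerate <- is.na(p)
      if (degenerate) p <- 1
    }
    out <- data.frame(gene = g, p_value = p, degenerate = degenerate,
                      row.names = NULL)
    for (l in grp_levels) {
      out[[paste0("mean_", l)]] <- means[[l]]
      out[[paste0("sd_", l)]] <- sds[[l]]
    }
    out
  })
  res <- do.call(rbind, rows)
  res$p_adj <- p.adjust(res$p_value, method = "BH")
  front <- c("gene", grep("^(mean|sd)_", names(res), value = TRUE),
             "p_value", "p_adj", "degenerate")
  res[, front]
}
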