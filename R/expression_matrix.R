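#' Gene-by-sample expression matrix
#'
#' Container for miRNA-seq-like abundance data: a genes x samples matrix of
#' non-negative counts (`scale = "counts"`) or real log2 signals
#' (`scale = "log2"`), with an optional per-sample group label. On the counts
#' scale a per-gene mean read count (row mean) is carried along, the usual
#' abundance summary when short-listing candidate normalizers.
#'
#' @param values numeric matrix with unique rownames (gene ids) and colnames
#'   (sample ids).
#' @param scale `"counts"` or `"log2"`.
#' @param groups optional character vector of per-sample labels, length
#'   `ncol(values)` (or named by sample id).
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(values, scale = c("counts", "log2"), groups = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_validation("values must be a numeric matrix")
  }
  # R may drop rownames entirely on empty subsets; only non-empty matrices
  # must carry unique gene ids.
  if (nrow(values) > 0L &&
      (is.null(rownames(values)) || anyDuplicated(rownames(values)))) {
    stop_validation("gene ids (rownames) must be present and unique")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  if (scale == "counts" && any(values < 0, na.rm = TRUE)) {
    stop_validation("counts-scale matrix must be non-negative")
  }
  if (!is.null(groups)) {
    if (length(groups) != ncol(values)) {
      stop_validation("groups must have one label per sample")
    }
    groups <- setNames(as.character(groups), colnames(values))
  }
  structure(
    list(values = values, scale = scale, groups = groups,
         mean_read_count = if (scale == "counts") rowMeans(values) else NULL),
    class = "expression_matrix"
  )
}

#' Read an expression matrix from a delimited file
#'
#' Gene ids in the first column, sample ids in the header; delimiter
#' auto-detected (tab vs comma).
#'
#' @param path file path.
#' @param scale `"counts"` or `"log2"`.
#' @param groups optional per-sample group labels.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale = c("counts", "log2"), groups = NULL) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = delim, header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  if (!is.numeric(m)) stop_validation("matrix body must be numeric")
  expression_matrix(m, scale = match.arg(scale), groups = groups)
}

#' Filter to expressed genes by counts-per-million
#'
#' Keeps genes with CPM >= `min_cpm` in at least `min_fraction` of samples.
#' Sequencing depth varies between libraries, so the threshold is applied on
#' the depth-normalized CPM scale rather than raw counts. The operation is
#' idempotent and leaves the sample set unchanged.
#'
#' @param m counts-scale [expression_matrix()].
#' @param min_cpm minimum counts-per-million (default 1).
#' @param min_fraction minimum fraction of samples at or above `min_cpm`
#'   (default 0.5).
#' @return filtered [expression_matrix()].
#' @export
filter_expressed <- function(m, min_cpm = 1, min_fraction = 0.5) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "counts") stop_scale("filter_expressed requires a counts-scale matrix")
  if (!is.numeric(min_cpm) || min_cpm < 0) stop_parameter("min_cpm must be >= 0")
  if (!is.numeric(min_fraction) || min_fraction < 0 || min_fraction > 1) {
    stop_parameter("min_fraction must be in [0, 1]")
  }
  cpm <- cpm_matrix(m$values)
  keep <- rowMeans(cpm >= min_cpm) >= min_fraction
  expression_matrix(m$values[keep, , drop = FALSE], scale = "counts",
                    groups = m$groups)
}

# CPM with zero-depth libraries mapped to all-zero columns.
cpm_matrix <- function(counts) {
  depth <- colSums(counts)
  depth[depth == 0] <- 1
  sweep(counts, 2L, depth, "/") * 1e6
}

#' Log2-CPM transform
#'
#' Converts a counts matrix to `log2(CPM + pseudocount)` signals, the scale
#' on which the NormFinder-style model and the iterative selection operate
#' (Cq data are already log2-scale and need no transform).
#'
#' @param m counts-scale [expression_matrix()].
#' @param pseudocount added before the log (default 1); must be > 0.
#' @return log2-scale [expression_matrix()] with identical gene/sample order.
#' @export
to_log2 <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "counts") stop_scale("to_log2 requires a counts-scale matrix")
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop_parameter("pseudocount must be > 0")
  }
  expression_matrix(log2(cpm_matrix(m$values) + pseudocount), scale = "log2",
                    groups = m$groups)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d gene(s) x %d sample(s), scale = %s%s\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (is.null(x$groups)) "" else
                sprintf(", %d group(s)", length(unique(x$groups)))))
  invisible(x)
}
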