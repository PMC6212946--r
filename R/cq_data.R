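#' Replicate-level quantification-cycle (Cq) table
#'
#' A `cq_table` is a tidy data frame of raw RT-qPCR readings, one row per
#' technical replicate, with columns `sample_id`, `group`, `target_id`,
#' `replicate` and `cq`. Cq (equivalent to Ct) is the PCR cycle at which
#' fluorescence crosses the detection threshold; lower Cq means higher
#' abundance. Cq values must be finite and positive and the
#' (sample, target, replicate) triple must be unique.
#'
#' Rows whose `cq` is `NA` (target undetected in that well) are dropped with
#' a warning; downstream stability estimators subset to samples measured for
#' every target.
#'
#' @param df data frame with the five columns above (any order, extra
#'   columns are kept).
#' @return `df` validated, classed `cq_table`.
#' @seealso [read_cq_table()], [collapse_replicates()]
#' @export
cq_table <- function(df) {
  required <- c("sample_id", "group", "target_id", "replicate", "cq")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_format(sprintf("missing required column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  df$target_id <- as.character(df$target_id)

  undetected <- is.na(df$cq) & !is.nan(df$cq)
  if (any(undetected)) {
    warning(sprintf("dropping %d row(s) with missing Cq (target undetected)",
                    sum(undetected)), call. = FALSE)
    df <- df[!undetected, , drop = FALSE]
  }
  if (!is.numeric(df$cq)) stop_validation("column 'cq' must be numeric")
  bad <- which(!is.finite(df$cq) | df$cq <= 0)
  if (length(bad) > 0L) {
    stop_validation(sprintf("non-finite or non-positive Cq at row %d", bad[1L]))
  }
  rep_bad <- which(!is.finite(df$replicate) | df$replicate < 1 |
                     df$replicate != round(df$replicate))
  if (length(rep_bad) > 0L) {
    stop_validation(sprintf("replicate must be a positive integer (row %d)", rep_bad[1L]))
  }
  key <- paste(df$sample_id, df$target_id, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop_validation(sprintf("duplicate (sample_id, target_id, replicate) at row %d",
                            which(duplicated(key))[1L]))
  }
  grp <- unique(df[, c("sample_id", "group")])
  if (anyDuplicated(grp$sample_id)) {
    stop_validation("a sample_id is assigned to more than one group")
  }
  rownames(df) <- NULL
  class(df) <- unique(c("cq_table", class(df)))
  df
}

#' Read a Cq table from a delimited file
#'
#' Expects a header naming (case-insensitively) the columns `sample_id`,
#' `group`, `target_id`, `replicate` and `cq`. The delimiter is auto-detected
#' (tab vs comma) from the header line unless forced. Literal `NaN` or other
#' non-numeric Cq entries are a validation error; empty/`NA` cells are
#' treated as undetected and dropped with a warning.
#'
#' @param path path to a TSV/CSV file.
#' @param delim `NULL` (auto), `"\t"` or `","`.
#' @param col_map optional named character vector mapping the required names
#'   to the file's column names, e.g. `c(cq = "Ct")`.
#' @return a [cq_table()]. File row order is preserved.
#' @export
read_cq_table <- function(path, delim = NULL, col_map = NULL) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  if (is.null(delim)) delim <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
                   colClasses = "character", na.strings = c("", "NA"))
  nm <- tolower(names(df))
  if (!is.null(col_map)) {
    for (std in names(col_map)) nm[nm == tolower(col_map[[std]])] <- std
  }
  names(df) <- nm
  required <- c("sample_id", "group", "target_id", "replicate", "cq")
  missing_cols <- setdiff(required, nm)
  if (length(missing_cols) > 0L) {
    stop_format(sprintf("missing required column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  cq_num <- suppressWarnings(as.numeric(df$cq))
  bad <- which(!is.na(df$cq) & (is.na(cq_num) | is.nan(cq_num)))
  if (length(bad) > 0L) {
    stop_validation(sprintf("invalid Cq value '%s' at row %d", df$cq[bad[1L]], bad[1L]))
  }
  df$cq <- cq_num
  rep_num <- suppressWarnings(as.numeric(df$replicate))
  if (anyNA(rep_num)) {
    stop_validation(sprintf("invalid replicate index at row %d", which(is.na(rep_num))[1L]))
  }
  df$replicate <- rep_num
  cq_table(df)
}

#' Collapse technical replicates into a Cq matrix
#'
#' Replicates are summarised per (target, sample) cell by the arithmetic mean
#' of Cq — on the linear expression scale this is the geometric mean, the
#' standard convention for log-domain qPCR data. The replicate sample
#' standard deviation (n-1 denominator, 0 for a single replicate) is kept per
#' cell and cells with SD above `sd_threshold` are flagged as
#' high-variance wells for QC.
#'
#' @param t a [cq_table()].
#' @param sd_threshold replicate-SD flag threshold in Cq units (default 0.5).
#' @return a `cq_matrix`: list with `cq` (targets x samples mean-Cq matrix),
#'   `sd` (replicate SD matrix), `flag` (logical matrix, SD > threshold),
#'   `groups` (named character vector per sample) and `sd_threshold`.
#' @export
collapse_replicates <- function(t, sd_threshold = 0.5) {
  if (!inherits(t, "cq_table")) t <- cq_table(t)
  if (nrow(t) == 0L) stop_insufficient("empty Cq table")
  if (!is.numeric(sd_threshold) || sd_threshold <= 0) {
    stop_parameter("sd_threshold must be > 0")
  }
  targets <- unique(t$target_id)
  samples <- unique(t$sample_id)
  mean_m <- matrix(NA_real_, length(targets), length(samples),
                   dimnames = list(targets, samples))
  sd_m <- mean_m
  cell <- split(t$cq, list(factor(t$target_id, targets),
                           factor(t$sample_id, samples)), sep = "\r")
  for (key in names(cell)) {
    v <- cell[[key]]
    if (length(v) == 0L) next
    idx <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    mean_m[idx[1L], idx[2L]] <- mean(v)
    sd_m[idx[1L], idx[2L]] <- sd1(v)
  }
  groups <- setNames(t$group[match(samples, t$sample_id)], samples)
  structure(
    list(cq = mean_m, sd = sd_m, flag = !is.na(sd_m) & sd_m > sd_threshold,
         groups = groups, sd_threshold = sd_threshold),
    class = "cq_matrix"
  )
}

#' Subset a Cq matrix by targets and/or samples
#'
#' @param x a `cq_matrix`.
#' @param i target selector (names, indices or logical).
#' @param j sample selector.
#' @param ... ignored.
#' @return the subsetted `cq_matrix`.
#' @export
`[.cq_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$cq))
  if (missing(j)) j <- seq_len(ncol(x$cq))
  structure(
    list(cq = x$cq[i, j, drop = FALSE], sd = x$sd[i, j, drop = FALSE],
         flag = x$flag[i, j, drop = FALSE],
         groups = x$groups[colnames(x$cq[i, j, drop = FALSE])],
         sd_threshold = x$sd_threshold),
    class = "cq_matrix"
  )
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat(sprintf("<cq_matrix> %d target(s) x %d sample(s), %d group(s); %d high-variance cell(s) (SD > %.2f)\n",
              nrow(x$cq), ncol(x$cq), length(unique(x$groups)),
              sum(x$flag, na.rm = TRUE), x$sd_threshold))
  invisible(x)
}
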