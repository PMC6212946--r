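#' Iterative greedy selection of a reference-gene set
#'
#' Builds nested candidate normalizer sets of increasing size. Iteration 1
#' scores every gene with [normfinder_stability()] and seeds the set with the
#' most stable gene. At each subsequent iteration, every remaining gene is
#' tentatively merged into the current set: the pseudo-gene profile is the
#' per-sample mean of the set's log2 signals (geometric mean of linear
#' expression), and its stability is scored within a background matrix of all
#' genes outside the tentative set plus the pseudo-gene — the combination is
#' never scored against its own members. The candidate whose pseudo-gene
#' scores lowest joins the set. The per-iteration minimum score traces how
#' much stability each additional gene buys; the mean over candidates traces
#' the background. Deterministic: ties break by gene id order.
#'
#' @param m log2-scale [expression_matrix()], `cq_matrix`, or plain numeric
#'   matrix of log2 signals (genes x samples).
#' @param max_k largest set size to build (default 100, the practical upper
#'   bound far beyond any RT-qPCR panel). The run also stops when fewer than
#'   3 genes would remain in the background matrix.
#' @param average_scale `"log2"` (default: arithmetic mean of log2 signals =
#'   geometric mean of expression) or `"linear"` (arithmetic mean of linear
#'   expression, log2-transformed back).
#' @param retain_members if `TRUE`, the pseudo-gene's member genes stay in
#'   the background matrix instead of being removed (default `FALSE`).
#' @return an `iteration_trace` data frame with columns `k`, `added`,
#'   `set` (comma-joined ids), `min_score`, `mean_score`; the selected gene
#'   sets are in `attr(, "sets")`.
#' @export
iterative_selection <- function(m, max_k = 100L, average_scale = c("log2", "linear"),
                                retain_members = FALSE) {
  average_scale <- match.arg(average_scale)
  if (!is_count(max_k)) stop_parameter("max_k must be a positive integer")
  inp <- stability_input(m, "log", "iterative_selection")
  x <- inp$x
  if (nrow(x) < 4L || ncol(x) < 3L) {
    stop_insufficient("iterative_selection needs >= 4 genes and >= 3 samples")
  }
  genes <- rownames(x)

  combine <- function(rows) {
    if (average_scale == "log2") colMeans(rows) else log2(colMeans(2^rows))
  }

  scores1 <- normfinder_stability(x)
  first <- genes[order(scores1, genes)][1L]
  selected <- first
  trace <- data.frame(k = 1L, added = first,
                      set = first,
                      min_score = min(scores1), mean_score = mean(scores1),
                      stringsAsFactors = FALSE)
  sets <- list(selected)

  while (length(selected) < max_k) {
    candidates <- setdiff(genes, selected)
    if (length(candidates) == 0L) break
    cand_scores <- rep(NA_real_, length(candidates))
    names(cand_scores) <- candidates
    for (cand in candidates) {
      members <- c(selected, cand)
      pseudo <- combine(x[members, , drop = FALSE])
      background <- if (retain_members) genes else setdiff(genes, members)
      bg <- rbind(x[background, , drop = FALSE], `.pseudo` = pseudo)
      if (nrow(bg) < 3L) {
        cand_scores <- cand_scores[0L]
        break
      }
      cand_scores[[cand]] <- normfinder_stability(bg)[[".pseudo"]]
    }
    if (length(cand_scores) == 0L) break
    best <- candidates[order(cand_scores, candidates)][1L]
    selected <- c(selected, best)
    trace <- rbind(trace, data.frame(
      k = length(selected), added = best,
      set = paste(selected, collapse = ","),
      min_score = min(cand_scores), mean_score = mean(cand_scores),
      stringsAsFactors = FALSE
    ))
    sets <- c(sets, list(selected))
  }
  rownames(trace) <- NULL
  attr(trace, "sets") <- sets
  class(trace) <- c("iteration_trace", "data.frame")
  trace
}

#' Suggest how many reference genes to combine
#'
#' Scans the iteration trace for the point of diminishing returns: the
#' smallest set size k whose relative improvement of the minimum stability
#' score, `(min_k - min_{k+1}) / min_k`, falls below `rel_gain_threshold`.
#' Negative or undefined gains (non-monotone or zero scores) are clamped to
#' 0. Returns the last k if the threshold is never met. Advisory only: the
#' full trace should be inspected alongside.
#'
#' @param trace an `iteration_trace` from [iterative_selection()].
#' @param rel_gain_threshold relative-gain cutoff (default 0.05).
#' @return integer set size.
#' @export
suggest_set_size <- function(trace, rel_gain_threshold = 0.05) {
  stopifnot(inherits(trace, "iteration_trace"))
  n <- nrow(trace)
  if (n < 2L) stop_insufficient("trace needs >= 2 iterations")
  mins <- trace$min_score
  gains <- (mins[-n] - mins[-1L]) / mins[-n]
  gains[!is.finite(gains) | gains < 0] <- 0
  hit <- which(gains < rel_gain_threshold)
  if (length(hit) > 0L) trace$k[hit[1L]] else trace$k[n]
}
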