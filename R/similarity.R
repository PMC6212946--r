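# Sequence-similarity screen for cross-hybridization risk among mature
# miRNAs. Probe-based RT-qPCR assays can bind near-identical family members
# (isomiRs and paralogues), inflating fold changes; high global identity,
# shared seeds and correlated expression flag pairs at risk.

valid_rna <- function(seq) grepl("^[ACGU]+$", seq)

# Normalize a sequence to the RNA alphabet, converting DNA T -> U.
normalize_rna <- function(seq, id = "sequence") {
  seq <- toupper(seq)
  if (grepl("T", seq, fixed = TRUE)) {
    warning(sprintf("%s: DNA alphabet detected, converting T -> U", id),
            call. = FALSE)
    seq <- gsub("T", "U", seq, fixed = TRUE)
  }
  if (!nzchar(seq)) stop_parameter(sprintf("%s: empty sequence", id))
  if (!valid_rna(seq)) {
    stop_validation(sprintf("%s: invalid character(s); alphabet is ACGU", id))
  }
  seq
}

#' Read mature miRNA sequences from a FASTA file
#'
#' Sequences are validated against the RNA alphabet (ACGU); DNA-alphabet
#' records are converted T to U with a warning. The seed — nucleotides at
#' positions 2-7 of the mature sequence, the principal determinant of target
#' recognition — is extracted for sequences of length >= 7.
#'
#' @param path FASTA file of mature miRNA sequences.
#' @return data frame with columns `id`, `seq`, `seed`.
#' @export
read_mirna_fasta <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  seqs <- vapply(seq_along(set), function(i) {
    normalize_rna(as.character(set[[i]]), ids[i])
  }, "")
  if (anyDuplicated(ids)) stop_validation("duplicate sequence ids in FASTA")
  data.frame(id = ids, seq = seqs,
             seed = ifelse(nchar(seqs) >= 7L, substr(seqs, 2L, 7L), NA_character_),
             row.names = NULL)
}

#' Needleman-Wunsch global alignment of two short sequences
#'
#' Optimal global alignment under linear gap penalties, with deterministic
#' traceback (tie order: diagonal, then up, then left). Percent identity is
#' `100 * matches / alignment columns` (gap columns included), which is
#' robust to the choice of scoring parameters and is the headline statistic
#' of the screen.
#'
#' @param a,b RNA sequences (character scalars; DNA converted with warning).
#' @param match,mismatch,gap integer scoring parameters
#'   (defaults +1 / -1 / -2).
#' @return list: `score`, `identity_pct`, `matches`, `columns`, and the two
#'   aligned strings `aligned_a`, `aligned_b`.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- normalize_rna(a, "a")
  b <- normalize_rna(b, "b")
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av)
  m <- length(bv)
  s <- matrix(0, n + 1L, m + 1L)
  s[, 1L] <- gap * 0:n
  s[1L, ] <- gap * 0:m
  for (i in seq_len(n)) {
    sub <- ifelse(av[i] == bv, match, mismatch)
    for (j in seq_len(m)) {
      s[i + 1L, j + 1L] <- max(s[i, j] + sub[j], s[i, j + 1L] + gap, s[i + 1L, j] + gap)
    }
  }
  # Traceback, preferring diagonal over up over left on ties.
  ra <- character(0)
  rb <- character(0)
  i <- n
  j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        s[i + 1L, j + 1L] == s[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && s[i + 1L, j + 1L] == s[i, j + 1L] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1L
    }
  }
  matches <- sum(ra == rb)
  list(score = s[n + 1L, m + 1L],
       identity_pct = 100 * matches / length(ra),
       matches = matches, columns = length(ra),
       aligned_a = paste(ra, collapse = ""), aligned_b = paste(rb, collapse = ""))
}

#' Seed identity of two mature miRNAs
#'
#' `TRUE` iff nucleotides at positions 2-7 (1-based, inclusive) of the two
#' mature sequences are identical. Only perfect seed matches are reported;
#' both sequences must be at least 7 nt.
#'
#' @inheritParams global_align
#' @return logical scalar.
#' @export
seed_identical <- function(a, b) {
  a <- normalize_rna(a, "a")
  b <- normalize_rna(b, "b")
  if (nchar(a) < 7L || nchar(b) < 7L) {
    stop_validation("seed comparison requires sequences of length >= 7")
  }
  substr(a, 2L, 7L) == substr(b, 2L, 7L)
}

#' Pairwise expression correlation
#'
#' Pearson correlation across samples of log2 signals for the requested gene
#' pairs. Zero-variance genes yield `NA` with a warning.
#'
#' @param m log2-scale [expression_matrix()] or plain matrix of log2 signals.
#' @param pairs two-column matrix or data frame of gene id pairs.
#' @return data frame `id1`, `id2`, `r`.
#' @export
expression_correlation <- function(m, pairs) {
  inp <- stability_input(m, "log", "expression_correlation")
  x <- inp$x
  if (ncol(x) < 3L) stop_insufficient("expression_correlation needs >= 3 samples")
  pairs <- as.matrix(pairs)
  missing_genes <- setdiff(unique(as.vector(pairs)), rownames(x))
  if (length(missing_genes) > 0L) {
    stop_consistency(sprintf("gene(s) not in matrix: %s",
                             paste(missing_genes, collapse = ", ")))
  }
  r <- apply(pairs, 1L, function(p) {
    v1 <- x[p[1L], ]
    v2 <- x[p[2L], ]
    if (sd(v1) == 0 || sd(v2) == 0) {
      warning(sprintf("zero-variance gene in pair (%s, %s): r undefined",
                      p[1L], p[2L]), call. = FALSE)
      return(NA_real_)
    }
    cor(v1, v2)
  })
  data.frame(id1 = pairs[, 1L], id2 = pairs[, 2L], r = r, row.names = NULL)
}

#' All-pairs miRNA similarity screen
#'
#' Runs [global_align()] and [seed_identical()] over every sequence pair and,
#' when an expression matrix is supplied, adds the pairwise Pearson
#' correlation of log2 expression for pairs present in the matrix.
#'
#' @param sequences data frame from [read_mirna_fasta()] (columns `id`,
#'   `seq`).
#' @param expr optional log2-scale [expression_matrix()].
#' @param match,mismatch,gap scoring parameters, see [global_align()].
#' @return data frame of `similarity_record`s: `id1`, `id2`, `score`,
#'   `identity_pct`, `seed_identical`, `expr_r`.
#' @export
similarity_screen <- function(sequences, expr = NULL,
                              match = 1, mismatch = -1, gap = -2) {
  if (nrow(sequences) < 2L) stop_insufficient("need >= 2 sequences")
  idx <- utils::combn(nrow(sequences), 2L)
  rows <- lapply(seq_len(ncol(idx)), function(c) {
    i <- idx[1L, c]
    j <- idx[2L, c]
    al <- global_align(sequences$seq[i], sequences$seq[j], match, mismatch, gap)
    data.frame(id1 = sequences$id[i], id2 = sequences$id[j],
               score = al$score, identity_pct = al$identity_pct,
               seed_identical = seed_identical(sequences$seq[i], sequences$seq[j]),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$expr_r <- NA_real_
  if (!is.null(expr)) {
    x <- stability_input(expr, "log", "similarity_screen")$x
    have <- out$id1 %in% rownames(x) & out$id2 %in% rownames(x)
    if (any(have)) {
      out$expr_r[have] <- expression_correlation(
        expr, cbind(out$id1[have], out$id2[have]))$r
    }
  }
  out
}
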