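# Shared fixtures, built in code.

# The 3x3 worked matrix: A and B track the per-sample trend exactly, C
# deviates in samples 2 and 3.
worked_matrix <- function() {
  rbind(A = c(20, 21, 22), B = c(20, 21, 22), C = c(20, 22, 21))
}

random_log2_matrix <- function(n_genes, n_samples, seed) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, mean = 22, sd = 1.5),
                n_genes, n_samples)
    dimnames(m) <- list(sprintf("g%02d", seq_len(n_genes)),
                        sprintf("s%02d", seq_len(n_samples)))
    m
  })
}

# Build a cq_matrix directly from a mean-Cq matrix (no replicate structure).
make_cq_matrix <- function(x, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", ncol(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  structure(
    list(cq = x, sd = x * 0, flag = x > Inf,
         groups = setNames(as.character(groups), colnames(x)),
         sd_threshold = 0.5),
    class = "cq_matrix"
  )
}

# Tidy replicate-level table from a named list sample -> target -> cq vector.
make_cq_table <- function(mat, groups, n_rep = 1L, rep_noise = 0) {
  rows <- list()
  for (s in seq_len(ncol(mat))) {
    for (g in seq_len(nrow(mat))) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = colnames(mat)[s], group = groups[s],
        target_id = rownames(mat)[g], replicate = seq_len(n_rep),
        cq = mat[g, s] + rep(0, n_rep)
      )
    }
  }
  cq_table(do.call(rbind, rows))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
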