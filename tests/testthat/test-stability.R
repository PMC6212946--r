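test_that("worked 3x3 matrix reproduces hand-computed scores", {
  x <- worked_matrix()
  nf <- normfinder_stability(x)
  expect_equal(unname(nf), c(1 / 3, 1 / 3, 2 / 3), tolerance = 1e-9)
  expect_equal(nf, oracle_normfinder(x), tolerance = 1e-12)

  gm <- genorm_m(x)
  expect_equal(unname(gm$M), c(0.5, 0.5, 1.0), tolerance = 1e-9)

  dct <- delta_ct_stability(x)
  expect_equal(unname(dct), c(0.5, 0.5, 1.0), tolerance = 1e-9)

  # regression: on the full panel geNorm M and delta-Ct coincide
  expect_equal(gm$M, dct, tolerance = 1e-12)

  # ranking: A and B before C in every method
  expect_equal(unname(gm$rank["C"]), 3L)
  expect_true(all(rank(nf, ties.method = "min")[c("A", "B")] == 1))
})

test_that("perfectly stable gene scores zero and sample shifts are absorbed", {
  x <- random_log2_matrix(5, 8, seed = 11)
  x["g01", ] <- colMeans(x[-1, ]) + 3  # tracks the sample effect exactly
  nf <- normfinder_stability(x)
  expect_lt(nf[["g01"]], 1e-10)

  shifted <- x
  shifted[, 3] <- shifted[, 3] + 5
  expect_equal(normfinder_stability(shifted), normfinder_stability(x),
               tolerance = 1e-12)
  expect_equal(genorm_m(shifted)$M, genorm_m(x)$M, tolerance = 1e-12)
  expect_equal(delta_ct_stability(shifted), delta_ct_stability(x),
               tolerance = 1e-12)
  # contrast: BestKeeper measures raw Cq dispersion and does change
  expect_false(isTRUE(all.equal(bestkeeper_stats(shifted)$sd,
                                bestkeeper_stats(x)$sd, tolerance = 1e-8)))
})

test_that("scores match brute-force oracles on random matrices", {
  for (seed in c(1, 2, 3, 4, 5)) {
    x <- random_log2_matrix(4, 6, seed = seed)
    expect_equal(normfinder_stability(x), oracle_normfinder(x), tolerance = 1e-9)
    expect_equal(genorm_m(x)$M, oracle_pairwise_sd_score(x), tolerance = 1e-9)
    expect_equal(delta_ct_stability(x), oracle_pairwise_sd_score(x),
                 tolerance = 1e-9)
    expect_equal(setNames(bestkeeper_stats(x)$sd, bestkeeper_stats(x)$gene),
                 oracle_bestkeeper_sd(x), tolerance = 1e-9)
  }
})

test_that("bestkeeper_stats computes SD, CV and index correlation", {
  x <- rbind(a = c(20, 21, 22), b = c(25, 25, 25))
  bk <- bestkeeper_stats(x)
  expect_equal(bk$sd, c(1, 0))
  expect_equal(bk$cv_pct[1], 100 / 21, tolerance = 1e-9)
  expect_equal(bk$rank, c(2L, 1L))  # constant gene is most "stable"

  # a single gene correlates perfectly with the index of itself
  solo <- bestkeeper_stats(rbind(a = c(20, 21, 22)))
  expect_equal(solo$r_index, 1)

  # mean-absolute-deviation option
  mad <- bestkeeper_stats(x, dispersion = "mad")
  expect_equal(mad$sd[1], mean(abs(c(20, 21, 22) - 21)))

  expect_error(bestkeeper_stats(rbind(a = 20)),
               class = "endoref_insufficient_data_error")
  expect_error(bestkeeper_stats(to_log2(expression_matrix(
    matrix(1:4, 2, dimnames = list(c("a", "b"), NULL))))),
    class = "endoref_scale_error")
})

test_that("normfinder grouped mode penalises intergroup deviation", {
  x <- random_log2_matrix(6, 12, seed = 3)
  groups <- rep(c("A", "B"), each = 6)
  # plant a gene with a clean group effect
  x["g02", ] <- mean(x["g02", ]) + c(rep(-1, 6), rep(1, 6))
  grouped <- normfinder_stability(x, groups = groups)
  ungrouped <- normfinder_stability(x)
  expect_gt(grouped[["g02"]] - ungrouped[["g02"]], 0.1)
  # genes without a group effect are scored similarly either way
  expect_equal(grouped[["g01"]], ungrouped[["g01"]], tolerance = 0.5)
  expect_error(normfinder_stability(x[1:2, ]),
               class = "endoref_insufficient_data_error")
})

test_that("comprehensive_rank is the geometric mean of the four ranks", {
  x <- random_log2_matrix(6, 8, seed = 21)
  res <- stability_analysis(make_cq_matrix(x))
  expect_s3_class(res, "stability_result")
  rk <- as.matrix(res[, c("rank_normfinder", "rank_genorm",
                          "rank_bestkeeper", "rank_delta_ct")])
  expect_equal(res$comp_score, apply(rk, 1, function(r) prod(r)^(1 / 4)),
               tolerance = 1e-12)
  # bounded by min and max of the per-method ranks
  expect_true(all(res$comp_score >= apply(rk, 1, min) - 1e-12))
  expect_true(all(res$comp_score <= apply(rk, 1, max) + 1e-12))
  # comp_rank is a strict permutation ordered by score
  expect_setequal(res$comp_rank, seq_len(nrow(res)))
  expect_true(!is.unsorted(res$comp_score))

  # hand example: ranks (1,2,4,8) -> 64^(1/4)
  expect_equal(prod(c(1, 2, 4, 8))^(1 / 4), 2.8284271, tolerance = 1e-6)

  # unanimous winner scores exactly 1
  winner <- res$gene[res$comp_rank == 1]
  if (all(rk[res$comp_rank == 1, ] == 1)) {
    expect_equal(res$comp_score[res$gene == winner], 1)
  }

  bad <- bestkeeper_stats(x[1:5, ])
  expect_error(
    comprehensive_rank(normfinder_stability(x), genorm_m(x), bad,
                       delta_ct_stability(x)),
    class = "endoref_consistency_error")
})

test_that("top_k_overlap returns the four sets and a partition of the union", {
  x <- random_log2_matrix(8, 10, seed = 5)
  res <- stability_analysis(make_cq_matrix(x))
  ov <- top_k_overlap(res, k = 5)
  expect_length(ov$sets, 4L)
  expect_true(all(lengths(ov$sets) == 5L))
  union_size <- length(unique(unlist(ov$sets)))
  expect_equal(sum(ov$venn$count), union_size)  # venn regions partition union

  # identical rankings across methods -> 4-way intersection of size k
  ident <- res
  for (col in c("rank_genorm", "rank_bestkeeper", "rank_delta_ct")) {
    ident[[col]] <- ident$rank_normfinder
  }
  ov2 <- top_k_overlap(ident, k = 4)
  expect_length(ov2$four_way, 4L)

  expect_error(top_k_overlap(res, k = 0), class = "endoref_parameter_error")
  expect_error(top_k_overlap(res, k = 99), class = "endoref_parameter_error")
})
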