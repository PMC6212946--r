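test_that("fit_standard_curve recovers exact and perturbed series", {
  # perfect doubling: Cq rises by 1/log10(2) per 10-fold dilution
  cq <- c(20, 23.32193, 26.64386)
  fit <- fit_standard_curve(c(1, 0.1, 0.01), cq)
  expect_equal(fit$slope, -3.32193, tolerance = 1e-5)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$efficiency_reported, 100)

  pert <- cq + c(0, 0.1, 0)
  fit2 <- fit_standard_curve(c(1, 0.1, 0.01), pert)
  expect_lt(fit2$r2, 1)
  expect_lt(abs(fit2$slope - fit$slope), 0.1)

  expect_error(fit_standard_curve(c(1, 0.1), c(20, 23)),
               class = "endoref_insufficient_data_error")
  expect_error(fit_standard_curve(c(1, -0.1, 0.01), cq),
               class = "endoref_parameter_error")
})

test_that("efficiency_from_slope implements E = 10^(-1/slope) - 1", {
  expect_equal(efficiency_from_slope(-1 / log10(2))$raw, 100, tolerance = 1e-9)
  # closed-form check at an arbitrary slope
  s <- -3.45
  expect_equal(efficiency_from_slope(s)$raw, (10^(-1 / s) - 1) * 100,
               tolerance = 1e-12)
  expect_equal(efficiency_from_slope(-3.33)$reported,
               round((10^(1 / 3.33) - 1) * 100))
  expect_error(efficiency_from_slope(0), class = "endoref_parameter_error")
  expect_error(efficiency_from_slope(2.5), class = "endoref_parameter_error")
})

test_that("relative_quantification follows the multi-reference ddCt model", {
  # targets t1, t2; refs r1..r3 with per-sample mean 22 everywhere
  genes <- c("t1", "t2", "r1", "r2", "r3")
  x <- matrix(22, 5, 6, dimnames = list(genes, paste0("s", 1:6)))
  x["r1", ] <- 20; x["r2", ] <- 22; x["r3", ] <- 24
  x["t1", ] <- c(22, 22.2, 21.8, 20, 20.2, 19.8)  # ~4x up in test group
  x["t2", ] <- x["r2", ]                           # equals a reference
  groups <- rep(c("ctrl", "case"), each = 3)
  m <- make_cq_matrix(x, groups)

  rq <- relative_quantification(m, targets = c("t1", "t2"), refs = c("r1", "r2", "r3"),
                                calibrator_group = "ctrl")
  t1 <- rq$summary[rq$summary$target == "t1", ]
  expect_equal(t1$ddcq, -2, tolerance = 1e-9)
  expect_equal(t1$rq, 4, tolerance = 1e-9)
  expect_equal(t1$log2fc, 2, tolerance = 1e-9)
  expect_equal(t1$log2fc, -t1$ddcq)
  expect_lt(t1$p_value, 0.01)

  # self-normalization: target identical to a reference in every sample
  t2 <- rq$summary[rq$summary$target == "t2", ]
  expect_equal(t2$rq, 1)
  expect_equal(t2$p_value, 1)  # both groups constant dCq

  # per-sample relative expression is 1 on average in the calibrator group
  ps <- rq$per_sample[rq$per_sample$target == "t2", ]
  expect_equal(ps$rel_expr, rep(1, 6))

  # reciprocal fold changes multiply to 1
  rq_rev <- relative_quantification(m, "t1", c("r1", "r2", "r3"),
                                    calibrator_group = "case")
  expect_equal(t1$rq * rq_rev$summary$rq[1], 1, tolerance = 1e-9)

  # invariance to a per-sample additive shift (absorbed by the aggregate)
  x2 <- sweep(x, 2, rnorm(6), "+")
  rq_shift <- relative_quantification(make_cq_matrix(x2, groups), "t1",
                                      c("r1", "r2", "r3"), "ctrl")
  expect_equal(rq_shift$summary$ddcq[1], t1$ddcq, tolerance = 1e-9)

  expect_error(relative_quantification(m, "t1", character(0), "ctrl"),
               class = "endoref_parameter_error")
  expect_error(relative_quantification(m, "t1", "nope", "ctrl"),
               class = "endoref_consistency_error")
  xna <- x; xna["r1", 2] <- NA
  expect_error(relative_quantification(make_cq_matrix(xna, groups), "t1",
                                       c("r1", "r2"), "ctrl"),
               class = "endoref_consistency_error")
  # tiny group: t-test skipped with warning, estimate still returned
  expect_warning(
    rq_small <- relative_quantification(
      make_cq_matrix(x[, 1:4], c("ctrl", "ctrl", "ctrl", "case")),
      "t1", c("r1", "r2", "r3"), "ctrl"),
    "skipped")
  expect_true(is.na(rq_small$summary$p_value[1]))
})

test_that("identical group distributions give t = 0 and p = 1", {
  x <- rbind(t = c(20, 21, 22, 20, 21, 22), r = rep(20, 6))
  m <- make_cq_matrix(x, rep(c("a", "b"), each = 3))
  rq <- relative_quantification(m, "t", "r", calibrator_group = "a")
  expect_equal(rq$summary$ddcq, 0)
  expect_equal(rq$summary$p_value, 1, tolerance = 1e-12)
})

test_that("group_uniformity_test runs per-gene ANOVA with BH adjustment", {
  withr::with_seed(5, {
    x <- matrix(rnorm(5 * 12, 22, 0.5), 5, 12,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  })
  x["g1", 7:12] <- x["g1", 7:12] + 3    # strong group effect
  x["g5", ] <- 25                       # degenerate: no variance at all
  groups <- rep(c("a", "b"), each = 6)
  res <- group_uniformity_test(make_cq_matrix(x, groups))
  expect_equal(res$p_adj, oracle_bh(res$p_value), tolerance = 1e-12)
  expect_true(all(res$p_adj >= res$p_value - 1e-15))
  expect_lt(res$p_adj[res$gene == "g1"], 0.05)
  expect_equal(res$p_value[res$gene == "g5"], 1)
  expect_true(res$degenerate[res$gene == "g5"])
  expect_equal(res$mean_a[res$gene == "g5"], 25)
  expect_equal(res$sd_b[res$gene == "g5"], 0)

  expect_error(group_uniformity_test(make_cq_matrix(x, c("a", rep("b", 11)))),
               class = "endoref_insufficient_data_error")
})

test_that("type-I error is near nominal on null data with shuffled labels", {
  n_genes <- 150
  withr::with_seed(77, {
    x <- matrix(rnorm(n_genes * 24, 23, 1), n_genes, 24,
                dimnames = list(sprintf("g%03d", 1:n_genes), NULL))
    groups <- sample(rep(c("a", "b", "c"), each = 8))
  })
  res <- group_uniformity_test(make_cq_matrix(x, groups))
  frac <- mean(res$p_value < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.08)
})
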