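# The F statistic is invariant under per-gene affine maps, so hand-computed
# values on raw group data carry over unchanged to the z-scored matrix the
# pipeline feeds in.

test_that("ANOVA F matches the sums-of-squares hand computation", {
  d <- one_gene_dataset(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  st <- gene_stats(d$Z, d$classes, stat = "anova")
  # SSB = 54, SSW = 6, F = (54/2)/(6/6) = 27
  expect_equal(st$statistic, 27, tolerance = 1e-12)
  expect_identical(st$df_between, 2L)
  expect_identical(st$df_within, 6L)
  expect_equal(st$p_value, pf(27, 2, 6, lower.tail = FALSE))

  # equal group means: SSB = 0 so F = 0, p = 1, not degenerate
  d0 <- one_gene_dataset(list(c(1, 3), c(2, 2), c(1, 3)))
  st0 <- gene_stats(d0$Z, d0$classes, stat = "anova")
  expect_equal(st0$statistic, 0)
  expect_equal(st0$p_value, 1)
  expect_false(st0$degenerate)
})

test_that("all three statistics match the reference implementations", {
  set.seed(7)
  n <- c(8, 11, 9)
  vals <- matrix(rnorm(100 * sum(n)), 100)
  expr <- expression_matrix(vals, sprintf("g%03d", 1:100),
                            sprintf("s%02d", seq_len(sum(n))))
  Z <- zscore_normalize(expr)
  cls3 <- sample_classes(rep(c("a", "b", "c"), n),
                         sample_ids = Z$sample_ids)

  st <- gene_stats(Z, cls3, "anova")
  ref <- ref_stats(Z, cls3, "anova")
  expect_lt(max(abs(st$statistic - ref[, 1])), 1e-10)
  expect_lt(max(abs(st$p_value - ref[, 2])), 1e-10)

  stw <- gene_stats(Z, cls3, "welch")
  refw <- ref_stats(Z, cls3, "welch")
  expect_lt(max(abs(stw$statistic - refw[, 1])), 1e-8)
  expect_lt(max(abs(stw$p_value - refw[, 2])), 1e-8)

  cls2 <- sample_classes(rep(c("a", "b"), c(14, 14)),
                         sample_ids = Z$sample_ids)
  stt <- gene_stats(Z, cls2, "ttest")
  reft <- ref_stats(Z, cls2, "ttest")
  expect_lt(max(abs(stt$statistic - reft[, 1])), 1e-10)
  expect_lt(max(abs(stt$p_value - reft[, 2])), 1e-10)
})

test_that("two-class identities hold: F = t^2, Welch F = Welch t^2", {
  set.seed(8)
  vals <- matrix(rnorm(50 * 20), 50)
  expr <- expression_matrix(vals, sprintf("g%02d", 1:50),
                            sprintf("s%02d", 1:20))
  Z <- zscore_normalize(expr)
  cls <- sample_classes(rep(c("x", "y"), c(9, 11)),
                        sample_ids = Z$sample_ids)
  f <- gene_stats(Z, cls, "anova")
  t2 <- gene_stats(Z, cls, "ttest")$statistic^2
  expect_lt(max(abs(f$statistic - t2)), 1e-9)
  expect_lt(max(abs(f$p_value - gene_stats(Z, cls, "ttest")$p_value)), 1e-9)

  wf <- gene_stats(Z, cls, "welch")
  welch_t2 <- vapply(seq_len(50), function(i) {
    unname(stats::t.test(Z$values[i, cls == "x"],
                         Z$values[i, cls == "y"])$statistic^2)
  }, 0)
  expect_lt(max(abs(wf$statistic - welch_t2)), 1e-9)
})

test_that("F is invariant to permuting samples within classes", {
  sim <- small_sim()
  Z <- zscore_normalize(sim$expr)
  st <- gene_stats(Z, sim$classes)
  set.seed(9)
  perm <- unlist(lapply(levels(sim$classes), function(lv) {
    idx <- which(as.character(sim$classes)[match(Z$sample_ids,
                                                 names(sim$classes))] == lv)
    sample(idx)
  }))
  Zp <- expression_matrix(Z$values[, perm], Z$gene_ids,
                          Z$sample_ids[perm], normalized = TRUE)
  stp <- gene_stats(Zp, sim$classes)
  expect_lt(max(abs(st$statistic - stp$statistic)), 1e-9)
})

test_that("degenerate and error contracts", {
  # constant gene: zero within- and between-class variance
  d <- one_gene_dataset(list(c(2, 2), c(2, 2)))
  st <- gene_stats(d$Z, d$classes)
  expect_true(st$degenerate)
  expect_equal(st$statistic, 0)
  expect_equal(st$p_value, 1)

  sim <- small_sim()
  Z <- zscore_normalize(sim$expr)
  expect_error(gene_stats(Z, sim$classes, "ttest"), "exactly 2 classes")
  singleton <- sample_classes(
    c(rep("a", length(Z$sample_ids) - 1), "b"),
    sample_ids = Z$sample_ids)
  expect_error(gene_stats(Z, singleton), ">= 2 samples")
  expect_error(gene_stats(sim$expr, sim$classes), "normalized")
})

test_that("identical groups give t = 0, p = 1", {
  d <- one_gene_dataset(list(c(1, 2, 3), c(1, 2, 3)))
  st <- gene_stats(d$Z, d$classes, "ttest")
  expect_equal(st$statistic, 0)
  expect_equal(st$p_value, 1)

  # equal means and variances: Welch statistic ~0, p ~1
  stw <- gene_stats(d$Z, d$classes, "welch")
  expect_lt(abs(stw$statistic), 1e-12)
  expect_equal(stw$p_value, 1, tolerance = 1e-9)
})

test_that("global null keeps the p < 0.05 rate at its nominal level", {
  sim0 <- simulate_dataset(sim_config(n_genes = 2000L,
                                      n_per_class = rep(15L, 3),
                                      n_pathways = 10L,
                                      pathway_size = c(5L, 10L),
                                      n_informative = 0L,
                                      effect_size = 0, seed = 31L))
  Z <- zscore_normalize(sim0$expr)
  st <- gene_stats(Z, sim0$classes)
  frac <- mean(st$p_value < 0.05)
  mc_se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(frac - 0.05), 3 * mc_se)
})
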