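test_that("contributing genes respect threshold, dataset and graph", {
  st <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                   statistic = c(9, 1, 8, 7),
                   p_value = c(0.01, 0.2, 0.03, 0.02))
  graph <- suppressMessages(gene_graph(rbind(c("gA", "gC")),
                                       nodes = c("gA", "gC")))
  data_genes <- c("gA", "gB", "gC", "gD")
  expect_identical(
    contributing_genes(c("gA", "gB"), st, graph, data_genes), "gA")
  # significant but absent from the graph: excluded
  expect_identical(
    contributing_genes(c("gA", "gD"), st, graph, data_genes), "gA")
  # nothing significant: legal empty result
  expect_identical(
    contributing_genes("gB", st, graph, data_genes), character(0))
})

test_that("activity algebra matches its closed form", {
  z <- rbind(c(0.3, -1.2, 2.0, -0.5), c(1.1, 0.4, -0.9, 0.2))
  Z <- expression_matrix(z, c("g1", "g2"), paste0("s", 1:4),
                         normalized = TRUE)
  st <- data.frame(gene_id = c("g1", "g2"), statistic = c(5, 3),
                   p_value = 0.01)

  # single gene: a(s) = z(s) whatever the positive weight
  w1 <- setNames(0.37, "g1")
  expect_equal(pathway_activity("g1", w1, st, Z), z[1, ],
               tolerance = 1e-12)

  # two genes, weights [3, 4]: a = (3 z1 + 4 z2)/5
  w <- setNames(c(3, 4), c("g1", "g2"))
  expect_equal(pathway_activity(c("g1", "g2"), w, st, Z),
               (3 * z[1, ] + 4 * z[2, ]) / 5, tolerance = 1e-12)

  # positive rescaling of the weight vector changes nothing
  a1 <- pathway_activity(c("g1", "g2"), w, st, Z)
  a2 <- pathway_activity(c("g1", "g2"), w * 17.3, st, Z)
  expect_lt(max(abs(a1 - a2)), 1e-10)

  # a negative statistic flips its gene's contribution
  st_neg <- transform(st, statistic = c(-5, 3))
  expect_equal(pathway_activity(c("g1", "g2"), w, st_neg, Z),
               (-3 * z[1, ] + 4 * z[2, ]) / 5, tolerance = 1e-12)

  expect_error(pathway_activity(c("g1", "g2"),
                                setNames(c(0, 0), c("g1", "g2")), st, Z),
               "no diffused weight")
})

test_that("activity matrix drops pathways without usable genes", {
  z <- matrix(rnorm(12), 3, dimnames = NULL)
  Z <- expression_matrix(z, c("g1", "g2", "g3"), paste0("s", 1:4),
                         normalized = TRUE)
  st <- data.frame(gene_id = c("g1", "g2", "g3"), statistic = c(5, 4, 1),
                   p_value = c(0.01, 0.02, 0.5))
  w <- setNames(c(0.5, 0.3, 0.2), c("g1", "g2", "g3"))
  ps <- pathway_set(list(pw1 = c("g1", "g2"), pw2 = "g3",
                         pw3 = c("g2", "g1"), dup = c("g1", "g2")))
  act <- infer_activity_matrix(ps, w, st, Z)
  expect_identical(rownames(act$values), c("pw1", "pw3", "dup"))
  # duplicated pathway under two IDs: identical rows
  expect_equal(act$values["pw1", ], act$values["dup", ])
  # rows equal the independent per-pathway computation (no cross-talk)
  expect_equal(unname(act$values["pw1", ]),
               pathway_activity(c("g1", "g2"), w, st, Z))
  expect_equal(unname(act$values["pw3", ]),
               pathway_activity(c("g2", "g1"), w, st, Z))

  st_ns <- transform(st, p_value = 0.9)
  expect_error(infer_activity_matrix(ps, w, st_ns, Z), "no pathway")
})

test_that("ranking orders by |F| with ID tie-break and clamps selection", {
  sim <- small_sim()
  Z <- zscore_normalize(sim$expr)
  st <- gene_stats(Z, sim$classes)
  w0 <- initial_weights(st, sim$graph)
  w <- random_walk_with_restart(build_transition(sim$graph), w0)
  act <- infer_activity_matrix(sim$pathways, w, st, Z)

  rk <- rank_and_select(act, sim$classes, n = 10)
  expect_identical(rk$table$rank, seq_len(nrow(rk$table)))
  expect_equal(sum(rk$table$selected), 10L)
  expect_true(all(diff(abs(rk$table$statistic)) <= 1e-12))

  # N larger than available: select everything
  rk_all <- rank_and_select(act, sim$classes, n = 1e6)
  expect_true(all(rk_all$table$selected))

  # exact tie via a duplicated activity row: lexicographic ID order
  dup_vals <- act$values[c(1, 1), , drop = FALSE]
  rownames(dup_vals) <- c("zzz", "aaa")
  dup_act <- structure(list(values = dup_vals,
                            contributing = act$contributing[c(1, 1)]),
                       class = "activity_matrix")
  rk2 <- rank_and_select(dup_act, sim$classes, n = 1)
  expect_identical(rk2$table$pathway_id, c("aaa", "zzz"))
  expect_identical(rk2$selected, "aaa")
})

test_that("reproducibility power follows its definition", {
  rk <- structure(list(table = NULL, selected = c("p1", "p2")),
                  class = "pathway_ranking")
  # hand evaluation: (5*4 + 2*1)/2 = 11
  expect_equal(reproducibility_power(rk, c(p1 = 5, p2 = 2),
                                     c(p1 = 4, p2 = 1)), 11)
  # single pathway: product of the two statistics
  rk1 <- structure(list(selected = "p1"), class = "pathway_ranking")
  expect_equal(reproducibility_power(rk1, c(p1 = 3.5), c(p1 = 3.5)),
               3.5^2)
  # all-zero test statistics annihilate the score
  expect_equal(reproducibility_power(rk, c(p1 = 5, p2 = 2),
                                     c(p1 = 0, p2 = 0)), 0)
  # selected pathway missing from test: skipped, N reduced
  expect_equal(reproducibility_power(rk, c(p1 = 5, p2 = 2), c(p1 = 4)),
               20)
  expect_error(reproducibility_power(rk, c(p1 = 5), c(q = 1)),
               "no selected pathway")
})

test_that("Cscore is symmetric and degree-1 homogeneous in each argument", {
  set.seed(13)
  rk <- structure(list(selected = paste0("p", 1:8)),
                  class = "pathway_ranking")
  a <- setNames(stats::runif(8, 0, 10), paste0("p", 1:8))
  b <- setNames(stats::runif(8, 0, 10), paste0("p", 1:8))
  expect_equal(reproducibility_power(rk, a, b),
               reproducibility_power(rk, b, a))
  expect_equal(reproducibility_power(rk, 3 * a, b),
               3 * reproducibility_power(rk, a, b))
})

test_that("planted pathways outrank null pathways in the selection", {
  sim <- small_sim()
  Z <- zscore_normalize(sim$expr)
  model <- pw_fit(Z, sim$classes, sim$pathways, sim$graph,
                  pw_config(top_n = 10, seed = 1))
  tab <- model$ranking$table
  planted <- tab$rank[tab$pathway_id %in% sim$informative]
  null_rk <- tab$rank[!tab$pathway_id %in% sim$informative]
  expect_lt(mean(planted), mean(null_rk))
  expect_gte(mean(sim$informative %in% model$ranking$selected), 0.9)
})
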