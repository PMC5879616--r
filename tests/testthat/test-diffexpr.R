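test_that("log2 fold change uses pseudocounted replicate means", {
  x <- make_expr(matrix(c(10, 10, 40, 40,
                          5, 5, 5, 5), nrow = 2, byrow = TRUE),
                 c("A", "B"))
  ct <- compute_contrast(x, "A", "B", method = "permutation")
  expect_equal(ct$log2fc[1], log2(41 / 11))
  expect_equal(ct$mean_fpkm_a[1], 10)
  expect_equal(ct$mean_fpkm_b[1], 40)
  # identical values in both groups: null fold change, permutation p = 1
  expect_equal(ct$log2fc[2], 0)
  expect_equal(ct$p_value[2], 1)
})

test_that("exact permutation p equals independent full enumeration at 2+2", {
  set.seed(31)
  vals <- matrix(2^rnorm(200, 5, 1.5), nrow = 50)
  x <- make_expr(vals, c("A", "B"))
  ct <- compute_contrast(x, "A", "B", method = "permutation")
  la <- log2(vals[, 1:2] + 1)
  lb <- log2(vals[, 3:4] + 1)
  oracle <- vapply(seq_len(nrow(vals)),
                   function(i) perm_enumeration(la[i, ], lb[i, ]), numeric(1))
  expect_equal(ct$p_value, oracle)
})

test_that("Monte-Carlo permutation agrees with enumeration within 3 SE", {
  set.seed(8)
  n_rep <- 6L  # 12 replicates total forces the Monte-Carlo path
  vals <- matrix(2^rnorm(20 * 2 * n_rep, 5, 1), nrow = 20)
  x <- make_expr(vals, c("A", "B"), replicates = n_rep)
  ct_mc <- compute_contrast(x, "A", "B", method = "permutation",
                            n_perm = 10000L, seed = 99)
  la <- log2(vals[, 1:n_rep] + 1)
  lb <- log2(vals[, n_rep + 1:n_rep] + 1)
  exact <- vapply(seq_len(nrow(vals)),
                  function(i) perm_enumeration(la[i, ], lb[i, ]), numeric(1))
  se <- sqrt(exact * (1 - exact) / 10000) + 1e-4
  expect_true(all(abs(ct_mc$p_value - exact) <= 3 * se + 2 / 10000))
})

test_that("BH adjustment matches a from-scratch reference on random p-vectors", {
  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "BH"), bh_reference(p))
  }
})

test_that("expressed mean averages condition means over the expressed universe", {
  # genes with condition-A means 0, 10, 20; all expressed somewhere
  vals <- matrix(c(0, 0, 4, 4,
                   10, 10, 0, 0,
                   20, 20, 1, 1), nrow = 3, byrow = TRUE)
  x <- make_expr(vals, c("A", "B"))
  expect_equal(expressed_mean(x, "A"), 10)
  expect_equal(expressed_mean(x, "B"), 5 / 3)
  # brute-force recomputation on synthetic data
  sim <- generate_expression(sim_config(
    n_per_class = setNames(rep(10L, 9), memory_types), seed = 2))
  v <- sim$expr$values
  sheet <- sim$expr$sheet
  cm <- sapply(unique(sheet$condition), function(cc) {
    rowMeans(v[, sheet$sample_id[sheet$condition == cc], drop = FALSE])
  })
  expect_equal(expressed_mean(sim$expr, "D1"),
               mean(cm[rowSums(cm > 0) > 0, "D1"]))
  # degenerate: all-zero matrix
  z <- make_expr(matrix(0, 2, 4), c("A", "B"))
  expect_error(expressed_mean(z, "A"), "no expressed genes")
})

test_that("direction calls honour inclusive thresholds and the floor", {
  crit <- deg_criteria()
  ct <- data.frame(gene_id = c("up", "floored", "down"),
                   log2fc = c(1.0, 2.0, -1.5),
                   p_value = c(0.01, 0.001, 0.0001),
                   q_value = c(0.05, 0.01, 0.001),
                   mean_fpkm_a = c(5, 5, 50),
                   mean_fpkm_b = c(20, 1, 5))
  out <- call_direction(ct, crit, floor_value_up = 10, floor_value_down = 10)
  expect_equal(out$call, c("+", "=", "-"))
  # unset q is a hard error
  ct$q_value[1] <- NA
  expect_error(call_direction(ct, crit, 10, 10), "q_value")
})

test_that("calls are monotone in the thresholds", {
  set.seed(77)
  ct <- data.frame(gene_id = sprintf("g%d", 1:300),
                   log2fc = rnorm(300, 0, 2),
                   p_value = runif(300),
                   q_value = runif(300),
                   mean_fpkm_a = runif(300, 0, 50),
                   mean_fpkm_b = runif(300, 0, 50))
  base <- call_direction(ct, deg_criteria(), 5, 5)$call
  stricter_q <- call_direction(ct, deg_criteria(q_threshold = 0.01), 5, 5)$call
  stricter_fc <- call_direction(ct, deg_criteria(fc_threshold = 2), 5, 5)$call
  expect_true(all(stricter_q[base == "="] == "="))
  expect_true(all(stricter_fc[base == "="] == "="))
})

test_that("per-gene outputs are invariant under gene-order permutation", {
  set.seed(4)
  vals <- matrix(2^rnorm(120, 5, 1.5), nrow = 30)
  x <- make_expr(vals, c("A", "B"))
  perm <- sample(nrow(vals))
  xp <- expr_set(x$values[perm, ], x$sheet)
  for (m in c("limma", "welch", "permutation")) {
    a <- called_contrast(x, "A", "B", method = m)
    b <- called_contrast(xp, "A", "B", method = m)
    reord <- match(a$gene_id, b$gene_id)
    expect_equal(a$p_value, b$p_value[reord])
    expect_equal(a$q_value, b$q_value[reord])
    expect_equal(a$call, b$call[reord])
  }
})

test_that("precomputed contrasts are ingested with BH recomputed when q absent", {
  x <- make_expr(matrix(c(10, 10, 40, 40,
                          8, 8, 2, 2,
                          5, 5, 5, 5), nrow = 3, byrow = TRUE),
                 c("A", "B"))
  pre <- data.frame(gene_id = c("g1", "g2", "g3"),
                    log2fc = c(2, -2, 0),
                    p_value = c(0.001, 0.002, 0.9))
  ct <- compute_contrast(x, "A", "B", method = "precomputed",
                         precomputed = pre)
  expect_equal(ct$q_value, stats::p.adjust(pre$p_value, "BH"))
  expect_equal(ct$mean_fpkm_b, c(40, 2, 5))
  # 1-replicate designs must be pointed at precomputed mode
  x1 <- make_expr(matrix(c(1, 2), nrow = 1), c("A", "B"), replicates = 1L)
  expect_error(compute_contrast(x1, "A", "B", method = "permutation"),
               "precomputed")
  # absent condition is a hard error
  expect_error(compute_contrast(x, "A", "Z"), "not found")
})
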