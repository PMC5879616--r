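test_that("well-formed matrix and sheet read back validated", {
  dir <- withr::local_tempdir()
  mat <- matrix(c(1.5, 0, 10, 20, 3, 4, 5, 6,
                  0.1, 0.2, 0.3, 0.4, 7, 8, 9, 10,
                  2, 2, 2, 2, 2, 2, 2, 2), nrow = 3, byrow = TRUE)
  x <- make_expr(mat, c("C1", "D1", "R1", "D2"))
  mp <- file.path(dir, "m.tsv"); sp <- file.path(dir, "s.tsv")
  write_expression(x, mp, sp)
  y <- read_expression(mp, sp)
  expect_s3_class(y, "expr_set")
  expect_equal(dim(y$values), c(3, 8))
  expect_setequal(y$sheet$condition, c("C1", "D1", "R1", "D2"))
})

test_that("duplicated gene ids are rejected by name", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "dup.tsv")
  writeLines(c("gene_id\tA_r1\tA_r2", "g1\t1\t2", "g1\t3\t4"), p)
  sp <- file.path(dir, "s.tsv")
  writeLines(c("sample_id\tcondition\treplicate", "A_r1\tA\t1", "A_r2\tA\t2"), sp)
  expect_error(read_expression(p, sp), "g1")
})

test_that("matrix/sheet sample mismatch and bad values are hard errors", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "m.tsv")
  writeLines(c("gene_id\tA_r1\tA_r2", "g1\t1\t2"), p)
  sp <- file.path(dir, "s.tsv")
  writeLines(c("sample_id\tcondition\treplicate",
               "A_r1\tA\t1", "B_r1\tB\t1"), sp)
  expect_error(read_expression(p, sp), "mismatch")

  p2 <- file.path(dir, "neg.tsv")
  writeLines(c("gene_id\tA_r1\tA_r2", "g1\t-1\t2"), p2)
  sp2 <- file.path(dir, "s2.tsv")
  writeLines(c("sample_id\tcondition\treplicate",
               "A_r1\tA\t1", "A_r2\tA\t2"), sp2)
  expect_error(read_expression(p2, sp2), "negative|non-numeric")
  p3 <- file.path(dir, "txt.tsv")
  writeLines(c("gene_id\tA_r1\tA_r2", "g1\tx\t2"), p3)
  expect_error(read_expression(p3, sp2), "row 1.*column 'A_r1'")
})

test_that("synthetic output round-trips losslessly to 12 significant digits", {
  dir <- withr::local_tempdir()
  sim <- generate_expression(sim_config(
    n_per_class = setNames(rep(3L, 9), memory_types), seed = 11))
  mp <- file.path(dir, "m.tsv"); sp <- file.path(dir, "s.tsv")
  write_expression(sim$expr, mp, sp)
  y <- read_expression(mp, sp)
  expect_equal(y$values, sim$expr$values, tolerance = 1e-12)
  expect_identical(y$sheet, sim$expr$sheet)
})

test_that("reader output is independent of input row order", {
  dir <- withr::local_tempdir()
  sim <- generate_expression(sim_config(
    n_per_class = setNames(rep(4L, 9), memory_types), seed = 5))
  mp <- file.path(dir, "m.tsv"); sp <- file.path(dir, "s.tsv")
  write_expression(sim$expr, mp, sp)
  lines <- readLines(mp)
  set.seed(1)
  writeLines(c(lines[1], sample(lines[-1])), mp)
  y <- read_expression(mp, sp)
  a1 <- class_recovery(list(expr = y, truth = sim$truth,
                            config = sim$config))
  a2 <- class_recovery(sim)
  t1 <- a1$table[order(a1$table$gene_id), ]
  t2 <- a2$table[order(a2$table$gene_id), ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1, t2)
})

test_that("ortholog maps collapse duplicates and count sides", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "om.tsv")
  writeLines(c("gene_a\tgene_b", "p1\tm1", "p1\tm2", "p2\tm1", "p1\tm1"), p)
  expect_warning(om <- read_ortholog_map(p), "duplicate")
  expect_equal(nrow(om), 3)
  expect_equal(attr(om, "n_a"), 2)
  expect_equal(attr(om, "n_b"), 2)
  # round trip preserves the pair set
  p2 <- file.path(dir, "om2.tsv")
  write_ortholog_map(om, p2)
  om2 <- read_ortholog_map(p2)
  expect_setequal(paste(om$gene_a, om$gene_b), paste(om2$gene_a, om2$gene_b))
  # empty file errors
  pe <- file.path(dir, "empty.tsv")
  writeLines("gene_a\tgene_b", pe)
  expect_error(read_ortholog_map(pe), "empty|non-empty")
})

test_that("GMT annotation sets round-trip and reject empty terms", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "a.gmt")
  writeLines(c("T1\tfirst term\tg1\tg2\tg3", "T2\t\tg4\tg5"), p)
  ann <- read_annotation_sets(p)
  expect_length(ann, 2)
  expect_setequal(ann$T1, c("g1", "g2", "g3"))
  p2 <- file.path(dir, "b.gmt")
  write_annotation_sets(ann, p2)
  expect_identical(read_annotation_sets(p2)$T2, ann$T2)
  pe <- file.path(dir, "bad.gmt")
  writeLines(c("T1\tdesc"), pe)
  expect_error(read_annotation_sets(pe), "zero member genes")
})

test_that("Ct tables require a reference Ct per sample/replicate", {
  ct <- data.frame(sample_id = "s1", condition = "C", biological_rep = 1,
                   gene_id = "T", role = "target", ct = 25)
  expect_error(stressmem:::validate_ct_table(ct), "reference")
  ct2 <- rbind(ct, data.frame(sample_id = "s1", condition = "C",
                              biological_rep = 1, gene_id = "R",
                              role = "reference", ct = 20))
  expect_silent(stressmem:::validate_ct_table(ct2))
})
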