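test_that("the 3x3 call mapping yields the nine types and four categories", {
  cases <- expand.grid(a = c("+", "-", "="), b = c("+", "-", "="),
                       stringsAsFactors = FALSE)
  res <- assign_memory_type(cases$a, cases$b)
  expect_setequal(res$memory_type, memory_types)
  expect_equal(res$memory_type, paste0("[", cases$a, "/", cases$b, "]"))
  expect_equal(res$category[res$memory_type == "[+/+]"], "memory")
  expect_equal(res$category[res$memory_type == "[=/+]"], "late-response")
  expect_equal(res$category[res$memory_type == "[=/=]"], "non-response")
  expect_equal(res$category[res$memory_type == "[-/=]"], "non-memory")
  expect_error(assign_memory_type("+", "?"), "invalid")
})

test_that("types partition the gene universe", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    a <- sample(c("+", "-", "="), n, replace = TRUE)
    b <- sample(c("+", "-", "="), n, replace = TRUE)
    res <- assign_memory_type(a, b)
    sm <- summarize_memory(res)
    expect_equal(sum(sm$type_counts), n)
    expect_equal(sum(sm$category_counts), n)
  }
})

test_that("summary reproduces the published ratio structure from raw counts", {
  sm <- summarize_memory(counts_to_assignments(switchgrass_counts))
  expect_equal(sm$n_memory, 741)
  expect_equal(sm$n_response, 1566)
  expect_equal(unname(sm$memory_type_pct),
               c(13, 51, 21, 15))  # [+/+], [+/-], [-/+], [-/-] of 741
  expect_equal(sm$memory_pct_of_response, 47.3)
  expect_equal(sm$n_deg, 7584)
  expect_equal(unname(sm$deg_type_pct[c("[+/=]", "[-/=]", "[=/+]", "[=/-]")]),
               c(4.4, 6.4, 41.6, 37.7))
  expect_equal(sm$response_pct_of_total, 3.3)
  # counts are additive over disjoint subsets and permutation-invariant
  assign <- counts_to_assignments(c("[+/+]" = 7, "[=/-]" = 5, "[=/=]" = 11))
  sm_all <- summarize_memory(assign)
  shuffled <- assign[sample(nrow(assign)), ]
  expect_equal(summarize_memory(shuffled), sm_all)
  split1 <- summarize_memory(assign[1:10, ])
  split2 <- summarize_memory(assign[11:nrow(assign), ])
  expect_equal(split1$type_counts + split2$type_counts, sm_all$type_counts)
})

test_that("an empty assignment table gives zeros with undefined percentages", {
  sm <- summarize_memory(assign_memory_type(character(), character()))
  expect_equal(sum(sm$type_counts), 0)
  expect_true(is.na(sm$memory_pct_of_response))
  expect_true(all(is.na(sm$memory_type_pct)))
})

test_that("venn reports match direct set arithmetic", {
  calls_a <- setNames(c("+", "+", "+", "="), paste0("g", 1:4))
  calls_b <- setNames(c("=", "+", "+", "+"), paste0("g", 1:4))
  v <- venn_sets(calls_a, calls_b, "+")
  expect_equal(v$n_common, 2)
  expect_setequal(v$common, c("g2", "g3"))
  expect_equal(v$n_union, 4)
  # identical sets
  vi <- venn_sets(calls_a, calls_a, "+")
  expect_equal(vi$n_only_a, 0)
  expect_equal(vi$n_common, vi$n_a)
  # mismatched universes are rejected
  expect_error(venn_sets(calls_a, calls_b[1:3], "+"), "universe")
})

test_that("inclusion-exclusion on printed overlap counts", {
  up <- venn_counts(811, 3679, 356)
  expect_equal(up$n_union, 4134)
  expect_equal(count_share(93, up$n_common, 2), 26.12)
  expect_equal(count_share(93, up$n_union, 1), 2.2)
  down <- venn_counts(755, 3534, 517)
  expect_equal(down$n_union, 3772)
  expect_equal(count_share(113, down$n_common, 2), 21.86)
  expect_equal(count_share(113, down$n_union, 1), 3.0)
})

test_that("venn identity holds on random call-vector instances", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    genes <- sprintf("g%d", seq_len(n))
    a <- setNames(sample(c("+", "-", "="), n, replace = TRUE), genes)
    b <- setNames(sample(c("+", "-", "="), n, replace = TRUE), genes)
    d <- sample(c("+", "-"), 1)
    v <- venn_sets(a, b, d)
    expect_equal(v$n_union, v$n_a + v$n_b - v$n_common)
    expect_equal(v$n_only_a + v$n_common, v$n_a)
    expect_equal(v$n_only_b + v$n_common, v$n_b)
  }
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  universe <- paste0("g", 1:4)
  ann <- list(T1 = c("g1", "g2"), Tall = universe)
  res <- enrich_terms(c("g1", "g2"), universe, ann)
  expect_equal(res$p_value[res$term_id == "T1"], 1 / 6)
  expect_equal(res$p_value[res$term_id == "Tall"], 1)
  expect_error(enrich_terms("zz", universe, ann), "outside the universe")
})

test_that("enrichment p-values equal brute-force subset enumeration", {
  set.seed(13)
  for (i in 1:15) {
    n <- sample(6:12, 1)
    universe <- sprintf("g%d", seq_len(n))
    term <- sample(universe, sample(1:n, 1))
    selected <- sample(universe, sample(1:(n - 1), 1))
    res <- enrich_terms(selected, universe, list(T = term))
    oracle <- hyper_enumeration(res$overlap, term, universe, length(selected))
    expect_equal(res$p_value, oracle)
  }
})
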