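# Shared fixtures and independent oracles.

# small expression set: genes x (conditions x replicates)
make_expr <- function(values, conditions, replicates = 2L,
                      genes = sprintf("g%d", seq_len(nrow(values)))) {
  samples <- as.vector(t(outer(conditions, seq_len(replicates),
                               function(cc, r) paste0(cc, "_r", r))))
  stopifnot(ncol(values) == length(samples))
  dimnames(values) <- list(genes, samples)
  sheet <- data.frame(sample_id = samples,
                      condition = rep(conditions, each = replicates),
                      replicate = rep(seq_len(replicates),
                                      times = length(conditions)))
  expr_set(values, sheet)
}

# assignment table realizing a named vector of per-type counts
counts_to_assignments <- function(counts) {
  type <- rep(names(counts), counts)
  assign_memory_type(substr(type, 2, 2), substr(type, 4, 4),
                     gene_id = sprintf("g%06d", seq_along(type)))
}

# from-scratch Benjamini-Hochberg, independent of stats::p.adjust
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}

# brute-force two-sided permutation p at small n: enumerate every split
perm_enumeration <- function(va, vb) {
  pooled <- c(va, vb)
  n <- length(pooled)
  na <- length(va)
  obs <- abs(mean(vb) - mean(va))
  splits <- utils::combn(n, na)
  mean(apply(splits, 2, function(ia) {
    abs(mean(pooled[-ia]) - mean(pooled[ia])) >= obs - 1e-12
  }))
}

# brute-force hypergeometric upper tail: enumerate every possible selected
# set of the same size and count those with at least the observed overlap
hyper_enumeration <- function(overlap, term, universe, n_selected) {
  sets <- utils::combn(length(universe), n_selected)
  mean(apply(sets, 2, function(ix) {
    length(intersect(universe[ix], term)) >= overlap
  }))
}

# minimal qPCR fixture: two conditions x two biological replicates,
# technical duplicates, one target and one reference gene
simple_ct <- function() {
  rows <- expand.grid(condition = c("cal", "trt"), biological_rep = 1:2,
                      tech = 1:2, stringsAsFactors = FALSE)
  rows$sample_id <- paste0(rows$condition, "_b", rows$biological_rep)
  tgt <- transform(rows, gene_id = "T", role = "target",
                   ct = ifelse(condition == "cal", 24, 25))
  ref <- transform(rows, gene_id = "R", role = "reference", ct = 20)
  rbind(tgt, ref)[, c("sample_id", "condition", "biological_rep",
                      "gene_id", "role", "ct")]
}

# Published summary counts used as worked-example inputs (gene tallies of
# the three-species repeated-dehydration comparison).
switchgrass_counts <- c("[+/+]" = 93, "[+/-]" = 381, "[-/+]" = 154,
                        "[-/-]" = 113, "[+/=]" = 337, "[-/=]" = 488,
                        "[=/+]" = 3158, "[=/-]" = 2860,
                        "[=/=]" = 47207 - (93 + 381 + 154 + 113 +
                                             337 + 488 + 3158 + 2860))
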