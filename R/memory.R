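#' The nine memory types and their categories
#'
#' A gene's behaviour over two successive stresses is written `[a/b]`,
#' where `a` is its direction call in the first-stress-vs-control contrast
#' and `b` its call in the second-stress-vs-first-stress contrast. The four
#' types whose response changes between stresses (`[+/+]`, `[+/-]`,
#' `[-/+]`, `[-/-]`) are memory genes; `[+/=]` and `[-/=]` repeat their
#' first response (non-memory); `[=/+]` and `[=/-]` respond only to the
#' second stress (late-response); `[=/=]` is non-response.
#'
#' @format Character vector of the nine `[a/b]` labels.
#' @export
memory_types <- c("[+/+]", "[+/-]", "[-/+]", "[-/-]",
                  "[+/=]", "[-/=]", "[=/+]", "[=/-]", "[=/=]")

#' @rdname memory_types
#' @format NULL
#' @export
memory_categories <- c("[+/+]" = "memory", "[+/-]" = "memory",
                       "[-/+]" = "memory", "[-/-]" = "memory",
                       "[+/=]" = "non-memory", "[-/=]" = "non-memory",
                       "[=/+]" = "late-response", "[=/-]" = "late-response",
                       "[=/=]" = "non-response")

check_calls <- function(calls, what) {
  bad <- setdiff(unique(calls), c("+", "-", "="))
  if (length(bad)) {
    stop("invalid ", what, " symbol(s): ", paste(bad, collapse = ", "),
         " (expected +, -, =)", call. = FALSE)
  }
  invisible(calls)
}

#' Assign memory types from two direction calls
#'
#' Deterministic 3x3 mapping of the paired calls onto the nine `[a/b]`
#' types, with the derived category (memory / non-memory / late-response /
#' non-response). Vectorized.
#'
#' @param call_first Direction calls (`+`, `-`, `=`) in the first contrast
#'   (first stress vs control).
#' @param call_second Direction calls in the second contrast (second stress
#'   vs first stress).
#' @param gene_id Optional gene identifiers.
#' @return Data frame with columns `gene_id`, `call_first`, `call_second`,
#'   `memory_type`, `category`.
#' @export
assign_memory_type <- function(call_first, call_second, gene_id = NULL) {
  if (length(call_first) != length(call_second)) {
    stop("call vectors differ in length", call. = FALSE)
  }
  check_calls(call_first, "first-contrast")
  check_calls(call_second, "second-contrast")
  if (is.null(gene_id)) gene_id <- as.character(seq_along(call_first))
  if (length(call_first) == 0L) {
    return(data.frame(gene_id = character(), call_first = character(),
                      call_second = character(), memory_type = character(),
                      category = character()))
  }
  type <- paste0("[", call_first, "/", call_second, "]")
  data.frame(gene_id = as.character(gene_id),
             call_first = call_first, call_second = call_second,
             memory_type = type,
             category = unname(memory_categories[type]),
             row.names = NULL)
}

#' Classify an experiment into memory types
#'
#' Joins two called contrast tables on gene id and assigns memory types.
#' Genes present in only one table are dropped with a warning.
#'
#' @param contrast_first Called contrast for first stress vs control.
#' @param contrast_second Called contrast for second stress vs first
#'   stress.
#' @return Assignment data frame as from [assign_memory_type()].
#' @export
classify_memory <- function(contrast_first, contrast_second) {
  if (anyNA(contrast_first$call) || anyNA(contrast_second$call)) {
    stop("contrasts must be called (run call_direction first)", call. = FALSE)
  }
  common <- intersect(contrast_first$gene_id, contrast_second$gene_id)
  n_drop <- length(union(contrast_first$gene_id, contrast_second$gene_id)) -
    length(common)
  if (n_drop > 0L) {
    warning(n_drop, " gene(s) absent from one contrast excluded from the universe",
            call. = FALSE)
  }
  a <- contrast_first$call[match(common, contrast_first$gene_id)]
  b <- contrast_second$call[match(common, contrast_second$gene_id)]
  assign_memory_type(a, b, gene_id = common)
}

# Round half away from zero, matching how the published percentage tables
# in this field are rounded (12.55% -> 13%).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

pct <- function(num, den, digits) {
  if (is.na(den) || den == 0) return(NA_real_)
  round_half_away(100 * num / den, digits)
}

#' Summarize memory-type assignments
#'
#' Counts per type and per category with the percentage conventions used in
#' published stress-memory tables: each memory type as an integer percent
#' of all memory genes; memory genes as a 1-decimal percent of all
#' dehydration-response genes (genes with a non-`=` first call); each
#' non-`[=/=]` type as a 1-decimal percent of all differentially expressed
#' genes (any non-`[=/=]` type). All denominators are reported explicitly.
#' Percentages are `NA` when their denominator is zero.
#'
#' @param assignments Data frame from [assign_memory_type()] /
#'   [classify_memory()].
#' @return List of class `memory_summary`.
#' @export
summarize_memory <- function(assignments) {
  type <- factor(assignments$memory_type, levels = memory_types)
  if (anyNA(type)) stop("unknown memory type in assignments", call. = FALSE)
  type_counts <- table(type)
  category <- factor(unname(memory_categories[as.character(type)]),
                     levels = c("memory", "non-memory", "late-response",
                                "non-response"))
  category_counts <- table(category)
  n_total <- length(type)
  n_memory <- as.integer(category_counts[["memory"]])
  n_response <- sum(assignments$call_first != "=")
  n_deg <- sum(as.character(type) != "[=/=]")

  mem_types <- memory_types[1:4]
  memory_type_pct <- stats::setNames(
    vapply(mem_types, function(tt) pct(type_counts[[tt]], n_memory, 0),
           numeric(1)), mem_types)
  deg_types <- memory_types[1:8]
  deg_type_pct <- stats::setNames(
    vapply(deg_types, function(tt) pct(type_counts[[tt]], n_deg, 1),
           numeric(1)), deg_types)

  structure(list(
    type_counts = stats::setNames(as.integer(type_counts), memory_types),
    category_counts = stats::setNames(as.integer(category_counts),
                                      levels(category)),
    n_total = n_total,
    n_response = n_response,
    n_deg = n_deg,
    n_memory = n_memory,
    memory_type_pct = memory_type_pct,
    deg_type_pct = deg_type_pct,
    memory_pct_of_response = pct(n_memory, n_response, 1),
    response_pct_of_total = pct(n_response, n_total, 1)
  ), class = "memory_summary")
}

#' @export
print.memory_summary <- function(x, ...) {
  cat("memory summary:", x$n_total, "genes;", x$n_response, "response;",
      x$n_memory, "memory")
  if (!is.na(x$memory_pct_of_response)) {
    cat(sprintf(" (%.1f%% of response genes)", x$memory_pct_of_response))
  }
  cat("\n")
  print(x$type_counts)
  invisible(x)
}

#' Share of one printed count in another
#'
#' Ratio arithmetic on already-tabulated counts, at the caller's decimal
#' precision, with half-away-from-zero rounding. Useful for reproducing the
#' percentage columns of published summary tables from their raw counts.
#'
#' @param numerator,denominator Counts.
#' @param digits Decimal places of the percentage.
#' @return Percentage (0-100), `NA` if the denominator is zero.
#' @export
count_share <- function(numerator, denominator, digits = 1) {
  pct(numerator, denominator, digits)
}

#' Two-set overlap (Venn) report from direction calls
#'
#' Given two call vectors over the same gene universe and a direction,
#' reports the sizes of the two sets, their intersection, differences and
#' union, plus the member lists.
#'
#' @param calls_a,calls_b Named character vectors of calls (`+`, `-`, `=`)
#'   over identical gene universes.
#' @param direction `"+"` or `"-"`: which call defines set membership.
#' @return List with `n_a`, `n_b`, `n_common`, `n_only_a`, `n_only_b`,
#'   `n_union` and members `common`, `only_a`, `only_b`.
#' @export
venn_sets <- function(calls_a, calls_b, direction = c("+", "-")) {
  direction <- match.arg(direction)
  if (is.null(names(calls_a)) || is.null(names(calls_b)) ||
      !setequal(names(calls_a), names(calls_b))) {
    stop("call vectors must be named over identical gene universes",
         call. = FALSE)
  }
  a <- names(calls_a)[calls_a == direction]
  b <- names(calls_b)[calls_b == direction]
  common <- intersect(a, b)
  list(n_a = length(a), n_b = length(b), n_common = length(common),
       n_only_a = length(setdiff(a, b)), n_only_b = length(setdiff(b, a)),
       n_union = length(union(a, b)),
       common = common, only_a = setdiff(a, b), only_b = setdiff(b, a))
}

#' Venn arithmetic on printed set sizes
#'
#' Inclusion-exclusion on counts alone: given |A|, |B| and |A n B|,
#' returns the derived difference and union sizes.
#'
#' @param n_a,n_b,n_common Set and intersection sizes.
#' @return List with `n_a`, `n_b`, `n_common`, `n_only_a`, `n_only_b`,
#'   `n_union`.
#' @export
venn_counts <- function(n_a, n_b, n_common) {
  stopifnot(n_common <= n_a, n_common <= n_b)
  list(n_a = n_a, n_b = n_b, n_common = n_common,
       n_only_a = n_a - n_common, n_only_b = n_b - n_common,
       n_union = n_a + n_b - n_common)
}

#' Hypergeometric term enrichment
#'
#' One-sided upper-tail hypergeometric test of each annotation term against
#' a selected gene set within a fixed universe, with Benjamini-Hochberg
#' adjustment across the tested terms. Annotation sets are intersected with
#' the universe first; terms with zero overlap are reported with their
#' computed tail probability.
#'
#' @param selected Character vector of selected genes (must be a subset of
#'   `universe`).
#' @param universe Character vector, the gene universe.
#' @param annotations Named list of gene-id vectors (e.g. from
#'   [read_annotation_sets()]).
#' @return Data frame with columns `term_id`, `overlap`, `term_size`,
#'   `selected_size`, `universe_size`, `p_value`, `q_value`, ordered by
#'   `p_value`.
#' @export
enrich_terms <- function(selected, universe, annotations) {
  selected <- unique(selected)
  universe <- unique(universe)
  extra <- setdiff(selected, universe)
  if (length(extra)) {
    stop("selected genes outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  n_univ <- length(universe)
  n_sel <- length(selected)
  rows <- lapply(names(annotations), function(tid) {
    term <- intersect(unique(annotations[[tid]]), universe)
    k <- length(intersect(term, selected))
    m <- length(term)
    p <- stats::phyper(k - 1, m, n_univ - m, n_sel, lower.tail = FALSE)
    data.frame(term_id = tid, overlap = k, term_size = m,
               selected_size = n_sel, universe_size = n_univ,
               p_value = p, row.names = NULL)
  })
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value), , drop = FALSE]
}

#' Write memory assignments / summary artifacts
#'
#' @param assignments Assignment data frame.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_assignments <- function(assignments, path) {
  write_tsv(assignments, path)
  invisible(path)
}

#' @rdname write_assignments
#' @param summary A `memory_summary`.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
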