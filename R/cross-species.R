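#' Classify ortholog pairs of memory genes by conservation
#'
#' For every ortholog pair whose species-A gene is a memory gene, records
#' the memory types on both sides and a pair category:
#' `conserved-same-type` when both sides are memory genes of the identical
#' type; `memory-different-type` when the B-side is a memory gene of
#' another type; otherwise the B-side's category (`non-memory`,
#' `late-response`, `non-response`). B-side genes absent from the species-B
#' assignment table are treated as non-response (`[=/=]`).
#'
#' @param map An `ortholog_map` (columns `gene_a`, `gene_b`).
#' @param assign_a,assign_b Assignment data frames (from
#'   [assign_memory_type()] or [classify_memory()]) for species A and B.
#' @return Data frame with columns `gene_a`, `gene_b`, `type_a`, `type_b`,
#'   `pair_category`. Empty (with a warning) when the map has no pairs with
#'   a memory-gene A side.
#' @export
classify_pairs <- function(map, assign_a, assign_b) {
  mem_types <- memory_types[1:4]
  type_a_all <- assign_a$memory_type[match(map$gene_a, assign_a$gene_id)]
  keep <- !is.na(type_a_all) & type_a_all %in% mem_types
  if (!any(keep)) {
    warning("no ortholog pairs with a memory-gene A side", call. = FALSE)
    return(data.frame(gene_a = character(), gene_b = character(),
                      type_a = character(), type_b = character(),
                      pair_category = character()))
  }
  gene_a <- map$gene_a[keep]
  gene_b <- map$gene_b[keep]
  type_a <- type_a_all[keep]
  type_b <- assign_b$memory_type[match(gene_b, assign_b$gene_id)]
  type_b[is.na(type_b)] <- "[=/=]"
  cat_b <- unname(memory_categories[type_b])
  pair_category <- ifelse(cat_b != "memory", cat_b,
                          ifelse(type_a == type_b, "conserved-same-type",
                                 "memory-different-type"))
  data.frame(gene_a = gene_a, gene_b = gene_b, type_a = type_a,
             type_b = type_b, pair_category = pair_category,
             row.names = NULL)
}

#' Summarize ortholog memory conservation
#'
#' Tallies the classified ortholog pairs by B-side response category
#' (pairs in `conserved-same-type` or `memory-different-type` count as
#' `memory`), with 1-decimal percentages over the total classified
#' orthologs, per-type conserved counts, and an explicit
#' numerator/denominator for the conserved share within each A-side memory
#' type. A per-gene rollup (an A-side memory gene is "conserved" if any of
#' its orthologs shares its type) is included as a secondary view.
#'
#' @param records Data frame from [classify_pairs()].
#' @param n_memory_a Number of memory genes in species A (for the
#'   with-ortholog coverage figure); optional.
#' @return List of class `conservation_summary`.
#' @export
conservation_summary <- function(records, n_memory_a = NA_integer_) {
  cats <- c("memory", "non-memory", "late-response", "non-response")
  n <- nrow(records)
  b_cat <- ifelse(records$pair_category %in%
                    c("conserved-same-type", "memory-different-type"),
                  "memory", records$pair_category)
  category_counts <- stats::setNames(
    vapply(cats, function(cc) sum(b_cat == cc), integer(1)), cats)
  category_pct <- stats::setNames(
    vapply(cats, function(cc) pct(category_counts[[cc]], n, 1), numeric(1)),
    cats)

  mem_types <- memory_types[1:4]
  conserved <- records$pair_category == "conserved-same-type"
  conserved_by_type <- stats::setNames(
    vapply(mem_types, function(tt) sum(conserved & records$type_a == tt),
           integer(1)), mem_types)
  # share of conserved pairs among memory-category orthologs of each A type
  memory_by_type <- stats::setNames(
    vapply(mem_types, function(tt) sum(b_cat == "memory" & records$type_a == tt),
           integer(1)), mem_types)
  conserved_share_by_type <- stats::setNames(
    vapply(mem_types, function(tt)
      pct(conserved_by_type[[tt]], memory_by_type[[tt]], 1), numeric(1)),
    mem_types)

  genes_with_ortholog <- unique(records$gene_a)
  genes_conserved <- unique(records$gene_a[conserved])

  structure(list(
    n_memory_a = n_memory_a,
    n_orthologs = n,
    n_memory_genes_with_ortholog = length(genes_with_ortholog),
    category_counts = category_counts,
    category_pct = category_pct,
    conserved_by_type = conserved_by_type,
    memory_by_type = memory_by_type,
    conserved_share_by_type = conserved_share_by_type,
    n_conserved_pairs = sum(conserved),
    memory_share_by_type = stats::setNames(
      vapply(mem_types, function(tt)
        pct(sum(b_cat == "memory" & records$type_a == tt),
            category_counts[["memory"]], 1), numeric(1)), mem_types),
    n_genes_any_conserved = length(genes_conserved)
  ), class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat("ortholog conservation:", x$n_orthologs, "classified orthologs of",
      x$n_memory_genes_with_ortholog, "memory genes\n")
  for (cc in names(x$category_counts)) {
    cat(sprintf("  %-14s %5d (%s%%)\n", cc, x$category_counts[[cc]],
                format(x$category_pct[[cc]])))
  }
  invisible(x)
}

#' @rdname conservation_summary
#' @param x A `conservation_summary`.
#' @param path Output JSON path.
#' @export
write_conservation_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
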