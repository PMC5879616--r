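#' Construct a validated expression set
#'
#' Bundles a gene-by-sample FPKM matrix with its sample sheet. The sample
#' sheet is authoritative for the condition/replicate structure; column order
#' in the matrix carries no meaning.
#'
#' @param values Numeric matrix of non-negative, finite FPKM values with
#'   unique gene identifiers as rownames and unique sample identifiers as
#'   colnames.
#' @param sheet Data frame with columns `sample_id`, `condition`,
#'   `replicate`; `(condition, replicate)` pairs must be unique and the
#'   sample ids must agree with the matrix columns as a set.
#' @return An object of class `expr_set`: a list with elements `values`
#'   and `sheet` (rows of `sheet` reordered to match `colnames(values)`).
#' @export
expr_set <- function(values, sheet) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  }
  dup <- unique(gid[duplicated(gid)])
  if (length(dup)) {
    stop("duplicated gene id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicated sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("negative or non-finite FPKM at gene '%s', sample '%s'",
                 gid[bad[1, 1]], sid[bad[1, 2]]), call. = FALSE)
  }
  sheet <- validate_sample_sheet(sheet)
  only_m <- setdiff(sid, sheet$sample_id)
  only_s <- setdiff(sheet$sample_id, sid)
  if (length(only_m) || length(only_s)) {
    stop("matrix/sheet sample mismatch; in matrix only: {",
         paste(only_m, collapse = ", "), "}; in sheet only: {",
         paste(only_s, collapse = ", "), "}", call. = FALSE)
  }
  sheet <- sheet[match(sid, sheet$sample_id), , drop = FALSE]
  rownames(sheet) <- NULL
  structure(list(values = values, sheet = sheet), class = "expr_set")
}

validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "condition", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$condition <- as.character(sheet$condition)
  sheet$replicate <- as.integer(sheet$replicate)
  if (anyNA(sheet$replicate) || any(sheet$replicate < 1)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  key <- paste(sheet$condition, sheet$replicate)
  if (anyDuplicated(key)) {
    stop("duplicated (condition, replicate) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  sheet[need]
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples (%d conditions)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sheet$condition))))
  invisible(x)
}

#' Read an expression matrix and its sample sheet
#'
#' The matrix is tab-separated with a `gene_id` first column and one column
#' per sample. The sample sheet (comma- or tab-separated, chosen by file
#' extension) has columns `sample_id`, `condition`, `replicate`. Missing
#' values are not permitted; pre-impute before reading.
#'
#' @param path Path to the TSV expression matrix.
#' @param sample_sheet_path Path to the sample sheet.
#' @return An [expr_set].
#' @export
read_expression <- function(path, sample_sheet_path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("expression matrix needs a gene_id column plus samples",
                           call. = FALSE)
  gid <- raw[[1L]]
  dup <- unique(gid[duplicated(gid)])
  if (length(dup)) {
    stop("duplicated gene id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(gid, colnames(vals))))
  bad <- which(is.na(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or negative FPKM at row %d (gene '%s'), column '%s'",
                 bad[1, 1], gid[bad[1, 1]], colnames(num)[bad[1, 2]]),
         call. = FALSE)
  }
  expr_set(num, read_sample_sheet(sample_sheet_path))
}

read_sample_sheet <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  validate_sample_sheet(utils::read.delim(path, sep = sep, header = TRUE,
                                          check.names = FALSE))
}

#' Write an expression set to disk
#'
#' Emits the matrix as TSV (`gene_id` first column) and the sheet as
#' CSV/TSV by extension, UTF-8 with LF endings and "." decimal separator.
#' Values round-trip through [read_expression()] to at least 12
#' significant digits.
#'
#' @param x An [expr_set].
#' @param path Output path for the matrix TSV.
#' @param sample_sheet_path Output path for the sample sheet.
#' @return Invisibly, `x`.
#' @export
write_expression <- function(x, path, sample_sheet_path) {
  stopifnot(inherits(x, "expr_set"))
  df <- data.frame(gene_id = rownames(x$values),
                   format(x$values, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  write_tsv(df, path)
  sep <- if (grepl("\\.csv$", sample_sheet_path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(x$sheet, sample_sheet_path, sep = sep, quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a two-species ortholog map
#'
#' TSV with header columns `gene_a`, `gene_b` and an optional numeric
#' `score`. Duplicate pairs are collapsed with a warning; many-to-many
#' mappings are permitted.
#'
#' @param path Path to the TSV file.
#' @return Data frame of class `ortholog_map` with unique `(gene_a,
#'   gene_b)` rows and attributes `n_a`/`n_b` (unique gene counts per side).
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  if (!all(c("gene_a", "gene_b") %in% names(df)) || nrow(df) == 0L) {
    stop("ortholog map must be a non-empty TSV with columns gene_a, gene_b",
         call. = FALSE)
  }
  if ("score" %in% names(df)) df$score <- as.numeric(df$score)
  ortholog_map(df)
}

#' @rdname read_ortholog_map
#' @param pairs Data frame with columns `gene_a`, `gene_b` and optional
#'   `score`, used to build the map in code rather than from a file.
#' @export
ortholog_map <- function(pairs) {
  if (nrow(pairs) == 0L) stop("ortholog map is empty", call. = FALSE)
  key <- paste(pairs$gene_a, pairs$gene_b, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate ortholog pair(s) collapsed",
            call. = FALSE)
    pairs <- pairs[!duplicated(key), , drop = FALSE]
  }
  rownames(pairs) <- NULL
  structure(pairs, class = c("ortholog_map", "data.frame"),
            n_a = length(unique(pairs$gene_a)),
            n_b = length(unique(pairs$gene_b)))
}

#' @rdname read_ortholog_map
#' @param x An `ortholog_map`.
#' @export
write_ortholog_map <- function(x, path) {
  write_tsv(as.data.frame(x), path)
  invisible(x)
}

#' Read GMT-style annotation sets
#'
#' One term per line: term id, description, then tab-separated member gene
#' ids. Terms with zero member genes are a hard error.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (one per term) with a
#'   `description` attribute, class `annotation_sets`.
#' @export
read_annotation_sets <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("annotation file is empty", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  ngene <- lengths(parts) - 2L
  if (any(ngene < 1L)) {
    stop("term(s) with zero member genes: ",
         paste(ids[ngene < 1L], collapse = ", "), call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  structure(sets, description = vapply(parts, `[[`, "", 2L),
            class = "annotation_sets")
}

#' @rdname read_annotation_sets
#' @param x An `annotation_sets` object (or plain named list of gene-id
#'   vectors).
#' @export
write_annotation_sets <- function(x, path) {
  desc <- attr(x, "description")
  if (is.null(desc)) desc <- rep("", length(x))
  lines <- vapply(seq_along(x), function(i) {
    paste(c(names(x)[i], desc[i], x[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(x)
}

#' Read a qPCR cycle-threshold table
#'
#' TSV with columns `sample_id`, `condition`, `biological_rep`, `gene_id`,
#' `role` (one of `target`/`reference`) and numeric `ct`. One row per
#' technical replicate. Every `(sample_id, biological_rep)` must carry at
#' least one reference-gene Ct.
#'
#' @param path Path to the TSV file.
#' @return Validated data frame.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  validate_ct_table(df)
}

validate_ct_table <- function(df) {
  need <- c("sample_id", "condition", "biological_rep", "gene_id", "role", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Ct table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(df$role %in% c("target", "reference"))) {
    stop("role must be 'target' or 'reference'", call. = FALSE)
  }
  df$ct <- as.numeric(df$ct)
  if (anyNA(df$ct)) stop("non-numeric ct value(s)", call. = FALSE)
  key <- unique(paste(df$sample_id, df$biological_rep, sep = "\r"))
  ref_key <- unique(paste(df$sample_id, df$biological_rep,
                          sep = "\r")[df$role == "reference"])
  orphan <- setdiff(key, ref_key)
  if (length(orphan)) {
    stop("sample/replicate without a reference-gene Ct: ",
         paste(gsub("\r", "/", orphan), collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a physiology (leaf-weight) table
#'
#' TSV with columns `fresh_weight`, `dry_weight`, `turgid_weight` (grams);
#' any additional identifier columns are passed through untouched.
#'
#' @param path Path to the TSV file.
#' @return Data frame.
#' @export
read_physio_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  need <- c("fresh_weight", "dry_weight", "turgid_weight")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("physiology table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (cn in need) df[[cn]] <- as.numeric(df[[cn]])
  df
}
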