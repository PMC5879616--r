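#' Differential-expression calling criteria
#'
#' The three-part DEG rule: a gene is called up (`+`) or down (`-`) in a
#' contrast when (i) the BH-adjusted q-value is at or below `q_threshold`,
#' (ii) the absolute log2 fold change is at or above `fc_threshold`, and
#' (iii) the gene clears the expression floor: its mean FPKM in the
#' stressed condition (for up calls) or the baseline condition (for down
#' calls) is at least `floor_fraction` of the mean FPKM over all expressed
#' genes in that condition. All thresholds are inclusive.
#'
#' @param q_threshold FDR cut-off (default 0.05).
#' @param fc_threshold Log2 fold-change cut-off (default 1).
#' @param floor_fraction Expression-floor fraction (default 0.20).
#' @param pseudocount Added to FPKM before taking logs (default 1.0).
#' @return List of class `deg_criteria`.
#' @export
deg_criteria <- function(q_threshold = 0.05, fc_threshold = 1,
                         floor_fraction = 0.20, pseudocount = 1.0) {
  stopifnot(q_threshold > 0, fc_threshold > 0, floor_fraction > 0,
            pseudocount > 0)
  structure(list(q_threshold = q_threshold, fc_threshold = fc_threshold,
                 floor_fraction = floor_fraction, pseudocount = pseudocount),
            class = "deg_criteria")
}

cond_matrix <- function(x, condition) {
  keep <- x$sheet$sample_id[x$sheet$condition == condition]
  if (!length(keep)) stop("condition '", condition, "' not found in sample sheet",
                          call. = FALSE)
  x$values[, keep, drop = FALSE]
}

cond_means <- function(x) {
  conds <- unique(x$sheet$condition)
  vapply(conds, function(cc) rowMeans(cond_matrix(x, cc)),
         numeric(nrow(x$values)))
}

#' Mean FPKM over expressed genes in one condition
#'
#' "Expressed" genes are those whose replicate-mean FPKM is greater than
#' zero in at least one condition of the whole design; this fixed gene
#' universe is then averaged (replicate-mean FPKM) within the requested
#' condition. Scaled by the floor fraction, this is the expression floor
#' used by [call_direction()].
#'
#' @param x An [expr_set].
#' @param condition Condition label.
#' @return Non-negative scalar.
#' @export
expressed_mean <- function(x, condition) {
  cm <- cond_means(x)
  if (!condition %in% colnames(cm)) {
    stop("condition '", condition, "' not found in sample sheet", call. = FALSE)
  }
  expressed <- rowSums(cm > 0) > 0
  if (!any(expressed)) stop("no expressed genes in the design", call. = FALSE)
  mean(cm[expressed, condition])
}

#' Convenience: floor values for a contrast
#'
#' Computes `floor_fraction * expressed_mean()` for the up side (condition
#' B, the stressed/later condition) and the down side (condition A, the
#' baseline of the contrast).
#'
#' @param x An [expr_set].
#' @param cond_a,cond_b Baseline and stressed condition labels.
#' @param criteria A [deg_criteria].
#' @return Named list with `floor_up` and `floor_down`.
#' @export
deg_floors <- function(x, cond_a, cond_b, criteria = deg_criteria()) {
  list(floor_up = criteria$floor_fraction * expressed_mean(x, cond_b),
       floor_down = criteria$floor_fraction * expressed_mean(x, cond_a))
}

row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  rowSums((m - rowMeans(m))^2) / (n - 1)
}

welch_pvalues <- function(la, lb) {
  na <- ncol(la); nb <- ncol(lb)
  if (na < 2L || nb < 2L) {
    stop("Welch test needs at least 2 replicates per group; ",
         "use method = 'precomputed' for unreplicated designs", call. = FALSE)
  }
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- row_vars(la); vb <- row_vars(lb)
  se2 <- va / na + vb / nb
  d <- mb - ma
  p <- numeric(length(d))
  zero <- se2 <= 0
  p[zero] <- ifelse(abs(d[zero]) < 1e-12, 1, 0)
  if (any(!zero)) {
    tt <- d[!zero] / sqrt(se2[!zero])
    df <- se2[!zero]^2 /
      ((va[!zero] / na)^2 / (na - 1) + (vb[!zero] / nb)^2 / (nb - 1))
    p[!zero] <- 2 * stats::pt(-abs(tt), df)
  }
  p
}

# Moderated t-test (limma) on per-replicate log2 FPKM: variance shrinkage
# across genes gives usable power at the 2-replicate design.
limma_pvalues <- function(la, lb) {
  na <- ncol(la); nb <- ncol(lb)
  if (na < 2L && nb < 2L) {
    stop("moderated t-test needs replication; use method = 'precomputed'",
         call. = FALSE)
  }
  d <- rowMeans(lb) - rowMeans(la)
  s2 <- (row_vars(la) * (na - 1) + row_vars(lb) * (nb - 1)) / (na + nb - 2)
  s2[is.na(s2)] <- 0
  if (all(s2 < 1e-20)) {
    # degenerate noiseless input: every group is constant
    return(ifelse(abs(d) < 1e-12, 1, 0))
  }
  m <- cbind(la, lb)
  design <- stats::model.matrix(~ rep(c(0, 1), c(na, nb)))
  fit <- limma::eBayes(limma::lmFit(m, design))
  fit$p.value[, 2L]
}

# Two-sided permutation test on the difference of group means, vectorized
# over genes. Exact enumeration of all C(n, na) label splits when the total
# replicate count is <= max_exact; otherwise Monte-Carlo with the given seed.
permutation_pvalues <- function(la, lb, n_perm = 10000L, seed = 20180402L,
                                max_exact = 10L) {
  na <- ncol(la); nb <- ncol(lb); n <- na + nb
  if (na < 2L && nb < 2L) {
    stop("permutation test needs more than 1 replicate per group; ",
         "use method = 'precomputed'", call. = FALSE)
  }
  m <- cbind(la, lb)
  obs <- abs(rowMeans(lb) - rowMeans(la))
  stat_for <- function(idx_a) {
    abs(rowMeans(m[, -idx_a, drop = FALSE]) - rowMeans(m[, idx_a, drop = FALSE]))
  }
  eps <- 1e-12
  if (n <= max_exact) {
    splits <- utils::combn(n, na)
    hits <- matrix(0L, nrow = nrow(m), ncol = ncol(splits))
    for (j in seq_len(ncol(splits))) {
      hits[, j] <- stat_for(splits[, j]) >= obs - eps
    }
    rowMeans(hits)
  } else {
    set.seed(seed)
    cnt <- integer(nrow(m))
    for (b in seq_len(n_perm)) {
      cnt <- cnt + (stat_for(sample.int(n, na)) >= obs - eps)
    }
    (1 + cnt) / (1 + n_perm)
  }
}

#' Compute a per-gene two-condition contrast
#'
#' Log2 fold change is `log2((mean_b + pseudocount) / (mean_a +
#' pseudocount))` on replicate-mean FPKM. P-values come from the chosen
#' method applied to per-replicate `log2(FPKM + pseudocount)` values:
#' `"limma"` (default) a moderated t-test (empirical-Bayes variance
#' shrinkage across genes, the standard choice for designs with very few
#' replicates); `"welch"` a per-gene Welch t-test; `"permutation"` a two-sided
#' permutation test on the difference of group means, enumerating all label
#' reassignments when the contrast has at most 10 replicates in total and
#' Monte-Carlo sampling with `seed` otherwise; `"precomputed"` ingests an
#' external per-gene table (e.g. from a count-model DE engine) and only the
#' condition means are computed here. Q-values are Benjamini-Hochberg over
#' all genes in the table.
#'
#' @param x An [expr_set].
#' @param cond_a,cond_b Baseline and comparison condition labels (fold
#'   change is B over A).
#' @param method One of `"limma"`, `"welch"`, `"permutation"`,
#'   `"precomputed"`.
#' @param precomputed For `method = "precomputed"`: data frame with columns
#'   `gene_id`, `log2fc`, `p_value` and optionally `q_value` (recomputed by
#'   BH when absent).
#' @param criteria A [deg_criteria] (supplies the pseudocount).
#' @param n_perm Monte-Carlo draws for large permutation designs.
#' @param seed Seed for Monte-Carlo permutation.
#' @return Data frame of class `contrast_table` with columns `gene_id`,
#'   `log2fc`, `p_value`, `q_value`, `mean_fpkm_a`, `mean_fpkm_b`, `call`
#'   (all `NA` until [call_direction()] is applied) and attributes
#'   `cond_a`/`cond_b`.
#' @export
compute_contrast <- function(x, cond_a, cond_b,
                             method = c("limma", "welch", "permutation",
                                        "precomputed"),
                             precomputed = NULL, criteria = deg_criteria(),
                             n_perm = 10000L, seed = 20180402L) {
  method <- match.arg(method)
  stopifnot(inherits(x, "expr_set"))
  va <- cond_matrix(x, cond_a)
  vb <- cond_matrix(x, cond_b)
  pc <- criteria$pseudocount
  mean_a <- rowMeans(va)
  mean_b <- rowMeans(vb)
  gene_id <- rownames(x$values)

  if (method == "precomputed") {
    need <- c("gene_id", "log2fc", "p_value")
    if (is.null(precomputed) || !all(need %in% names(precomputed))) {
      stop("precomputed table must have columns gene_id, log2fc, p_value",
           call. = FALSE)
    }
    idx <- match(gene_id, precomputed$gene_id)
    missing <- gene_id[is.na(idx)]
    if (length(missing)) {
      warning(length(missing), " gene(s) absent from the precomputed table ",
              "are excluded from the contrast", call. = FALSE)
      keep <- !is.na(idx)
      gene_id <- gene_id[keep]; mean_a <- mean_a[keep]; mean_b <- mean_b[keep]
      idx <- idx[keep]
    }
    log2fc <- precomputed$log2fc[idx]
    p <- precomputed$p_value[idx]
    q <- if ("q_value" %in% names(precomputed) &&
             !anyNA(precomputed$q_value[idx])) {
      precomputed$q_value[idx]
    } else {
      stats::p.adjust(p, method = "BH")
    }
  } else {
    log2fc <- log2((mean_b + pc) / (mean_a + pc))
    la <- log2(va + pc)
    lb <- log2(vb + pc)
    p <- switch(method,
                limma = limma_pvalues(la, lb),
                welch = welch_pvalues(la, lb),
                permutation = permutation_pvalues(la, lb, n_perm = n_perm,
                                                  seed = seed))
    q <- stats::p.adjust(p, method = "BH")
  }

  res <- data.frame(gene_id = gene_id, log2fc = log2fc, p_value = p,
                    q_value = q, mean_fpkm_a = mean_a, mean_fpkm_b = mean_b,
                    call = NA_character_, row.names = NULL)
  attr(res, "cond_a") <- cond_a
  attr(res, "cond_b") <- cond_b
  class(res) <- c("contrast_table", "data.frame")
  res
}

#' Set direction calls on a contrast table
#'
#' Applies the three-part DEG rule (inclusive thresholds): `+` requires
#' `q <= q_threshold`, `log2fc >= fc_threshold` and `mean_fpkm_b >=
#' floor_value_up`; `-` requires `q <= q_threshold`, `log2fc <=
#' -fc_threshold` and `mean_fpkm_a >= floor_value_down`; everything else is
#' `=`.
#'
#' @param contrast A `contrast_table` from [compute_contrast()].
#' @param criteria A [deg_criteria].
#' @param floor_value_up,floor_value_down Absolute FPKM floors, normally
#'   `floor_fraction * expressed_mean()` of the stressed and baseline
#'   condition respectively (see [deg_floors()]).
#' @return The contrast table with the `call` column set to `+`, `-` or `=`.
#' @export
call_direction <- function(contrast, criteria = deg_criteria(),
                           floor_value_up = 0, floor_value_down = 0) {
  if (anyNA(contrast$q_value)) stop("q_value is unset", call. = FALSE)
  up <- contrast$q_value <= criteria$q_threshold &
    contrast$log2fc >= criteria$fc_threshold &
    contrast$mean_fpkm_b >= floor_value_up
  down <- contrast$q_value <= criteria$q_threshold &
    contrast$log2fc <= -criteria$fc_threshold &
    contrast$mean_fpkm_a >= floor_value_down
  contrast$call <- ifelse(up, "+", ifelse(down, "-", "="))
  contrast
}

#' One-step called contrast
#'
#' Runs [compute_contrast()], derives the expression floors with
#' [deg_floors()], and applies [call_direction()].
#'
#' @inheritParams compute_contrast
#' @return A called `contrast_table`.
#' @export
called_contrast <- function(x, cond_a, cond_b,
                            method = c("limma", "welch", "permutation",
                                       "precomputed"),
                            precomputed = NULL, criteria = deg_criteria(),
                            n_perm = 10000L, seed = 20180402L) {
  ct <- compute_contrast(x, cond_a, cond_b, method = method,
                         precomputed = precomputed, criteria = criteria,
                         n_perm = n_perm, seed = seed)
  fl <- deg_floors(x, cond_a, cond_b, criteria)
  call_direction(ct, criteria, fl$floor_up, fl$floor_down)
}

#' Write a contrast table as TSV
#'
#' @param contrast A `contrast_table`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_contrast <- function(contrast, path) {
  write_tsv(as.data.frame(contrast), path)
  invisible(path)
}

#' Read a contrast table written by [write_contrast()] (or a minimal
#' external table with `gene_id`, `log2fc`, `p_value`).
#'
#' @param path Path to the TSV.
#' @return Data frame.
#' @export
read_contrast <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!all(c("gene_id", "log2fc") %in% names(df))) {
    stop("contrast table must have at least gene_id and log2fc columns",
         call. = FALSE)
  }
  df
}
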