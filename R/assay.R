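#' Relative expression by the delta-delta-Ct method
#'
#' Classic 2^(-ddCt) quantification with a fixed amplification efficiency
#' of 2. Technical replicates are averaged first; then per biological
#' replicate dCt = Ct(target) - Ct(reference); ddCt = dCt - mean dCt of the
#' calibrator condition; RQ = 2^(-ddCt). Biological replicates are
#' aggregated on the log2 scale (mean of -ddCt, exponentiated), so the
#' reported mean RQ is a geometric-type mean and the spread is the SD of
#' log2 RQ. By construction the calibrator condition's mean RQ is exactly 1.
#'
#' @param ct Ct table (see [read_ct_table()]): columns `sample_id`,
#'   `condition`, `biological_rep`, `gene_id`, `role`, `ct`.
#' @param target Target gene id.
#' @param reference Reference (internal control) gene id.
#' @param calibrator_condition Condition used as calibrator.
#' @return List with `per_rep` (condition, biological_rep, delta_ct,
#'   delta_delta_ct, rq, log2_rq) and `summary` (condition, n, rq_mean,
#'   log2_rq_mean, log2_rq_sd).
#' @export
relative_expression_ddct <- function(ct, target, reference,
                                     calibrator_condition) {
  ct <- validate_ct_table(ct)
  tgt <- ct[ct$gene_id == target & ct$role == "target", , drop = FALSE]
  ref <- ct[ct$gene_id == reference & ct$role == "reference", , drop = FALSE]
  if (!nrow(tgt)) stop("no target Ct rows for gene '", target, "'",
                       call. = FALSE)
  key <- function(d) paste(d$condition, d$biological_rep, sep = "\r")
  # technical replicates averaged first
  tmean <- tapply(tgt$ct, key(tgt), mean)
  rmean <- tapply(ref$ct, key(ref), mean)
  orphan <- setdiff(names(tmean), names(rmean))
  if (length(orphan)) {
    smp <- tgt$sample_id[match(orphan, key(tgt))]
    stop("missing reference Ct for sample(s): ",
         paste(unique(smp), collapse = ", "), call. = FALSE)
  }
  cond_rep <- do.call(rbind, strsplit(names(tmean), "\r", fixed = TRUE))
  per <- data.frame(condition = cond_rep[, 1],
                    biological_rep = cond_rep[, 2],
                    delta_ct = as.numeric(tmean) -
                      as.numeric(rmean[names(tmean)]),
                    row.names = NULL)
  if (!calibrator_condition %in% per$condition) {
    stop("calibrator condition '", calibrator_condition,
         "' not present in the Ct table", call. = FALSE)
  }
  cal_mean <- mean(per$delta_ct[per$condition == calibrator_condition])
  per$delta_delta_ct <- per$delta_ct - cal_mean
  per$rq <- 2^(-per$delta_delta_ct)
  per$log2_rq <- -per$delta_delta_ct
  agg <- split(per, per$condition)
  summary <- do.call(rbind, lapply(agg, function(d) {
    data.frame(condition = d$condition[1], n = nrow(d),
               rq_mean = 2^mean(d$log2_rq),
               log2_rq_mean = mean(d$log2_rq),
               log2_rq_sd = stats::sd(d$log2_rq), row.names = NULL)
  }))
  rownames(summary) <- NULL
  list(per_rep = per, summary = summary)
}

#' Compare trained vs untrained relative expression (memory persistence)
#'
#' Welch two-sample t-test on log2 relative quantities over biological
#' replicates, one comparison per replanting interval. A significant
#' difference is labelled `memory-retained`; otherwise `baseline`. Fewer
#' than two biological replicates on either side yields
#' `insufficient-replication`.
#'
#' @param log2_rq_trained,log2_rq_untrained Numeric vectors of log2 RQ per
#'   biological replicate (trained plants under the second stress vs
#'   untrained plants under their first stress).
#' @param alpha Two-sided significance level (default 0.05).
#' @return List with `verdict`, `p_value`, `estimate` (mean log2
#'   difference, trained minus untrained).
#' @export
persistence_compare <- function(log2_rq_trained, log2_rq_untrained,
                                alpha = 0.05) {
  if (length(log2_rq_trained) < 2L || length(log2_rq_untrained) < 2L) {
    return(list(verdict = "insufficient-replication", p_value = NA_real_,
                estimate = mean(log2_rq_trained) - mean(log2_rq_untrained)))
  }
  est <- mean(log2_rq_trained) - mean(log2_rq_untrained)
  v1 <- stats::var(log2_rq_trained); v2 <- stats::var(log2_rq_untrained)
  if (v1 + v2 == 0) {
    p <- if (abs(est) < 1e-12) 1 else 0
  } else {
    p <- stats::t.test(log2_rq_trained, log2_rq_untrained,
                       var.equal = FALSE)$p.value
  }
  list(verdict = if (p < alpha) "memory-retained" else "baseline",
       p_value = p, estimate = est)
}

#' Relative water content
#'
#' `RWC (%) = (fresh - dry) / (turgid - dry) * 100`. Scale-invariant in
#' the three weights. Values outside [0, 100] (i.e. inputs violating
#' `dry <= fresh <= turgid`) are returned but flagged.
#'
#' @param fresh_weight,dry_weight,turgid_weight Weights (g), vectorized.
#' @return Numeric vector of percentages with a logical attribute
#'   `flagged` marking out-of-range values.
#' @export
rwc <- function(fresh_weight, dry_weight, turgid_weight) {
  if (any(turgid_weight <= dry_weight)) {
    stop("turgid weight must exceed dry weight", call. = FALSE)
  }
  out <- (fresh_weight - dry_weight) / (turgid_weight - dry_weight) * 100
  structure(out, flagged = out < 0 | out > 100)
}

#' Water loss from detached leaves
#'
#' Fraction of the initial fresh weight lost at each time point:
#' `loss(t) = (w0 - w(t)) / w0`. Time must be strictly increasing and
#' weights positive. The result carries a `monotone` attribute, `FALSE`
#' when the loss series ever decreases (i.e. apparent weight gain).
#'
#' @param time Numeric vector, strictly increasing; the first entry is the
#'   reference point.
#' @param weight Positive weights at each time.
#' @return Data frame (`time`, `weight`, `loss_fraction`) with attribute
#'   `monotone`.
#' @export
water_loss_curve <- function(time, weight) {
  if (length(time) != length(weight)) stop("time/weight length mismatch",
                                           call. = FALSE)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing",
                                 call. = FALSE)
  if (any(weight <= 0)) stop("weights must be positive", call. = FALSE)
  loss <- (weight[1] - weight) / weight[1]
  structure(data.frame(time = time, weight = weight, loss_fraction = loss),
            monotone = all(diff(loss) >= 0))
}
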