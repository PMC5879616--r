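#' Simulation configuration for planted-class expression data
#'
#' Emulates the repeated-stress RNA-seq design: four conditions (control
#' C1, first stress D1, recovery R1, second stress D2) with two biological
#' replicates each, lognormal baseline expression, and per-contrast planted
#' log2 fold changes that realize a chosen memory class per gene.
#'
#' @param n_per_class Named integer vector: genes per memory class. Names
#'   must be the nine `[a/b]` types ([memory_types]); defaults to 200 per
#'   class.
#' @param baseline_log2_mean,baseline_log2_sd Baseline log2-FPKM
#'   distribution (defaults 5 and 1.5).
#' @param delta Planted log2 fold-change magnitude per contrast (default 3).
#' @param noise_sd Replicate noise SD on the log2 scale (default 0.25).
#' @param replicates Biological replicates per condition (default 2).
#' @param conditions Condition labels, in order control, first stress,
#'   recovery, second stress.
#' @param floor_margin_log2 Extra log2 headroom enforced between every
#'   planted-DEG gene and the 20% expression floor (default 0.75), so that
#'   class identity is decided by the contrasts rather than by floor
#'   boundary effects.
#' @param seed Mandatory integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_per_class = stats::setNames(rep(200L, 9), memory_types),
                       baseline_log2_mean = 5, baseline_log2_sd = 1.5,
                       delta = 3, noise_sd = 0.25, replicates = 2L,
                       conditions = c("C1", "D1", "R1", "D2"),
                       floor_margin_log2 = 0.75, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(names(n_per_class)) ||
      !all(names(n_per_class) %in% memory_types)) {
    stop("n_per_class must be named by memory types", call. = FALSE)
  }
  if (any(n_per_class < 0)) stop("negative gene counts", call. = FALSE)
  stopifnot(noise_sd >= 0, baseline_log2_sd >= 0, replicates >= 1,
            length(conditions) == 4)
  structure(list(n_per_class = n_per_class,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 delta = delta, noise_sd = noise_sd,
                 replicates = as.integer(replicates),
                 conditions = conditions,
                 floor_margin_log2 = floor_margin_log2,
                 seed = as.integer(seed)),
            class = "sim_config")
}

parse_type <- function(type) {
  # "[a/b]" -> c(a, b)
  c(substr(type, 2, 2), substr(type, 4, 4))
}

dir_sign <- function(sym) c("+" = 1, "-" = -1, "=" = 0)[sym]

#' Generate an expression matrix with planted memory classes
#'
#' Condition means are constructed so that the planted class holds by
#' definition at zero noise: e.g. for class `[+/+]`, D1 = C1 + delta and
#' D2 = D1 + delta on the log2 scale; the recovery condition sits at the
#' control level. Baselines of planted differential genes are lifted, where
#' needed, until the relevant condition clears the 20% expression floor
#' (plus `floor_margin_log2`) and the pseudocounted fold change clears the
#' threshold, so the planted class is consistent with the DEG criteria.
#' Replicate FPKM values are `2^(condition mean + N(0, noise_sd))`.
#' Generation is a pure function of the config: the same seed yields
#' identical output.
#'
#' @param config A [sim_config].
#' @return List with `expr` (an [expr_set]), `truth` (gene_id, class,
#'   call_first, call_second, planted log2 condition means) and `config`.
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  npc <- config$n_per_class
  classes <- rep(names(npc), npc)
  n <- length(classes)
  if (n == 0L) stop("no genes requested", call. = FALSE)
  gene_id <- sprintf("SYNG%05d", seq_len(n))
  base <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)

  d1 <- vapply(classes, function(cl) dir_sign(parse_type(cl)[1]), numeric(1))
  d2 <- vapply(classes, function(cl) dir_sign(parse_type(cl)[2]), numeric(1))
  delta <- config$delta
  marg <- config$floor_margin_log2
  ff <- 0.20          # floor fraction the planted classes are guarded against
  fc_min <- 1 + 0.1   # pseudocounted |log2FC| headroom for planted DEGs

  for (iter in 1:200) {
    mC <- base
    mD1 <- base + delta * d1
    mD2 <- mD1 + delta * d2
    fC <- 2^mC; fD1 <- 2^mD1; fD2 <- 2^mD2
    floorC <- ff * mean(fC); floorD1 <- ff * mean(fD1); floorD2 <- ff * mean(fD2)

    # required log2 level per gene on the side the floor rule inspects
    req <- rep(-Inf, n)
    req <- pmax(req, ifelse(d1 > 0, log2(floorD1) + marg - mD1, -Inf) + base)
    req <- pmax(req, ifelse(d1 < 0, log2(floorC) + marg, -Inf))
    req <- pmax(req, ifelse(d2 > 0, log2(floorD2) + marg - mD2 + base, -Inf))
    req <- pmax(req, ifelse(d2 < 0, log2(floorD1) + marg - mD1 + base, -Inf))
    # pseudocounted fold-change headroom (relevant only at very low FPKM)
    fc1 <- abs(log2((fD1 + 1) / (fC + 1)))
    fc2 <- abs(log2((fD2 + 1) / (fD1 + 1)))
    low <- (d1 != 0 & fc1 < fc_min) | (d2 != 0 & fc2 < fc_min)
    req <- pmax(req, ifelse(low, base + 1, -Inf))

    viol <- which(base < req)
    if (!length(viol)) break
    base[viol] <- req[viol] + 0.01
    if (iter == 200) stop("floor-consistency enforcement did not converge",
                          call. = FALSE)
  }

  cond <- config$conditions
  means <- cbind(mC, mD1, base, mD2)   # C1, D1, R1 (= control level), D2
  colnames(means) <- cond[c(1, 2, 3, 4)]
  means[, cond[3]] <- base

  reps <- config$replicates
  samples <- as.vector(t(outer(cond, seq_len(reps),
                               function(cc, r) paste0(cc, "_r", r))))
  values <- matrix(NA_real_, n, length(samples),
                   dimnames = list(gene_id, samples))
  for (cc in cond) {
    for (r in seq_len(reps)) {
      eps <- stats::rnorm(n, 0, config$noise_sd)
      values[, paste0(cc, "_r", r)] <- 2^(means[, cc] + eps)
    }
  }
  sheet <- data.frame(sample_id = samples,
                      condition = rep(cond, each = reps),
                      replicate = rep(seq_len(reps), times = length(cond)))
  truth <- data.frame(gene_id = gene_id, class = classes,
                      call_first = substr(classes, 2, 2),
                      call_second = substr(classes, 4, 4),
                      log2_c1 = means[, cond[1]], log2_d1 = means[, cond[2]],
                      log2_r1 = means[, cond[3]], log2_d2 = means[, cond[4]],
                      row.names = NULL)
  list(expr = expr_set(values, sheet), truth = truth, config = config)
}

#' Generate an ortholog map with a planted conservation rate
#'
#' Wires each sampled species-A memory gene to a species-B gene so that a
#' pair is `conserved-same-type` with probability `conservation_rate`
#' (Bernoulli per pair); the remainder are distributed over the other
#' categories according to `category_props`.
#'
#' @param truth_a,truth_b Truth tables from [generate_expression()] (need
#'   columns `gene_id`, `class`).
#' @param conservation_rate Probability in [0, 1] that a pair is conserved
#'   with the identical memory type.
#' @param seed Integer seed.
#' @param n_pairs Number of pairs to draw (default: one per species-A
#'   memory gene).
#' @param category_props Named proportions (renormalized over the
#'   non-conserved remainder) for `memory-different-type`, `non-memory`,
#'   `late-response`, `non-response`.
#' @return List with `map` (an `ortholog_map`), `pair_truth` (planted
#'   category per pair) and `expected` (expected category counts).
#' @export
generate_ortholog_map <- function(truth_a, truth_b, conservation_rate, seed,
                                  n_pairs = NULL,
                                  category_props = c(
                                    "memory-different-type" = 0.09,
                                    "non-memory" = 0.21,
                                    "late-response" = 0.17,
                                    "non-response" = 0.53)) {
  if (conservation_rate < 0 || conservation_rate > 1) {
    stop("conservation_rate must be in [0, 1]", call. = FALSE)
  }
  mem <- memory_types[1:4]
  a_pool <- truth_a[truth_a$class %in% mem, , drop = FALSE]
  if (!nrow(a_pool)) stop("truth_a contains no memory genes", call. = FALSE)
  if (is.null(n_pairs)) n_pairs <- nrow(a_pool)
  set.seed(seed)
  idx <- if (n_pairs <= nrow(a_pool)) {
    sample.int(nrow(a_pool), n_pairs)
  } else {
    sample.int(nrow(a_pool), n_pairs, replace = TRUE)
  }
  gene_a <- a_pool$gene_id[idx]
  class_a <- a_pool$class[idx]

  props <- category_props / sum(category_props)
  cats <- ifelse(stats::runif(n_pairs) < conservation_rate,
                 "conserved-same-type",
                 sample(names(props), n_pairs, replace = TRUE, prob = props))

  class_pool <- split(truth_b$gene_id, truth_b$class)
  pool_for <- function(cat, cls) {
    switch(cat,
           "conserved-same-type" = class_pool[[cls]],
           "memory-different-type" =
             unlist(class_pool[setdiff(mem, cls)], use.names = FALSE),
           "non-memory" = unlist(class_pool[memory_types[5:6]],
                                 use.names = FALSE),
           "late-response" = unlist(class_pool[memory_types[7:8]],
                                    use.names = FALSE),
           "non-response" = class_pool[["[=/=]"]])
  }
  gene_b <- vapply(seq_len(n_pairs), function(i) {
    pool <- pool_for(cats[i], class_a[i])
    if (!length(pool)) stop("truth_b lacks genes for category ", cats[i],
                            call. = FALSE)
    pool[sample.int(length(pool), 1L)]
  }, "")

  # many-to-many duplicates are legitimate; collapse exact duplicates only
  pairs <- data.frame(gene_a = gene_a, gene_b = gene_b)
  dup <- duplicated(paste(gene_a, gene_b, sep = "\r"))
  expected <- c("conserved-same-type" = n_pairs * conservation_rate,
                (1 - conservation_rate) * n_pairs * props)
  list(map = suppressWarnings(ortholog_map(pairs)),
       pair_truth = data.frame(gene_a = gene_a, gene_b = gene_b,
                               planted_category = cats)[!dup, ],
       expected = expected)
}

#' Generate a qPCR Ct table with planted memory persistence
#'
#' Emulates the persistence assay: trained plants (one prior
#' stress/recovery cycle) and untrained plants are replanted for a set of
#' intervals, then stressed and assayed by qPCR. For memory genes the
#' trained response exceeds the untrained response by `effect *
#' decay[interval]` log2 units; non-memory genes respond identically in
#' both groups. Reference-gene Ct is constant across samples up to noise.
#'
#' @param genes Data frame with columns `gene_id` and logical `memory`.
#' @param intervals Replanting intervals in days (default 3, 5, 7).
#' @param decay Named numeric vector mapping interval to the retained
#'   fraction of the planted effect (default `c("3" = 1, "5" = 0.9,
#'   "7" = 0.1)`).
#' @param effect Planted log2 memory effect at full retention (default 3).
#' @param d1_response Log2 response of an untrained plant to its first
#'   stress (default 2).
#' @param base_ct,ref_ct Baseline target and reference Ct (defaults 26, 20).
#' @param ct_noise SD of Ct noise per technical replicate (default 0.1).
#' @param bio_noise SD of per-biological-replicate Ct shift (default 0.1).
#' @param n_biological,n_technical Replicates (defaults 3 and 3).
#' @param seed Integer seed.
#' @return List with `ct` (a Ct table as in [read_ct_table()]; conditions
#'   `C`, `D1_day<d>`, `D2_day<d>`; reference gene `REF`) and `truth`
#'   (gene, interval, planted log2 trained-minus-untrained difference).
#' @export
generate_ct_table <- function(genes, intervals = c(3, 5, 7),
                              decay = c("3" = 1, "5" = 0.9, "7" = 0.1),
                              effect = 3, d1_response = 2,
                              base_ct = 26, ref_ct = 20,
                              ct_noise = 0.1, bio_noise = 0.1,
                              n_biological = 3L, n_technical = 3L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (!all(as.character(intervals) %in% names(decay))) {
    stop("decay must name every interval", call. = FALSE)
  }
  set.seed(seed)
  conds <- c("C", as.vector(rbind(paste0("D1_day", intervals),
                                  paste0("D2_day", intervals))))
  expr_for <- function(gene_mem, cond) {
    if (cond == "C") return(0)
    d <- sub("^D[12]_day", "", cond)
    if (startsWith(cond, "D1_")) d1_response
    else d1_response + ifelse(gene_mem, effect * decay[[d]], 0)
  }
  rows <- list()
  truth <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes$gene_id[gi]; gmem <- genes$memory[gi]
    for (cond in conds) {
      mu <- expr_for(gmem, cond)
      for (b in seq_len(n_biological)) {
        shift <- stats::rnorm(1, 0, bio_noise)
        smp <- paste0(cond, "_b", b)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = smp, condition = cond, biological_rep = b,
          gene_id = g, role = "target",
          ct = base_ct - mu + shift + stats::rnorm(n_technical, 0, ct_noise))
      }
    }
    for (d in intervals) {
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = g, interval = d,
        planted_log2_diff = if (gmem) effect * decay[[as.character(d)]] else 0)
    }
  }
  # one shared reference gene per sample
  for (cond in conds) {
    for (b in seq_len(n_biological)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste0(cond, "_b", b), condition = cond,
        biological_rep = b, gene_id = "REF", role = "reference",
        ct = ref_ct + stats::rnorm(n_technical, 0, ct_noise))
    }
  }
  list(ct = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' End-to-end recovery of planted classes
#'
#' Runs the full classification pipeline (two called contrasts, memory
#' typing) on a generated dataset and reports the fraction of genes whose
#' assigned class equals the planted class.
#'
#' @param sim Output of [generate_expression()].
#' @param criteria A [deg_criteria].
#' @param method Test method passed to [called_contrast()].
#' @return List with `recovery` (fraction in [0, 1]), `n`, and the
#'   assignment table merged with the truth.
#' @export
class_recovery <- function(sim, criteria = deg_criteria(),
                           method = "limma") {
  cond <- sim$config$conditions
  c1 <- called_contrast(sim$expr, cond[1], cond[2], method = method,
                        criteria = criteria)
  c2 <- called_contrast(sim$expr, cond[2], cond[4], method = method,
                        criteria = criteria)
  assign <- classify_memory(c1, c2)
  merged <- merge(assign, sim$truth[, c("gene_id", "class")], by = "gene_id")
  list(recovery = mean(merged$memory_type == merged$class),
       n = nrow(merged), table = merged)
}
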