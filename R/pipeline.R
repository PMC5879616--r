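#' Run the stress-memory analysis pipeline
#'
#' Orchestrates the stages behind a single configuration: `simulate`
#' (planted-truth expression data), `contrast` (the two called contrasts),
#' `classify` (memory typing), `summarize`, `venn`, `enrich`, `conserve`,
#' `ddct`, `physio`, or `all`. Every stage writes plain-text artifacts to
#' `outdir` plus a `manifest.json` recording the configuration, its hash,
#' the seed and the package version, sufficient to reproduce any output.
#' Partially written files keep a `.partial` suffix if a stage fails.
#'
#' Configuration (YAML file or R list) fields, all optional unless the
#' requested stage needs them:
#' \describe{
#'   \item{seed}{integer, required.}
#'   \item{criteria}{q_threshold, fc_threshold, floor_fraction, pseudocount.}
#'   \item{method}{"welch", "permutation" or "precomputed".}
#'   \item{contrasts}{memory_pair (first: c(A,B), second: c(A,B)) and
#'     venn_pair (the two conditions each compared to the control for the
#'     overlap analysis); defaults first = C1 vs D1, second = D1 vs D2,
#'     venn = D1 and D2 each vs C1.}
#'   \item{simulate}{arguments for [sim_config()].}
#'   \item{expression, sample_sheet}{input paths when not simulating.}
#'   \item{annotations}{GMT path for the enrich stage.}
#'   \item{ortholog_map, assignments_b}{paths for the conserve stage.}
#'   \item{ct_table, ddct}{Ct TSV path and target/reference/calibrator.}
#'   \item{physio}{physiology TSV path.}
#' }
#'
#' @param subcommand One of `simulate`, `contrast`, `classify`,
#'   `summarize`, `venn`, `enrich`, `conserve`, `ddct`, `physio`, `all`.
#' @param config YAML path or named list.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, a named list of the paths written.
#' @export
run_pipeline <- function(subcommand, config, outdir = ".") {
  stages <- c("simulate", "contrast", "classify", "summarize", "venn",
              "enrich", "conserve", "ddct", "physio", "all")
  if (!subcommand %in% stages) {
    config_error("subcommand", "must be one of ", paste(stages, collapse = ", "))
  }
  cfg <- load_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  env <- new.env(parent = emptyenv())

  todo <- if (subcommand == "all") {
    c(if (!is.null(cfg$simulate)) "simulate",
      "contrast", "classify", "summarize", "venn",
      if (!is.null(cfg$annotations)) "enrich",
      if (!is.null(cfg$ortholog_map)) "conserve",
      if (!is.null(cfg$ct_table)) "ddct",
      if (!is.null(cfg$physio)) "physio")
  } else subcommand
  for (st in todo) {
    out <- c(out, switch(st,
      simulate = stage_simulate(cfg, outdir, env),
      contrast = stage_contrast(cfg, outdir, env),
      classify = stage_classify(cfg, outdir, env),
      summarize = stage_summarize(cfg, outdir, env),
      venn = stage_venn(cfg, outdir, env),
      enrich = stage_enrich(cfg, outdir, env),
      conserve = stage_conserve(cfg, outdir, env),
      ddct = stage_ddct(cfg, outdir, env),
      physio = stage_physio(cfg, outdir, env)))
  }
  out$manifest <- write_manifest(cfg, outdir, out)
  invisible(out)
}

config_error <- function(field, ...) {
  stop(structure(class = c("pipeline_config_error", "error", "condition"),
                 list(message = paste0("config field '", field, "': ", ...),
                      call = NULL)))
}

load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) config_error("(path)", "file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("(root)", "must be a list or YAML path")
  if (is.null(config$seed)) config_error("seed", "is required")
  config$seed <- as.integer(config$seed)
  config
}

cfg_criteria <- function(cfg) {
  cr <- cfg$criteria
  deg_criteria(q_threshold = cr$q_threshold %||% 0.05,
               fc_threshold = cr$fc_threshold %||% 1,
               floor_fraction = cr$floor_fraction %||% 0.20,
               pseudocount = cr$pseudocount %||% 1.0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cfg_pairs <- function(cfg) {
  ct <- cfg$contrasts
  list(first = unlist(ct$memory_pair$first %||% c("C1", "D1")),
       second = unlist(ct$memory_pair$second %||% c("D1", "D2")),
       venn_control = ct$venn_pair$control %||% "C1",
       venn_conditions = unlist(ct$venn_pair$conditions %||% c("D1", "D2")))
}

# write to <path>.partial, rename into place on success
deliver <- function(path, writer) {
  tmp <- paste0(path, ".partial")
  writer(tmp)
  file.rename(tmp, path)
  path
}

need_file <- function(cfg, field) {
  p <- cfg[[field]]
  if (is.null(p)) config_error(field, "is required for this stage")
  if (!file.exists(p)) config_error(field, "file not found: ", p)
  p
}

get_expr <- function(cfg, outdir, env) {
  if (!is.null(env$expr)) return(env$expr)
  if (!is.null(cfg$expression)) {
    env$expr <- read_expression(need_file(cfg, "expression"),
                                need_file(cfg, "sample_sheet"))
  } else {
    mp <- file.path(outdir, "expression.tsv")
    sp <- file.path(outdir, "sample_sheet.tsv")
    if (!file.exists(mp)) {
      config_error("expression", "no expression input and no simulated matrix at ", mp)
    }
    env$expr <- read_expression(mp, sp)
  }
  env$expr
}

stage_simulate <- function(cfg, outdir, env) {
  sc <- cfg$simulate %||% list()
  npc <- if (!is.null(sc$n_per_class)) {
    stats::setNames(as.integer(unlist(sc$n_per_class)),
                    names(sc$n_per_class))
  } else stats::setNames(rep(200L, 9), memory_types)
  config <- sim_config(n_per_class = npc,
                       baseline_log2_mean = sc$baseline_log2_mean %||% 5,
                       baseline_log2_sd = sc$baseline_log2_sd %||% 1.5,
                       delta = sc$delta %||% 3,
                       noise_sd = sc$noise_sd %||% 0.25,
                       replicates = sc$replicates %||% 2L,
                       seed = cfg$seed)
  sim <- generate_expression(config)
  env$expr <- sim$expr
  env$truth <- sim$truth
  list(expression = deliver(file.path(outdir, "expression.tsv"), function(p) {
         write_expression(sim$expr, p, file.path(outdir, "sample_sheet.tsv"))
       }),
       sample_sheet = file.path(outdir, "sample_sheet.tsv"),
       truth = deliver(file.path(outdir, "truth.tsv"),
                       function(p) write_tsv(sim$truth, p)))
}

stage_contrast <- function(cfg, outdir, env) {
  x <- get_expr(cfg, outdir, env)
  pr <- cfg_pairs(cfg)
  crit <- cfg_criteria(cfg)
  method <- cfg$method %||% "welch"
  env$contrast_first <- called_contrast(x, pr$first[1], pr$first[2],
                                        method = method, criteria = crit,
                                        seed = cfg$seed)
  env$contrast_second <- called_contrast(x, pr$second[1], pr$second[2],
                                         method = method, criteria = crit,
                                         seed = cfg$seed)
  list(contrast_first = deliver(file.path(outdir, "contrast_first.tsv"),
         function(p) write_contrast(env$contrast_first, p)),
       contrast_second = deliver(file.path(outdir, "contrast_second.tsv"),
         function(p) write_contrast(env$contrast_second, p)))
}

get_contrasts <- function(cfg, outdir, env) {
  if (is.null(env$contrast_first)) {
    p1 <- cfg$contrast_first %||% file.path(outdir, "contrast_first.tsv")
    p2 <- cfg$contrast_second %||% file.path(outdir, "contrast_second.tsv")
    if (!file.exists(p1)) config_error("contrast_first", "file not found: ", p1)
    if (!file.exists(p2)) config_error("contrast_second", "file not found: ", p2)
    env$contrast_first <- read_contrast(p1)
    env$contrast_second <- read_contrast(p2)
  }
  list(first = env$contrast_first, second = env$contrast_second)
}

stage_classify <- function(cfg, outdir, env) {
  ct <- get_contrasts(cfg, outdir, env)
  env$assignments <- classify_memory(ct$first, ct$second)
  list(assignments = deliver(file.path(outdir, "assignments.tsv"),
         function(p) write_assignments(env$assignments, p)))
}

get_assignments <- function(cfg, outdir, env) {
  if (is.null(env$assignments)) {
    p <- cfg$assignments %||% file.path(outdir, "assignments.tsv")
    if (!file.exists(p)) config_error("assignments", "file not found: ", p)
    env$assignments <- utils::read.delim(p, sep = "\t")
  }
  env$assignments
}

stage_summarize <- function(cfg, outdir, env) {
  sm <- summarize_memory(get_assignments(cfg, outdir, env))
  counts <- data.frame(memory_type = names(sm$type_counts),
                       count = sm$type_counts,
                       category = unname(memory_categories[names(sm$type_counts)]),
                       row.names = NULL)
  list(summary_tsv = deliver(file.path(outdir, "summary.tsv"),
         function(p) write_tsv(counts, p)),
       summary_json = deliver(file.path(outdir, "summary.json"),
         function(p) write_summary_json(sm, p)))
}

stage_venn <- function(cfg, outdir, env) {
  x <- get_expr(cfg, outdir, env)
  pr <- cfg_pairs(cfg)
  crit <- cfg_criteria(cfg)
  method <- cfg$method %||% "welch"
  ctrl <- pr$venn_control
  cA <- called_contrast(x, ctrl, pr$venn_conditions[1], method = method,
                        criteria = crit, seed = cfg$seed)
  cB <- called_contrast(x, ctrl, pr$venn_conditions[2], method = method,
                        criteria = crit, seed = cfg$seed)
  a <- stats::setNames(cA$call, cA$gene_id)
  b <- stats::setNames(cB$call, cB$gene_id)
  rows <- do.call(rbind, lapply(c("+", "-"), function(dd) {
    v <- venn_sets(a, b, dd)
    data.frame(direction = dd, n_a = v$n_a, n_b = v$n_b,
               n_common = v$n_common, n_only_a = v$n_only_a,
               n_only_b = v$n_only_b, n_union = v$n_union)
  }))
  list(venn = deliver(file.path(outdir, "venn.tsv"),
                      function(p) write_tsv(rows, p)))
}

stage_enrich <- function(cfg, outdir, env) {
  ann <- read_annotation_sets(need_file(cfg, "annotations"))
  assign <- get_assignments(cfg, outdir, env)
  selected <- assign$gene_id[assign$category == "memory"]
  res <- enrich_terms(selected, assign$gene_id, ann)
  list(enrichment = deliver(file.path(outdir, "enrichment.tsv"),
                            function(p) write_tsv(res, p)))
}

stage_conserve <- function(cfg, outdir, env) {
  map <- read_ortholog_map(need_file(cfg, "ortholog_map"))
  assign_a <- get_assignments(cfg, outdir, env)
  assign_b <- utils::read.delim(need_file(cfg, "assignments_b"), sep = "\t")
  rec <- classify_pairs(map, assign_a, assign_b)
  sm <- conservation_summary(rec, sum(assign_a$category == "memory"))
  list(conservation_records = deliver(file.path(outdir, "conservation.tsv"),
         function(p) write_tsv(rec, p)),
       conservation_summary = deliver(file.path(outdir, "conservation.json"),
         function(p) write_conservation_json(sm, p)))
}

stage_ddct <- function(cfg, outdir, env) {
  ct <- read_ct_table(need_file(cfg, "ct_table"))
  dd <- cfg$ddct
  for (f in c("target", "reference", "calibrator")) {
    if (is.null(dd[[f]])) config_error(paste0("ddct$", f), "is required")
  }
  res <- relative_expression_ddct(ct, dd$target, dd$reference, dd$calibrator)
  list(ddct = deliver(file.path(outdir, "ddct.tsv"),
                      function(p) write_tsv(res$summary, p)))
}

stage_physio <- function(cfg, outdir, env) {
  ph <- read_physio_table(need_file(cfg, "physio"))
  r <- rwc(ph$fresh_weight, ph$dry_weight, ph$turgid_weight)
  ph$rwc_percent <- as.numeric(r)
  ph$flagged <- attr(r, "flagged")
  list(physio = deliver(file.path(outdir, "rwc.tsv"),
                        function(p) write_tsv(ph, p)))
}

write_manifest <- function(cfg, outdir, out) {
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    config = cfg,
    config_md5 = unname(tools::md5sum(tmp)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("stressmem")),
    outputs = lapply(out, function(p) {
      if (is.character(p) && file.exists(p)) unname(tools::md5sum(p)) else NULL
    }))
  unlink(tmp)
  deliver(file.path(outdir, "manifest.json"), function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         na = "null")
  })
}
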