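#' Run the full pipeline from a configuration
#'
#' Orchestrates preprocess -> differential -> enrichment gate ->
#' connectivity -> ranking for every patient pair in the expression input,
#' writing per-patient result files plus a machine-readable run manifest
#' (JSON) recording the configuration, its hash, the seed, gene-universe
#' intersection sizes and the counts at each stage. Reruns with the same
#' configuration and seed produce byte-identical outputs.
#'
#' The configuration is a YAML file or an equivalent named list:
#'
#' ```yaml
#' expression: expr.tsv        # or .gct
#' gmt: pathways.gmt
#' bank: bank_dir/             # instances.tsv + ranks.tsv
#' pairs: {P1: [P1_pre, P1_post]}
#' out_dir: results/
#' preprocess: {log2: false, log2_offset: 0, quantile: true,
#'              snr_threshold: 2, snr_keep_rule: at_least_threshold}
#' fold_threshold: 2
#' enrichment: {method: ks_permutation, alpha: 0.05, n_perm: 1000}
#' connectivity: {mode: combined, halve: true}
#' counting: {alpha: 0.05, min_abs_score: 0}
#' k: 10
#' seed: 1
#' ```
#'
#' `preprocess.noise` (per-sample noise estimates) enables the SNR filter,
#' which is applied before normalization. Under-specified method choices
#' (enrichment flavor, score combination, SNR keep rule) are echoed as
#' warnings on first use so every report states the conventions it used.
#'
#' @param config Path to a YAML config or a named list as above.
#' @return Invisibly, a list with one [pbsc()] fit per patient and the
#'   manifest, which is also written to `out_dir/manifest.json`.
#' @export
run_pbsc <- function(config) {
  cfg <- .load_config(config)
  for (p in c(cfg$expression, cfg$gmt, cfg$bank))
    if (!file.exists(p) && !dir.exists(p)) stop("input not found: ", p)

  pairs <- .pairs_from_config(cfg)
  expr <- read_expression_matrix(cfg$expression, pairs = pairs)
  pathways <- read_gmt(cfg$gmt)
  bank <- if (dir.exists(cfg$bank)) read_reference_bank(cfg$bank)
          else read_reference_bank(cfg$bank, cfg$bank_ranks)

  pp <- cfg$preprocess
  if (!is.null(pp$noise)) {
    warning("SNR filter uses keep rule '", pp$snr_keep_rule,
            "' (threshold ", pp$snr_threshold, "), applied before normalization")
    expr <- snr_filter(expr, unlist(pp$noise), threshold = pp$snr_threshold,
                       keep = pp$snr_keep_rule)
  }
  if (isTRUE(pp$log2)) expr <- log2_transform(expr, offset = pp$log2_offset)
  if (isTRUE(pp$quantile)) expr <- quantile_normalize(expr)

  warning("enrichment mode '", cfg$enrichment$method,
          "'; connectivity mode '", cfg$connectivity$mode,
          "' (halve = ", cfg$connectivity$halve, ")")

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- list()
  stage_counts <- list()
  for (patient in expr$pairs$patient) {
    fit <- suppressMessages(pbsc(
      expr, bank, pathways, patient = patient,
      fold_threshold = cfg$fold_threshold,
      enrichment_method = cfg$enrichment$method,
      enrichment_alpha = cfg$enrichment$alpha,
      n_perm = cfg$enrichment$n_perm,
      connectivity_mode = cfg$connectivity$mode,
      halve = cfg$connectivity$halve,
      count_alpha = cfg$counting$alpha,
      min_abs_score = cfg$counting$min_abs_score,
      k = cfg$k, seed = cfg$seed))
    write_pbsc(fit, cfg$out_dir)
    fits[[patient]] <- fit
    stage_counts[[patient]] <- list(
      n_up = length(fit$signature$up), n_down = length(fit$signature$down),
      n_pathways_tested = nrow(fit$enrichment),
      n_pathways_selected = length(fit$selected),
      status = if (length(fit$selected)) "ok" else "no pathways selected",
      n_connectivity_cells = nrow(fit$connectivity),
      n_instances_reported = nrow(fit$report))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("pbsc")),
    config = cfg,
    config_hash = .config_hash(cfg),
    seed = cfg$seed,
    universe = list(expression_genes = nrow(expr$values),
                    bank_genes = length(gene_universe(bank)),
                    shared_genes = length(intersect(rownames(expr$values),
                                                    gene_universe(bank)))),
    stages = stage_counts)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(fits = fits, manifest = manifest))
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a YAML path or a named list")
  defaults <- list(
    preprocess = list(log2 = FALSE, log2_offset = 0, quantile = TRUE,
                      snr_threshold = 2,
                      snr_keep_rule = "at_least_threshold", noise = NULL),
    fold_threshold = 2,
    enrichment = list(method = "ks_permutation", alpha = 0.05, n_perm = 1000),
    connectivity = list(mode = "combined", halve = TRUE),
    counting = list(alpha = 0.05, min_abs_score = 0),
    k = 10, seed = 1L, out_dir = "pbsc_results")
  cfg <- utils::modifyList(defaults, config)
  for (key in c("expression", "gmt", "bank"))
    if (is.null(cfg[[key]])) stop("config is missing required key: ", key)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.pairs_from_config <- function(cfg) {
  if (is.null(cfg$pairs)) return(NULL)
  if (is.data.frame(cfg$pairs)) return(cfg$pairs)
  data.frame(patient = names(cfg$pairs),
             pre = vapply(cfg$pairs, `[[`, "", 1L),
             post = vapply(cfg$pairs, `[[`, "", 2L),
             stringsAsFactors = FALSE, row.names = NULL)
}

.config_hash <- function(cfg) {
  canonical <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # md5 of the canonical JSON; identifies a run configuration in the manifest
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(canonical, f)
  unname(tools::md5sum(f))
}

#' Diagnose identifier compatibility of the pipeline inputs
#'
#' Reports, without running the pipeline, the gene-identifier overlap
#' between the expression matrix, the reference bank and the pathway
#' collection, duplicate identifiers encountered, and patients with a
#' missing or incomplete pre/post pair. A zero expression/bank overlap is
#' flagged as fatal: [run_pbsc()] would stop on it.
#'
#' @param config As in [run_pbsc()].
#' @return A list of class `"pbsc_diagnostics"` with elements
#'   `overlap_pct` (expression vs bank, expression vs pathways, bank vs
#'   pathways), `n_genes`, `duplicates`, `pair_problems`, `fatal`.
#' @export
validate_inputs <- function(config) {
  cfg <- .load_config(config)
  expr_genes <- pathway_genes <- bank_genes <- character()
  duplicates <- character()
  pair_problems <- character()

  if (file.exists(cfg$expression)) {
    raw <- withCallingHandlers(
      read_expression_matrix(cfg$expression),
      warning = function(w) {
        duplicates <<- c(duplicates, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    expr_genes <- rownames(raw$values)
    pairs <- .pairs_from_config(cfg)
    if (!is.null(pairs))
      for (i in seq_len(nrow(pairs))) {
        miss <- setdiff(c(pairs$pre[i], pairs$post[i]), colnames(raw$values))
        if (length(miss))
          pair_problems <- c(pair_problems,
                             paste0("patient ", pairs$patient[i],
                                    ": missing sample(s) ",
                                    paste(miss, collapse = ", ")))
      }
  } else pair_problems <- c(pair_problems, "expression file not found")
  if (file.exists(cfg$gmt))
    pathway_genes <- unique(unlist(unclass(read_gmt(cfg$gmt)),
                                   use.names = FALSE))
  if (dir.exists(cfg$bank) || file.exists(cfg$bank))
    bank_genes <- gene_universe(
      if (dir.exists(cfg$bank)) read_reference_bank(cfg$bank)
      else read_reference_bank(cfg$bank, cfg$bank_ranks))

  pct <- function(a, b)
    if (!length(a) || !length(b)) NA_real_
    else 100 * length(intersect(a, b)) / length(unique(a))
  overlap <- c(expression_vs_bank = pct(expr_genes, bank_genes),
               expression_vs_pathways = pct(expr_genes, pathway_genes),
               bank_vs_pathways = pct(bank_genes, pathway_genes))
  fatal <- isTRUE(overlap[["expression_vs_bank"]] == 0)
  if (fatal)
    warning("expression and bank universes are disjoint; run_pbsc would fail")
  structure(list(overlap_pct = overlap,
                 n_genes = c(expression = length(expr_genes),
                             bank = length(bank_genes),
                             pathways = length(pathway_genes)),
                 duplicates = duplicates, pair_problems = pair_problems,
                 fatal = fatal),
            class = "pbsc_diagnostics")
}

#' @export
print.pbsc_diagnostics <- function(x, ...) {
  cat("Input diagnostics\n")
  for (nm in names(x$overlap_pct))
    cat(sprintf("  %-24s %s\n", nm,
                if (is.na(x$overlap_pct[[nm]])) "n/a"
                else sprintf("%.1f%%", x$overlap_pct[[nm]])))
  if (length(x$duplicates)) cat("  duplicates:", x$duplicates, sep = "\n    ")
  if (length(x$pair_problems))
    cat("  pair problems:", x$pair_problems, sep = "\n    ")
  if (x$fatal) cat("  FATAL: expression/bank universes disjoint\n")
  invisible(x)
}
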