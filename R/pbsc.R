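#' Pathway-based similarity comparison of a patient pair against a bank
#'
#' The main entry point. For one patient's paired (pre/post) log2
#' expression profile, the method proceeds in four stages:
#' ranks genes by paired log2 fold change and calls the 2-fold up/down tag
#' signature ([paired_log2fc()], [tag_signature()]); gates pathways on
#' enrichment at p < `enrichment_alpha` ([ks_permutation_enrichment()] or
#' [hypergeometric_enrichment()], then [select_pathways()]); scores the
#' signature against every bank instance within every selected pathway
#' with the signed KS connectivity statistic ([connectivity_table()]); and
#' aggregates per-instance signed pathway counts into a top-`k` report
#' ([count_pathways()], [top_k_report()]). Positive counts mark reference
#' compounds whose expression effect mimics the treatment, negative counts
#' compounds that reverse it.
#'
#' The expression matrix and the bank must share gene identifiers; the
#' analysis runs on their intersection and stops if it is empty.
#'
#' @param expression An [expression_matrix()] of log2 intensities
#'   (preprocess first; see [log2_transform()], [quantile_normalize()]).
#' @param bank A [reference_bank()].
#' @param pathways A [pathway_collection()].
#' @param patient Patient id in `expression$pairs`; defaults to the first.
#' @param fold_threshold Fold-change threshold for the tag signature.
#' @param enrichment_method `"ks_permutation"` (default) or
#'   `"hypergeometric"`.
#' @param enrichment_alpha Pathway selection level (raw p, no correction).
#' @param n_perm Permutations for the enrichment null and the per-cell
#'   connectivity p-values.
#' @param connectivity_mode `"combined"` (default) or `"single_set"`.
#' @param halve Halve the combined two-group score (see
#'   [pathway_connectivity()]).
#' @param count_alpha Per-cell significance level for a pathway to count;
#'   `count_alpha = 1` counts every nonzero-score pathway.
#' @param min_abs_score Minimum |score| for a pathway to count.
#' @param k Report size.
#' @param rank_by Report ordering, `"total"` or `"max"`.
#' @param seed Integer seed for all permutation draws.
#' @return An object of class `"pbsc"`; see [summary.pbsc()]. Components:
#'   `ranking`, `signature`, `enrichment`, `selected` (the gated
#'   [pathway_collection()]), `connectivity`, `summaries`, `report`,
#'   `universe` (shared gene ids), `params`, `call`.
#' @examples
#' sim <- simulate_bank(simulation_config(n_genes = 300, n_instances = 8,
#'                                        n_pathways = 20, signature_size = 20,
#'                                        pathway_size_range = c(10, 40),
#'                                        seed = 7))
#' pat <- simulate_patient_pair(simulation_config(n_genes = 300,
#'                                                signature_size = 20, seed = 7),
#'                              sim$truth, "inst001")
#' fit <- pbsc(pat, sim$bank, sim$pathways, n_perm = 200, seed = 7)
#' summary(fit)
#' @export
pbsc <- function(expression, bank, pathways, patient = NULL,
                 fold_threshold = 2,
                 enrichment_method = c("ks_permutation", "hypergeometric"),
                 enrichment_alpha = 0.05, n_perm = 1000,
                 connectivity_mode = c("combined", "single_set"),
                 halve = TRUE, count_alpha = 0.05, min_abs_score = 0,
                 k = 10, rank_by = c("total", "max"), seed = 1L) {
  stopifnot(inherits(expression, "expression_matrix"),
            inherits(bank, "reference_bank"),
            inherits(pathways, "pathway_collection"))
  enrichment_method <- match.arg(enrichment_method)
  connectivity_mode <- match.arg(connectivity_mode)
  rank_by <- match.arg(rank_by)
  if (is.null(expression$pairs) || !nrow(expression$pairs))
    stop("`expression` carries no patient pairing")
  if (is.null(patient)) patient <- expression$pairs$patient[[1]]

  universe <- intersect(rownames(expression$values), gene_universe(bank))
  if (!length(universe))
    stop("expression matrix and reference bank share no gene identifiers; ",
         "check that both use the same (pre-mapped) gene ids")

  expr_shared <- expression_matrix(
    expression$values[universe, , drop = FALSE], pairs = expression$pairs)
  ranking <- paired_log2fc(expr_shared, patient)
  sig <- withCallingHandlers(
    tag_signature(ranking, fold_threshold = fold_threshold),
    warning = function(w) invokeRestart("muffleWarning"))

  enr <- if (enrichment_method == "ks_permutation")
    ks_permutation_enrichment(ranking, pathways, n_perm = n_perm, seed = seed)
  else
    suppressWarnings(hypergeometric_enrichment(sig, pathways, universe))
  selected <- select_pathways(enr, pathways, alpha = enrichment_alpha)

  if (length(selected) && (length(sig$up) || length(sig$down))) {
    cells <- connectivity_table(sig, bank, selected,
                                mode = connectivity_mode, halve = halve,
                                n_perm = n_perm, seed = seed + 1L)
  } else {
    cells <- connectivity_table(sig, bank,
                                structure(list(), descriptions = character(),
                                          class = "pathway_collection"),
                                n_perm = 0)
  }
  summaries <- count_pathways(cells, alpha = count_alpha,
                              min_abs_score = min_abs_score)
  report <- top_k_report(summaries, k = k, rank_by = rank_by)

  structure(list(patient = patient, ranking = ranking, signature = sig,
                 enrichment = enr, selected = selected,
                 connectivity = cells, summaries = summaries,
                 report = report, universe = universe,
                 params = list(fold_threshold = fold_threshold,
                               enrichment_method = enrichment_method,
                               enrichment_alpha = enrichment_alpha,
                               n_perm = n_perm,
                               connectivity_mode = connectivity_mode,
                               halve = halve, count_alpha = count_alpha,
                               min_abs_score = min_abs_score, k = k,
                               rank_by = rank_by, seed = seed),
                 call = match.call()),
            class = "pbsc")
}

#' @export
print.pbsc <- function(x, ...) {
  cat("Pathway-based similarity comparison\n")
  cat(sprintf("  patient: %s  (universe: %d genes)\n", x$patient,
              length(x$universe)))
  cat(sprintf("  signature: %d up / %d down at %g-fold\n",
              length(x$signature$up), length(x$signature$down),
              x$params$fold_threshold))
  cat(sprintf("  pathways selected: %d of %d (%s, p < %g)\n",
              length(x$selected), nrow(x$enrichment),
              x$params$enrichment_method, x$params$enrichment_alpha))
  if (!length(x$selected)) {
    cat("  no pathways selected; report is empty\n")
  } else if (nrow(x$report)) {
    top <- x$report[1, ]
    cat(sprintf("  top instance: %s (%s, %s) with %s pathways\n",
                top$instance_id, top$compound, top$dose, top$pathway_counts))
  }
  invisible(x)
}

#' Summarize a pathway-based similarity comparison
#'
#' @param object A [pbsc()] fit.
#' @param ... Unused.
#' @return `object`, invisibly, after printing the stage counts and the
#'   top-k instance table.
#' @export
summary.pbsc <- function(object, ...) {
  print(object)
  if (nrow(object$report)) {
    cat("\nTop instances:\n")
    print(object$report[, c("instance_id", "compound", "dose",
                            "positive_count", "negative_count",
                            "pathway_counts")], row.names = FALSE)
  }
  invisible(object)
}

#' Plot signed pathway counts of the top instances
#'
#' Horizontal bars: positive counts to the right (mimicking compounds),
#' negative counts to the left (reversing compounds).
#'
#' @param x A [pbsc()] fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.pbsc <- function(x, ...) {
  r <- x$report
  if (!nrow(r)) {
    graphics::plot.new()
    graphics::title(main = "No pathways selected")
    return(invisible(x))
  }
  r <- r[rev(seq_len(nrow(r))), ]
  h <- rbind(-r$negative_count, r$positive_count)
  graphics::barplot(h, names.arg = paste(r$compound, r$dose), horiz = TRUE,
                    beside = FALSE, las = 1, cex.names = 0.7,
                    col = c("steelblue", "firebrick"),
                    xlab = "pathways (reversing <- | -> mimicking)", ...)
  graphics::abline(v = 0)
  invisible(x)
}

#' Write all per-patient result files of a fit
#'
#' Writes the ranking CSV and tag lists, the enrichment CSV (with a
#' selected flag), the long-format connectivity CSV and the top-k report
#' (CSV and plain text) under `dir`, prefixed by the patient id.
#'
#' @param fit A [pbsc()] fit.
#' @param dir Output directory, created if needed.
#' @return Character vector of files written, invisibly.
#' @export
write_pbsc <- function(fit, dir) {
  stopifnot(inherits(fit, "pbsc"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, fit$patient)
  files <- write_signature_files(fit$ranking, fit$signature, stem)
  enr <- fit$enrichment
  enr$selected <- enr$pathway %in% names(fit$selected)
  f_enr <- paste0(stem, ".enrichment.csv")
  utils::write.csv(enr, f_enr, row.names = FALSE)
  f_conn <- paste0(stem, ".connectivity.csv")
  conn <- as.data.frame(fit$connectivity)
  conn <- cbind(patient = rep(fit$patient, nrow(conn)), conn)
  utils::write.csv(conn, f_conn, row.names = FALSE)
  f_rep <- write_report(fit$report, paste0(stem, ".top"))
  invisible(c(files, f_enr, f_conn, f_rep))
}
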