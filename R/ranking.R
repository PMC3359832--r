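#' Signed pathway counts per reference instance
#'
#' Aggregates a connectivity table into one summary row per instance: the
#' number of pathways scored positive (the instance mimics the treatment)
#' and negative (it reverses it). A pathway counts when its |score| clears
#' `min_abs_score` and its permutation p-value is below `alpha`; with
#' `alpha = 1` and `min_abs_score = 0` every nonzero-score pathway counts
#' (a pure sign count). `sum_abs_score` accumulates |score| over counted
#' pathways and serves as the report tie-break key.
#'
#' @param cells A [connectivity_table()].
#' @param alpha Per-cell significance level; requires p-values in `cells`
#'   when < 1.
#' @param min_abs_score Minimum |score| for a pathway to count.
#' @return A data frame with columns `instance_id`, `compound`, `dose`,
#'   `positive_count`, `negative_count`, `total_count`, `sum_abs_score`,
#'   one row per instance appearing in `cells`.
#' @export
count_pathways <- function(cells, alpha = 0.05, min_abs_score = 0) {
  stopifnot(inherits(cells, "connectivity_table"))
  if (alpha < 1 && nrow(cells) && anyNA(cells$p_value))
    stop("`alpha` < 1 requires per-cell p-values; rerun with n_perm > 0")
  counted <- abs(cells$score) >= min_abs_score & cells$score != 0 &
    (alpha >= 1 | cells$p_value < alpha)
  ids <- unique(cells$instance_id)
  if (!length(ids))
    return(data.frame(instance_id = character(), compound = character(),
                      dose = character(), positive_count = integer(),
                      negative_count = integer(), total_count = integer(),
                      sum_abs_score = numeric(), stringsAsFactors = FALSE))
  out <- data.frame(
    instance_id = ids,
    compound = cells$compound[match(ids, cells$instance_id)],
    dose = cells$dose[match(ids, cells$instance_id)],
    positive_count = 0L, negative_count = 0L, total_count = 0L,
    sum_abs_score = 0, stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(cells)) {
    hit <- cells[counted, , drop = FALSE]
    pos <- tapply(hit$score > 0, hit$instance_id, sum)
    neg <- tapply(hit$score < 0, hit$instance_id, sum)
    sas <- tapply(abs(hit$score), hit$instance_id, sum)
    m <- match(out$instance_id, names(pos))
    out$positive_count <- ifelse(is.na(m), 0L, as.integer(pos[m]))
    out$negative_count <- ifelse(is.na(m), 0L, as.integer(neg[m]))
    out$sum_abs_score <- ifelse(is.na(m), 0, as.numeric(sas[m]))
    out$total_count <- out$positive_count + out$negative_count
  }
  out
}

#' Render signed pathway counts in report style
#'
#' Counts (20, 1) render as `"20+ 1\u2212"` (the Unicode minus sign); a zero component is omitted
#' and counts (0, 0) render as `"0"`.
#'
#' @param positive,negative Non-negative integer vectors.
#' @return Character vector.
#' @export
format_pathway_counts <- function(positive, negative) {
  stopifnot(length(positive) == length(negative))
  vapply(seq_along(positive), function(i) {
    parts <- c(if (positive[[i]] > 0) paste0(positive[[i]], "+"),
               if (negative[[i]] > 0) paste0(negative[[i]], "\u2212"))
    if (!length(parts)) "0" else paste(parts, collapse = " ")
  }, "")
}

#' Top-k instance report
#'
#' Orders instance summaries by total pathway count (or, with
#' `rank_by = "max"`, by the larger of the positive and negative counts)
#' descending, breaking ties by `sum_abs_score` descending and then by
#' `instance_id` lexicographically, and keeps the top `k`.
#'
#' @param summaries Output of [count_pathways()].
#' @param k Number of instances to report (>= 1).
#' @param rank_by `"total"` (default) or `"max"`.
#' @return A data frame with columns `instance_id`, `compound`, `dose`,
#'   `positive_count`, `negative_count`, `total_count`, `sum_abs_score`
#'   and the rendered `pathway_counts` string.
#' @export
top_k_report <- function(summaries, k = 10, rank_by = c("total", "max")) {
  rank_by <- match.arg(rank_by)
  if (k < 1) stop("`k` must be >= 1")
  key <- if (rank_by == "total") summaries$total_count else
    pmax(summaries$positive_count, summaries$negative_count)
  o <- order(-key, -summaries$sum_abs_score, summaries$instance_id)
  top <- summaries[utils::head(o, k), , drop = FALSE]
  top$pathway_counts <- format_pathway_counts(top$positive_count,
                                              top$negative_count)
  rownames(top) <- NULL
  top
}

#' Write the top-k report as CSV and a plain-text table
#'
#' @param report A [top_k_report()].
#' @param stem Output path stem; writes `<stem>.csv` and `<stem>.txt`.
#' @return The files written, invisibly.
#' @export
write_report <- function(report, stem) {
  dir.create(dirname(stem), showWarnings = FALSE, recursive = TRUE)
  files <- paste0(stem, c(".csv", ".txt"))
  utils::write.csv(report, files[[1]], row.names = FALSE)
  txt <- report[, c("instance_id", "compound", "dose", "pathway_counts")]
  names(txt) <- c("Instance ID", "Drug molecule", "Dose", "Pathway counts")
  widths <- pmax(nchar(names(txt)),
                 sapply(txt, function(col) max(0L, nchar(col))))
  fmt_row <- function(vals) paste(mapply(formatC, vals, width = widths,
                                         flag = "-"), collapse = "  ")
  con <- file(files[[2]], open = "w", encoding = "UTF-8")
  on.exit(close(con))
  body <- if (nrow(txt)) vapply(seq_len(nrow(txt)),
                                function(i) fmt_row(as.list(txt[i, ])), "")
          else character()
  writeLines(c(fmt_row(names(txt)), body), con)
  invisible(files)
}
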