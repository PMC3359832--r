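#' Paired log2 fold changes for one patient
#'
#' With a single pre/post pair per patient and the matrix already on the
#' log2 scale, the per-gene fold change is simply post minus pre. Genes are
#' ranked from most up- to most down-regulated; ties in fold change are
#' broken by gene id lexicographic order so the ranking is a deterministic
#' total order.
#'
#' @param x An [expression_matrix()] of log2 intensities with a pairing
#'   entry for `patient`.
#' @param patient Patient identifier present in `x$pairs`.
#' @return A data frame of class `"differential_ranking"` with columns
#'   `gene`, `log2fc`, `rank`, sorted by decreasing `log2fc`.
#' @export
paired_log2fc <- function(x, patient) {
  stopifnot(inherits(x, "expression_matrix"))
  if (is.null(x$pairs) || !patient %in% x$pairs$patient)
    stop("unknown patient: ", patient)
  p <- x$pairs[x$pairs$patient == patient, ]
  lfc <- x$values[, p$post] - x$values[, p$pre]
  o <- order(-lfc, rownames(x$values))
  out <- data.frame(gene = rownames(x$values)[o], log2fc = unname(lfc[o]),
                    rank = seq_along(lfc), stringsAsFactors = FALSE)
  class(out) <- c("differential_ranking", "data.frame")
  out
}

#' Up/down tag signature from a differential ranking
#'
#' Applies a fold-change threshold (default 2-fold, i.e. |log2FC| >= 1,
#' inclusive) to split the ranking into an up-regulated and a down-regulated
#' tag list, each ordered by decreasing |log2FC|.
#'
#' @param ranking A [paired_log2fc()] result.
#' @param fold_threshold Fold-change threshold on the linear scale, > 1.
#' @return An object of class `"tag_signature"`: a list with `up`, `down`
#'   (ordered character vectors) and `fc_threshold`. Both lists may be
#'   empty, with a warning; downstream scoring skips empty groups.
#' @export
tag_signature <- function(ranking, fold_threshold = 2) {
  stopifnot(inherits(ranking, "differential_ranking"))
  if (fold_threshold <= 1) stop("`fold_threshold` must be > 1")
  cut <- log2(fold_threshold)
  up <- ranking$gene[ranking$log2fc >= cut]
  # ranking is sorted descending, so up is already by decreasing |log2FC|
  down_rows <- ranking[ranking$log2fc <= -cut, ]
  down <- down_rows$gene[order(down_rows$log2fc, down_rows$gene)]
  if (!length(up) && !length(down))
    warning("no genes pass the ", fold_threshold, "-fold threshold; ",
            "both tag lists are empty")
  structure(list(up = up, down = down, fc_threshold = fold_threshold),
            class = "tag_signature")
}

#' @export
print.tag_signature <- function(x, ...) {
  cat(sprintf("tag_signature (%g-fold): %d up, %d down\n",
              x$fc_threshold, length(x$up), length(x$down)))
  invisible(x)
}

#' Write ranking and tag-list files for one patient
#'
#' Writes the full ranking as CSV (gene, log2fc, rank) and the tag lists in
#' the classic one-gene-per-line convention (`<stem>.up.txt`,
#' `<stem>.dn.txt`).
#'
#' @param ranking A [paired_log2fc()] result.
#' @param sig A [tag_signature()].
#' @param stem Output path stem, e.g. `"out/patientA"`.
#' @return Character vector of the files written, invisibly.
#' @export
write_signature_files <- function(ranking, sig, stem) {
  stopifnot(inherits(ranking, "differential_ranking"),
            inherits(sig, "tag_signature"))
  dir.create(dirname(stem), showWarnings = FALSE, recursive = TRUE)
  files <- paste0(stem, c(".ranking.csv", ".up.txt", ".dn.txt"))
  utils::write.csv(as.data.frame(ranking), files[[1]], row.names = FALSE)
  writeLines(sig$up, files[[2]])
  writeLines(sig$down, files[[3]])
  invisible(files)
}
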