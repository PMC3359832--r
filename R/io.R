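#' Construct an expression matrix with optional pre/post pairing
#'
#' The central expression container: a numeric genes-by-samples matrix with
#' unique gene and sample identifiers, plus an optional pairing table that
#' maps each patient to a pre-treatment and a post-treatment sample column.
#'
#' @param values Numeric matrix, genes in rows (unique rownames) and samples
#'   in columns (unique colnames). All entries must be finite.
#' @param pairs Optional data frame with columns `patient`, `pre`, `post`
#'   naming, for each patient, the pre- and post-treatment sample columns.
#' @return An object of class `"expression_matrix"`: a list with elements
#'   `values` and `pairs`.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' x <- expression_matrix(m, pairs = data.frame(patient = "P1",
#'                                              pre = "s1", post = "s2"))
#' dim(x$values)
#' @export
expression_matrix <- function(values, pairs = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(gid))
    stop("duplicate gene identifiers: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample identifiers: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("`values` contains non-finite entries")
  if (!is.null(pairs)) {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    need <- c("patient", "pre", "post")
    if (!all(need %in% names(pairs)))
      stop("`pairs` must have columns patient, pre, post")
    pairs <- pairs[, need]
    if (anyDuplicated(pairs$patient))
      stop("duplicate patient identifiers in `pairs`")
    bad <- setdiff(c(pairs$pre, pairs$post), sid)
    if (length(bad))
      stop("`pairs` references unknown samples: ", paste(bad, collapse = ", "))
    if (any(pairs$pre == pairs$post))
      stop("`pairs` must reference two distinct samples per patient")
  }
  structure(list(values = values, pairs = pairs), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$pairs))
    cat(sprintf("  %d patient pair(s): %s\n", nrow(x$pairs),
                paste(x$pairs$patient, collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV or GCT
#'
#' Tab-separated layout: a header row of sample identifiers and one row per
#' gene, the first column holding the gene identifier. GCT 1.2 layout: the
#' `#1.2` version line, a dimensions line, then NAME/Description columns
#' before the samples. Duplicate gene rows are collapsed to their mean with
#' a warning.
#'
#' @param path Path to the file.
#' @param format One of `"auto"` (sniff GCT by its `#1.2` first line),
#'   `"tsv"`, `"gct"`.
#' @param pairs Optional pairing data frame passed to [expression_matrix()].
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, format = c("auto", "tsv", "gct"),
                                   pairs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (format == "auto")
    format <- if (length(lines) && startsWith(lines[[1]], "#1.2")) "gct" else "tsv"

  if (format == "gct") {
    if (length(lines) < 3 || !startsWith(lines[[1]], "#1.2"))
      stop("malformed GCT header at line 1: expected '#1.2'")
    dims <- suppressWarnings(as.integer(strsplit(lines[[2]], "\t| +")[[1]]))
    if (length(dims) < 2 || anyNA(dims[1:2]))
      stop("malformed GCT dimensions at line 2")
    body <- lines[-(1:2)]
    tab <- .parse_matrix_lines(body, first_line_no = 3L, skip_cols = 2L)
    if (nrow(tab$values) != dims[[1]] || ncol(tab$values) != dims[[2]])
      stop(sprintf("GCT dimensions line says %d x %d but body has %d x %d",
                   dims[[1]], dims[[2]], nrow(tab$values), ncol(tab$values)))
  } else {
    tab <- .parse_matrix_lines(lines, first_line_no = 1L, skip_cols = 1L)
  }
  vals <- .collapse_duplicate_genes(tab$values)
  expression_matrix(vals, pairs = pairs)
}

# Shared tab-delimited matrix body parser. skip_cols = 1 keeps only the id
# column (TSV); 2 drops a Description column as well (GCT).
.parse_matrix_lines <- function(lines, first_line_no, skip_cols) {
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    stop("malformed header at line ", first_line_no, ": file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < skip_cols + 1L)
    stop("malformed header at line ", first_line_no,
         ": expected id column(s) plus at least one sample")
  samples <- header[-seq_len(skip_cols)]
  n_col <- length(header)
  rows <- fields[-1]
  ids <- character(length(rows))
  vals <- matrix(NA_real_, length(rows), length(samples))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    line_no <- first_line_no + i
    if (length(f) != n_col)
      stop(sprintf("line %d has %d fields, expected %d", line_no, length(f), n_col))
    ids[[i]] <- f[[1]]
    v <- suppressWarnings(as.numeric(f[-seq_len(skip_cols)]))
    if (anyNA(v)) {
      j <- which(is.na(v))[[1]]
      stop(sprintf("non-numeric value '%s' for gene '%s' in column '%s'",
                   f[skip_cols + j], f[[1]], samples[[j]]))
    }
    vals[i, ] <- v
  }
  dimnames(vals) <- list(ids, samples)
  list(values = vals)
}

.collapse_duplicate_genes <- function(vals) {
  ids <- rownames(vals)
  if (!anyDuplicated(ids)) return(vals)
  dups <- unique(ids[duplicated(ids)])
  warning("collapsing ", length(dups), " duplicated gene id(s) by mean: ",
          paste(utils::head(dups, 5), collapse = ", "),
          if (length(dups) > 5) ", ..." else "")
  keep <- !duplicated(ids)
  out <- vals[keep, , drop = FALSE]
  for (g in dups)
    out[g, ] <- colMeans(vals[ids == g, , drop = FALSE])
  out
}

#' Write an expression matrix to TSV or GCT
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @param format `"tsv"` or `"gct"` (1.2).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  if (format == "tsv") {
    header <- paste(c("gene", colnames(v)), collapse = "\t")
    body <- paste(rownames(v),
                  apply(v, 1, function(r) paste(format(r, digits = 15), collapse = "\t")),
                  sep = "\t")
    writeLines(c(header, body), path)
  } else {
    header <- paste(c("NAME", "Description", colnames(v)), collapse = "\t")
    body <- paste(rownames(v), "na",
                  apply(v, 1, function(r) paste(format(r, digits = 15), collapse = "\t")),
                  sep = "\t")
    writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t"), header, body), path)
  }
  invisible(path)
}

#' Construct a pathway collection
#'
#' @param sets Named list of character vectors of gene identifiers. Names
#'   must be unique, each set non-empty; genes within a set are deduplicated.
#' @param descriptions Optional character vector of per-pathway descriptions,
#'   recycled to `length(sets)`.
#' @return An object of class `"pathway_collection"`: a named list of
#'   character vectors with a `descriptions` attribute. Gene membership is
#'   case-sensitive exact match throughout the package.
#' @export
pathway_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("`sets` must be a named list")
  if (anyDuplicated(names(sets)))
    stop("duplicate pathway names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0))
    stop("every pathway must contain at least one gene")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d pathway(s), sizes %s\n", length(x),
              if (length(x)) paste(range(lengths(x)), collapse = "-") else "-"))
  invisible(x)
}

#' @export
`[.pathway_collection` <- function(x, i) {
  desc <- attr(x, "descriptions")
  y <- unclass(x)[i]
  pathway_collection(y, descriptions = desc[names(y)])
}

#' Read a pathway collection from a GMT file
#'
#' One pathway per line: name, description, then one or more member genes,
#' tab-separated. File order is preserved; duplicate genes within a line are
#' deduplicated; a duplicate pathway name is an error.
#'
#' @param path Path to the GMT file.
#' @return A [pathway_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT parse error at line ", short[[1]],
         ": expected name, description and at least one gene")
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  pathway_collection(sets, descriptions = desc)
}

#' Write a pathway collection to a GMT file
#'
#' @param pathways A [pathway_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  stopifnot(inherits(pathways, "pathway_collection"))
  desc <- attr(pathways, "descriptions")
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, desc[[nm]], pathways[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a reference signature bank
#'
#' A bank holds one ranked expression profile per perturbation instance
#' (one compound x dose x cell-line treatment), stored as a rank matrix:
#' genes in rows, instances in columns, each column a permutation of
#' 1..N with rank 1 the most up-regulated gene.
#'
#' @param meta Data frame with columns `instance_id`, `compound`, `dose`,
#'   `cell_line` (may be empty strings), one row per instance.
#' @param ranks Integer matrix of per-instance gene ranks; rownames are the
#'   shared gene universe, colnames are instance ids matching `meta`.
#' @return An object of class `"reference_bank"`.
#' @export
reference_bank <- function(meta, ranks) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("instance_id", "compound", "dose", "cell_line")
  if (!all(need %in% names(meta)))
    stop("`meta` must have columns ", paste(need, collapse = ", "))
  meta <- meta[, need]
  meta[] <- lapply(meta, as.character)
  if (anyDuplicated(meta$instance_id))
    stop("duplicate instance ids in `meta`")
  if (!is.matrix(ranks) || is.null(rownames(ranks)) || is.null(colnames(ranks)))
    stop("`ranks` must be a matrix with gene rownames and instance colnames")
  if (anyDuplicated(rownames(ranks))) stop("duplicate gene ids in `ranks`")
  missing_ranks <- setdiff(meta$instance_id, colnames(ranks))
  if (length(missing_ranks))
    stop("instances in metadata without a rank column: ",
         paste(missing_ranks, collapse = ", "))
  extra <- setdiff(colnames(ranks), meta$instance_id)
  if (length(extra))
    stop("rank columns without metadata: ", paste(extra, collapse = ", "))
  ranks <- ranks[, meta$instance_id, drop = FALSE]
  n <- nrow(ranks)
  if (!is.numeric(ranks) || anyNA(ranks) || any(ranks != round(ranks)))
    stop("`ranks` must contain whole-number ranks")
  storage.mode(ranks) <- "integer"
  for (id in colnames(ranks)) {
    r <- unname(ranks[, id])
    if (anyNA(r) || !identical(sort(r), seq_len(n)))
      stop("rank column for instance '", id,
           "' is not a permutation of 1..", n)
  }
  structure(list(meta = meta, ranks = ranks), class = "reference_bank")
}

#' @export
print.reference_bank <- function(x, ...) {
  cat(sprintf("reference_bank: %d instance(s) over %d genes, %d compound(s)\n",
              ncol(x$ranks), nrow(x$ranks), length(unique(x$meta$compound))))
  invisible(x)
}

#' Gene universe of a reference bank
#' @param bank A [reference_bank()].
#' @return Character vector of gene identifiers shared by all instances.
#' @export
gene_universe <- function(bank) {
  stopifnot(inherits(bank, "reference_bank"))
  rownames(bank$ranks)
}

#' Ranked profile of one bank instance
#'
#' @param bank A [reference_bank()].
#' @param instance_id Instance identifier.
#' @return Character vector of gene ids ordered from most up-regulated
#'   (rank 1) to most down-regulated (rank N).
#' @export
ranked_profile <- function(bank, instance_id) {
  stopifnot(inherits(bank, "reference_bank"))
  if (!instance_id %in% colnames(bank$ranks))
    stop("unknown instance: ", instance_id)
  rownames(bank$ranks)[order(bank$ranks[, instance_id])]
}

#' Read a reference bank from its two-file dialect
#'
#' The bank is stored as a metadata TSV (`instance_id`, `compound`, `dose`,
#' `cell_line`) plus a rank-matrix TSV (first column gene ids, one column of
#' ranks per instance, each a permutation of 1..N). `path` may be a
#' directory containing `instances.tsv` and `ranks.tsv`, or the metadata
#' file path with `ranks_path` given explicitly.
#'
#' @param path Directory or metadata file path.
#' @param ranks_path Rank-matrix path (required when `path` is a file).
#' @return A [reference_bank()].
#' @export
read_reference_bank <- function(path, ranks_path = NULL) {
  if (dir.exists(path)) {
    meta_path <- file.path(path, "instances.tsv")
    ranks_path <- file.path(path, "ranks.tsv")
  } else {
    meta_path <- path
    if (is.null(ranks_path))
      stop("`ranks_path` is required when `path` is not a directory")
  }
  for (p in c(meta_path, ranks_path))
    if (!file.exists(p)) stop("file not found: ", p)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            colClasses = "character", check.names = FALSE)
  tab <- .parse_matrix_lines(readLines(ranks_path), first_line_no = 1L,
                             skip_cols = 1L)
  reference_bank(meta, tab$values)
}

#' Write a reference bank to a directory
#'
#' @param bank A [reference_bank()].
#' @param dir Output directory (created if needed); writes `instances.tsv`
#'   and `ranks.tsv`.
#' @return `dir`, invisibly.
#' @export
write_reference_bank <- function(bank, dir) {
  stopifnot(inherits(bank, "reference_bank"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(bank$meta, file.path(dir, "instances.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  header <- paste(c("gene", colnames(bank$ranks)), collapse = "\t")
  body <- paste(rownames(bank$ranks),
                apply(bank$ranks, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), file.path(dir, "ranks.tsv"))
  invisible(dir)
}

#' Collapse replicate instances of a reference bank
#'
#' Instances sharing the given metadata key are merged into a single
#' instance whose profile is the re-ranking of the mean per-gene rank across
#' replicates; rank ties are broken by gene id lexicographic order, so the
#' merge is deterministic and invariant to the order of the replicates. The
#' merged instance keeps the first replicate's `instance_id`; metadata
#' fields outside the key are taken from the first replicate.
#'
#' @param bank A [reference_bank()].
#' @param key Character vector of metadata fields to group by, a subset of
#'   `c("compound", "dose", "cell_line")`.
#' @return A [reference_bank()] with one instance per key group.
#' @export
merge_replicate_instances <- function(bank,
                                      key = c("compound", "dose", "cell_line")) {
  stopifnot(inherits(bank, "reference_bank"))
  if (!length(key) || !all(key %in% c("compound", "dose", "cell_line")))
    stop("`key` must be a non-empty subset of compound, dose, cell_line")
  grp <- interaction(bank$meta[key], drop = TRUE, lex.order = TRUE)
  genes <- rownames(bank$ranks)
  ord_lex <- order(genes)
  first <- !duplicated(grp)
  ids <- bank$meta$instance_id[first]
  n <- nrow(bank$ranks)
  ranks <- matrix(NA_integer_, n, length(ids),
                  dimnames = list(genes, ids))
  for (i in seq_along(ids)) {
    members <- bank$meta$instance_id[grp == grp[first][i]]
    mr <- rowMeans(bank$ranks[, members, drop = FALSE])
    # order by mean rank, ties by gene id; then invert to rank positions
    o <- order(mr, genes)
    r <- integer(n)
    r[o] <- seq_len(n)
    ranks[, i] <- r
  }
  reference_bank(bank$meta[first, , drop = FALSE], ranks)
}
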