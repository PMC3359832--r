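#' Hypergeometric over-representation of the differential gene set
#'
#' For each pathway, tests whether the differential set (union of the up
#' and down tag lists) overlaps the pathway more than expected from a
#' uniform draw out of the measured universe: one-sided upper-tail
#' hypergeometric probability P(X >= k) with k the observed overlap, using
#' pathway-within-universe sizes. Pathways disjoint from the universe are
#' skipped with a message.
#'
#' @param sig A [tag_signature()]; the DE set is `union(sig$up, sig$down)`.
#' @param pathways A [pathway_collection()].
#' @param universe Character vector: all measured genes eligible for the
#'   draw. The DE set is intersected with it.
#' @return A data frame with one row per retained pathway: `pathway`,
#'   `method`, `statistic` (the overlap k), `p_value`,
#'   `n_pathway_genes_in_universe`, `n_de_in_pathway`, in input order.
#' @export
hypergeometric_enrichment <- function(sig, pathways, universe) {
  stopifnot(inherits(sig, "tag_signature"),
            inherits(pathways, "pathway_collection"))
  universe <- unique(universe)
  de <- intersect(union(sig$up, sig$down), universe)
  if (!length(de))
    warning("empty differential set; all enrichment p-values are 1")
  M <- length(universe)
  sizes <- vapply(pathways, function(g) length(intersect(g, universe)), 0L)
  skip <- sizes == 0
  if (any(skip))
    message(sum(skip), " pathway(s) disjoint from the universe were skipped")
  keep <- names(pathways)[!skip]
  k <- vapply(pathways[keep], function(g) length(intersect(g, de)), 0L)
  K <- sizes[keep]
  p <- stats::phyper(k - 1, K, M - K, length(de), lower.tail = FALSE)
  data.frame(pathway = keep, method = "hypergeometric",
             statistic = as.numeric(k), p_value = unname(p),
             n_pathway_genes_in_universe = unname(K),
             n_de_in_pathway = unname(k),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank-based pathway enrichment with a gene-label permutation null
#'
#' Scores each pathway's member genes, taken as a single gene group, with
#' the signed KS statistic against the full differential ranking, and
#' compares |KS| with the same statistic for random gene subsets of the
#' same size drawn from the ranked universe. The permutation p-value uses
#' the +1 correction, `p = (1 + #\{|KS_perm| >= |KS_obs|\}) / (n_perm + 1)`,
#' so it is never exactly 0. Null samples are shared between pathways of
#' equal restricted size, which leaves each p-value's distribution
#' unchanged. Pathways with no member in the ranking are skipped.
#'
#' @param ranking A [paired_log2fc()] result (the full gene ranking).
#' @param pathways A [pathway_collection()].
#' @param n_perm Number of random subsets per pathway size (>= 100).
#' @param seed Optional integer seed; identical seeds give identical
#'   p-values.
#' @return A data frame as in [hypergeometric_enrichment()] with
#'   `method = "ks_permutation"` and `statistic` the observed signed KS.
#' @export
ks_permutation_enrichment <- function(ranking, pathways, n_perm = 1000,
                                      seed = NULL) {
  stopifnot(inherits(ranking, "differential_ranking"),
            inherits(pathways, "pathway_collection"))
  if (n_perm < 100) stop("`n_perm` must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  genes <- ranking$gene
  N <- length(genes)
  pos_of <- seq_len(N)
  names(pos_of) <- genes

  sizes <- vapply(pathways, function(g) sum(g %in% genes), 0L)
  skip <- sizes == 0
  if (any(skip))
    message(sum(skip), " pathway(s) with no measured gene were skipped")
  keep <- names(pathways)[!skip]

  null_abs <- new.env(parent = emptyenv())  # |KS| null sample per size t
  stat <- p <- numeric(length(keep))
  nde <- integer(length(keep))
  de_cut <- abs(ranking$log2fc) >= log2(2)  # informational only
  for (i in seq_along(keep)) {
    members <- pathways[[keep[[i]]]]
    V <- sort.int(unname(pos_of[members[members %in% genes]]))
    t <- length(V)
    stat[[i]] <- ks_statistic(V, N)
    key <- as.character(t)
    if (is.null(null_abs[[key]]))
      null_abs[[key]] <- abs(.ks_rows(.random_positions(n_perm, t, N), N))
    p[[i]] <- (1 + sum(null_abs[[key]] >= abs(stat[[i]]))) / (n_perm + 1)
    nde[[i]] <- sum(de_cut[ranking$gene %in% members])
  }
  data.frame(pathway = keep, method = "ks_permutation",
             statistic = stat, p_value = p,
             n_pathway_genes_in_universe = unname(sizes[keep]),
             n_de_in_pathway = nde,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select enriched pathways by p-value
#'
#' Retains pathways with enrichment p strictly below `alpha`, preserving
#' the collection's order. No multiple-testing correction is applied by
#' default, matching the method's raw 0.05 gate; set `adjust = "BH"` for a
#' Benjamini-Hochberg FDR gate instead.
#'
#' @param results Enrichment data frame from one of the enrichment
#'   functions.
#' @param pathways The [pathway_collection()] the results refer to.
#' @param alpha Selection level in (0, 1\]; pathways with p < alpha pass.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return The selected sub-collection, a [pathway_collection()] (possibly
#'   empty, as a plain empty list with the class attached).
#' @export
select_pathways <- function(results, pathways, alpha = 0.05,
                            adjust = c("none", "BH")) {
  stopifnot(inherits(pathways, "pathway_collection"))
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]")
  p <- results$p_value
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  hit <- results$pathway[p < alpha]
  sel <- names(pathways)[names(pathways) %in% hit]
  if (!length(sel))
    return(structure(list(), descriptions = character(),
                     class = "pathway_collection"))
  pathways[sel]
}
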