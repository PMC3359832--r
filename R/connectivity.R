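#' Signed Kolmogorov-Smirnov connectivity statistic
#'
#' The rank-based statistic used throughout Connectivity-Map-style signature
#' matching. Given the positions `V` (1-based, within a ranked list of `N`
#' genes) of the `t` tag genes, ordered increasingly, it computes
#'
#'   p = max_j ( j/t - V(j)/N ),   n = max_j ( V(j)/N - (j-1)/t )
#'
#' and returns `p` when `p > n` (tags cluster at the top of the list),
#' `-n` when `n > p` (tags cluster at the bottom), and 0 when `p == n`.
#' Tag genes concentrated at the top of a reference ranking therefore give a
#' positive value (the reference mimics the query) and concentration at the
#' bottom a negative one (the reference reverses it). The value lies in
#' \[-1, 1\]; the extremes for a list of length `N` are `1 - t/N` (tags
#' occupy the top `t` positions, `t <= N - 2`) and `-(N - t + 1)/N` (the
#' bottom `t`). At `t = N - 1` the top-loaded configuration has `p = n =
#' 1/N` exactly, so the tie rule returns 0. Numerators are evaluated in
#' exact integer arithmetic so such ties are detected reliably.
#'
#' @param V Integer positions of the tag genes in the ranked list,
#'   strictly increasing, within 1..N. An unsorted vector of distinct
#'   positions is sorted first.
#' @param N Length of the ranked list.
#' @return The signed KS value.
#' @examples
#' ks_statistic(1:3, 10)            # top-loaded: 1 - 3/10
#' ks_statistic(8:10, 10)           # bottom-loaded: -(10 - 3 + 1)/10
#' ks_statistic(c(1, 2, 8), 10)
#' @export
ks_statistic <- function(V, N) {
  t <- length(V)
  if (t == 0) stop("`V` must contain at least one position")
  if (anyDuplicated(V)) stop("`V` positions must be distinct")
  V <- sort(as.numeric(V))
  if (V[[1]] < 1 || V[[t]] > N) stop("`V` positions must lie in 1..N")
  # common-denominator form: j/t - V/N = (jN - Vt) / (tN). The numerators
  # are exact integers, so the p vs n comparison (and the tie -> 0 rule)
  # is free of floating-point noise.
  j <- seq_len(t)
  p_num <- max(j * N - V * t)
  n_num <- max(V * t - (j - 1) * N)
  if (p_num > n_num) p_num / (t * N)
  else if (n_num > p_num) -n_num / (t * N)
  else 0
}

# Vectorized KS over rows of a position matrix (each row one draw of t
# sorted positions). Used by the permutation nulls, where millions of
# evaluations may be needed.
.ks_rows <- function(Vmat, N) {
  t <- ncol(Vmat)
  jN <- matrix(seq_len(t) * N, nrow(Vmat), t, byrow = TRUE)
  p_num <- .rowMax(jN - Vmat * t)
  n_num <- .rowMax(Vmat * t - jN + N)
  ifelse(p_num > n_num, p_num, ifelse(n_num > p_num, -n_num, 0)) / (t * N)
}

.rowMax <- function(m) do.call(pmax, as.data.frame(m))

# Draw n_draw sorted position vectors of size t from 1..N (rows).
.random_positions <- function(n_draw, t, N) {
  m <- matrix(NA_integer_, n_draw, t)
  for (i in seq_len(n_draw)) m[i, ] <- sort.int(sample.int(N, t))
  m
}

#' Connectivity of a tag signature with one reference profile in one pathway
#'
#' Restricts the reference instance's ranked profile to the pathway's genes
#' (order preserved, positions renumbered 1..N) and scores the signature's
#' tag genes against that restricted list. In `"combined"` mode the up and
#' down tag groups are scored separately (`ks_up`, `ks_down`) and combined
#' the classic way: 0 when both share a sign (incoherent signature), else
#' `(ks_up - ks_down) / 2`, which keeps the score in \[-1, 1\]; when one
#' group is empty the other's KS is used alone (the down group with flipped
#' sign). In `"single_set"` mode the union of up and down tags is scored as
#' one group. Positive scores mean the reference mimics the query effect,
#' negative that it reverses it.
#'
#' @param sig A [tag_signature()].
#' @param profile Ranked gene ids of the reference instance (most
#'   up-regulated first), e.g. from [ranked_profile()].
#' @param pathway Character vector of pathway member genes.
#' @param mode `"combined"` (default) or `"single_set"`.
#' @param halve Divide the combined two-group score by 2 (default TRUE).
#'   Disabling reproduces the unhalved convention, with range \[-2, 2\].
#' @return A list with `ks_up`, `ks_down` (NA when that group has no tag in
#'   the pathway), `score`, `n` (restricted list length), `t_up`, `t_down`;
#'   or `NULL` when no tag gene falls in the pathway-restricted list.
#' @export
pathway_connectivity <- function(sig, profile, pathway,
                                 mode = c("combined", "single_set"),
                                 halve = TRUE) {
  stopifnot(inherits(sig, "tag_signature"))
  mode <- match.arg(mode)
  restricted <- profile[profile %in% pathway]
  N <- length(restricted)
  if (N == 0) return(NULL)
  v_up <- which(restricted %in% sig$up)
  v_dn <- which(restricted %in% sig$down)
  t_up <- length(v_up)
  t_dn <- length(v_dn)
  if (t_up + t_dn == 0) return(NULL)

  if (mode == "single_set") {
    ks <- ks_statistic(sort(c(v_up, v_dn)), N)
    return(list(ks_up = NA_real_, ks_down = NA_real_, score = ks,
                n = N, t_up = t_up, t_down = t_dn))
  }
  ks_up <- if (t_up) ks_statistic(v_up, N) else NA_real_
  ks_dn <- if (t_dn) ks_statistic(v_dn, N) else NA_real_
  score <- .combine_ks(ks_up, ks_dn, halve)
  list(ks_up = ks_up, ks_down = ks_dn, score = score,
       n = N, t_up = t_up, t_down = t_dn)
}

.combine_ks <- function(ks_up, ks_dn, halve) {
  if (is.na(ks_up)) return(-ks_dn)
  if (is.na(ks_dn)) return(ks_up)
  if (sign(ks_up) == sign(ks_dn)) return(0)
  (ks_up - ks_dn) / (if (halve) 2 else 1)
}

# Vectorized combined score for permutation draws: ks_up, ks_dn numeric
# vectors (NA allowed for an absent group, constant per call).
.combine_ks_vec <- function(ks_up, ks_dn, halve) {
  if (all(is.na(ks_up))) return(-ks_dn)
  if (all(is.na(ks_dn))) return(ks_up)
  same <- sign(ks_up) == sign(ks_dn)
  out <- (ks_up - ks_dn) / (if (halve) 2 else 1)
  out[same] <- 0
  out
}

#' Permutation null for a connectivity score
#'
#' Draws `n_perm` random placements of the tag genes within the
#' pathway-restricted list (positions uniform without replacement,
#' preserving the up/down group sizes) and recomputes the score for each.
#' Returns the vector of permuted scores; the per-cell p-value is
#' `(1 + #\{|perm| >= |observed|\}) / (n_perm + 1)`, computed by
#' [connectivity_significance()]. The null depends only on `(N, t_up,
#' t_down, mode)`, so callers scoring many instances against the same
#' pathway can reuse one null sample.
#'
#' @param N Restricted list length.
#' @param t_up,t_down Tag group sizes within the restricted list (one may
#'   be 0, not both).
#' @param n_perm Number of permutations (>= 100).
#' @param mode,halve As in [pathway_connectivity()].
#' @return Numeric vector of `n_perm` permuted scores.
#' @export
connectivity_null <- function(N, t_up, t_down, n_perm = 1000,
                              mode = c("combined", "single_set"),
                              halve = TRUE) {
  mode <- match.arg(mode)
  if (n_perm < 100) stop("`n_perm` must be >= 100")
  if (t_up + t_down == 0) stop("at least one tag group must be non-empty")
  if (t_up + t_down > N) stop("more tags than list positions")
  if (mode == "single_set") {
    pos <- .random_positions(n_perm, t_up + t_down, N)
    return(.ks_rows(pos, N))
  }
  pos <- .random_positions(n_perm, t_up + t_down, N)
  if (t_up == 0) {
    ks_up <- rep(NA_real_, n_perm)
    ks_dn <- .ks_rows(pos, N)
  } else if (t_down == 0) {
    ks_up <- .ks_rows(pos, N)
    ks_dn <- rep(NA_real_, n_perm)
  } else {
    # first t_up of each draw form the up group: a uniform random split
    up <- t(apply(pos, 1, function(v) sort.int(v[seq_len(t_up)])))
    dn <- t(apply(pos, 1, function(v) sort.int(v[-seq_len(t_up)])))
    ks_up <- .ks_rows(up, N)
    ks_dn <- .ks_rows(dn, N)
  }
  .combine_ks_vec(ks_up, ks_dn, halve)
}

#' Permutation p-value for an observed connectivity score
#'
#' @param score Observed score.
#' @param null Permuted scores from [connectivity_null()].
#' @return Two-sided permutation p-value with the +1 correction, never
#'   exactly 0.
#' @export
connectivity_significance <- function(score, null) {
  (1 + sum(abs(null) >= abs(score))) / (length(null) + 1)
}

#' Score a tag signature against every bank instance in every pathway
#'
#' The pathway-restricted list length and tag group sizes are identical for
#' all instances of a bank (they share one gene universe), so one
#' permutation null per pathway serves every instance.
#'
#' @param sig A [tag_signature()]. Tag genes absent from the bank's
#'   universe are dropped before scoring, with a message.
#' @param bank A [reference_bank()].
#' @param pathways A [pathway_collection()] (typically the enriched
#'   sub-collection from [select_pathways()]).
#' @param mode,halve As in [pathway_connectivity()].
#' @param n_perm Permutations per pathway for the per-cell p-value; set to
#'   0 to skip significance (p is NA).
#' @param seed Optional integer seed for the permutation draws.
#' @return A data frame of class `"connectivity_table"` with one row per
#'   (instance, pathway) cell: `instance_id`, `compound`, `dose`,
#'   `pathway`, `ks_up`, `ks_down`, `score`, `p_value`. Cells where no tag
#'   gene falls in the pathway are omitted.
#' @export
connectivity_table <- function(sig, bank, pathways,
                               mode = c("combined", "single_set"),
                               halve = TRUE, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(sig, "tag_signature"), inherits(bank, "reference_bank"),
            inherits(pathways, "pathway_collection"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  universe <- gene_universe(bank)
  dropped <- length(setdiff(c(sig$up, sig$down), universe))
  if (dropped)
    message(dropped, " tag gene(s) absent from the bank universe were dropped")
  sig <- structure(list(up = intersect(sig$up, universe),
                        down = intersect(sig$down, universe),
                        fc_threshold = sig$fc_threshold),
                   class = "tag_signature")
  profiles <- lapply(bank$meta$instance_id, ranked_profile, bank = bank)
  names(profiles) <- bank$meta$instance_id

  rows <- vector("list", length(pathways) * nrow(bank$meta))
  k <- 0L
  for (pw in names(pathways)) {
    members <- pathways[[pw]]
    null <- NULL
    for (i in seq_len(nrow(bank$meta))) {
      id <- bank$meta$instance_id[[i]]
      cell <- pathway_connectivity(sig, profiles[[id]], members,
                                   mode = mode, halve = halve)
      if (is.null(cell)) next
      p <- NA_real_
      if (n_perm > 0) {
        if (is.null(null))
          null <- connectivity_null(cell$n, cell$t_up, cell$t_down,
                                    n_perm = n_perm, mode = mode,
                                    halve = halve)
        p <- connectivity_significance(cell$score, null)
      }
      k <- k + 1L
      rows[[k]] <- data.frame(instance_id = id,
                              compound = bank$meta$compound[[i]],
                              dose = bank$meta$dose[[i]],
                              pathway = pw,
                              ks_up = cell$ks_up, ks_down = cell$ks_down,
                              score = cell$score, p_value = p,
                              stringsAsFactors = FALSE)
    }
  }
  out <- if (k) do.call(rbind, rows[seq_len(k)]) else
    data.frame(instance_id = character(), compound = character(),
               dose = character(), pathway = character(),
               ks_up = numeric(), ks_down = numeric(),
               score = numeric(), p_value = numeric(),
               stringsAsFactors = FALSE)
  class(out) <- c("connectivity_table", "data.frame")
  out
}
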