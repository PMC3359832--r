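# Shared fixtures and independent oracles for the test suite.

# Literal transcription of the signed KS formula as a double loop over the
# common-denominator numerators (j/t - V/N = (jN - Vt)/(tN), all integers),
# independent of the vectorized implementation it checks.
ks_oracle <- function(V, N) {
  V <- sort(V)
  t <- length(V)
  p_num <- -Inf
  n_num <- -Inf
  for (j in seq_len(t)) {
    if (j * N - V[j] * t > p_num) p_num <- j * N - V[j] * t
    if (V[j] * t - (j - 1) * N > n_num) n_num <- V[j] * t - (j - 1) * N
  }
  if (p_num > n_num) p_num / (t * N)
  else if (n_num > p_num) -n_num / (t * N)
  else 0
}

tiny_expression <- function() {
  v <- matrix(c(1, 2, 3, 3, 2, 1), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s_pre", "s_post")))
  expression_matrix(v, pairs = data.frame(patient = "P1", pre = "s_pre",
                                          post = "s_post"))
}

tiny_bank <- function() {
  genes <- c("g1", "g2", "g3", "g4")
  ranks <- cbind(inst1 = 1:4, inst2 = 4:1)
  rownames(ranks) <- genes
  meta <- data.frame(instance_id = c("inst1", "inst2"),
                     compound = c("drugA", "drugB"),
                     dose = c("1 uM", "10 uM"),
                     cell_line = c("", ""), stringsAsFactors = FALSE)
  reference_bank(meta, ranks)
}

# A signature given directly, bypassing the fold-change machinery.
make_signature <- function(up, down, fc = 2) {
  structure(list(up = up, down = down, fc_threshold = fc),
            class = "tag_signature")
}

# A ranking given directly as gene order (most up-regulated first).
make_ranking <- function(genes, log2fc = rev(seq_along(genes))) {
  out <- data.frame(gene = genes, log2fc = log2fc,
                    rank = seq_along(genes), stringsAsFactors = FALSE)
  class(out) <- c("differential_ranking", "data.frame")
  out
}

small_sim_config <- function(seed = 1, ...) {
  simulation_config(n_genes = 400, n_instances = 10, n_pathways = 25,
                    pathway_size_range = c(8, 40), signature_size = 20,
                    affected_pathways_per_instance = 4, seed = seed, ...)
}
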