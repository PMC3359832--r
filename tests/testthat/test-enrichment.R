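test_that("hypergeometric enrichment matches the enumerated tail", {
  universe <- paste0("g", 1:10)
  sig <- make_signature(up = paste0("g", 1:3), down = paste0("g", 4:5))
  pw <- pathway_collection(list(hit = paste0("g", 1:5),
                                cold = paste0("g", 6:10),
                                outside = c("x1", "x2")))
  expect_message(res <- hypergeometric_enrichment(sig, pw, universe),
                 "skipped")
  # perfect overlap of a 5-gene pathway with the 5 DE genes in a
  # 10-gene universe: P(X >= 5) = 1/C(10,5) = 1/252
  expect_equal(res$p_value[res$pathway == "hit"], 1 / 252)
  # zero overlap: upper tail including P(X >= 0) is 1
  expect_equal(res$p_value[res$pathway == "cold"], 1)
  expect_false("outside" %in% res$pathway)
  expect_equal(res$n_de_in_pathway[res$pathway == "hit"], 5)
  expect_equal(res$n_pathway_genes_in_universe[res$pathway == "hit"], 5)
})

test_that("an empty differential set yields p = 1 everywhere with a warning", {
  universe <- paste0("g", 1:10)
  sig <- make_signature(up = character(), down = character())
  pw <- pathway_collection(list(a = paste0("g", 1:5)))
  expect_warning(res <- hypergeometric_enrichment(sig, pw, universe),
                 "empty differential")
  expect_equal(res$p_value, 1)
})

test_that("rank-KS enrichment flags a top-loaded pathway as extreme", {
  genes <- sprintf("g%03d", 1:200)
  r <- make_ranking(genes, seq(5, -5, length.out = 200))
  pw <- pathway_collection(list(top = genes[1:10],
                                random = genes[c(3, 50, 77, 120, 199)]))
  res <- ks_permutation_enrichment(r, pw, n_perm = 500, seed = 9)
  # members occupying the top t positions maximize |KS| over same-size sets
  expect_equal(res$p_value[res$pathway == "top"], 1 / 501)
  expect_equal(res$statistic[res$pathway == "top"], 1 - 10 / 200)
  expect_gt(res$p_value[res$pathway == "random"], 0.05)
})

test_that("rank-KS enrichment is deterministic under a seed and skips
           unmeasured pathways", {
  genes <- sprintf("g%03d", 1:100)
  r <- make_ranking(genes)
  pw <- pathway_collection(list(a = genes[seq(5, 60, 5)], b = genes[70:90],
                                ghost = c("nope1", "nope2")))
  expect_message(r1 <- ks_permutation_enrichment(r, pw, n_perm = 200, seed = 4),
                 "skipped")
  r2 <- suppressMessages(
    ks_permutation_enrichment(r, pw, n_perm = 200, seed = 4))
  expect_identical(r1$p_value, r2$p_value)
  expect_false("ghost" %in% r1$pathway)
})

test_that("rank-KS p-values ignore relabeling outside the pathway", {
  genes <- sprintf("g%03d", 1:80)
  members <- genes[c(4, 9, 33, 57, 70)]
  r <- make_ranking(genes)
  relabeled <- genes
  outside <- setdiff(genes, members)
  relabeled[match(outside, genes)] <- paste0("x_", outside)
  r2 <- make_ranking(relabeled)
  pw <- pathway_collection(list(m = members))
  p1 <- ks_permutation_enrichment(r, pw, n_perm = 300, seed = 8)$p_value
  p2 <- ks_permutation_enrichment(r2, pw, n_perm = 300, seed = 8)$p_value
  expect_identical(p1, p2)
})

test_that("rank-KS p-values are approximately uniform under the null", {
  set.seed(55)
  genes <- sprintf("g%04d", 1:1000)
  r <- make_ranking(sample(genes))
  sets <- lapply(1:150, function(i) sample(genes, sample(10:50, 1)))
  names(sets) <- sprintf("pw%03d", 1:150)
  res <- ks_permutation_enrichment(r, pathway_collection(sets),
                                   n_perm = 400, seed = 56)
  expect_gt(mean(res$p_value < 0.5), 0.38)
  expect_lt(mean(res$p_value < 0.5), 0.62)
})

test_that("pathway selection uses strict p < alpha and preserves order", {
  pw <- pathway_collection(list(a = "g1", b = "g2", c = "g3"))
  res <- data.frame(pathway = c("a", "b", "c"),
                    p_value = c(0.01, 0.05, 0.2))
  sel <- select_pathways(res, pw, alpha = 0.05)
  expect_identical(names(sel), "a")  # 0.05 itself is not selected
  expect_identical(names(select_pathways(res, pw, alpha = 1)),
                   c("a", "b", "c"))
  none <- select_pathways(res, pw, alpha = 0.001)
  expect_length(none, 0)
  expect_s3_class(none, "pathway_collection")
  expect_error(select_pathways(res, pw, alpha = 0), "alpha")
})

test_that("selection is monotone in alpha and a subset of the input", {
  set.seed(12)
  pw <- pathway_collection(setNames(as.list(paste0("g", 1:30)),
                                    paste0("pw", 1:30)))
  res <- data.frame(pathway = names(pw), p_value = runif(30))
  prev <- character()
  for (alpha in c(0.05, 0.1, 0.3, 0.8, 1)) {
    sel <- names(select_pathways(res, pw, alpha = alpha))
    expect_true(all(prev %in% sel))
    expect_true(all(sel %in% names(pw)))
    prev <- sel
  }
})

test_that("an optional BH gate is stricter than the raw gate", {
  pw <- pathway_collection(setNames(as.list(paste0("g", 1:20)),
                                    paste0("pw", 1:20)))
  set.seed(13)
  res <- data.frame(pathway = names(pw),
                    p_value = c(0.001, 0.04, runif(18, 0.2, 1)))
  raw <- names(select_pathways(res, pw, alpha = 0.05))
  bh <- names(select_pathways(res, pw, alpha = 0.05, adjust = "BH"))
  expect_true(all(bh %in% raw))
  expect_true(length(bh) <= length(raw))
})
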