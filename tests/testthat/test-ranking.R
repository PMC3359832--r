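make_cells <- function(df) {
  df$compound <- ifelse(is.na(match(df$instance_id, df$instance_id)), "",
                        paste0("drug_", df$instance_id))
  df$dose <- "1 uM"
  df$ks_up <- NA_real_
  df$ks_down <- NA_real_
  df <- df[, c("instance_id", "compound", "dose", "pathway",
               "ks_up", "ks_down", "score", "p_value")]
  class(df) <- c("connectivity_table", "data.frame")
  df
}

test_that("pathway counting applies the score sign, p and magnitude filters", {
  cells <- make_cells(data.frame(
    instance_id = "i1",
    pathway = c("a", "b", "c"),
    score = c(0.9, -0.8, 0.1),
    p_value = c(0.01, 0.02, 0.6), stringsAsFactors = FALSE))
  s <- count_pathways(cells, alpha = 0.05)
  expect_equal(s$positive_count, 1)
  expect_equal(s$negative_count, 1)
  expect_equal(s$total_count, 2)
  expect_equal(s$sum_abs_score, 1.7)

  # permissive preset: every nonzero-score pathway counts
  s2 <- count_pathways(cells, alpha = 1)
  expect_equal(s2$positive_count, 2)
  expect_equal(s2$negative_count, 1)

  s3 <- count_pathways(cells, alpha = 1, min_abs_score = 0.5)
  expect_equal(s3$total_count, 2)

  zero <- make_cells(data.frame(instance_id = "i1", pathway = c("a", "b"),
                                score = c(0, 0), p_value = c(1, 1),
                                stringsAsFactors = FALSE))
  sz <- count_pathways(zero, alpha = 1)
  expect_equal(sz$positive_count, 0)
  expect_equal(sz$negative_count, 0)
})

test_that("counts are invariant to the order of the cells", {
  set.seed(61)
  cells <- make_cells(data.frame(
    instance_id = rep(paste0("i", 1:5), each = 8),
    pathway = rep(paste0("pw", 1:8), 5),
    score = round(runif(40, -1, 1), 2),
    p_value = runif(40), stringsAsFactors = FALSE))
  a <- count_pathways(cells)
  perm <- cells[sample(nrow(cells)), ]
  class(perm) <- class(cells)
  b <- count_pathways(perm)
  b <- b[match(a$instance_id, b$instance_id), ]
  rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("counting without p-values requires the permissive preset", {
  cells <- make_cells(data.frame(instance_id = "i1", pathway = "a",
                                 score = 0.5, p_value = NA_real_,
                                 stringsAsFactors = FALSE))
  expect_error(count_pathways(cells, alpha = 0.05), "p-values")
  expect_equal(count_pathways(cells, alpha = 1)$positive_count, 1)
})

test_that("mirror-image instances have mirrored counts", {
  cells <- make_cells(data.frame(
    instance_id = rep(c("fwd", "rev"), each = 4),
    pathway = rep(paste0("pw", 1:4), 2),
    score = c(0.8, -0.4, 0.6, 0, -0.8, 0.4, -0.6, 0),
    p_value = rep(c(0.01, 0.2, 0.03, 1), 2), stringsAsFactors = FALSE))
  s <- count_pathways(cells, alpha = 0.05)
  fwd <- s[s$instance_id == "fwd", ]
  rev <- s[s$instance_id == "rev", ]
  expect_equal(fwd$positive_count, rev$negative_count)
  expect_equal(fwd$negative_count, rev$positive_count)
})

test_that("the report orders by total count with deterministic tie-breaks", {
  s <- data.frame(
    instance_id = c("i_b", "i_a", "i_c", "i_d"),
    compound = paste0("drug", 1:4), dose = "1 uM",
    positive_count = c(20, 18, 20, 5),
    negative_count = c(2, 3, 2, 0),
    total_count = c(22, 21, 22, 5),
    sum_abs_score = c(5.1, 9, 4.9, 1), stringsAsFactors = FALSE)
  rep <- top_k_report(s, k = 3)
  # ties at 22 broken by sum_abs_score (5.1 beats 4.9)
  expect_identical(rep$instance_id, c("i_b", "i_c", "i_a"))
  expect_equal(nrow(top_k_report(s, k = 10)), 4)

  # equal sum_abs_score falls through to the id tie-break
  s$sum_abs_score <- 1
  rep2 <- top_k_report(s, k = 4)
  expect_identical(rep2$instance_id[1:2], c("i_b", "i_c"))

  s$positive_count[4] <- 0; s$negative_count[4] <- 30; s$total_count[4] <- 30
  rep3 <- top_k_report(s, k = 1, rank_by = "max")
  expect_identical(rep3$instance_id, "i_d")
})

test_that("pathway counts render in the printed-table style", {
  expect_identical(format_pathway_counts(20, 1), "20+ 1−")
  expect_identical(format_pathway_counts(22, 0), "22+")
  expect_identical(format_pathway_counts(0, 20), "20−")
  expect_identical(format_pathway_counts(0, 0), "0")
  expect_identical(format_pathway_counts(c(3, 0), c(1, 4)),
                   c("3+ 1−", "4−"))
})

test_that("report files are written as CSV plus aligned text", {
  d <- withr::local_tempdir()
  s <- data.frame(instance_id = "i1", compound = "Chlorpropamide",
                  dose = "100 uM", positive_count = 20L,
                  negative_count = 1L, total_count = 21L,
                  sum_abs_score = 8.2, stringsAsFactors = FALSE)
  files <- write_report(top_k_report(s), file.path(d, "top"))
  expect_true(all(file.exists(files)))
  txt <- readLines(files[[2]], encoding = "UTF-8")
  expect_match(txt[[1]], "Drug molecule")
  expect_match(txt[[2]], "20\\+ 1−")
  back <- read.csv(files[[1]])
  expect_equal(back$positive_count, 20)
})
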