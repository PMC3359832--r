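test_that("ks_statistic reproduces hand-computed and closed-form cases", {
  # top-loaded: 1 - t/N; bottom-loaded: -(N - t + 1)/N
  expect_equal(ks_statistic(1:3, 10), 0.7)
  expect_equal(ks_statistic(8:10, 10), -0.8)
  # V = (1, 2, 8): p = max(7/30, 14/30, 1/5) = 7/15, n = max(1/10, -2/15, 2/15)
  expect_equal(ks_statistic(c(1, 2, 8), 10), 7 / 15)
  expect_error(ks_statistic(integer(), 10), "at least one")
  expect_error(ks_statistic(c(1, 1), 10), "distinct")
  expect_error(ks_statistic(c(0, 5), 10), "1..N")
})

test_that("ks_statistic agrees with the literal double-loop oracle", {
  set.seed(33)
  for (i in 1:1000) {
    N <- sample(2:50, 1)
    t <- sample.int(N, 1)
    V <- sort(sample.int(N, t))
    expect_identical(ks_statistic(V, N), ks_oracle(V, N))
  }
})

test_that("ks_statistic is bounded and attains the closed-form extremes", {
  for (N in 3:50) {
    for (t in 1:(N - 2)) {
      expect_equal(ks_statistic(1:t, N), 1 - t / N)
      expect_equal(ks_statistic((N - t + 1):N, N), -(N - t + 1) / N)
    }
    # at t = N - 1 the top extreme has p = n = 1/N: the tie rule gives 0,
    # while the bottom extreme still follows its closed form
    expect_identical(ks_statistic(1:(N - 1), N), 0)
    expect_equal(ks_statistic(2:N, N), -2 / N)
  }
  set.seed(34)
  for (i in 1:200) {
    N <- sample(2:50, 1)
    V <- sort(sample.int(N, sample.int(N, 1)))
    ks <- ks_statistic(V, N)
    expect_gte(ks, -1)
    expect_lte(ks, 1)
  }
})

test_that("pathway connectivity follows the sign conventions", {
  profile <- paste0("g", 1:10)
  pathway <- profile
  # up tags on top, down tags at bottom: strong mimicry
  sig <- make_signature(up = c("g1", "g2"), down = c("g9", "g10"))
  cell <- pathway_connectivity(sig, profile, pathway)
  expect_gt(cell$ks_up, 0)
  expect_lt(cell$ks_down, 0)
  expect_equal(cell$score, (cell$ks_up - cell$ks_down) / 2)
  expect_gt(cell$score, 0.5)

  # both groups at the top share a sign: incoherent, score 0
  sig2 <- make_signature(up = c("g1", "g2"), down = c("g3", "g4"))
  expect_equal(pathway_connectivity(sig2, profile, pathway)$score, 0)

  # one empty group: the other carries the score; down flips sign
  sig3 <- make_signature(up = character(), down = c("g1", "g2"))
  cell3 <- pathway_connectivity(sig3, profile, pathway)
  expect_equal(cell3$score, -cell3$ks_down)
  expect_lt(cell3$score, 0)

  # no tag genes in the pathway: cell is skipped
  sig4 <- make_signature(up = "absent", down = character())
  expect_null(pathway_connectivity(sig4, profile, pathway))
})

test_that("the profile is restricted to the pathway before scoring", {
  profile <- paste0("g", 1:100)
  pathway <- c("g1", "g2", "g99", "g100", "g50")
  sig <- make_signature(up = c("g1", "g2"), down = character())
  cell <- pathway_connectivity(sig, profile, pathway)
  expect_equal(cell$n, 5)
  # restricted positions are 1,2 of 5: the top extreme, KS = 1 - 2/5
  expect_equal(cell$ks_up, 1 - 2 / 5)
  expect_equal(cell$score, cell$ks_up)
})

test_that("combined score is antisymmetric under profile reversal", {
  # Reversing the ranking maps a group's (p, n) to (n - 1/N, p + 1/N), so
  # exact negation needs every bottom-decided group (ks = -n) to be
  # decided by a margin n - p > 2/N; at or below that margin the reversed
  # group ties or flips sign, collapsing the combined score toward 0.
  decisive <- function(V, N) {
    t <- length(V)
    j <- seq_len(t)
    p <- max(j * N - V * t)
    n <- max(V * t - (j - 1) * N)
    p > n || n - p > 2 * t   # numerators on the common denominator t*N
  }
  set.seed(35)
  checked <- 0
  while (checked < 80) {
    N <- sample(10:60, 1)
    profile <- sample(sprintf("g%03d", 1:N))
    genes <- sample(profile, sample(4:min(N, 12), 1))
    half <- max(1, length(genes) %/% 2)
    sig <- make_signature(up = genes[seq_len(half)],
                          down = genes[-seq_len(half)])
    if (!length(sig$up) || !length(sig$down)) next
    fwd <- pathway_connectivity(sig, profile, profile)$score
    bwd <- pathway_connectivity(sig, rev(profile), profile)$score
    if (fwd == 0) next
    v_up <- which(profile %in% sig$up)
    v_dn <- which(profile %in% sig$down)
    if (decisive(v_up, N) && decisive(v_dn, N)) {
      expect_equal(bwd, -fwd)
      checked <- checked + 1
    }
  }
})

test_that("single_set mode scores the pooled tag list", {
  profile <- paste0("g", 1:10)
  sig <- make_signature(up = c("g1", "g2"), down = c("g3", "g4"))
  cell <- pathway_connectivity(sig, profile, profile, mode = "single_set")
  expect_equal(cell$score, ks_statistic(1:4, 10))
  expect_true(is.na(cell$ks_up) && is.na(cell$ks_down))
})

test_that("halving can be disabled for the unhalved convention", {
  profile <- paste0("g", 1:10)
  sig <- make_signature(up = c("g1", "g2"), down = c("g9", "g10"))
  h <- pathway_connectivity(sig, profile, profile, halve = TRUE)
  u <- pathway_connectivity(sig, profile, profile, halve = FALSE)
  expect_equal(u$score, 2 * h$score)
})

test_that("permutation nulls are deterministic and flag extreme scores", {
  set.seed(36)
  null <- connectivity_null(20, 3, 3, n_perm = 500)
  expect_length(null, 500)
  # a maximal configuration beats every permutation
  expect_equal(connectivity_significance(2, null), 1 / 501)
  # every permuted score at least ties with itself
  expect_gte(connectivity_significance(0, null), 0.9)

  set.seed(77); a <- connectivity_null(30, 4, 2, n_perm = 200)
  set.seed(77); b <- connectivity_null(30, 4, 2, n_perm = 200)
  expect_identical(a, b)
  expect_error(connectivity_null(10, 0, 0), "non-empty")
  expect_error(connectivity_null(5, 3, 3), "more tags")
})

test_that("permutation p-values for random tags are calibrated", {
  # single_set mode: the score has no atom, so the p-value is close to
  # uniform; combined mode: incoherent (same-sign) draws score 0 and get
  # p = 1, so the p-value is conservative but never anti-conservative
  set.seed(37)
  N <- 40
  null_single <- connectivity_null(N, 8, 0, n_perm = 1000,
                                   mode = "single_set")
  p_single <- replicate(400, connectivity_significance(
    ks_statistic(sort(sample.int(N, 8)), N), null_single))
  expect_gt(mean(p_single < 0.5), 0.40)
  expect_lt(mean(p_single < 0.5), 0.60)
  expect_gt(mean(p_single < 0.1), 0.05)
  expect_lt(mean(p_single < 0.1), 0.16)

  null_comb <- connectivity_null(N, 4, 4, n_perm = 1000)
  p_comb <- replicate(400, {
    pos <- sample.int(N, 8)
    ks_up <- ks_statistic(sort(pos[1:4]), N)
    ks_dn <- ks_statistic(sort(pos[5:8]), N)
    score <- if (sign(ks_up) == sign(ks_dn)) 0 else (ks_up - ks_dn) / 2
    connectivity_significance(score, null_comb)
  })
  expect_lt(mean(p_comb < 0.05), 0.09)
  expect_lt(mean(p_comb < 0.1), 0.15)
})

test_that("connectivity_table scores every instance in every pathway", {
  bank <- tiny_bank()  # inst1: g1..g4; inst2 reversed
  pw <- pathway_collection(list(all = c("g1", "g2", "g3", "g4")))
  sig <- make_signature(up = "g1", down = "g4")
  tab <- connectivity_table(sig, bank, pw, n_perm = 100, seed = 5)
  expect_s3_class(tab, "connectivity_table")
  expect_equal(nrow(tab), 2)
  s1 <- tab$score[tab$instance_id == "inst1"]
  s2 <- tab$score[tab$instance_id == "inst2"]
  expect_gt(s1, 0)   # inst1 mimics the signature
  expect_equal(s2, -s1)  # inst2 is its exact reversal
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
})

test_that("tag genes outside the bank universe are dropped with a message", {
  bank <- tiny_bank()
  pw <- pathway_collection(list(all = c("g1", "g2", "g3", "g4")))
  sig <- make_signature(up = c("g1", "gX"), down = "g4")
  expect_message(tab <- connectivity_table(sig, bank, pw, n_perm = 0),
                 "dropped")
  expect_equal(nrow(tab), 2)
  expect_true(all(is.na(tab$p_value)))
})
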