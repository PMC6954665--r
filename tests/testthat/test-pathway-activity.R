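test_that("raw pathway scores are weighted sums over present members", {
  dereg <- make_dereg(c(A = 1, B = 2, C = 3))
  members <- tibble::tibble(gene_id = c("A", "B", "C"), weight = 1)
  expect_equal(pathway_raw_score(dereg, members)$raw_score, 6)

  # activators and an inhibitor cancel
  dereg2 <- make_dereg(c(A = 2, B = 2, C = 4))
  members2 <- tibble::tibble(gene_id = c("A", "B", "C"),
                             weight = c(1, 1, -1))
  expect_equal(pathway_raw_score(dereg2, members2)$raw_score, 0)

  # random pathway equals an independent dot-product oracle
  set.seed(5)
  for (rep in 1:5) {
    scores <- rnorm(40)
    names(scores) <- sprintf("G%02d", 1:40)
    pick <- sample(names(scores), 10)
    w <- sample(c(-1, 1), 10, replace = TRUE) * runif(10, 0.5, 2)
    got <- pathway_raw_score(make_dereg(scores),
                             tibble::tibble(gene_id = pick, weight = w))
    oracle <- 0
    for (i in seq_along(pick)) oracle <- oracle + w[i] * scores[[pick[i]]]
    expect_equal(got$raw_score, oracle)
  }

  # no member scored -> not assessable
  none <- pathway_raw_score(make_dereg(c(X = 1)),
                            tibble::tibble(gene_id = c("A", "B", "C"),
                                           weight = 1))
  expect_false(none$assessable)
})

test_that("activity normalization is the pooled midrank position", {
  # above every one of 999 nulls -> 0.999
  expect_equal(normalize_activity(10, seq_len(999) / 1000), 1000 / 1001,
               tolerance = 1e-12)
  expect_equal(round(normalize_activity(10, seq_len(999) / 1000), 3), 0.999)
  # equal to the null median (odd count) -> 0.5
  nulls <- seq(-499, 499)
  expect_equal(normalize_activity(0, nulls), 0.5)
  # all-zero deregulation: every score ties -> 0.5 by symmetry
  expect_equal(normalize_activity(0, rep(0, 999)), 0.5)

  # sign-symmetric score distribution: mean activity across simulated
  # degenerate pathways stays at 0.5
  set.seed(9)
  acts <- replicate(200, {
    nulls <- rnorm(199)
    normalize_activity(rnorm(1), nulls)
  })
  expect_lt(abs(mean(acts) - 0.5), 0.02)
})

test_that("empirical p-values follow the add-one permutation formula", {
  set.seed(2)
  dereg <- make_dereg(setNames(rnorm(50), sprintf("G%02d", 1:50)))
  # observed more extreme than every permutation -> 1 / (n_perm + 1)
  ep <- empirical_pvalue(1e6, dereg, weights = rep(1, 5), n_perm = 999)
  expect_equal(ep$p_value, 1 / 1000)

  # pathway covering all scored genes with equal weights: every
  # permutation returns the same sum, p = 1
  ep_all <- empirical_pvalue(sum(dereg$score), dereg,
                             weights = rep(1, 50), n_perm = 200)
  expect_equal(ep_all$p_value, 1)

  expect_error(empirical_pvalue(1, dereg, rep(1, 5), n_perm = 10),
               "n_perm")
})

test_that("exhaustive permutation p matches full enumeration", {
  dereg <- make_dereg(c(A = 1.2, B = -0.4, C = 2.1, D = 0.3, E = -1.7))
  w <- c(1, -1, 1, 1)
  obs <- sum(w * dereg$score[1:4])
  got <- empirical_pvalue(obs, dereg, w, exhaustive = TRUE)
  # independent oracle: enumerate every ordered 4-tuple via expand.grid
  grid <- expand.grid(i1 = 1:5, i2 = 1:5, i3 = 1:5, i4 = 1:5)
  grid <- grid[apply(grid, 1, function(r) length(unique(r)) == 4), ]
  oracle_null <- apply(grid, 1, function(r) sum(w * dereg$score[r]))
  expect_equal(length(got$null_scores), nrow(grid))
  expect_equal(sort(got$null_scores), sort(unname(oracle_null)),
               tolerance = 1e-12)
  oracle_p <- (1 + sum(abs(oracle_null) >= abs(obs))) /
    (length(oracle_null) + 1)
  expect_equal(got$p_value, oracle_p)
})

# textbook step-up BH, written independently of any library routine
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

test_that("BH adjustment equals the textbook step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  set.seed(4)
  p <- runif(50)
  expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  # never decreases and never exceeds 1
  expect_true(all(adjust_bh(p) >= p))
  expect_true(all(adjust_bh(p) <= 1))
  expect_error(adjust_bh(c(0.5, 0)), "0, 1")
})

test_that("activity labels respect the interval boundaries", {
  expect_equal(label_activity(0.4), "medium")
  expect_equal(label_activity(0.6), "medium")
  expect_equal(label_activity(0.61), "high")
  expect_equal(label_activity(1), "high")
  expect_equal(label_activity(0), "low")
  expect_equal(label_activity(0.399), "low")
  expect_error(label_activity(1.2), "\\[0, 1\\]")
})

test_that("pathway scoring is reproducible and scale equivariant", {
  kb <- test_kb()
  set.seed(31)
  dereg <- make_dereg(setNames(rnorm(330), kb$xref$symbol))
  pa1 <- score_pathways(dereg, kb, n_perm = 200, seed = 5)
  pa2 <- score_pathways(dereg, kb, n_perm = 200, seed = 5)
  expect_identical(pa1, pa2)
  expect_true(all(pa1$activity >= 0 & pa1$activity <= 1, na.rm = TRUE))
  expect_true(all(pa1$p_adjusted >= pa1$p_value, na.rm = TRUE))
  expect_true(all(pa1$label[pa1$assessable] ==
                    label_activity(pa1$activity[pa1$assessable])))

  # doubling all scores with the same permutation stream leaves the
  # rank-based activity and p-value unchanged
  doubled <- dereg
  doubled$score <- 2 * doubled$score
  pa3 <- score_pathways(doubled, kb, n_perm = 200, seed = 5)
  expect_equal(pa3$activity, pa1$activity)
  expect_equal(pa3$p_value, pa1$p_value)
})

test_that("pathways with too few scored members are not assessable", {
  kb <- test_kb()
  few <- make_dereg(c(BRCA1 = 1, GENE0001 = 0.2, GENE0002 = -0.3,
                      GENE0003 = 0.8, GENE0004 = 0.1))
  pa <- score_pathways(few, kb, n_perm = 100, seed = 1)
  dr <- pa[pa$pathway_id == "DNA_repair", ]
  expect_false(dr$assessable)   # 1/15 members scored is below 25%
  expect_true(is.na(dr$activity))
})

test_that("similarity ranking is the mean-squared-distance order", {
  q <- c(p1 = 0.5, p2 = 0.5, p3 = 0.5)
  cohort <- tibble::tibble(sample_id = c("S1", "S2", "S3"),
                           p1 = c(0.5, 0, 1), p2 = c(0.5, 0, 1),
                           p3 = c(0.5, 0, 1))
  r <- rank_similar_samples(q, cohort)
  expect_equal(r$sample_id[1], "S1")
  expect_equal(r$distance[1], 0)
  # all-zero query vs all-one reference over 20 pathways -> distance 1
  q20 <- setNames(rep(0, 20), sprintf("pw%02d", 1:20))
  c20 <- tibble::as_tibble(c(list(sample_id = "R"),
                             setNames(as.list(rep(1, 20)), names(q20))))
  expect_equal(rank_similar_samples(q20, c20)$distance, 1)

  # random cohort ordering equals an independent recomputed sort
  set.seed(12)
  ref <- tibble::as_tibble(cbind(
    data.frame(sample_id = sprintf("S%02d", 1:30)),
    matrix(runif(30 * 20), 30, dimnames = list(NULL, names(q20)))))
  qr <- setNames(runif(20), names(q20))
  got <- rank_similar_samples(qr, ref)
  oracle <- vapply(seq_len(30), function(i) {
    mean((as.numeric(ref[i, names(q20)]) - qr)^2)
  }, numeric(1))
  expect_equal(got$sample_id,
               ref$sample_id[order(oracle, ref$sample_id)])
  # ties broken lexicographically by construction: distances match too
  expect_equal(got$distance, sort(oracle))
})

test_that("radar export keeps the pathway order and reference overlays", {
  kb <- test_kb()
  set.seed(8)
  dereg <- make_dereg(setNames(rnorm(330), kb$xref$symbol))
  pa <- score_pathways(dereg, kb, n_perm = 100, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  export_radar(pa, path)
  back <- jsonlite::read_json(path)
  expect_equal(unlist(back$pathway_order), pa$pathway_id)
  expect_equal(length(back$activities), 20)
})
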