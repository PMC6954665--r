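test_that("mutation grading combines impact with SIFT/PolyPhen", {
  fs <- make_mutations("CYP2D6", "frameshift_variant")
  expect_equal(grade_mutation(fs), "severe")
  mis_del <- make_mutations("TP53", "missense_variant", sift = 0.02,
                            polyphen = 0.1)
  expect_equal(grade_mutation(mis_del), "damaging")
  mis_pp <- make_mutations("TP53", "missense_variant", sift = 0.4,
                           polyphen = 0.9)
  expect_equal(grade_mutation(mis_pp), "damaging")
  mis_ben <- make_mutations("TP53", "missense_variant", sift = 0.5,
                            polyphen = 0.2)
  expect_equal(grade_mutation(mis_ben), "moderate")
  syn <- make_mutations("TP53", "synonymous_variant")
  expect_equal(grade_mutation(syn), "low")
  other <- make_mutations("TP53", "other")
  expect_equal(grade_mutation(other), "unknown")

  # monotone: raising impact to HIGH never lowers the grade
  ranks <- match(c(grade_mutation(mis_ben),
                   grade_mutation(dplyr::mutate(mis_ben, impact = "HIGH"))),
                 c("severe", "damaging", "moderate", "low", "unknown"))
  expect_lte(ranks[2], ranks[1])
})

test_that("segment-to-gene mapping is the length-weighted overlap mean", {
  models <- tibble::tibble(gene_id = c("A", "B"), chrom = "chr1",
                           start = c(100L, 1000L), end = c(299L, 1399L))
  # gene fully inside one segment
  seg1 <- tibble::tibble(chrom = "chr1", start = 1L, end = 500L,
                         log_ratio = 1.2, origin = "somatic")
  got <- map_segments_to_genes(seg1, models)
  expect_equal(got$gene_id, "A")
  expect_equal(got$log_ratio, 1.2)
  expect_equal(got$call, "amplified")

  # gene split 50/50 across two segments of 1.0 and 0.0 -> 0.5, amplified
  seg2 <- tibble::tibble(chrom = "chr1", start = c(1000L, 1200L),
                         end = c(1199L, 1399L), log_ratio = c(1, 0),
                         origin = "somatic")
  got2 <- map_segments_to_genes(seg2, models)
  expect_equal(got2$log_ratio[got2$gene_id == "B"], 0.5)
  expect_equal(got2$call[got2$gene_id == "B"], "amplified")

  # genes with no overlap are omitted; neutral/deleted calls honored
  seg3 <- tibble::tibble(chrom = "chr1", start = 100L, end = 299L,
                         log_ratio = -0.9, origin = "somatic")
  got3 <- map_segments_to_genes(seg3, models)
  expect_equal(got3$gene_id, "A")
  expect_equal(got3$call, "deleted")
})

test_that("random segment mapping equals a per-base oracle", {
  set.seed(21)
  models <- tibble::tibble(
    gene_id = sprintf("G%03d", 1:40),
    chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
    start = as.integer(sample(1:800, 40) * 5)
  ) %>% dplyr::mutate(end = start + as.integer(sample(20:120, 40)))
  segs <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 60, replace = TRUE),
    start = as.integer(sample(1:4000, 60))
  ) %>% dplyr::mutate(end = start + as.integer(sample(10:400, 60)),
                      log_ratio = round(rnorm(60, 0, 0.6), 3),
                      origin = "somatic")
  got <- suppressWarnings(map_segments_to_genes(segs, models))
  # oracle: accumulate segment values base by base over each gene body
  for (i in seq_len(nrow(models))) {
    vals <- c()
    for (p in models$start[i]:models$end[i]) {
      hit <- which(segs$chrom == models$chrom[i] & segs$start <= p &
                     segs$end >= p)
      vals <- c(vals, segs$log_ratio[hit])
    }
    j <- match(models$gene_id[i], got$gene_id)
    if (length(vals) == 0) {
      expect_true(is.na(j))
    } else {
      expect_equal(got$log_ratio[j], mean(vals), tolerance = 1e-9)
      # conservation: weighted mean within [min, max] of overlaps
      expect_gte(got$log_ratio[j], min(vals) - 1e-9)
      expect_lte(got$log_ratio[j], max(vals) + 1e-9)
    }
  }
})

test_that("driver prioritization gates on the catalog and scores channels", {
  kb <- test_kb()
  bundle <- assemble_bundle(
    deregulation = make_dereg(c(TP53 = 0.1, MYC = 2.5, GENE0001 = 5)),
    mutations = make_mutations("TP53", "frameshift_variant"),
    cna = tibble::tibble(gene_id = "ERBB2", log_ratio = 1.1,
                         call = "amplified")
  )
  drv <- prioritize_drivers(bundle, kb$drivers)
  # TP53 severe, catalog weight 3 -> 3 * 3 = 9, top of the list
  expect_equal(drv$gene_id[1], "TP53")
  expect_equal(drv$priority_score[1], 9)
  expect_true("MYC" %in% drv$gene_id)          # expression channel
  expect_true("ERBB2" %in% drv$gene_id)        # cna channel
  expect_false("GENE0001" %in% drv$gene_id)    # not in the catalog
  expect_false("BRCA1" %in% drv$gene_id)       # catalog but unaltered

  # stable under input order permutation
  set.seed(14)
  shuffled <- bundle
  shuffled$deregulation <- bundle$deregulation[sample.int(3), ]
  drv2 <- prioritize_drivers(shuffled, kb$drivers[sample.int(nrow(kb$drivers)), ])
  expect_equal(drv2, drv)
})

test_that("driver ordering equals an independent scoring oracle", {
  kb <- test_kb()
  set.seed(33)
  genes <- sample(kb$drivers$gene_id, 12)
  bundle <- assemble_bundle(
    deregulation = make_dereg(setNames(rnorm(12, 0, 2), genes)),
    mutations = make_mutations(
      sample(genes, 6),
      sample(c("missense_variant", "stop_gained", "synonymous_variant"),
             6, replace = TRUE),
      sift = runif(6), polyphen = runif(6)),
    cna = tibble::tibble(gene_id = sample(genes, 4),
                         log_ratio = rnorm(4, 0, 0.6)) %>%
      dplyr::mutate(call = dplyr::case_when(log_ratio >= 0.3 ~ "amplified",
                                            log_ratio <= -0.3 ~ "deleted",
                                            TRUE ~ "neutral"))
  )
  got <- prioritize_drivers(bundle, kb$drivers)
  # independent re-scoring with plain loops
  pts <- c(severe = 3, damaging = 2, moderate = 1, low = 0, unknown = 0)
  oracle <- list()
  for (i in seq_len(nrow(kb$drivers))) {
    g <- kb$drivers$gene_id[i]
    ch <- 0; grade <- "unknown"
    mg <- bundle$mutations[bundle$mutations$gene_id == g, ]
    if (nrow(mg) > 0) {
      gr <- grade_mutation(mg)
      grade <- gr[which.min(match(gr, c("severe", "damaging", "moderate",
                                        "low", "unknown")))]
      if (grade %in% c("severe", "damaging", "moderate")) ch <- ch + 1
    }
    j <- match(g, bundle$cna$gene_id)
    if (!is.na(j) && bundle$cna$call[j] != "neutral") ch <- ch + 1
    j <- match(g, bundle$deregulation$gene_id)
    if (!is.na(j) && abs(bundle$deregulation$score[j]) >= 2) ch <- ch + 1
    if (ch > 0) {
      oracle[[g]] <- kb$drivers$priority_weight[i] * pts[[grade]] + (ch - 1)
    }
  }
  ord <- names(oracle)[order(-unlist(oracle), names(oracle))]
  expect_equal(got$gene_id, ord)
  expect_equal(got$priority_score, unname(unlist(oracle)[got$gene_id]))
})
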