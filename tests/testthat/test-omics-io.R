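test_that("expression tables parse, collapse duplicates and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttumor\tctrl1\tctrl2",
               "TP53\t5\t3\t4", "BRCA1\t2\t2\t2", "MYC\t9\t1\t2"), path)
  expr <- read_expression(path)
  expect_equal(nrow(expr), 3)
  expect_true(all(lengths(expr$control_values) == 2))
  expect_equal(expr$tumor_value[expr$gene_id == "MYC"], 9)

  # duplicated gene rows collapse by mean with a warning
  writeLines(c("gene_id\ttumor\tctrl1",
               "TP53\t4\t1", "TP53\t6\t3"), path)
  expect_warning(dup <- read_expression(path), "duplicated")
  expect_equal(dup$tumor_value, 5)
  expect_equal(dup$control_values[[1]], 2)

  # non-numeric cell is fatal with location
  writeLines(c("gene_id\ttumor\tctrl1", "TP53\toops\t1"), path)
  expect_error(read_expression(path), "row 1.*tumor")

  # 1000-gene synthetic round trip
  set.seed(42)
  big <- tibble::tibble(
    gene_id = sprintf("G%04d", 1:1000),
    tumor_value = rnorm(1000, 8),
    control_values = purrr::map(1:1000, ~ rnorm(3, 8))
  )
  out <- withr::local_tempfile(fileext = ".tsv")
  write_expression(big, out)
  back <- read_expression(out)
  expect_equal(back$tumor_value, big$tumor_value, tolerance = 1e-9)
  expect_equal(do.call(rbind, back$control_values),
               do.call(rbind, big$control_values), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("deregulation scores follow the fold-change / z-score contract", {
  lfc <- compute_deregulation(tibble::tibble(
    gene_id = "A", tumor_value = 7, control_values = list(3)))
  expect_equal(lfc$score, 1)              # log2(8/4)
  expect_equal(lfc$score_kind, "log_fold_change")

  z <- compute_deregulation(tibble::tibble(
    gene_id = "A", tumor_value = 10, control_values = list(c(2, 4, 6))))
  expect_equal(z$score, 3)                # (10 - 4) / 2, sample sd
  expect_equal(z$score_kind, "z_score")

  # tumor equal to controls -> 0 under both kinds
  same1 <- compute_deregulation(tibble::tibble(
    gene_id = "A", tumor_value = 5, control_values = list(5)))
  same2 <- compute_deregulation(tibble::tibble(
    gene_id = "A", tumor_value = 5, control_values = list(c(4, 5, 6))))
  expect_equal(same1$score, 0)
  expect_equal(same2$score, 0)

  # zero-spread controls: score 0 and flagged, not infinite
  flat <- compute_deregulation(tibble::tibble(
    gene_id = "A", tumor_value = 9, control_values = list(c(2, 2, 2))))
  expect_equal(flat$score, 0)
  expect_true(flat$flagged)

  expect_error(compute_deregulation(tibble::tibble(
    gene_id = "A", tumor_value = 1, control_values = list(numeric(0)))),
    "control")
})

test_that("deregulation is order independent and z-scores are calibrated", {
  set.seed(7)
  expr <- tibble::tibble(
    gene_id = sprintf("G%04d", 1:5000),
    tumor_value = rnorm(5000, 5, 2),
    control_values = purrr::map(1:5000, ~ rnorm(30, 5, 2))
  )
  fwd <- compute_deregulation(expr)
  perm <- sample.int(5000)
  rev <- compute_deregulation(expr[perm, ])
  expect_equal(rev$score[order(perm)], fwd$score)

  # tumor and controls i.i.d. from the same normal: the z-score
  # distribution approaches standard normal for a well-sized control set
  expect_gt(stats::ks.test(fwd$score, "pnorm")$p.value, 0.01)
})

write_test_vcf <- function(path, rows) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Cons",
           "equence annotations from VeP. Format: Allele|Consequence|",
           "IMPACT|SYMBOL|SIFT|PolyPhen\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", rows), path)
}

test_that("VCF parsing splits alleles, reads CSQ and round-trips", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    "chr1\t1100\t.\tA\tG\t50\tPASS\tCSQ=G|missense_variant|MODERATE|TP53|0.02|0.9",
    "chr2\t500\t.\tA\tC,T\t50\tPASS\tCSQ=C|synonymous_variant|LOW|BRCA1||,T|stop_gained|HIGH|BRCA1||"
  ))
  muts <- read_vcf(path, origin = "somatic")
  expect_equal(nrow(muts), 3)  # one per ALT allele
  m1 <- muts[muts$pos == 1100, ]
  expect_equal(m1$consequence, "missense_variant")
  expect_equal(m1$gene_id, "TP53")
  expect_equal(m1$sift, 0.02)
  multi <- muts[muts$pos == 500, ]
  expect_equal(nrow(multi), 2)
  expect_setequal(multi$alt, c("C", "T"))
  expect_equal(multi$consequence[multi$alt == "T"], "stop_gained")

  # round trip preserves the variant key exactly
  out <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(muts, out)
  back <- read_vcf(out, origin = "somatic")
  expect_equal(back[c("chrom", "pos", "ref", "alt", "origin")],
               muts[c("chrom", "pos", "ref", "alt", "origin")])
  expect_equal(back$consequence, muts$consequence)

  # malformed line is fatal with its line number
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tA"), path)
  expect_error(read_vcf(path, "somatic"), "line 3")
})

test_that("parsed record count equals an independent ALT-walking oracle", {
  set.seed(11)
  n <- 200
  rows <- vapply(seq_len(n), function(i) {
    n_alt <- sample(1:3, 1)
    alts <- paste(sample(c("C", "G", "T"), n_alt), collapse = ",")
    sprintf("chr%d\t%d\t.\tA\t%s\t50\tPASS\t.",
            sample(1:5, 1), i * 37, alts)
  }, character(1))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, rows)
  muts <- read_vcf(path, origin = "germline")
  # oracle: walk raw lines and count comma-separated ALT alleles
  oracle <- sum(vapply(rows, function(r) {
    length(strsplit(strsplit(r, "\t")[[1]][5], ",")[[1]])
  }, numeric(1)))
  expect_equal(nrow(muts), oracle)
  expect_true(all(muts$consequence == "other"))
  expect_true(all(muts$impact == "MODIFIER"))
})

test_that("identifier mapping is total, idempotent and collision-safe", {
  kb <- test_kb()
  m <- map_identifiers("ENSG00000141510", kb$xref)
  expect_equal(unname(m), "TP53")
  expect_equal(unname(map_identifiers(c("7157", "672"), kb$xref)),
               c("TP53", "BRCA1"))
  expect_equal(unname(map_identifiers("P04637", kb$xref)), "TP53")

  # unknown symbols are preserved under the reserved prefix
  got <- map_identifiers(c("TP53", "FOOBAR1"), kb$xref)
  expect_equal(unname(got), c("TP53", "unmapped:FOOBAR1"))

  # idempotence and totality over a large mixed draw
  set.seed(3)
  ids <- c(sample(kb$xref$symbol, 300), sprintf("NOVEL%02d", 1:60))
  once <- unname(map_identifiers(ids, kb$xref))
  twice <- unname(map_identifiers(once, kb$xref))
  expect_equal(twice, once)
  expect_equal(length(once), length(ids))

  # mixed namespaces above 20% minority are ambiguous
  expect_error(
    detect_namespace(c(rep("TP53", 6), rep("ENSG00000141510", 4))),
    "ambiguous")
})

test_that("SEG and methylation readers enforce their contracts", {
  seg_path <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\tnum_mark\tseg_mean",
               "S1\tchr1\t100\t5000\t20\t0.8",
               "S1\tchr2\t1\t9000\t30\t-0.4"), seg_path)
  seg <- read_seg(seg_path, origin = "somatic")
  expect_equal(nrow(seg), 2)
  expect_equal(seg$log_ratio, c(0.8, -0.4))

  writeLines(c("sample\tchrom\tstart\tend\tnum_mark\tseg_mean",
               "S1\tchr1\t5000\t100\t20\t0.8"), seg_path)
  expect_error(read_seg(seg_path), "start > end")

  meth_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id tumor control_1",
               "TP53 0.8 0.3", "BRCA1 0.2 0.25"), meth_path)
  meth <- read_methylation(meth_path)
  diff <- compute_methylation_diff(meth)
  expect_equal(diff$score_kind[1], "log_fold_change")
  expect_gt(diff$score[diff$gene_id == "TP53"], 1)

  # beta outside [0,1] is a fatal range error
  writeLines(c("gene_id tumor control_1", "TP53 1.2 0.3"), meth_path)
  expect_error(read_methylation(meth_path), "out of \\[0,1\\]")
})

test_that("clinical records validate tri-states and ranges", {
  rec <- make_clinical(er_status = "positive", grade = 2,
                       ki67_percent = 30)
  expect_s3_class(rec, "clinical_record")
  expect_equal(rec$pr_status, "unknown")
  expect_error(make_clinical(er_status = "maybe"), "er_status")
  expect_error(make_clinical(ki67_percent = 140), "out of range")
  expect_error(clinical_record(), "patient_id")
})

test_that("assembled bundles share one identifier namespace", {
  kb <- test_kb()
  dereg <- make_dereg(c("ENSG00000141510" = 2, "ENSG00000012048" = -1,
                        "ENSG00009999999" = 0.5))
  bundle <- assemble_bundle(deregulation = dereg, xref = kb$xref)
  expect_setequal(bundle$deregulation$gene_id,
                  c("TP53", "BRCA1", "unmapped:ENSG00009999999"))
  expect_error(assemble_bundle(clinical = make_clinical()),
               "at least one omics channel")
})
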