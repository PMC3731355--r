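test_that("top window minimizes p, then larger statistic, then position", {
  res <- S4Vectors::DataFrame(
    window_size = c(10, 10, 10), start_index = c(5, 1, 9),
    statistic = c(2.0, 3.1, 3.1), p_unadjusted = c(0.2, 0.05, 0.05),
    p_adjusted = c(0.5, 0.3, 0.3))
  expect_equal(topWindow(res)$start_index, 1L)      # tie on p -> |stat|
  res$statistic <- c(2, 3.1, 3.1)
  res$p_unadjusted <- c(0.05, 0.05, 0.05)
  expect_equal(topWindow(res)$start_index, 1L)      # full tie -> position
  expect_equal(topWindow(res[1, ])$start_index, 5L)
  expect_error(topWindow(res[0, ]), "empty")
})

test_that("BED intervals select SNPs under the half-open convention", {
  ge <- toyGE(rbind(c(0, 1), c(1, 0), c(0, 1)), pos = c(100L, 150L, 300L),
              chrom = "chr6")
  bed <- withr::local_tempfile(fileext = ".bed")
  # [99,100) covers 1-based pos 100; [100,200) starts after it
  writeLines(c("chr6\t99\t100\tGR", "chr6\t100\t200\tNFKB"), bed)
  ann <- readAnnotationBed(bed)
  hit <- annotateTF(ge, ann)
  expect_equal(hit$id, c("v1", "v2"))
  expect_equal(hit$labels[hit$id == "v1"], "GR")    # pos 100 only in [99,100)
  expect_equal(hit$labels[hit$id == "v2"], "NFKB")  # pos 150 in [100,200)
  # a SNP inside two intervals carries both labels on one row
  writeLines(c("chr6\t90\t110\tGR", "chr6\t95\t105\tNFKB"), bed)
  both <- annotateTF(ge, readAnnotationBed(bed))
  expect_equal(nrow(both), 1L)
  expect_equal(both$labels, "GR,NFKB")
})

test_that("LD cross-filter keeps strong-LD candidates and is monotone", {
  set.seed(31)
  base <- sample(0:2, 40, replace = TRUE)
  noisy <- function(x, k) { i <- sample(40, k); x[i] <- sample(0:2, k, TRUE); x }
  d <- rbind(ref1 = base,
             same = base,                    # r2 = 1
             near = noisy(base, 4),          # strong LD
             far  = noisy(base, 25),         # weak LD
             orth = sample(0:2, 40, TRUE),   # ~independent
             mono = rep(1L, 40))             # undefined LD
  ge <- toyGE(d, ids = rownames(d))
  cand <- c("same", "near", "far", "orth", "mono", "ref1")
  kept <- ldCrossFilter(ge, cand, reference = "ref1", threshold = 0.8)
  # all-pairs brute-force oracle over the same dosage rows
  oracle <- vapply(cand, function(id) {
    if (id == "ref1") return(TRUE)
    if (sd(d[id, ]) == 0) return(FALSE)
    cor(d[id, ], d["ref1", ])^2 > 0.8
  }, TRUE)
  expect_equal(kept, cand[oracle])
  # monotone in threshold: raising it never adds candidates
  for (th in c(0.2, 0.5, 0.9, 0.99)) {
    lo <- ldCrossFilter(ge, cand, "ref1", threshold = th)
    expect_true(all(kept %in% lo | th <= 0.8))
    hi <- ldCrossFilter(ge, cand, "ref1", threshold = min(1, th + 0.1))
    expect_true(all(hi %in% lo))
  }
})

test_that("candidate report renders locations and percent MAF", {
  # 60 samples: 5 of 120 alleles -> MAF 4.2% printed "4%"; 1 of 120 -> <1%
  d <- rbind(c(rep(1L, 5), rep(0L, 55)), c(1L, rep(0L, 59)))
  ge <- toyGE(d, pos = c(35715933L, 35720889L),
              ids = c("rs73748206x", "rs148128369x"),
              region_label = c("Intron 2", "Intron 1"))
  ann <- data.frame(id = c("rs73748206x", "rs148128369x"),
                    chrom = "chr6", pos = c(35715933L, 35720889L),
                    labels = c("GR", "NFKB"))
  rep <- buildCandidateReport(ann, ge)
  expect_equal(rep$location, c("35715933/Intron 2", "35720889/Intron 1"))
  expect_equal(rep$maf, c("4%", "<1%"))
  expect_equal(rep$tf, c("GR", "NFKB"))
  empty <- buildCandidateReport(ann[0, ], ge)
  expect_equal(nrow(empty), 0L)
  expect_equal(colnames(empty), c("id", "location", "maf", "tf"))
})

test_that("the prioritization cascade preserves set inclusions", {
  cfg <- simulationConfig(n_samples = 40, n_variants = 60, seed = 13,
                          causal_window = c(20, 15),
                          survival_log_hr = log(2), expression_effect = 0.6)
  sim <- simulateCohort(cfg)
  fx <- withr::local_tempdir()
  writeFixture(fx, cfg)
  ann <- readAnnotationBed(file.path(fx, "annotation.bed"))
  plan <- scanPlan(c(10, 15), includeWholeRegion = FALSE)
  grp <- dichotomizeAtMedian(sim$probes)
  dm <- dmafScan(sim$ge, grp, plan, B = 100, seed = 1, exhaustiveCap = 1)
  sv <- survivalScan(sim$ge, sim$survival$time, sim$survival$event, plan,
                     B = 100, seed = 2, exhaustiveCap = 1)
  pri <- prioritizeCandidates(sim$ge, sv, dm, ann)
  expect_true(all(pri$report$id %in% pri$ld_filtered))
  expect_true(all(pri$ld_filtered %in% pri$annotated$id))
  expect_true(all(pri$annotated$id %in% pri$window_snps))
  expect_equal(nrow(pri$report), length(pri$ld_filtered))
})
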