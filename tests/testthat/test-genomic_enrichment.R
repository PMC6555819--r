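test_that("reciprocal overlap matches the all-pairs oracle on random interval sets", {
  withr::with_seed(90, {
    for (rep in 1:8) {
      a <- random_regions(sample(50:200, 1))
      b <- random_regions(sample(50:200, 1))
      frac <- sample(c(0.25, 0.5, 0.9), 1)
      got <- reciprocal_overlap(a, b, frac)
      want <- oracle_reciprocal(a, b, frac)
      expect_equal(got$start, want$start)
      expect_equal(got$chrom, want$chrom)
    }
  })
})

test_that("reciprocal overlap boundary and degenerate cases", {
  a <- data.frame(chrom = "chr1", start = 0, end = 100)
  b <- data.frame(chrom = "chr1", start = 50, end = 150)
  # overlap 50 = exactly 50% of both lengths: boundary counts
  expect_equal(nrow(reciprocal_overlap(a, b, 0.5)), 1L)
  expect_equal(nrow(reciprocal_overlap(a, b, 0.51)), 0L)
  expect_equal(nrow(reciprocal_overlap(a, a, 1)), 1L)
  far <- data.frame(chrom = "chr1", start = 5000, end = 5100)
  expect_equal(nrow(reciprocal_overlap(a, far, 0.5)), 0L)
  expect_error(reciprocal_overlap(a, b, 0), "frac")
})

test_that("negatives are size-matched, ChIP-free and reproducible", {
  withr::with_seed(91, {
    dnase <- data.frame(chrom = "chr1",
                        start = seq(0, 90000, by = 3000),
                        end = seq(0, 90000, by = 3000) + 2200)
    chip <- data.frame(chrom = "chr1", start = c(3000, 12000, 30000),
                       end = c(4500, 13800, 31000))
    pos <- data.frame(chrom = "chr1", start = c(100, 500, 900),
                      end = c(400, 1100, 1900))
  })
  neg <- build_negatives(dnase, chip, pos, rng_seed = 92)
  expect_equal(sort(neg$end - neg$start), sort(pos$end - pos$start))
  expect_equal(nrow(reciprocal_overlap(neg, chip, frac = 1e-9)), 0L)
  # no overlap at all with chip, not just reciprocal
  for (i in seq_len(nrow(neg)))
    expect_true(all(neg$end[i] <= chip$start | neg$start[i] >= chip$end))
  expect_identical(build_negatives(dnase, chip, pos, rng_seed = 92), neg)

  big <- data.frame(chrom = "chr1", start = 0, end = 50000)
  expect_error(build_negatives(dnase, chip, big, rng_seed = 1),
               "insufficient")
})

test_that("region scores equal exhaustive window/strand enumeration", {
  withr::with_seed(93, {
    pwm <- pwm_from_pfm(random_pfm(9), background = dnase_background())
    for (rep in 1:25) {
      s <- rand_seq(100)
      expect_equal(score_region(s, pwm), oracle_score(s, unclass(pwm)),
                   tolerance = 1e-12)
      expect_equal(score_region(rc_chr(s), pwm), score_region(s, pwm),
                   tolerance = 1e-12)
    }
    # consensus scores the per-position maximum sum
    cons <- paste(BASES[apply(unclass(pwm), 2, which.max)], collapse = "")
    expect_equal(score_region(cons, pwm), sum(apply(unclass(pwm), 2, max)),
                 tolerance = 1e-12)
    # N contributes zero
    pwm1 <- pwm_from_pfm(random_pfm(4))
    sN <- "ACGTNNNN"
    expect_equal(score_region(sN, pwm1), oracle_score(sN, unclass(pwm1)),
                 tolerance = 1e-12)
    expect_error(score_region("ACG", pwm), "shorter")
  })
})

test_that("AUC equals brute-force pair counting and the U identity holds", {
  withr::with_seed(94, {
    for (rep in 1:30) {
      pos <- sample(1:8, sample(3:20, 1), replace = TRUE)  # ties guaranteed
      neg <- sample(1:8, sample(3:20, 1), replace = TRUE)
      r <- roc_auc(pos, neg)
      expect_equal(r$auc, oracle_auc(pos, neg), tolerance = 1e-12)
      expect_equal(r$auc, r$u_statistic / (r$n_pos * r$n_neg),
                   tolerance = 1e-12)
      # complementarity for tie-free inputs
      posc <- rnorm(12)
      negc <- rnorm(15)
      expect_equal(roc_auc(posc, negc)$auc + roc_auc(negc, posc)$auc, 1,
                   tolerance = 1e-12)
    }
  })
  expect_equal(roc_auc(c(5, 6, 7), c(1, 2, 3))$auc, 1)
  expect_error(roc_auc(numeric(0), 1:3), "non-empty")
  r5 <- roc_auc(rnorm(20), rnorm(20), n_models = 5)
  expect_equal(r5$p_adjusted, min(1, r5$p_value * 5))
})

test_that("ROC curve points trace the score sweep", {
  r <- roc_auc(c(3, 2, 1), c(2.5, 0.5, 0))
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
})

test_that("active-peak filter applies strand-aware upstream windows", {
  tss <- data.frame(gene = c("up_plus", "up_minus", "not_de"),
                    chrom = "chr1",
                    position = c(50000, 50000, 120000),
                    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  de <- c("up_plus", "up_minus")
  peaks <- data.frame(
    chrom = "chr1",
    start = c(44000, 34000, 50200, 61000, 119000),
    end = c(45000, 35000, 51200, 62000, 119500),
    name = c("in5kb_plus", "out15kb", "in_minus_window", "out_minus",
             "near_non_de"), stringsAsFactors = FALSE)
  kept <- active_peak_filter(peaks, tss, de, window = 10000)
  expect_setequal(kept$name, c("in5kb_plus", "in_minus_window"))
  # minus-strand window is [p, p + window): position 61000 with window 10000
  # would only be reached by a window starting at 51000+
  kept50 <- active_peak_filter(peaks, tss, de, window = 50000)
  expect_true(all(c("out15kb", "out_minus") %in% kept50$name))
  expect_false("near_non_de" %in% kept50$name)
  both <- active_peak_filter(peaks, tss, de, window = 10000,
                             geometry = "up_and_down")
  expect_true("in_minus_window" %in% both$name)
  expect_error(active_peak_filter(peaks, tss, de, geometry = "sideways"),
               "unknown geometry")
  tss_ns <- tss
  tss_ns$strand <- "."
  expect_error(active_peak_filter(peaks, tss_ns, de), "strand")
})

test_that("planted versus unplanted benchmarks separate as expected", {
  pfm <- fx("dr1_pfm", function() mode_truth("full", 2, 1, rng_seed = 1)$pfm)
  pwm <- pwm_from_pfm(pfm, background = dnase_background())
  bench <- simulate_genomic_benchmark(120, 120, 200, pfm,
                                      planted_fraction = 0.9, rng_seed = 95)
  r <- roc_auc(score_regions(bench$pos, bench$genome, pwm),
               score_regions(bench$neg, bench$genome, pwm))
  expect_gte(r$auc, 0.9)
  expect_lt(r$p_adjusted, 1e-6)

  null <- simulate_genomic_benchmark(150, 150, 200, pfm,
                                     planted_fraction = 0, rng_seed = 96)
  r0 <- roc_auc(score_regions(null$pos, null$genome, pwm),
                score_regions(null$neg, null$genome, pwm))
  expect_gt(r0$auc, 0.4)
  expect_lt(r0$auc, 0.6)
})

test_that("BED round-trips through rtracklayer preserve 0-based coordinates", {
  regions <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 999L),
                        end = c(150L, 2000L), strand = c("+", "."),
                        name = c("a", "b"), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".bed")
  write_bed(regions, f)
  back <- read_bed(f)
  expect_equal(back$start, regions$start)
  expect_equal(back$end, regions$end)
  expect_equal(back$chrom, regions$chrom)
})
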