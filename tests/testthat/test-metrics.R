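ref60 <- make_ref(paste(rep("ACGTTGCAAT", 6), collapse = ""))

test_that("alignment_error_rates applies the stated denominators", {
  refstr <- as.character(ref60[[1]])
  # perfect 50M match
  rec_perfect <- list(qname = "p", chrom = "chr1", pos = 1, cigar = "50M",
                      seq = substr(refstr, 1, 50))
  # 10 aligned bases, 1 mismatch, 1-base deletion: 5M1D5M with a mismatch
  s10 <- substr(refstr, 1, 5)
  s2 <- substr(refstr, 7, 11)
  mm <- paste0(substr(s10, 1, 4), chartr("ACGT", "GTAC", substr(s10, 5, 5)))
  rec_del <- list(qname = "d", chrom = "chr1", pos = 1, cigar = "5M1D5M",
                  seq = paste0(mm, s2))
  # 10 aligned bases with a 2-base insertion
  rec_ins <- list(qname = "i", chrom = "chr1", pos = 1, cigar = "5M2I5M",
                  seq = paste0(substr(refstr, 1, 5), "TT",
                               substr(refstr, 6, 10)))
  sam <- write_test_sam(list(rec_perfect, rec_del, rec_ins),
                        c(chr1 = 60L))
  aln <- parse_alignments(sam)
  er <- alignment_error_rates(aln, ref60)
  er <- er[match(c("p", "d", "i"),
                 S4Vectors::mcols(aln)$qname), ]
  expect_equal(er$e_sub, c(0, 0.1, 0))
  expect_equal(er$p_id, c(100, 90, 100))
  expect_equal(er$e_del, c(0, 1 / 11, 0))
  expect_equal(er$e_ins, c(0, 0, 2 / 12))
})

test_that("classify_calls matches the naive oracle and conserves totals", {
  set.seed(42)
  for (k in 1:20) {
    n_t <- sample(5:50, 1); n_c <- sample(5:50, 1)
    pool <- sample(1000, 60)
    truth <- data.frame(chrom = "c", pos = sample(pool, n_t),
                        genotype = sample(c("het", "hom-alt"), n_t, TRUE))
    calls <- data.frame(chrom = "c", pos = sample(pool, n_c),
                        genotype = sample(c("het", "hom-alt"), n_c, TRUE))
    got <- classify_calls(calls, truth)
    want <- oracle_classify(calls, truth)
    expect_equal(got$tp, want$tp)
    expect_equal(got$fp, want$fp)
    expect_equal(got$fn, want$fn)
    expect_equal(got$tp + got$fn, nrow(truth))
    expect_equal(got$tp + got$fp, nrow(calls))
  }
})

test_that("genotype mismatches are double-counted", {
  truth <- data.frame(chrom = "c", pos = 100, genotype = "hom-alt")
  calls <- data.frame(chrom = "c", pos = 100, genotype = "het")
  got <- classify_calls(calls, truth)
  expect_equal(c(got$tp, got$fp, got$fn), c(0, 1, 1))
  ident <- classify_calls(truth, truth)
  expect_equal(c(ident$fdr, ident$fnr, ident$f1), c(0, 0, 1))
  # empty call set: FDR defined as 0
  empty <- classify_calls(calls[0, ], truth)
  expect_equal(empty$fdr, 0)
  expect_error(classify_calls(rbind(calls, calls), truth), "duplicated")
})

test_that("f1_from_rates is the harmonic mean of precision and recall", {
  expect_equal(f1_from_rates(0, 0), 1)
  expect_equal(f1_from_rates(1, 0.3), 0)
  set.seed(7)
  fdr <- runif(50); fnr <- runif(50)
  p <- 1 - fdr; r <- 1 - fnr
  expect_equal(f1_from_rates(fdr, fnr), 2 * p * r / (p + r), tolerance = 1e-15)
})

test_that("switch_error_rate counts discordant adjacent pairs", {
  truth <- data.frame(chrom = "c", pos = 1:4 * 100, hap_of_alt = c(1, 1, 2, 1),
                      phase_set = 1)
  calls <- truth
  expect_equal(switch_error_rate(calls, truth)$rate, 0)
  # flip one middle site: 2 discordant of 3 adjacent pairs
  flipped <- truth
  flipped$hap_of_alt[2] <- 2
  expect_equal(switch_error_rate(flipped, truth)$rate, 2 / 3)
  # global relabelling is not a switch
  swapped <- truth
  swapped$hap_of_alt <- 3 - swapped$hap_of_alt
  expect_equal(switch_error_rate(swapped, truth)$rate, 0)
  # symmetry in calls/truth
  expect_equal(switch_error_rate(flipped, truth)$switches,
               switch_error_rate(truth, flipped)$switches)
  # restricted mode only evaluates read-spanned pairs
  sp <- data.frame(chrom = "c", pos1 = 100, pos2 = 200)
  res <- switch_error_rate(flipped, truth, mode = "read-spanned",
                           spanned_pairs = sp)
  expect_equal(res$pairs, 1)
  expect_equal(res$rate, 1)
  # no evaluable pairs -> NA sentinel
  one <- truth[1, ]
  expect_true(is.na(switch_error_rate(one, truth)$rate))
})

test_that("switch errors across call phase-set boundaries are not counted", {
  truth <- data.frame(chrom = "c", pos = 1:4 * 100, hap_of_alt = c(1, 2, 1, 2),
                      phase_set = 1)
  calls <- truth
  calls$phase_set <- c(1, 1, 2, 2)
  calls$hap_of_alt <- c(1, 2, 2, 1)   # second set globally flipped
  expect_equal(switch_error_rate(calls, truth)$pairs, 2)
  expect_equal(switch_error_rate(calls, truth)$switches, 0)
})

test_that("proportion reproduces display-precision percentages", {
  expect_equal(proportion(69, 45219, digits = 2), 0.15)
  expect_equal(proportion(173, 788782, digits = 2), 0.02)
  expect_equal(proportion(21, 35, digits = 0), 60)
  expect_equal(proportion(32, 35, digits = 0), 91)
  expect_equal(proportion(0, 7), 0)
  expect_error(proportion(1, 0), "positive")
})
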