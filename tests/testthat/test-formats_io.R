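ref <- make_ref(paste(rep("ACGTACGTAC", 10), collapse = ""))  # 100 bp

test_that("parse_alignments handles identity, deletion and empty input", {
  refstr <- as.character(ref[[1]])
  sam <- write_test_sam(list(
    list(qname = "r1", chrom = "chr1", pos = 1, cigar = "10M",
         seq = substr(refstr, 1, 10)),
    list(qname = "r2", chrom = "chr1", pos = 11, cigar = "5M1D5M",
         seq = paste0(substr(refstr, 11, 15), substr(refstr, 17, 21)))),
    c(chr1 = 100L))
  aln <- parse_alignments(sam)
  expect_equal(length(aln), 2)
  w <- BiocGenerics::width(aln)   # reference span
  expect_equal(w[S4Vectors::mcols(aln)$qname == "r1"], 10)
  expect_equal(w[S4Vectors::mcols(aln)$qname == "r2"], 11)
  qw <- GenomicAlignments::qwidth(aln)
  expect_equal(qw[S4Vectors::mcols(aln)$qname == "r2"], 10)
  empty <- write_test_sam(list(), c(chr1 = 100L))
  expect_equal(length(parse_alignments(empty)), 0)
})

test_that("parse_alignments rejects malformed records", {
  bad <- write_test_sam(list(
    list(qname = "bad", chrom = "chr1", pos = 1, cigar = "10M",
         seq = "ACGT", qual = "IIII")), c(chr1 = 100L))
  expect_error(parse_alignments(bad), "malformed")
})

test_that("build_pileup tallies categories and strand, and conserves reads", {
  refstr <- as.character(ref[[1]])
  site <- data.frame(chrom = "chr1", pos = 15, ref = substr(refstr, 15, 15),
                     alt = "T")
  recs <- c(
    lapply(1:6, function(i) list(qname = paste0("ref", i), chrom = "chr1",
                                 pos = 11, cigar = "10M",
                                 seq = substr(refstr, 11, 20))),
    lapply(1:4, function(i) list(qname = paste0("del", i), chrom = "chr1",
                                 pos = 11, cigar = "4M1D5M",
                                 seq = paste0(substr(refstr, 11, 14),
                                              substr(refstr, 16, 20)),
                                 flag = 16L)),
    list(list(qname = "far", chrom = "chr1", pos = 50, cigar = "10M",
              seq = substr(refstr, 50, 59))))
  sam <- write_test_sam(recs, c(chr1 = 100L))
  pu <- build_pileup(parse_alignments(sam), site)
  expect_equal(pu$ref_fwd, 6)
  expect_equal(pu$del_rev, 4)
  expect_equal(pu$coverage, 6)
  expect_equal(pu$physical_coverage, 10)
  expect_equal(with(pu, ref_fwd + ref_rev + alt_fwd + alt_rev + other_fwd +
                      other_rev + del_fwd + del_rev), 10)
  expect_error(build_pileup(parse_alignments(sam),
                            data.frame(chrom = "chr1", pos = 500,
                                       ref = "A", alt = "T")),
               "beyond reference end")
})

test_that("extract_observations drops unusable reads and codes alleles", {
  refstr <- as.character(ref[[1]])
  sites <- data.frame(chrom = "chr1", pos = c(15, 25),
                      ref = c(substr(refstr, 15, 15), substr(refstr, 25, 25)),
                      alt = c("T", "G"))
  alt_seq <- substr(refstr, 11, 30)
  substr(alt_seq, 5, 5) <- "T"      # alt at site 1
  recs <- list(
    list(qname = "alt1", chrom = "chr1", pos = 11, cigar = "20M",
         seq = alt_seq, qual = strrep("+", 20)),   # phred 10
    list(qname = "refread", chrom = "chr1", pos = 11, cigar = "20M",
         seq = substr(refstr, 11, 30)),
    list(qname = "nouse", chrom = "chr1", pos = 14, cigar = "2M1D1M",
         seq = "XXX"))  # spans site 15 with a deletion only -> dropped
  recs[[3]]$seq <- paste0(substr(refstr, 14, 15), substr(refstr, 17, 17))
  recs[[3]]$cigar <- "2M1D1M"
  recs[[3]]$pos <- 14
  recs[[3]]$seq <- paste0(substr(refstr, 14, 14), substr(refstr, 16, 17))
  recs[[3]]$cigar <- "1M1D2M"   # deletion covers pos 15
  sam <- write_test_sam(recs, c(chr1 = 100L))
  obs <- suppressMessages(extract_observations(parse_alignments(sam), sites))
  expect_equal(attr(obs, "n_reads_dropped"), 1)
  expect_setequal(attr(obs, "reads")$qname, c("alt1", "refread"))
  a1 <- obs[obs$read == which(attr(obs, "reads")$qname == "alt1"), ]
  expect_equal(a1$s[a1$site == 1], 1L)
  expect_equal(a1$b[a1$site == 1], 10L)
  expect_equal(a1$s[a1$site == 2], 0L)
})

test_that("VCF writing round-trips through the standard reader", {
  sites <- data.frame(
    chrom = "sim1", pos = c(100L, 250L, 300L),
    ref = c("A", "C", "G"), alt = c("G", "T", "A"),
    qual = c(51.5, 200, 33),
    genotype = c("het", "hom-alt", "het"),
    filter_status = c("PASS", "PASS", "low_qual"),
    phase_set = c(7L, NA, NA),
    hap_of_alt = c(1L, NA, NA),
    pe = c(5.1234, NA, 1.02),
    sb1 = c(12L, NA, 3L), sb2 = c(9L, NA, 4L),
    annotations = c("", "", "homopolymer,low_qual"),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".vcf")
  write_phased_vcf(sites, path, ref_lengths = c(sim1 = 1000L))
  back <- read_vcf(path)
  expect_equal(back$pos, sites$pos)
  expect_equal(back$ref, sites$ref)
  expect_equal(back$alt, sites$alt)
  expect_equal(back$qual, sites$qual)
  expect_equal(back$genotype, sites$genotype)
  expect_equal(back$phase_set, sites$phase_set)
  expect_equal(back$hap_of_alt, sites$hap_of_alt)
  expect_equal(back$pe, sites$pe, tolerance = 1e-4)
  expect_equal(back$sb1, sites$sb1)
  expect_equal(back$annotations, sites$annotations)
  expect_equal(back$filter_status, sites$filter_status)
})

test_that("read_vcf skips indels and multi-allelic records", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=c1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S", sep = "\t"),
    "c1\t10\t.\tA\tG\t50\tPASS\t.\tGT\t0/1",
    "c1\t20\t.\tAT\tA\t50\tPASS\t.\tGT\t0/1",      # indel
    "c1\t30\t.\tC\tG,T\t50\tPASS\t.\tGT\t1/2"),    # multi-allelic
    path)
  expect_message(v <- read_vcf(path), "skipped 2")
  expect_equal(nrow(v), 1)
  expect_equal(v$pos, 10)
})

test_that("read_bed converts to 1-based inclusive regions", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t200", "chr2\t0\t50"), bed)
  r <- read_bed(bed)
  expect_equal(r$start, c(100, 1))
  expect_equal(r$end, c(200, 50))
  truth <- data.frame(chrom = c("chr1", "chr1"), pos = c(150, 300),
                      genotype = "het")
  cl <- classify_calls(truth, truth, region = r[1, ])
  expect_equal(cl$tp, 1)
})

test_that("spanned_site_pairs reports genome-adjacent co-spanned pairs", {
  sites <- data.frame(chrom = "c", pos = c(100, 200, 300))
  obs <- data.frame(read = c(1, 1, 2, 2), site = c(1, 2, 2, 3),
                    s = 0, b = 20)
  sp <- spanned_site_pairs(obs, sites)
  expect_equal(nrow(sp), 2)
  expect_setequal(sp$pos1, c(100, 200))
  # a read skipping the middle site yields no adjacent pair
  obs2 <- data.frame(read = 1, site = c(1, 3), s = 0, b = 20)
  expect_equal(nrow(spanned_site_pairs(obs2, sites)), 0)
})
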