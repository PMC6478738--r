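# Fixture builders: everything is generated in code, no stored data.

# tiny reference as a named DNAStringSet
make_ref <- function(seq, name = "chr1") {
  r <- Biostrings::DNAStringSet(seq)
  names(r) <- name
  r
}

# write a SAM file from a record list; each record is
# list(qname, flag, chrom, pos, cigar, seq, qual)
write_test_sam <- function(records, ref_lengths, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  lines <- vapply(records, function(r) {
    paste(r$qname, r$flag %||% 0L, r$chrom, r$pos, r$mapq %||% 60L,
          r$cigar, "*", 0L, 0L, r$seq,
          r$qual %||% strrep("I", nchar(gsub("-", "", r$seq))), sep = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Synthetic diploid phasing instance built directly at the observation
# level (no files): n_sites het sites, reads_per_hap reads per haplotype,
# every read spanning all sites.  An observation flips ref <-> alt when a
# base error hits the opposite allele: under the biallelic reduction that
# is err/3 of the err implied by phred b, renormalised to the kept
# (ref/alt) categories — the same regime the alignment-level extractor
# produces.  Returns obs plus the true haplotype of each read and of
# each site's alternate allele.
make_diploid_obs <- function(n_sites = 10, reads_per_hap = 10, b = 13,
                             seed = 1, span = NULL, flip = NULL) {
  set.seed(seed)
  e <- 10^(-b / 10)
  err <- flip %||% ((e / 3) / (1 - e + e / 3))
  hap_of_alt <- sample(1:2, n_sites, replace = TRUE)
  n_reads <- 2 * reads_per_hap
  read_hap <- rep(1:2, each = reads_per_hap)
  rows <- list()
  for (r in seq_len(n_reads)) {
    sites <- if (is.null(span)) seq_len(n_sites) else {
      st <- sample.int(max(1, n_sites - span + 1), 1)
      st:(min(n_sites, st + span - 1))
    }
    truth_allele <- as.integer(hap_of_alt[sites] == read_hap[r])
    obs_allele <- ifelse(runif(length(sites)) < err,
                         1L - truth_allele, truth_allele)
    rows[[r]] <- data.frame(read = r, site = sites, s = obs_allele, b = b,
                            strand = sample(c("+", "-"), 1))
  }
  obs <- do.call(rbind, rows)
  attr(obs, "read_hap") <- read_hap
  attr(obs, "hap_of_alt") <- hap_of_alt
  obs
}

# minimal annotated call table for filter tests (positions fit a 2 kb ref)
make_calls <- function(n, qual = 100, genotype = "het", coverage = 48L,
                       pos = NULL) {
  q <- as.integer(coverage %/% 4)
  data.frame(chrom = "chr1", pos = pos %||% seq(100, by = 50, length.out = n),
             ref = "A", alt = "G", qual = qual, genotype = genotype,
             n_ref = 2L * q, n_alt = 2L * q,
             srf = q, srr = q, saf = q, sar = q,
             coverage = coverage, physical_coverage = coverage,
             del_frac = 0, stringsAsFactors = FALSE)
}
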