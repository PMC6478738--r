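# Annotation battery and filter policies.  Annotations mark contexts in
# which noisy long-read calls fail: homopolymer runs (deletion-driven
# misalignment), low coverage, many in-read deletions, strand imbalance,
# low site quality, and poor phase separation.  Two policies mirror the
# pre-phasing ("qual": QUAL + contamination model only) and post-phasing
# ("phasing": QUAL plus phase-entropy and strand checks on heterozygous
# calls) filtering strategies.

#' Filter policy
#'
#' @param name `"qual"` (QUAL threshold only), `"phasing"` (QUAL plus
#'   phase-entropy and strand-bias removal of heterozygous calls) or
#'   `"custom"`
#' @param qual_threshold minimum QUAL retained (phred); chosen on
#'   simulated data, see the methods vignette
#' @param coverage_floor per-base coverage below this is flagged
#'   `low_coverage` (40x)
#' @param del_ceiling fraction of spanning reads with an in-read deletion
#'   at or above this is flagged `high_deletion` (0.40)
#' @param homopolymer_len minimal run length of identical reference bases
#'   that triggers the `homopolymer` flag (5)
#' @param strand_phred flag `strand_bias` when the phred-scaled two-sided
#'   binomial(0.5) strand-imbalance statistic of the reference- or
#'   alternate-supporting reads reaches this value (30); see the methods
#'   vignette for the direction of this test
#' @param pe_threshold heterozygous calls with phase entropy below this
#'   are flagged `bad_phasing`.  No canonical default exists; 2.0 sits
#'   between the PE of a haplotype-balanced false site (near the
#'   `log10(16) ~ 1.2` symmetric minimum) and the floor of a true
#'   heterozygote (about 2.1 even when high base qualities pin theta to
#'   the raw allele fraction); see the methods vignette
#' @param theta_floor a heterozygous call is also flagged `bad_phasing`
#'   when neither haplotype's fitted alternate-emission probability
#'   reaches this value: a true het must place its alternate allele on
#'   one haplotype, whereas a false site's alternate observations are
#'   absorbed by the base-error term and both thetas collapse towards 0
#'   (which, by the symmetry of PE, would otherwise look like a cleanly
#'   phased site)
#' @return list of class `filter_policy`
#' @export
filter_policy <- function(name = c("phasing", "qual", "custom"),
                          qual_threshold = 30, coverage_floor = 40,
                          del_ceiling = 0.40, homopolymer_len = 5,
                          strand_phred = 30, pe_threshold = 2.0,
                          theta_floor = 0.5) {
  name <- match.arg(name)
  stopifnot(qual_threshold >= 0, coverage_floor > 0, del_ceiling > 0,
            homopolymer_len > 0, strand_phred > 0, pe_threshold > 0,
            theta_floor >= 0, theta_floor < 1)
  structure(list(name = name, qual_threshold = qual_threshold,
                 coverage_floor = coverage_floor, del_ceiling = del_ceiling,
                 homopolymer_len = homopolymer_len,
                 strand_phred = strand_phred, pe_threshold = pe_threshold,
                 theta_floor = theta_floor),
            class = "filter_policy")
}

#' Homopolymer annotation
#'
#' A site is flagged when its position lies within, or immediately flanks,
#' a maximal run of one repeated base of length at least `min_run` in the
#' reference.  Flanking bases are included because deletion-induced
#' misalignment at a run corrupts the bases on either side of it, not only
#' the run itself.
#'
#' @param reference [Biostrings::DNAStringSet] named by contig
#' @param chrom,pos site coordinates (vectorised, 1-based)
#' @param min_run run-length trigger
#' @return logical vector
#' @export
annotate_homopolymer <- function(reference, chrom, pos, min_run = 5) {
  out <- logical(length(pos))
  for (ctg in unique(chrom)) {
    i <- which(chrom == ctg)
    if (!ctg %in% names(reference)) stopf("contig '%s' not in reference", ctg)
    rs <- reference[[ctg]]
    if (any(pos[i] < 1 | pos[i] > length(rs)))
      stopf("site outside reference on contig '%s'", ctg)
    r <- rle(as.integer(charToRaw(as.character(rs))))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$lengths >= min_run)
    if (length(runs) == 0) next
    ir <- IRanges::IRanges(pmax(1L, starts[runs] - 1L),
                           pmin(length(rs), ends[runs] + 1L))
    hit <- IRanges::overlapsAny(IRanges::IRanges(pos[i], pos[i]), ir)
    out[i] <- hit
  }
  out
}

# phred-scaled two-sided exact binomial(0.5) strand-imbalance statistic:
# large values mean strong evidence of imbalance
strand_bias_phred <- function(fwd, rev) {
  mapply(function(f, r) {
    if (f + r == 0) return(0)
    prob_to_phred(binom.test(f, f + r, 0.5)$p.value)
  }, fwd, rev)
}

#' Annotate a call set
#'
#' Computes the annotation battery for each call: `homopolymer`,
#' `low_coverage` (per-base coverage below the floor), `high_deletion`
#' (deletion fraction of spanning reads at/above the ceiling, physical
#' coverage as denominator), `strand_bias` (phred-scaled two-sided
#' binomial(0.5) statistic of the reference- or alternate-supporting
#' reads at/above the threshold), `low_qual`, and, when phasing metrics
#' are present, `bad_phasing` (PE below threshold; `NA` PE, i.e. an
#' unphaseable singleton site, is not flagged).  Also adds `n_flags` and
#' the `annotations` summary string.
#'
#' @param calls call data.frame from [call_variants()] (columns `qual`,
#'   `coverage`, `physical_coverage`, `del_frac`, `srf`, `srr`, `saf`,
#'   `sar`)
#' @param reference [Biostrings::DNAStringSet] named by contig
#' @param phase optional phased-site table from [phase_reads()] matched to
#'   `calls` rows (needs column `pe`); alternatively `calls` may already
#'   carry a `pe` column
#' @param policy a [filter_policy()]
#' @return `calls` with logical flag columns, `n_flags`, `annotations`
#' @export
annotate_calls <- function(calls, reference, phase = NULL,
                           policy = filter_policy()) {
  calls <- as.data.frame(calls)
  if (!is.null(phase)) calls$pe <- phase$pe
  calls$homopolymer <- annotate_homopolymer(reference, calls$chrom, calls$pos,
                                            policy$homopolymer_len)
  calls$low_coverage <- calls$coverage < policy$coverage_floor
  del_frac <- calls$del_frac %||%
    (1 - calls$coverage / pmax(calls$physical_coverage, 1L))
  calls$high_deletion <- del_frac >= policy$del_ceiling
  srp <- strand_bias_phred(calls$srf, calls$srr)
  sap <- strand_bias_phred(calls$saf, calls$sar)
  calls$strand_bias <- srp >= policy$strand_phred | sap >= policy$strand_phred
  calls$low_qual <- calls$qual < policy$qual_threshold
  if (!is.null(calls$pe)) {
    calls$bad_phasing <- !is.na(calls$pe) & calls$genotype == "het" &
      calls$pe < policy$pe_threshold
    if (!is.null(calls$theta1)) {
      # a het whose alternate sits on neither haplotype is not a het
      theta_max <- pmax(calls$theta1, calls$theta2)
      calls$bad_phasing <- calls$bad_phasing |
        (!is.na(theta_max) & calls$genotype == "het" &
           theta_max < policy$theta_floor)
    }
  }
  flags <- intersect(vcf_flag_names, names(calls))
  fl <- as.matrix(calls[, flags, drop = FALSE])
  calls$n_flags <- rowSums(fl, na.rm = TRUE)
  calls$annotations <- apply(fl, 1, function(x)
    paste(flags[which(x)], collapse = ","))
  calls
}

#' Apply a filter policy to an annotated call set
#'
#' The `"qual"` policy retains calls with `QUAL >= qual_threshold`.  The
#' `"phasing"` policy additionally removes heterozygous calls flagged
#' `bad_phasing` or `strand_bias`.  Removed calls record the flag(s) that
#' removed them in `filter_status`.
#'
#' @param calls annotated call set from [annotate_calls()]
#' @param policy a [filter_policy()]
#' @return list: `calls` (retained, `filter_status = "PASS"`), `removed`
#'   (with failing flags in `filter_status`), `counts` (removals per flag;
#'   a call removed by several flags counts towards each)
#' @export
apply_policy <- function(calls, policy = filter_policy()) {
  calls <- as.data.frame(calls)
  if (is.null(calls$low_qual)) stopf("calls must be annotated first")
  fail <- matrix(FALSE, nrow(calls), 0)
  fail <- cbind(fail, low_qual = calls$low_qual)
  if (policy$name == "phasing") {
    if (is.null(calls$bad_phasing))
      stopf("the phasing policy needs phasing metrics; run phase_reads() first")
    fail <- cbind(fail,
                  bad_phasing = calls$bad_phasing & calls$genotype == "het",
                  strand_bias = calls$strand_bias & calls$genotype == "het")
  }
  removed <- rowSums(fail) > 0
  status <- apply(fail, 1, function(x)
    if (any(x)) paste(colnames(fail)[x], collapse = ";") else "PASS")
  calls$filter_status <- status
  counts <- colSums(fail)
  list(calls = calls[!removed, , drop = FALSE],
       removed = calls[removed, , drop = FALSE],
       counts = counts)
}
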