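# Standard-format I/O and construction of the internal pileup /
# observation structures.  Coordinates are 1-based inclusive throughout
# the user-facing interfaces (SAM/VCF convention).

# SAM input is converted to sorted, indexed BAM on the fly so the
# htslib-backed readers can be used.
as_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  tryCatch(
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE),
    error = function(e) stopf("malformed SAM '%s': %s", path, conditionMessage(e)))
}

#' Read primary alignments from a SAM/BAM file
#'
#' @param path SAM or BAM file with sequences and base qualities
#' @param keep_secondary keep secondary/supplementary alignments
#'   (default: primary only)
#' @param min_mapq minimum mapping quality; 0 keeps everything, including
#'   multi-mapping reads
#' @return a [GenomicAlignments::GAlignments] with metadata columns
#'   `qname`, `flag`, `mapq`, `seq`, `qual`; strand comes from the flag
#' @export
parse_alignments <- function(path, keep_secondary = FALSE, min_mapq = 0) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) validate_sam(path)
  bam <- as_bam(path)
  flag <- if (keep_secondary) Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
          else Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                      isSecondaryAlignment = FALSE,
                                      isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("qname", "flag", "mapq", "seq", "qual"),
    mapqFilter = if (min_mapq > 0) as.integer(min_mapq) else NA_integer_)
  GenomicAlignments::readGAlignments(bam, param = param)
}

# htslib drops records whose CIGAR and sequence disagree (with a stderr
# warning only), so the format-error contract is enforced up front.
validate_sam <- function(path) {
  ln <- readLines(path)
  body <- ln[!startsWith(ln, "@")]
  if (length(body) == 0) return(invisible(TRUE))
  sp <- strsplit(body, "\t", fixed = TRUE)
  qn <- vapply(sp, `[`, character(1), 1)
  cig <- vapply(sp, `[`, character(1), 6)
  sq <- vapply(sp, `[`, character(1), 10)
  qlen <- vapply(cig, function(cg) {
    if (cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    if (sum(nchar(ops)) != nchar(cg)) return(-1L)
    consume <- grepl("[MIS=X]$", ops)
    sum(as.integer(sub(".$", "", ops[consume])))
  }, integer(1))
  bad <- which(!is.na(qlen) & sq != "*" & qlen != nchar(sq))
  if (length(bad) > 0)
    stopf("malformed CIGAR/sequence length for read '%s'", qn[bad[1]])
  invisible(TRUE)
}

# Reference-space layout of read sequences and base qualities: deletions
# become "-", insertions are removed, so character k of the result sits at
# reference position start + k - 1.
layer_reference <- function(alignments) {
  cig <- GenomicAlignments::cigar(alignments)
  seqs <- S4Vectors::mcols(alignments)$seq
  quals <- S4Vectors::mcols(alignments)$qual
  laid_seq <- GenomicAlignments::sequenceLayer(seqs, cig,
                                               from = "query", to = "reference")
  laid_qual <- GenomicAlignments::sequenceLayer(
    as(quals, "BStringSet"), cig, from = "query", to = "reference",
    D.letter = "!", N.letter = "!")
  list(seq = as.character(laid_seq), qual = as.character(laid_qual),
       chrom = as.character(GenomeInfoDb::seqnames(alignments)),
       start = BiocGenerics::start(alignments),
       end = BiocGenerics::end(alignments),
       strand = as.character(BiocGenerics::strand(alignments)))
}

#' Per-site pileup counts from alignments
#'
#' Tallies, for each candidate site, the spanning reads by observed base
#' category (exact reference base, exact alternate base, anything else =
#' "other", in-read deletion) and strand.  Reads not spanning a site
#' contribute nothing; a read deleted at the site increments only the
#' deletion count.
#'
#' @param alignments a [GenomicAlignments::GAlignments] from
#'   [parse_alignments()]
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`
#' @return data.frame, one row per site: strand-split counts `ref_fwd`,
#'   `ref_rev`, `alt_fwd`, `alt_rev`, `other_fwd`, `other_rev`, `del_fwd`,
#'   `del_rev`, plus `coverage` (per-base coverage, deletions excluded)
#'   and `physical_coverage` (spanning reads, deletions included)
#' @export
build_pileup <- function(alignments, sites) {
  sites <- as.data.frame(sites)
  sl <- GenomeInfoDb::seqlengths(alignments)
  for (i in seq_len(nrow(sites))) {
    ln <- sl[sites$chrom[i]]
    if (!is.na(ln) && sites$pos[i] > ln)
      stopf("site %s:%d beyond reference end (%d)",
            sites$chrom[i], sites$pos[i], ln)
  }
  obs <- site_observations(alignments, sites)
  n <- nrow(sites)
  cnt <- function(cat, str)
    as.integer(rowsum_vec(as.numeric(obs$category == cat & obs$strand == str),
                          obs$site, n))
  out <- data.frame(
    ref_fwd = cnt("ref", "+"), ref_rev = cnt("ref", "-"),
    alt_fwd = cnt("alt", "+"), alt_rev = cnt("alt", "-"),
    other_fwd = cnt("other", "+"), other_rev = cnt("other", "-"),
    del_fwd = cnt("del", "+"), del_rev = cnt("del", "-"))
  out$coverage <- out$ref_fwd + out$ref_rev + out$alt_fwd + out$alt_rev +
    out$other_fwd + out$other_rev
  out$physical_coverage <- out$coverage + out$del_fwd + out$del_rev
  out
}

# Raw per-(read, site) observations: every spanning read yields one row
# with its base category at the site.  Internal workhorse for
# build_pileup() and extract_observations().
site_observations <- function(alignments, sites) {
  lay <- layer_reference(alignments)
  gr_reads <- GenomicRanges::GRanges(lay$chrom,
                                     IRanges::IRanges(lay$start, lay$end))
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$pos, sites$pos))
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_reads)
  si <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  off <- sites$pos[si] - lay$start[ri] + 1L
  base <- substr_vec(lay$seq, ri, off)
  qch <- substr_vec(lay$qual, ri, off)
  b <- as.integer(vapply(qch, function(x) as.integer(charToRaw(x)), integer(1))) - 33L
  category <- ifelse(base == "-", "del",
                     ifelse(base == sites$ref[si], "ref",
                            ifelse(base == sites$alt[si], "alt", "other")))
  data.frame(site = si, read = ri, category = category, b = b,
             strand = lay$strand[ri], stringsAsFactors = FALSE)
}

substr_vec <- function(strings, idx, off) substring(strings[idx], off, off)

#' Extract phasing observations at heterozygous sites
#'
#' Builds the observation table consumed by [em_fit()] / [phase_reads()]:
#' one row per (read, site) where the read shows the exact reference or
#' alternate base.  "Other" bases and in-read deletions carry no phase
#' information under the biallelic model and are excluded; reads left with
#' no usable observation are dropped (their count is reported).
#'
#' @inheritParams build_pileup
#' @return data.frame with columns `read` (contiguous 1..n across usable
#'   reads), `site`, `s` (0 = ref, 1 = alt), `b` (phred base quality),
#'   `strand`; attributes `reads` (data.frame mapping read index to
#'   `qname`) and `n_reads_dropped`
#' @export
extract_observations <- function(alignments, sites) {
  sites <- as.data.frame(sites)
  raw <- site_observations(alignments, sites)
  usable <- raw[raw$category %in% c("ref", "alt"), , drop = FALSE]
  spanning <- unique(raw$read)
  kept <- sort(unique(usable$read))
  n_dropped <- length(setdiff(spanning, kept))
  if (n_dropped > 0)
    message(sprintf("dropped %d read(s) with no usable het observation", n_dropped))
  idx <- match(usable$read, kept)
  out <- data.frame(read = idx, site = usable$site,
                    s = as.integer(usable$category == "alt"),
                    b = usable$b, strand = usable$strand,
                    stringsAsFactors = FALSE)
  out <- out[order(out$read, out$site), , drop = FALSE]
  rownames(out) <- NULL
  qn <- S4Vectors::mcols(alignments)$qname
  attr(out, "reads") <- data.frame(read = seq_along(kept), qname = qn[kept],
                                   stringsAsFactors = FALSE)
  attr(out, "n_reads_dropped") <- n_dropped
  out
}

#' Genome-adjacent heterozygous site pairs co-spanned by a read
#'
#' Used by [switch_error_rate()]'s `"read-spanned"` mode.
#'
#' @param obs observation table from [extract_observations()]
#' @param sites the heterozygous site table the observations refer to
#' @return data.frame `chrom`, `pos1`, `pos2`
#' @export
spanned_site_pairs <- function(obs, sites) {
  sites <- as.data.frame(sites)
  pairs <- unique(do.call(rbind, lapply(split(obs$site, obs$read), function(u) {
    u <- sort(unique(u))
    adj <- u[-length(u)] + 1L == u[-1]   # genome-adjacent in the het list
    if (!any(adj)) return(NULL)
    same <- sites$chrom[u[-length(u)]] == sites$chrom[u[-1]]
    keep <- adj & same
    cbind(u[-length(u)][keep], u[-1][keep])
  })))
  if (is.null(pairs) || nrow(pairs) == 0)
    return(data.frame(chrom = character(), pos1 = integer(), pos2 = integer()))
  data.frame(chrom = sites$chrom[pairs[, 1]],
             pos1 = sites$pos[pairs[, 1]], pos2 = sites$pos[pairs[, 2]],
             stringsAsFactors = FALSE)
}

## ---- VCF ----

vcf_flag_names <- c("homopolymer", "low_coverage", "high_deletion",
                    "strand_bias", "low_qual", "bad_phasing")

#' Read biallelic SNVs from a VCF file
#'
#' Indels, MNVs and multi-allelic records are skipped with a message (the
#' analysis is SNV-only).  Recognises the package's own INFO tags (PE,
#' SB1, SB2, ANN) and the GT/PS genotype fields when present.
#'
#' @param path VCF file (plain text or bgzipped)
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `genotype` (`"het"`/`"hom-alt"`/`"hom-ref"`), `filter_status`,
#'   `phase_set`, `hap_of_alt`, and, when present in INFO, `pe`, `sb1`,
#'   `sb2`, `annotations`
#' @export
read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- lengths(altl)
  alt1 <- rep(NA_character_, length(rr))
  has1 <- n_alt == 1
  alt1[has1] <- as.character(unlist(altl[has1]))
  snv <- has1 & nchar(ref) == 1 & !is.na(alt1) & nchar(alt1) == 1 &
    ref %in% BASES & alt1 %in% BASES
  n_skip <- sum(!snv)
  if (n_skip > 0)
    message(sprintf("skipped %d non-SNV/multi-allelic record(s)", n_skip))
  keep <- which(snv)
  gt <- ps <- NULL
  gmat <- VariantAnnotation::geno(vcf)
  if ("GT" %in% names(gmat)) gt <- gmat$GT[keep, 1]
  if ("PS" %in% names(gmat)) ps <- gmat$PS[keep, 1]
  genotype <- rep(NA_character_, length(keep))
  hap_of_alt <- rep(NA_integer_, length(keep))
  if (!is.null(gt)) {
    genotype <- ifelse(gt %in% c("0/1", "1/0", "0|1", "1|0"), "het",
                       ifelse(gt %in% c("1/1", "1|1"), "hom-alt",
                              ifelse(gt %in% c("0/0", "0|0"), "hom-ref",
                                     NA_character_)))
    hap_of_alt[gt == "1|0"] <- 1L
    hap_of_alt[gt == "0|1"] <- 2L
  }
  out <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr))[keep],
    pos = BiocGenerics::start(rr)[keep],
    ref = ref[keep], alt = alt1[keep],
    qual = as.numeric(rr$QUAL)[keep],
    genotype = genotype,
    filter_status = as.character(rr$FILTER)[keep],
    phase_set = if (is.null(ps)) NA_integer_ else suppressWarnings(as.integer(ps)),
    hap_of_alt = hap_of_alt,
    stringsAsFactors = FALSE)
  info <- VariantAnnotation::info(vcf)
  tags <- c(pe = "PE", sb1 = "SB1", sb2 = "SB2")
  for (nm in names(tags)) {
    if (tags[[nm]] %in% colnames(info))
      out[[nm]] <- as.numeric(info[[tags[[nm]]]])[keep]
  }
  if ("ANN" %in% colnames(info)) {
    ann <- info$ANN[keep]
    out$annotations <- vapply(ann, function(x)
      if (length(x) == 0 || all(is.na(x))) "" else paste(x, collapse = ","),
      character(1))
  }
  rownames(out) <- NULL
  out
}

#' Write a (possibly phased) SNV call set as VCF 4.2
#'
#' Phased heterozygous genotypes use the `|` separator with the phase-set
#' identifier in the `PS` FORMAT field; phasing metrics (PE, SB1, SB2) and
#' annotation flags (ANN) go into INFO.  `read_vcf(write_phased_vcf(x))`
#' round-trips all fields.
#'
#' @param sites data.frame as produced by the caller/phaser: columns
#'   `chrom`, `pos`, `ref`, `alt`, `qual`, `genotype`, optionally
#'   `filter_status`, `phase_set`, `hap_of_alt`, `pe`, `sb1`, `sb2`,
#'   `annotations`
#' @param path output file
#' @param ref_lengths optional named vector of contig lengths for
#'   `##contig` header lines
#' @param sample sample name for the genotype column
#' @return `path`, invisibly
#' @export
write_phased_vcf <- function(sites, path, ref_lengths = NULL,
                             sample = "SAMPLE") {
  sites <- as.data.frame(sites)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=phasecall",
    if (!is.null(ref_lengths))
      sprintf("##contig=<ID=%s,length=%d>", names(ref_lengths),
              as.integer(ref_lengths)),
    "##INFO=<ID=PE,Number=1,Type=Float,Description=\"Phase entropy -log10(t1*t2*(1-t1)*(1-t2)) of the haplotype emission probabilities\">",
    "##INFO=<ID=SB1,Number=1,Type=Integer,Description=\"Forward-strand reads assigned to haplotype 1 in the phase set\">",
    "##INFO=<ID=SB2,Number=1,Type=Integer,Description=\"Forward-strand reads assigned to haplotype 2 in the phase set\">",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Annotation flags\">",
    sprintf("##FILTER=<ID=%s,Description=\"%s\">", vcf_flag_names,
            c("site intersects or flanks a homopolymer run",
              "per-base coverage below floor",
              "deletion fraction of spanning reads above ceiling",
              "haplotype strand-bias statistic above threshold",
              "QUAL below threshold",
              "phase entropy below threshold")),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))

  fmt_num <- function(x, fmt) ifelse(is.na(x), NA, sprintf(fmt, x))
  info <- rep("", nrow(sites))
  add_info <- function(info, tag, val) {
    has <- !is.na(val) & val != ""
    piece <- paste0(tag, "=", val)
    ifelse(has, ifelse(info == "", piece, paste(info, piece, sep = ";")), info)
  }
  if (!is.null(sites$pe)) info <- add_info(info, "PE", fmt_num(sites$pe, "%.4f"))
  if (!is.null(sites$sb1)) info <- add_info(info, "SB1", fmt_num(sites$sb1, "%d"))
  if (!is.null(sites$sb2)) info <- add_info(info, "SB2", fmt_num(sites$sb2, "%d"))
  if (!is.null(sites$annotations))
    info <- add_info(info, "ANN", ifelse(is.na(sites$annotations), "",
                                         sites$annotations))
  info[info == ""] <- "."

  phase_set <- sites$phase_set %||% rep(NA_integer_, nrow(sites))
  hap <- sites$hap_of_alt %||% rep(NA_integer_, nrow(sites))
  phased <- sites$genotype == "het" & !is.na(phase_set) & !is.na(hap)
  gt <- ifelse(sites$genotype == "hom-alt", "1/1",
               ifelse(sites$genotype == "hom-ref", "0/0",
                      ifelse(phased, ifelse(hap == 1L, "1|0", "0|1"), "0/1")))
  fmt <- ifelse(phased, "GT:PS", "GT")
  smp <- ifelse(phased, paste0(gt, ":", phase_set), gt)
  filt <- sites$filter_status %||% rep("PASS", nrow(sites))
  filt[is.na(filt) | filt == ""] <- "PASS"

  lines <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
                 ifelse(is.na(sites$qual), ".", sprintf("%.6g", sites$qual)),
                 filt, info, fmt, smp, sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a BED file as a 1-based region table
#'
#' @param path BED file (0-based half-open intervals)
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive), ready
#'   for [classify_calls()]'s `region` argument
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr), stringsAsFactors = FALSE)
}
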