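# Evaluation arithmetic: alignment error decomposition, call
# classification with genotype-mismatch double counting, switch error.

#' Alignment error rates of long-read alignments
#'
#' Decomposes each alignment's disagreement with the reference into three
#' rates:
#' * `e_sub`: mismatched base pairs / aligned (non-gap) base pairs,
#' * `e_del`: deleted reference bases / aligned reference length
#'   (aligned bases + deleted bases),
#' * `e_ins`: inserted read bases / aligned read length
#'   (aligned bases + inserted bases),
#' and the percent identity `p_id = 100 * (1 - e_sub)`.
#'
#' @param alignments a [GenomicAlignments::GAlignments] as returned by
#'   [parse_alignments()] (needs the `seq` metadata column)
#' @param reference a [Biostrings::DNAStringSet] holding the reference
#'   sequences named by contig
#' @return data.frame, one row per alignment: `e_sub`, `e_del`, `e_ins`,
#'   `p_id`, `aligned` (aligned base pairs), plus an `aggregate` attribute
#'   with the length-weighted means (substitutions weighted by aligned
#'   bases, deletions by aligned reference length, insertions by aligned
#'   read length). Alignments with zero aligned bases get `NA` rates.
#' @export
alignment_error_rates <- function(alignments, reference) {
  stopifnot(is(alignments, "GAlignments"))
  cig <- GenomicAlignments::cigar(alignments)
  opt <- GenomicAlignments::cigarOpTable(cig)
  n_m <- opt[, "M"] + opt[, "="] + opt[, "X"]
  n_d <- opt[, "D"]
  n_i <- opt[, "I"]

  # mismatches: compare reference-layered read sequence to the reference
  seqs <- S4Vectors::mcols(alignments)$seq
  if (is.null(seqs)) stopf("alignments carry no read sequences")
  laid <- GenomicAlignments::sequenceLayer(seqs, cig, from = "query",
                                           to = "reference")
  chrom <- as.character(GenomeInfoDb::seqnames(alignments))
  st <- BiocGenerics::start(alignments)
  en <- BiocGenerics::end(alignments)
  n_mm <- integer(length(alignments))
  for (ctg in unique(chrom)) {
    i <- which(chrom == ctg)
    if (!ctg %in% names(reference)) stopf("contig '%s' not in reference", ctg)
    refwin <- Biostrings::extractAt(
      reference[[ctg]], IRanges::IRanges(st[i], en[i]))
    cmp <- Biostrings::compareStrings(laid[i], refwin)
    # "?" marks a mismatch; gaps ("-"/"+") are not substitutions
    n_mm[i] <- vapply(cmp, function(x)
      sum(charToRaw(x) == charToRaw("?")), integer(1))
  }

  e_sub <- ifelse(n_m > 0, n_mm / n_m, NA_real_)
  e_del <- ifelse(n_m + n_d > 0, n_d / (n_m + n_d), NA_real_)
  e_ins <- ifelse(n_m + n_i > 0, n_i / (n_m + n_i), NA_real_)
  out <- data.frame(e_sub = e_sub, e_del = e_del, e_ins = e_ins,
                    p_id = 100 * (1 - e_sub), aligned = n_m)
  ok <- n_m > 0
  attr(out, "aggregate") <- c(
    e_sub = sum(n_mm[ok]) / sum(n_m[ok]),
    e_del = sum(n_d[ok]) / sum(n_m[ok] + n_d[ok]),
    e_ins = sum(n_i[ok]) / sum(n_m[ok] + n_i[ok]))
  out
}

#' Classify variant calls against a truth set
#'
#' Position + genotype matching for biallelic SNVs: a call matching a truth
#' site in both position and genotype is a true positive; a call at a
#' position absent from the truth is a false positive; a truth site absent
#' from the calls is a false negative; a call at a truth position with a
#' different genotype is counted BOTH as a false positive and as a false
#' negative.  Under this double counting `TP + FN = |truth|` and
#' `TP + FP = |calls|` always hold.
#'
#' @param calls,truth data.frames with columns `chrom`, `pos`, `genotype`
#'   (`"het"` or `"hom-alt"`); positions must be unique within each set
#' @param region optional data.frame (`chrom`, `start`, `end`, 1-based
#'   inclusive) restricting both sets
#' @return list of class `call_classification`: `tp`, `fp`, `fn`, `fdr`,
#'   `fnr`, `precision`, `recall`, `f1`.  An empty call set has `fdr = 0`
#'   (no discoveries were false).
#' @export
classify_calls <- function(calls, truth, region = NULL) {
  restrict <- function(x) {
    if (is.null(region) || nrow(x) == 0) return(x)
    keep <- rep(FALSE, nrow(x))
    for (i in seq_len(nrow(region))) {
      keep <- keep | (x$chrom == region$chrom[i] &
                        x$pos >= region$start[i] & x$pos <= region$end[i])
    }
    x[keep, , drop = FALSE]
  }
  calls <- restrict(as.data.frame(calls))
  truth <- restrict(as.data.frame(truth))
  key <- function(x) paste(x$chrom, x$pos)
  if (anyDuplicated(key(calls))) stopf("duplicated positions in call set")
  if (anyDuplicated(key(truth))) stopf("duplicated positions in truth set")

  m <- match(key(calls), key(truth))
  gt_match <- !is.na(m) & calls$genotype == truth$genotype[m]
  tp <- sum(gt_match)
  fp <- nrow(calls) - tp            # novel positions + genotype mismatches
  fn <- nrow(truth) - tp            # missed positions + genotype mismatches
  fdr <- if (tp + fp == 0) 0 else fp / (tp + fp)
  fnr <- if (tp + fn == 0) 0 else fn / (tp + fn)
  structure(list(tp = tp, fp = fp, fn = fn, fdr = fdr, fnr = fnr,
                 precision = 1 - fdr, recall = 1 - fnr,
                 f1 = f1_from_rates(fdr, fnr)),
            class = "call_classification")
}

#' @export
print.call_classification <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d | FDR %.4f  FNR %.4f  F1 %.4f\n",
              x$tp, x$fp, x$fn, x$fdr, x$fnr, x$f1))
  invisible(x)
}

#' F1 score from FDR and FNR
#'
#' Harmonic mean of precision (`1 - FDR`) and recall (`1 - FNR`):
#' `F1 = 2 / (1/(1 - FDR) + 1/(1 - FNR))`.  Returns 0 when either rate is
#' 1 (continuity).
#'
#' @param fdr,fnr rates in `[0, 1]` (vectorised)
#' @return F1 in `[0, 1]`
#' @examples
#' f1_from_rates(0.128, 0.144)  # 0.864
#' @export
f1_from_rates <- function(fdr, fnr) {
  stopifnot(all(fdr >= 0 & fdr <= 1), all(fnr >= 0 & fnr <= 1))
  p <- 1 - fdr; r <- 1 - fnr
  ifelse(p == 0 | r == 0, 0, 2 * p * r / (p + r))
}

#' Switch error rate of phased calls against phased truth
#'
#' Walks adjacent pairs of heterozygous sites shared between the call and
#' truth sets within each call phase set and counts a switch whenever the
#' relative phase of the pair (alternate alleles on the same vs opposite
#' haplotypes) disagrees with the truth.  The rate is switches / evaluated
#' pairs; it is invariant to relabelling the haplotypes of any phase set in
#' either input.
#'
#' @param calls,truth data.frames with columns `chrom`, `pos`,
#'   `hap_of_alt` (1 or 2) and, for `calls`, `phase_set`; truth may carry a
#'   `phase_set` too (default: one set per chromosome)
#' @param mode `"all"` evaluates every adjacent shared pair within a phase
#'   set; `"read-spanned"` restricts to pairs co-spanned by at least one
#'   read, supplied via `spanned_pairs`
#' @param spanned_pairs data.frame (`chrom`, `pos1`, `pos2`) of site pairs
#'   co-spanned by a read; required for `mode = "read-spanned"`
#' @return list: `rate` (NA when no pair is evaluable), `switches`,
#'   `pairs`
#' @export
switch_error_rate <- function(calls, truth, mode = c("all", "read-spanned"),
                              spanned_pairs = NULL) {
  mode <- match.arg(mode)
  calls <- as.data.frame(calls); truth <- as.data.frame(truth)
  if (is.null(truth$phase_set)) truth$phase_set <- truth$chrom
  key <- function(x) paste(x$chrom, x$pos)
  m <- match(key(calls), key(truth))
  sh <- which(!is.na(m) & !is.na(calls$hap_of_alt) &
                !is.na(truth$hap_of_alt[m]))
  switches <- 0L; pairs <- 0L
  for (grp in split(sh, paste(calls$chrom[sh], calls$phase_set[sh]))) {
    grp <- grp[order(calls$pos[grp])]
    if (length(grp) < 2) next
    for (k in seq_len(length(grp) - 1)) {
      i <- grp[k]; j <- grp[k + 1]
      # truth relative phase is only defined within one truth phase set
      if (truth$phase_set[m[i]] != truth$phase_set[m[j]]) next
      if (mode == "read-spanned") {
        if (is.null(spanned_pairs)) stopf("spanned_pairs required")
        hit <- any(spanned_pairs$chrom == calls$chrom[i] &
                     spanned_pairs$pos1 == calls$pos[i] &
                     spanned_pairs$pos2 == calls$pos[j])
        if (!hit) next
      }
      same_call <- calls$hap_of_alt[i] == calls$hap_of_alt[j]
      same_truth <- truth$hap_of_alt[m[i]] == truth$hap_of_alt[m[j]]
      pairs <- pairs + 1L
      if (same_call != same_truth) switches <- switches + 1L
    }
  }
  list(rate = if (pairs == 0) NA_real_ else switches / pairs,
       switches = switches, pairs = pairs)
}

#' Percentage from a count ratio
#'
#' @param num,den non-negative counts, `den > 0`
#' @param digits display precision; the default rounds like the usual
#'   two-significant-figure percentage reporting
#' @return `100 * num / den`, rounded to `digits` when given
#' @examples
#' proportion(69, 45219, digits = 2)  # 0.15
#' proportion(21, 35, digits = 0)     # 60
#' @export
proportion <- function(num, den, digits = NULL) {
  if (any(den <= 0)) stopf("denominator must be positive")
  p <- 100 * num / den
  if (!is.null(digits)) p <- round(p, digits)
  p
}
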