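# Per-site, frequency-based diploid SNV caller with
# contamination-adjusted expected allele fractions.  At per-base error
# rates above 10% the classical 0 / 0.5 / 1 expected allele fractions
# misfit the data badly; the contamination parameters shift the expected
# reference/alternate read probabilities per genotype instead.

#' Genotype model for the frequency-based caller
#'
#' The model is a binomial on the (ref, alt) read counts at a site with a
#' genotype-specific alternate-read probability:
#' hom-ref `e`, het `1 - c_het`, hom-alt `1 - c_hom` (default
#' interpretation) or `c_hom` (`hom_interp = "literal"`).
#'
#' @param c_het first contamination parameter: probability of a
#'   reference-consistent read at a heterozygous site (shifts the expected
#'   alternate fraction from 0.5 down to `1 - c_het`)
#' @param c_hom second contamination parameter.  Default interpretation
#'   (`"ref-consistent"`): probability of a reference-consistent read at a
#'   hom-alt site, so the expected alternate fraction there is
#'   `1 - c_hom`.  The `"literal"` interpretation takes it as the
#'   alternate-read probability itself; that reading makes hom-alt calls
#'   nearly impossible at the usual 0.1--0.6 values and is kept only for
#'   comparison.
#' @param e alternate-read probability at a hom-ref site (per-allele base
#'   error, roughly a third of the substitution error rate)
#' @param min_alt minimum count of the alternate allele before a site is
#'   considered a putative variant (the `-C` rule)
#' @param hom_interp see `c_hom`
#' @return list of class `genotype_model`
#' @export
genotype_model <- function(c_het = 0.7, c_hom = 0.1, e = 0.05,
                           min_alt = 5L,
                           hom_interp = c("ref-consistent", "literal")) {
  hom_interp <- match.arg(hom_interp)
  stopifnot(c_het > 0, c_het < 1, c_hom > 0, c_hom < 1, e > 0, e < 1,
            min_alt >= 1)
  p_alt <- c(hom_ref = e, het = 1 - c_het,
             hom_alt = if (hom_interp == "ref-consistent") 1 - c_hom else c_hom)
  structure(list(c_het = c_het, c_hom = c_hom, e = e,
                 min_alt = as.integer(min_alt), hom_interp = hom_interp,
                 p_alt = p_alt), class = "genotype_model")
}

#' Per-genotype binomial log-likelihoods
#'
#' @param n_ref,n_alt reference / alternate read counts (vectorised)
#' @param model a [genotype_model()]
#' @return matrix with columns `hom_ref`, `het`, `hom_alt`; rows with
#'   `n_ref + n_alt == 0` are `NA` (no-call)
#' @export
genotype_likelihoods <- function(n_ref, n_alt, model = genotype_model()) {
  n <- n_ref + n_alt
  ll <- vapply(model$p_alt, function(p) {
    out <- dbinom(n_alt, n, p, log = TRUE)
    out[n == 0] <- NA_real_
    out
  }, numeric(length(n)))
  if (length(n) == 1) ll <- matrix(ll, nrow = 1,
                                   dimnames = list(NULL, names(model$p_alt)))
  ll
}

# QUAL: phred-scaled posterior probability that the site is non-reference
# under a flat prior over the three genotypes, capped at 3000.
qual_from_loglik <- function(ll) {
  m <- apply(ll, 1, max)
  w <- exp(ll - m)
  post_ref <- w[, "hom_ref"] / rowSums(w)
  prob_to_phred(post_ref)
}

#' Call a single site from pileup counts
#'
#' Applies the minimum-alternate-count rule, then picks the
#' maximum-likelihood genotype under the contamination-adjusted binomial
#' model.  Hom-ref decisions and sites below the count threshold return
#' `NULL` (no-call).
#'
#' @param counts one row of [build_pileup()] output (needs `ref_fwd`,
#'   `ref_rev`, `alt_fwd`, `alt_rev`; other/deletion columns are used for
#'   the coverage fields when present)
#' @param site data.frame row with `chrom`, `pos`, `ref`, `alt`
#' @param model a [genotype_model()]
#' @return one-row data.frame (chrom, pos, ref, alt, qual, genotype,
#'   strand-split counts, coverage) or `NULL`
#' @export
call_site <- function(counts, site, model = genotype_model()) {
  n_ref <- counts$ref_fwd + counts$ref_rev
  n_alt <- counts$alt_fwd + counts$alt_rev
  if (n_alt < model$min_alt) return(NULL)
  ll <- genotype_likelihoods(n_ref, n_alt, model)
  if (any(is.na(ll))) return(NULL)
  g <- colnames(ll)[which.max(ll[1, ])]
  if (g == "hom_ref") return(NULL)
  data.frame(chrom = site$chrom, pos = site$pos, ref = site$ref,
             alt = site$alt, qual = qual_from_loglik(ll),
             genotype = ifelse(g == "het", "het", "hom-alt"),
             n_ref = n_ref, n_alt = n_alt,
             srf = counts$ref_fwd, srr = counts$ref_rev,
             saf = counts$alt_fwd, sar = counts$alt_rev,
             coverage = counts$coverage %||% (n_ref + n_alt),
             physical_coverage = counts$physical_coverage %||%
               (n_ref + n_alt),
             stringsAsFactors = FALSE)
}

#' Genome-wide SNV calling from an alignment file
#'
#' Runs an htslib pileup over the whole alignment set (mapping quality 0
#' and base quality 0 included, matching a `-Q 0 -A` style depth
#' definition), picks the most frequent non-reference base at each
#' position as the candidate alternate, and genotypes every position with
#' at least `model$min_alt` alternate observations.
#'
#' @param path SAM/BAM file
#' @param reference [Biostrings::DNAStringSet] named by contig
#' @param model a [genotype_model()]
#' @return data.frame of het and hom-alt calls: `chrom`, `pos`, `ref`,
#'   `alt`, `qual`, `genotype`, counts (`n_ref`, `n_alt`, `srf`, `srr`,
#'   `saf`, `sar`), `coverage`, `physical_coverage`, `del_frac`
#' @export
call_variants <- function(path, reference, model = genotype_model()) {
  calls_from_counts(genome_pileup(path, reference), model)
}

# htslib pileup over the whole alignment file, widened to one row per
# position with per-(base, strand) counts and the reference base
genome_pileup <- function(path, reference) {
  bam <- as_bam(path)
  pp <- Rsamtools::PileupParam(
    max_depth = 100000L, min_base_quality = 0L, min_mapq = 0L,
    min_nucleotide_depth = 1L, distinguish_strands = TRUE,
    include_deletions = TRUE, include_insertions = FALSE)
  pu <- Rsamtools::pileup(bam, pileupParam = pp)
  pu$chrom <- as.character(pu$seqnames)
  pu$nucleotide <- as.character(pu$nucleotide)
  pu$strand <- as.character(pu$strand)
  pu <- data.table::as.data.table(pu)

  # wide per-position count table: one column per (base, strand)
  wide <- data.table::dcast(pu, chrom + pos ~ nucleotide + strand,
                            value.var = "count", fill = 0L)
  for (col in as.vector(outer(c(BASES, "-"), c("+", "-"), paste, sep = "_")))
    if (!col %in% names(wide))
      data.table::set(wide, j = col, value = 0L)

  # reference base per position
  refv <- rep(NA_character_, nrow(wide))
  for (ctg in unique(wide$chrom)) {
    i <- which(wide$chrom == ctg)
    refv[i] <- as.character(Biostrings::extractAt(
      reference[[ctg]], IRanges::IRanges(wide$pos[i], wide$pos[i])))
  }
  data.table::set(wide, j = "ref", value = refv)
  wide
}

calls_from_counts <- function(wide, model) {
  fwd <- as.matrix(wide[, paste0(BASES, "_+"), with = FALSE])
  rev <- as.matrix(wide[, paste0(BASES, "_-"), with = FALSE])
  tot <- fwd + rev
  n_pos <- nrow(wide)
  ref_idx <- match(wide$ref, BASES)
  ok_ref <- !is.na(ref_idx)

  # candidate alternate: most frequent non-reference base (ties by base order)
  altcnt <- tot
  altcnt[cbind(seq_len(n_pos), ref_idx)[ok_ref, , drop = FALSE]] <- -1L
  alt_idx <- max.col(altcnt, ties.method = "first")
  ij_ref <- cbind(seq_len(n_pos), ref_idx)
  ij_alt <- cbind(seq_len(n_pos), alt_idx)
  n_ref <- tot[ij_ref]
  n_alt <- altcnt[ij_alt]

  dels <- wide[["-_+"]] + wide[["-_-"]]
  coverage <- rowSums(tot)
  physical <- coverage + dels

  keep <- ok_ref & n_alt >= model$min_alt
  if (!any(keep)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), qual = numeric(), genotype = character(),
                      n_ref = integer(), n_alt = integer(), srf = integer(),
                      srr = integer(), saf = integer(), sar = integer(),
                      coverage = integer(), physical_coverage = integer(),
                      del_frac = numeric(), stringsAsFactors = FALSE))
  }
  i <- which(keep)
  ll <- genotype_likelihoods(n_ref[i], n_alt[i], model)
  g_idx <- max.col(ll, ties.method = "first")
  qual <- qual_from_loglik(ll)
  out <- data.frame(
    chrom = wide$chrom[i], pos = wide$pos[i],
    ref = wide$ref[i], alt = BASES[alt_idx[i]],
    qual = qual,
    genotype = c("hom-ref", "het", "hom-alt")[g_idx],
    n_ref = n_ref[i], n_alt = n_alt[i],
    srf = fwd[ij_ref][i], srr = rev[ij_ref][i],
    saf = fwd[ij_alt][i], sar = rev[ij_alt][i],
    coverage = coverage[i], physical_coverage = physical[i],
    del_frac = ifelse(physical[i] > 0, dels[i] / physical[i], 0),
    stringsAsFactors = FALSE)
  out <- out[out$genotype != "hom-ref", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select contamination parameters by best F1 against a truth set
#'
#' Mirrors the grid-search protocol used to configure the caller: the
#' first contamination parameter is varied over 0.6/0.7/0.8 (and
#' optionally the second over its grid), calls are filtered at the
#' policy's QUAL threshold, and the parameter pair with the best F1
#' against the truth wins.  Tune on one data set and apply the winner to
#' another (the original workflow derived cutoffs on one chromosome and
#' applied them genome-wide).
#'
#' @param path SAM/BAM file of the tuning data set
#' @param reference [Biostrings::DNAStringSet]
#' @param truth truth variant table (`chrom`, `pos`, `genotype`)
#' @param c_het_grid,c_hom_grid parameter grids
#' @param e,min_alt fixed remaining model parameters
#' @param qual_threshold QUAL cut applied before scoring
#' @return list: `model` (the winning [genotype_model()]), `table`
#'   (data.frame of the grid with F1/FDR/FNR per cell)
#' @export
tune_contamination <- function(path, reference, truth,
                               c_het_grid = c(0.6, 0.7, 0.8),
                               c_hom_grid = 0.1, e = 0.05, min_alt = 5L,
                               qual_threshold = 30) {
  wide <- genome_pileup(path, reference)
  grid <- expand.grid(c_het = c_het_grid, c_hom = c_hom_grid)
  scores <- lapply(seq_len(nrow(grid)), function(i) {
    m <- genotype_model(c_het = grid$c_het[i], c_hom = grid$c_hom[i],
                        e = e, min_alt = min_alt)
    calls <- calls_from_counts(wide, m)
    calls <- calls[calls$qual >= qual_threshold, , drop = FALSE]
    cl <- classify_calls(calls, truth)
    data.frame(c_het = grid$c_het[i], c_hom = grid$c_hom[i],
               f1 = cl$f1, fdr = cl$fdr, fnr = cl$fnr)
  })
  tab <- do.call(rbind, scores)
  best <- which.max(tab$f1)
  list(model = genotype_model(c_het = tab$c_het[best],
                              c_hom = tab$c_hom[best],
                              e = e, min_alt = min_alt),
       table = tab)
}
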