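# Diploid genome and long-read simulator.  Emulates an idealized noisy
# long-read run: per-read accuracy drawn from a truncated normal, errors
# placed uniformly at random within the read and apportioned among
# substitutions, insertions and deletions by a configurable "difference
# ratio".  The generating alignment is emitted as a truth SAM so no
# aligner is needed downstream, and the planted variants as a phased
# truth VCF.

#' Simulation configuration
#'
#' Defaults describe the sequencing run the simulator emulates: mean read
#' length 6373 bp; per-read accuracy Normal(0.795, 0.20) truncated to
#' `[0.40, 1]`, so mean total error is about 20.6% matching the observed
#' 12.7/4.7/3.2 substitution/deletion/insertion split; substitution-heavy
#' difference ratio 60:35:5 (the deletion-heavy preset is 30:30:40);
#' heterozygous SNVs at 1 per kb plus homozygous-alternate SNVs at 0.5
#' per kb.
#'
#' @param ref_length reference length in bp
#' @param het_density,hom_density expected heterozygous /
#'   homozygous-alternate SNVs per bp
#' @param mean_read_length mean of the log-normal read-length distribution
#' @param read_length_sdlog shape (sdlog) of the read-length distribution
#' @param accuracy_mean,accuracy_sd,accuracy_min per-read accuracy draw:
#'   Normal(mean, sd) truncated to `[accuracy_min, 1]`
#' @param difference_ratio length-3 numeric, relative
#'   substitution:insertion:deletion error proportions (normalised
#'   internally)
#' @param depth_per_haplotype mean coverage contributed by each haplotype
#' @param seed integer seed; identical configs and seeds give identical
#'   output
#' @param contig contig name of the simulated reference
#' @return list of class `sim_config`
#' @export
sim_config <- function(ref_length = 1e5, het_density = 1e-3,
                       hom_density = 5e-4, mean_read_length = 6373,
                       read_length_sdlog = 0.55, accuracy_mean = 0.795,
                       accuracy_sd = 0.20, accuracy_min = 0.40,
                       difference_ratio = c(sub = 60, ins = 35, del = 5),
                       depth_per_haplotype = 40, seed = 1L,
                       contig = "sim1") {
  stopifnot(ref_length >= 1000, het_density >= 0, het_density < 1,
            hom_density >= 0, hom_density < 1, mean_read_length > 0,
            length(difference_ratio) == 3, all(difference_ratio > 0),
            accuracy_min >= 0, accuracy_min < 1, accuracy_sd > 0,
            depth_per_haplotype >= 0)
  names(difference_ratio) <- c("sub", "ins", "del")
  structure(list(ref_length = as.integer(ref_length),
                 het_density = het_density, hom_density = hom_density,
                 mean_read_length = mean_read_length,
                 read_length_sdlog = read_length_sdlog,
                 accuracy_mean = accuracy_mean, accuracy_sd = accuracy_sd,
                 accuracy_min = accuracy_min,
                 difference_ratio = difference_ratio / sum(difference_ratio),
                 depth_per_haplotype = depth_per_haplotype,
                 seed = as.integer(seed), contig = contig),
            class = "sim_config")
}

# distinct positions, no two closer than 2 bp
draw_positions <- function(n, L, taken = integer(0)) {
  pos <- integer(0)
  guard <- 0
  while (length(pos) < n) {
    guard <- guard + 1
    if (guard > 1000) stopf("variant density too high for reference length")
    cand <- sample.int(L, n - length(pos), replace = TRUE)
    all_pos <- c(taken, pos)
    ok <- vapply(cand, function(p) all(abs(all_pos - p) > 1) || length(all_pos) == 0,
                 logical(1))
    cand <- unique(cand[ok])
    # also enforce spacing within the new batch
    if (length(cand) > 1) {
      cand <- sort(cand)
      cand <- cand[c(TRUE, diff(cand) > 1)]
    }
    pos <- c(pos, cand)
  }
  sort(pos[seq_len(n)])
}

#' Simulate a diploid genome with planted SNVs
#'
#' Draws a random reference, plants heterozygous SNVs (each on one
#' haplotype, chosen at random) and homozygous-alternate SNVs (on both),
#' with no two variants within 1 bp of each other.  Variant counts are
#' Poisson at the configured densities.
#'
#' @param config a [sim_config()]
#' @return list: `reference`, `hap1`, `hap2`
#'   ([Biostrings::DNAStringSet]s), `truth` (data.frame `chrom`, `pos`,
#'   `ref`, `alt`, `genotype`, `hap_of_alt`, `phase_set`), `config`
#' @export
simulate_diploid <- function(config = sim_config()) {
  set.seed(config$seed)
  L <- config$ref_length
  ref_chars <- sample(BASES, L, replace = TRUE)
  n_het <- rpois(1, L * config$het_density)
  n_hom <- rpois(1, L * config$hom_density)
  pos_het <- draw_positions(n_het, L)
  pos_hom <- draw_positions(n_hom, L, taken = pos_het)

  alt_of <- function(refb) {
    idx <- match(refb, BASES)
    BASES[((idx - 1L + sample.int(3, length(refb), replace = TRUE)) %% 4L) + 1L]
  }
  truth <- data.frame(
    chrom = rep(config$contig, n_het + n_hom),
    pos = c(pos_het, pos_hom),
    ref = ref_chars[c(pos_het, pos_hom)],
    genotype = rep(c("het", "hom-alt"), c(n_het, n_hom)),
    hap_of_alt = c(sample(1:2, n_het, replace = TRUE), rep(NA_integer_, n_hom)),
    phase_set = rep(1L, n_het + n_hom),
    stringsAsFactors = FALSE)
  truth$alt <- alt_of(truth$ref)
  truth <- truth[order(truth$pos), c("chrom", "pos", "ref", "alt", "genotype",
                                     "hap_of_alt", "phase_set")]
  rownames(truth) <- NULL

  h1 <- h2 <- ref_chars
  het <- truth$genotype == "het"
  on1 <- het & truth$hap_of_alt == 1L
  on2 <- het & truth$hap_of_alt == 2L
  h1[truth$pos[on1 | !het]] <- truth$alt[on1 | !het]
  h2[truth$pos[on2 | !het]] <- truth$alt[on2 | !het]

  mk <- function(x) {
    s <- Biostrings::DNAStringSet(paste(x, collapse = ""))
    names(s) <- config$contig
    s
  }
  list(reference = mk(ref_chars), hap1 = mk(h1), hap2 = mk(h2),
       truth = truth, config = config)
}

# Truncated-normal accuracy by rejection.  accuracy_mean is the target
# mean of the TRUNCATED draw (truncating Normal(0.795, 0.2) to [0.4, 1]
# would otherwise inflate the realised mean accuracy to ~0.75-err... i.e.
# deflate accuracy and inflate error to ~25%); the underlying normal mean
# is solved for so the realised mean error matches the stated ~20.5%.
draw_accuracy <- function(n, config) {
  sd <- config$accuracy_sd; lo <- config$accuracy_min; hi <- 1
  trunc_mean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  # monotone in mu; invert on a fine grid (closed form is NaN-prone in the
  # far tails where the truncation window has no mass)
  mus <- seq(lo - 1, hi + 1, by = 1e-3)
  tm <- vapply(mus, trunc_mean, numeric(1))
  ok <- is.finite(tm)
  mu <- stats::approx(tm[ok], mus[ok], xout = config$accuracy_mean,
                      rule = 2)$y
  # inverse-CDF sampling of the truncated normal (no rejection loop)
  u <- runif(n, stats::pnorm(lo, mu, sd), stats::pnorm(hi, mu, sd))
  pmin(hi, pmax(lo, stats::qnorm(u, mu, sd)))
}

#' Simulate error-bearing long reads from a diploid genome
#'
#' Reads are drawn uniformly from each haplotype at the configured
#' per-haplotype depth.  Each read's error rate is `1 - accuracy`;
#' errors fall uniformly at random within the read and are apportioned
#' among substitution (a uniformly random different base), single-base
#' insertion (a uniformly random base) and single-base deletion by the
#' difference ratio.  Base qualities encode the per-read error rate.
#' Every read carries its exact generating alignment (CIGAR), so no
#' aligner is needed.
#'
#' @param sim output of [simulate_diploid()]
#' @param config a [sim_config()]; defaults to the one inside `sim`
#' @return data.frame of reads: `qname`, `hap`, `strand`, `chrom`, `pos`
#'   (1-based leftmost), `cigar`, `seq` (aligned orientation), `qual`,
#'   `accuracy`.  Zero depth gives an empty frame with a warning.
#' @export
simulate_reads <- function(sim, config = sim$config) {
  set.seed(config$seed + 1L)
  L <- config$ref_length
  ratio <- config$difference_ratio
  haps <- list(charToRaw(as.character(sim$hap1[[1]])),
               charToRaw(as.character(sim$hap2[[1]])))
  base_raw <- charToRaw(paste(BASES, collapse = ""))

  # starts are spread over L + len - 1 positions so coverage is uniform
  # across the contig (edges included); scale the read count accordingly
  n_per_hap <- round(config$depth_per_haplotype *
                       (L + config$mean_read_length) / config$mean_read_length)
  if (n_per_hap == 0) {
    warning("depth 0: no reads simulated")
    return(data.frame(qname = character(), hap = integer(),
                      strand = character(), chrom = character(),
                      pos = integer(), cigar = character(), seq = character(),
                      qual = character(), accuracy = numeric(),
                      stringsAsFactors = FALSE))
  }

  meanlog <- log(config$mean_read_length) - config$read_length_sdlog^2 / 2
  out <- vector("list", 2 * n_per_hap)
  k <- 0
  for (h in 1:2) {
    lens <- pmax(200L, pmin(as.integer(round(
      stats::rlnorm(n_per_hap, meanlog, config$read_length_sdlog))),
      10L * as.integer(config$mean_read_length)))
    starts <- floor(runif(n_per_hap, 2 - lens, L + 1))  # uniform coverage incl. edges
    accs <- draw_accuracy(n_per_hap, config)
    strands <- sample(c("+", "-"), n_per_hap, replace = TRUE)
    for (i in seq_len(n_per_hap)) {
      s0 <- max(1L, as.integer(starts[i]))
      e0 <- min(L, as.integer(starts[i]) + lens[i] - 1L)
      if (e0 - s0 + 1L < 100L) next
      k <- k + 1
      out[[k]] <- mutate_read(haps[[h]], s0, e0, 1 - accs[i], ratio, base_raw)
      out[[k]]$hap <- h
      out[[k]]$strand <- strands[i]
      out[[k]]$accuracy <- accs[i]
      out[[k]]$qname <- sprintf("hap%d_read%06d", h, i)
    }
  }
  out <- out[seq_len(k)]
  reads <- data.frame(
    qname = vapply(out, `[[`, character(1), "qname"),
    hap = vapply(out, `[[`, integer(1), "hap"),
    strand = vapply(out, `[[`, character(1), "strand"),
    chrom = config$contig,
    pos = vapply(out, `[[`, integer(1), "pos"),
    cigar = vapply(out, `[[`, character(1), "cigar"),
    seq = vapply(out, `[[`, character(1), "seq"),
    qual = vapply(out, `[[`, character(1), "qual"),
    accuracy = vapply(out, `[[`, numeric(1), "accuracy"),
    stringsAsFactors = FALSE)
  reads
}

# introduce errors into the template haps[s0..e0]; returns pos/cigar/seq/qual
mutate_read <- function(hap_raw, s0, e0, err, ratio, base_raw) {
  tmpl <- hap_raw[s0:e0]
  m <- length(tmpl)
  p_sub <- err * ratio[["sub"]]; p_ins <- err * ratio[["ins"]]
  p_del <- err * ratio[["del"]]
  u <- runif(m)
  st <- integer(m)                      # 0 match, 1 sub, 2 del, 3 ins+match
  st[u < p_sub] <- 1L
  st[u >= p_sub & u < p_sub + p_del] <- 2L
  st[u >= p_sub + p_del & u < p_sub + p_del + p_ins] <- 3L

  n_out <- ifelse(st == 2L, 0L, ifelse(st == 3L, 2L, 1L))
  outpos <- cumsum(n_out) - n_out + 1L
  seq_out <- tmpl[rep.int(seq_len(m), n_out)]
  subs <- which(st == 1L)
  if (length(subs) > 0) {
    # map A/C/G/T raw byte to 1..4, then shift by 1..3 for a different base
    code <- integer(length(subs))
    for (b in 1:4) code[tmpl[subs] == base_raw[b]] <- b
    newc <- ((code - 1L + sample.int(3, length(subs), replace = TRUE)) %% 4L) + 1L
    seq_out[outpos[subs]] <- base_raw[newc]
  }
  ins <- which(st == 3L)
  if (length(ins) > 0)
    seq_out[outpos[ins]] <- base_raw[sample.int(4, length(ins), replace = TRUE)]

  # cigar ops: one per emitted/deleted unit
  n_op <- ifelse(st == 3L, 2L, 1L)
  oppos <- cumsum(n_op) - n_op + 1L
  ops <- rep.int(1L, sum(n_op))          # 1 = M, 2 = D, 3 = I
  ops[oppos[st == 2L]] <- 2L
  ops[oppos[ins]] <- 3L
  r <- rle(ops)
  # alignments cannot start/end with a deletion
  lead_del <- 0L
  if (r$values[1] == 2L) {
    lead_del <- r$lengths[1]
    r$values <- r$values[-1]; r$lengths <- r$lengths[-1]
  }
  if (length(r$values) > 0 && r$values[length(r$values)] == 2L) {
    r$values <- r$values[-length(r$values)]
    r$lengths <- r$lengths[-length(r$lengths)]
  }
  cigar <- paste0(r$lengths, c("M", "D", "I")[r$values], collapse = "")

  q <- max(2L, min(40L, as.integer(round(-10 * log10(max(err, 1e-4))))))
  list(pos = s0 + lead_del, cigar = cigar,
       seq = rawToChar(seq_out),
       qual = strrep(rawToChar(as.raw(q + 33L)), length(seq_out)))
}

#' Write simulated reads as SAM (and optionally FASTQ)
#'
#' The SAM records the exact generating alignment; reverse-strand reads
#' get flag 16 and, in the FASTQ, the reverse-complemented (physical)
#' sequence.
#'
#' @param reads data.frame from [simulate_reads()]
#' @param ref_lengths named integer vector of contig lengths
#' @param sam_path output SAM path
#' @param fastq_path optional FASTQ path
#' @return `sam_path`, invisibly
#' @export
write_sam <- function(reads, ref_lengths, sam_path, fastq_path = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  lines <- paste(reads$qname, flag, reads$chrom, reads$pos, 60L, reads$cigar,
                 "*", 0L, 0L, reads$seq, reads$qual, sep = "\t")
  writeLines(c(hdr, lines), sam_path)
  if (!is.null(fastq_path)) {
    seqs <- Biostrings::DNAStringSet(reads$seq)
    neg <- reads$strand == "-"
    seqs[neg] <- Biostrings::reverseComplement(seqs[neg])
    qual <- reads$qual       # constant per read, so reversal is a no-op
    writeLines(paste0("@", reads$qname, "\n", as.character(seqs), "\n+\n",
                      qual), fastq_path)
  }
  invisible(sam_path)
}

#' Write a reference or haplotype as FASTA
#' @param seqs a named [Biostrings::DNAStringSet]
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Inject a phase-inconsistent false heterozygous site into an
#' observation table
#'
#' Validation utility: rewrites the observations at one site so the
#' alternate allele occurs in a random subset of the spanning reads,
#' independent of haplotype — the signature of a false variant.  Used to
#' test that the phase-entropy filter removes such sites.
#'
#' @param obs observation table from [extract_observations()]
#' @param site site index to corrupt
#' @param frac probability that a spanning read shows the alternate
#' @return `obs` with the site's allele codes redrawn
#' @export
inject_false_het <- function(obs, site, frac = 0.5) {
  i <- which(obs$site == site)
  obs$s[i] <- rbinom(length(i), 1, frac)
  obs
}
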