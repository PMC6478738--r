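# Two-haplotype emission-probability model for read-backed phasing.
#
# A diploid sample has two haplotypes and no recombination within a phase
# block.  Read r comes from latent haplotype H_r in {1,2} with prior
# P(H_r) = 0.5.  At heterozygous site t, a read from haplotype h carries the
# alternate base with emission probability theta[t, h].  The observed base
# s_{r,j} differs from the latent base g_{r,j} with the phred error
# probability of its base quality.  The latent base is marginalised
# analytically, so the per-observation likelihood is a two-term mixture and
# EM only has to handle the read-to-haplotype assignment.

#' Base-observation probability from a phred quality
#'
#' Probability of observing allele code `s` when the underlying base is `g`,
#' both coded 0 (reference) / 1 (alternate), given the phred base quality
#' `b`.  With `eps = 10^(-b/10)` this is `1 - eps` on a match and `eps` on a
#' mismatch: after biallelic reduction only the two allele codes exist, so
#' the whole error mass goes to the opposite code (not `eps/3`).
#'
#' @param s observed allele code, 0 or 1 (vectorised)
#' @param g candidate underlying allele code, 0 or 1
#' @param b phred-scaled base quality, `>= 0`
#' @return probability in (0, 1]
#' @examples
#' psi(1, 1, 10)  # 0.9
#' psi(1, 0, 20)  # 0.01
#' @export
psi <- function(s, g, b) {
  if (any(b < 0)) stopf("negative phred base quality")
  if (!all(s %in% c(0, 1)) || !all(g %in% c(0, 1)))
    stopf("allele codes must be 0 (ref) or 1 (alt)")
  eps <- phred_to_prob(b)
  ifelse(s == g, 1 - eps, eps)
}

#' Likelihood of one read's observations given a haplotype
#'
#' Product over the read's heterozygous sites of the mixture
#' `psi(s, 1, b) * theta[u, h] + psi(s, 0, b) * (1 - theta[u, h])`, i.e. the
#' latent base is summed out analytically.
#'
#' @param read list or data.frame with elements/columns `u` (site indices
#'   into the rows of `theta`), `s` (observed allele codes) and `b` (phred
#'   base qualities)
#' @param h haplotype, 1 or 2
#' @param theta emission matrix, `n_sites x 2`, alternate-allele emission
#'   probabilities
#' @return probability in (0, 1]
#' @export
read_hap_likelihood <- function(read, h, theta) {
  u <- read$u; s <- read$s; b <- read$b
  if (length(u) == 0) stopf("read spans zero usable heterozygous sites")
  th <- theta[u, h]
  prod(psi(s, 1, b) * th + psi(s, 0, b) * (1 - th))
}

#' Complete-data log-likelihood at fixed haplotype assignments
#'
#' Log of the joint probability of the observations and the given read
#' assignments: per read, the 0.5 haplotype prior (applied once per read)
#' times the product over its sites of the emission mixture.
#'
#' @param reads list of reads as in [read_hap_likelihood()]
#' @param hap_assignments integer vector, one haplotype (1/2) per read
#' @param theta emission matrix
#' @return log-probability (0 for zero reads)
#' @export
complete_data_loglik <- function(reads, hap_assignments, theta) {
  if (length(reads) == 0) return(0)
  stopifnot(length(hap_assignments) == length(reads))
  sum(vapply(seq_along(reads), function(r) {
    log(0.5) + log(read_hap_likelihood(reads[[r]], hap_assignments[r], theta))
  }, numeric(1)))
}

#' EM configuration for the phasing model
#'
#' @param tol convergence tolerance on the change of the observed-data
#'   log-likelihood
#' @param max_iter maximum EM iterations
#' @param seed integer seed for the random initialisation
#' @param n_starts number of random restarts; the start with the highest
#'   final observed-data log-likelihood wins (deterministic given `seed`)
#' @param eps_theta clamp for theta at every M-step, keeping phase entropy
#'   finite
#' @return list of class `em_config`
#' @export
em_config <- function(tol = 1e-4, max_iter = 200L, seed = 1L,
                      n_starts = 3L, eps_theta = 1e-6) {
  stopifnot(tol > 0, max_iter >= 1, n_starts >= 1, eps_theta > 0, eps_theta < 0.5)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), n_starts = as.integer(n_starts),
                 eps_theta = eps_theta), class = "em_config")
}

# Validate and normalise an observation table: one row per (read, site)
# usable observation, columns read (1..n_reads), site (1..n_sites),
# s in {0,1}, b >= 0.
check_obs <- function(obs, n_sites) {
  obs <- as.data.frame(obs)
  stopifnot(all(c("read", "site", "s", "b") %in% names(obs)))
  if (nrow(obs) == 0) stopf("no usable observations")
  if (n_sites < 1) stopf("n_sites must be >= 1")
  if (any(obs$site < 1 | obs$site > n_sites)) stopf("site index out of range")
  if (!all(obs$s %in% c(0, 1))) stopf("allele codes must be 0/1")
  if (any(obs$b < 0)) stopf("negative base quality")
  obs
}

#' Fit the two-haplotype emission model by EM
#'
#' E-step: posterior over the haplotype of each read, proportional to
#' `0.5 *` the read likelihood under each haplotype.  M-step: `theta[t, h]`
#' becomes the haplotype-posterior-weighted fraction of observations at `t`
#' whose latent base is alternate, where the latent-base responsibility
#' folds in the phred base quality.  Iterates until the observed-data
#' log-likelihood (haplotypes marginalised) improves by less than `tol`.
#'
#' Initialisation draws `theta` from Uniform(0.2, 0.8) under the configured
#' seed, anchoring the first site at (0.9, 0.1) to break the global
#' haplotype-label symmetry deterministically.  Multiple restarts keep the
#' best final log-likelihood.
#'
#' @param obs observation table: one row per usable (read, site)
#'   observation with columns `read` (integer, 1..n_reads), `site`
#'   (integer, 1..n_sites), `s` (0 = ref, 1 = alt), `b` (phred base
#'   quality)
#' @param n_sites number of heterozygous sites (rows of `theta`)
#' @param config an [em_config()]
#' @return list with `theta` (`n_sites x 2`; `NA` rows for sites covered by
#'   no read, flagged in `estimable`), `posterior` (`n_reads x 2`),
#'   `loglik_trace` (observed-data log-likelihood per iteration of the
#'   winning start), `loglik`, `n_iter`, `converged`, `estimable`
#' @export
em_fit <- function(obs, n_sites, config = em_config()) {
  obs <- check_obs(obs, n_sites)
  reads <- sort(unique(obs$read))
  n_reads <- max(reads)
  if (length(setdiff(seq_len(n_reads), reads)) > 0)
    stopf("read indices must be contiguous 1..n_reads (drop empty reads first)")

  site <- obs$site
  read <- obs$read
  eps  <- phred_to_prob(obs$b)
  psi1 <- ifelse(obs$s == 1, 1 - eps, eps)   # P(obs | g = alt)
  psi0 <- ifelse(obs$s == 0, 1 - eps, eps)   # P(obs | g = ref)
  estimable <- tabulate(site, n_sites) > 0L

  run_start <- function(start_seed, theta0 = NULL) {
    set.seed(start_seed)
    theta <- matrix(runif(2 * n_sites, 0.2, 0.8), n_sites, 2)
    t1 <- which(estimable)[1]
    theta[t1, ] <- c(0.9, 0.1)
    if (!is.null(theta0)) theta <- theta0
    trace <- numeric(0)
    post <- NULL
    prev <- -Inf
    converged <- FALSE
    for (it in seq_len(config$max_iter)) {
      # E-step
      p1 <- psi1 * theta[site, 1] + psi0 * (1 - theta[site, 1])
      p2 <- psi1 * theta[site, 2] + psi0 * (1 - theta[site, 2])
      l1 <- rowsum_vec(log(p1), read, n_reads)
      l2 <- rowsum_vec(log(p2), read, n_reads)
      m <- pmax(l1, l2)
      w1 <- exp(l1 - m); w2 <- exp(l2 - m)       # prior 0.5 cancels
      post <- cbind(w1, w2) / (w1 + w2)
      ll <- sum(log(0.5) + m + log(w1 + w2))     # observed-data loglik
      trace <- c(trace, ll)
      if (ll - prev < config$tol && it > 1) { converged <- TRUE; break }
      prev <- ll
      # M-step: responsibility of the alternate latent base per observation
      g1 <- psi1 * theta[site, 1] / p1
      g2 <- psi1 * theta[site, 2] / p2
      w1o <- post[read, 1]; w2o <- post[read, 2]
      th1 <- rowsum_vec(w1o * g1, site, n_sites) / rowsum_vec(w1o, site, n_sites)
      th2 <- rowsum_vec(w2o * g2, site, n_sites) / rowsum_vec(w2o, site, n_sites)
      theta <- cbind(th1, th2)
      theta[!is.finite(theta)] <- 0.5
      theta <- pmin(pmax(theta, config$eps_theta), 1 - config$eps_theta)
    }
    list(theta = theta, posterior = post, loglik_trace = trace,
         loglik = trace[length(trace)], n_iter = length(trace),
         converged = converged)
  }

  # start 1: greedy read-linkage initialisation (avoids the label-domain
  # flips a random start develops on long site chains); remaining starts:
  # random, anchored at the first site
  fits <- c(
    list(run_start(config$seed, linkage_theta_init(obs, n_sites))),
    lapply(seq_len(config$n_starts - 1L),
           function(k) run_start(config$seed + k)))
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  best$theta[!estimable, ] <- NA_real_
  dimnames(best$theta) <- list(NULL, c("hap1", "hap2"))
  dimnames(best$posterior) <- list(NULL, c("hap1", "hap2"))
  best$estimable <- estimable
  best
}

# Greedy chain initialisation of theta: every pair of sites co-observed
# on a read votes on whether their alternate alleles ride the same
# haplotype (allele codes agree) or opposite ones.  Sites are then phased
# left to right, each taking the relative phase of its strongest link
# (largest absolute net vote) to an earlier site.  Using all within-read
# pairs, not just adjacent sites, means a false variant interleaved among
# true hets — whose votes are noise centred on zero — cannot become the
# only bridge and flip the downstream chain.  The resulting +1/-1 phases
# seed theta at 0.85/0.15, which EM refines.
linkage_theta_init <- function(obs, n_sites) {
  dt <- data.table::data.table(read = obs$read, site = obs$site, s = obs$s)
  pr <- dt[dt, on = "read", allow.cartesian = TRUE]
  pr <- pr[pr$site < pr$i.site]
  phase <- rep(1L, n_sites)
  if (nrow(pr) > 0) {
    pr$vote <- 2L * (pr$s == pr$i.s) - 1L
    agg <- pr[, list(w = sum(vote)), by = list(t1 = site, t2 = i.site)]
    agg <- agg[order(agg$t2, -abs(agg$w), agg$t1)]
    agg <- agg[!duplicated(agg$t2)]         # strongest link per target
    link <- rep(NA_integer_, n_sites)
    wlink <- integer(n_sites)
    link[agg$t2] <- agg$t1
    wlink[agg$t2] <- agg$w
    for (tt in seq_len(n_sites)) {
      if (!is.na(link[tt]))
        phase[tt] <- if (wlink[tt] >= 0) phase[link[tt]] else -phase[link[tt]]
    }
  }
  th1 <- ifelse(phase > 0, 0.85, 0.15)
  cbind(th1, 1 - th1)
}

# rowsum into a dense vector indexed 1..n (groups absent -> 0)
rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

#' Phase entropy of a site
#'
#' `-log10(theta1 * theta2 * (1 - theta1) * (1 - theta2))`.  High values
#' mean clean haplotype separation (theta near 0 on one haplotype and near
#' 1 on the other); a false variant, whose alternate observations are
#' independent of haplotype, drives both thetas towards 0.5 and the score
#' towards its minimum `log10(16) ~ 1.204`.
#'
#' @param theta1,theta2 per-haplotype alternate-allele emission
#'   probabilities (vectorised)
#' @param eps_theta clamp applied before taking logs so the result is finite
#' @return phase entropy, `>= log10(16)` up to the clamp
#' @export
phase_entropy <- function(theta1, theta2, eps_theta = 1e-6) {
  t1 <- pmin(pmax(theta1, eps_theta), 1 - eps_theta)
  t2 <- pmin(pmax(theta2, eps_theta), 1 - eps_theta)
  -log10(t1 * t2 * (1 - t1) * (1 - t2))
}

#' Per-haplotype strand bias counts
#'
#' Hard-assigns each read to its maximum-posterior haplotype (ties go to
#' haplotype 1) and counts forward-strand reads per haplotype.
#'
#' @param strand character vector, `"+"`/`"-"` per read
#' @param posterior `n_reads x 2` haplotype posterior matrix
#' @return list with `sb1`, `sb2` (forward-strand read counts), `n1`, `n2`
#'   (total reads per haplotype) and `hap` (the hard assignments)
#' @export
haplotype_strand_bias <- function(strand, posterior) {
  stopifnot(length(strand) == nrow(posterior))
  hap <- ifelse(posterior[, 1] >= posterior[, 2], 1L, 2L)
  fwd <- strand == "+"
  list(sb1 = sum(fwd & hap == 1L), sb2 = sum(fwd & hap == 2L),
       n1 = sum(hap == 1L), n2 = sum(hap == 2L), hap = hap)
}

#' Partition heterozygous sites into phase sets
#'
#' Sites are nodes; a read spanning two or more sites connects them.  Phase
#' sets are the connected components; a site spanned by no multi-site read
#' is its own singleton set (its relative phase is undetermined).
#'
#' @param obs observation table as in [em_fit()]
#' @param n_sites number of heterozygous sites
#' @return integer vector of length `n_sites`: phase-set id per site,
#'   numbered by first site in the set
#' @export
build_phase_sets <- function(obs, n_sites) {
  obs <- as.data.frame(obs)
  edges <- integer(0)
  if (nrow(obs) > 0) {
    sp <- split(obs$site, obs$read)
    sp <- lapply(sp, function(u) sort(unique(u)))
    sp <- sp[lengths(sp) >= 2]
    if (length(sp) > 0) {
      # consecutive pairs are enough for connectivity
      edges <- unlist(lapply(sp, function(u) rbind(u[-length(u)], u[-1])))
    }
  }
  g <- igraph::make_empty_graph(n = n_sites, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  # renumber by first appearance along the genome
  match(memb, unique(memb))
}

#' Phase heterozygous sites from read observations
#'
#' Runs the full phasing stack on an observation table: phase-set
#' construction, independent EM fits per multi-site phase set, and the
#' derived quality metrics.  Singleton phase sets (no read links the site
#' to another heterozygous site) cannot be phased and get `NA` metrics;
#' downstream filters pass them through rather than treating missing
#' evidence as bad phasing.
#'
#' @param obs observation table with columns `read`, `site`, `s`, `b` and a
#'   per-read strand (column `strand`, `"+"`/`"-"`)
#' @param n_sites number of heterozygous sites
#' @param config an [em_config()]
#' @param refine_below_pe optional phase-entropy threshold: if set, sites
#'   whose first-pass PE falls below it are dropped and the affected phase
#'   sets are refitted once (mitigates false variants distorting the phase
#'   of their neighbours); dropped sites keep their first-pass metrics
#' @return list with `sites` (data.frame: site, phase_set, theta1, theta2,
#'   pe, hap_of_alt, n_reads_hap1, n_reads_hap2, sb1, sb2), `read_hap`
#'   (hard assignment per input read index, `NA` for unphased reads) and
#'   `n_reads_dropped` (reads with no usable observation)
#' @export
phase_reads <- function(obs, n_sites, config = em_config(),
                        refine_below_pe = NULL) {
  obs <- as.data.frame(obs)
  if (!"strand" %in% names(obs)) obs$strand <- "+"
  obs <- check_obs(obs, n_sites)
  ps <- build_phase_sets(obs, n_sites)

  res <- data.frame(site = seq_len(n_sites), phase_set = ps,
                    theta1 = NA_real_, theta2 = NA_real_, pe = NA_real_,
                    hap_of_alt = NA_integer_,
                    n_reads_hap1 = 0L, n_reads_hap2 = 0L,
                    sb1 = NA_integer_, sb2 = NA_integer_)
  read_hap <- rep(NA_integer_, max(obs$read))

  fit_set <- function(set_id, sub) {
    sites_in <- sort(unique(res$site[res$phase_set == set_id]))
    loc_site <- match(sub$site, sites_in)
    reads_in <- sort(unique(sub$read))
    loc_read <- match(sub$read, reads_in)
    loc <- data.frame(read = loc_read, site = loc_site, s = sub$s, b = sub$b)
    fit <- em_fit(loc, length(sites_in),
                  em_config(tol = config$tol, max_iter = config$max_iter,
                            seed = config$seed + set_id,
                            n_starts = config$n_starts,
                            eps_theta = config$eps_theta))
    # per-read strand in the order of reads_in
    strand_r <- vapply(seq_along(reads_in),
                       function(i) sub$strand[loc_read == i][1], character(1))
    sb <- haplotype_strand_bias(strand_r, fit$posterior)
    list(sites_in = sites_in, reads_in = reads_in, fit = fit, sb = sb,
         loc = loc)
  }

  apply_fit <- function(f) {
    th <- f$fit$theta
    pe <- phase_entropy(th[, 1], th[, 2], config$eps_theta)
    idx <- f$sites_in
    res$theta1[idx] <<- th[, 1]
    res$theta2[idx] <<- th[, 2]
    res$pe[idx] <<- pe
    res$hap_of_alt[idx] <<- ifelse(is.na(th[, 1]), NA_integer_,
                                   ifelse(th[, 1] >= th[, 2], 1L, 2L))
    res$sb1[idx] <<- f$sb$sb1
    res$sb2[idx] <<- f$sb$sb2
    hap_per_obs <- f$sb$hap[f$loc$read]
    n1 <- rowsum_vec(as.numeric(hap_per_obs == 1L), f$loc$site, length(idx))
    n2 <- rowsum_vec(as.numeric(hap_per_obs == 2L), f$loc$site, length(idx))
    res$n_reads_hap1[idx] <<- as.integer(n1)
    res$n_reads_hap2[idx] <<- as.integer(n2)
    read_hap[f$reads_in] <<- f$sb$hap
  }

  multi <- names(which(table(ps) >= 2))
  for (set_id in as.integer(multi)) {
    sub <- obs[ps[obs$site] == set_id, , drop = FALSE]
    apply_fit(fit_set(set_id, sub))
  }

  if (!is.null(refine_below_pe)) {
    bad <- which(!is.na(res$pe) & res$pe < refine_below_pe)
    if (length(bad) > 0) {
      keep_obs <- obs[!(obs$site %in% bad), , drop = FALSE]
      affected <- unique(res$phase_set[bad])
      for (set_id in affected) {
        sub <- keep_obs[ps[keep_obs$site] == set_id, , drop = FALSE]
        if (length(unique(sub$site)) >= 2 && nrow(sub) > 0)
          apply_fit(fit_set(set_id, sub))
      }
    }
  }

  n_total_reads <- max(obs$read)
  list(sites = res, read_hap = read_hap,
       n_reads_dropped = n_total_reads - length(unique(obs$read)))
}
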