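# Independent oracles, deliberately naive: enumeration and 1-D numeric
# maximisation only, sharing no code with the implementation under test.

# complete-data log-likelihood of an assignment with theta profiled out:
# per (site, haplotype), maximise the product of the observation mixtures
# over theta in the clamped range by golden-section search
oracle_profile_loglik <- function(obs, assignment, eps_theta = 1e-6) {
  ll <- sum(log(0.5) * length(unique(obs$read)))
  for (t in sort(unique(obs$site))) {
    for (h in 1:2) {
      sub <- obs[obs$site == t & assignment[obs$read] == h, , drop = FALSE]
      if (nrow(sub) == 0) next
      eps <- 10^(-sub$b / 10)
      psi1 <- ifelse(sub$s == 1, 1 - eps, eps)
      psi0 <- ifelse(sub$s == 0, 1 - eps, eps)
      f <- function(th) sum(log(psi1 * th + psi0 * (1 - th)))
      opt <- optimize(f, c(eps_theta, 1 - eps_theta), maximum = TRUE,
                      tol = 1e-10)
      ll <- ll + opt$objective
    }
  }
  ll
}

# maximum profiled complete-data log-likelihood over all 2^n_reads
# haplotype assignments
oracle_best_assignment <- function(obs, n_reads) {
  best <- -Inf
  for (mask in 0:(2^n_reads - 1)) {
    a <- as.integer(intToBits(mask))[seq_len(n_reads)] + 1L
    ll <- oracle_profile_loglik(obs, a)
    if (ll > best) best <- ll
  }
  best
}

# likelihood of one read's observations by exhaustive enumeration of the
# latent base vector
oracle_read_likelihood <- function(read, h, theta) {
  J <- length(read$u)
  total <- 0
  for (mask in 0:(2^J - 1)) {
    g <- as.integer(intToBits(mask))[seq_len(J)]
    eps <- 10^(-read$b / 10)
    p_obs <- ifelse(read$s == g, 1 - eps, eps)
    p_g <- ifelse(g == 1, theta[read$u, h], 1 - theta[read$u, h])
    total <- total + prod(p_obs * p_g)
  }
  total
}

# naive double-loop call classifier with genotype-mismatch double counting
oracle_classify <- function(calls, truth) {
  tp <- fp <- fn <- 0
  for (i in seq_len(nrow(calls))) {
    j <- which(truth$chrom == calls$chrom[i] & truth$pos == calls$pos[i])
    if (length(j) == 0) fp <- fp + 1
    else if (truth$genotype[j] == calls$genotype[i]) tp <- tp + 1
    else fp <- fp + 1
  }
  for (j in seq_len(nrow(truth))) {
    i <- which(calls$chrom == truth$chrom[j] & calls$pos == truth$pos[j])
    if (length(i) == 0) fn <- fn + 1
    else if (calls$genotype[i] != truth$genotype[j]) fn <- fn + 1
  }
  list(tp = tp, fp = fp, fn = fn)
}
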