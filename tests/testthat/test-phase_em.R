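test_that("psi follows the phred error model", {
  expect_equal(psi(1, 1, 10), 0.9)
  expect_equal(psi(1, 0, 20), 0.01)
  expect_equal(psi(0, 0, 3), 1 - 10^-0.3, tolerance = 1e-12)
  expect_equal(psi(0, 0, 3), 0.4988, tolerance = 1e-4)
  # match + mismatch probabilities partition the two allele codes
  for (b in c(3, 10, 30)) expect_equal(psi(1, 1, b) + psi(0, 1, b), 1)
  expect_error(psi(1, 1, -5), "negative")
  expect_error(psi(2, 1, 10), "allele codes")
})

test_that("read_hap_likelihood collapses and mixes correctly", {
  theta <- matrix(c(1, 0.5, 0, 0.5), 2, 2)   # site1: (1,0); site2: (0.5,0.5)
  r <- list(u = 1L, s = 1L, b = 10)
  expect_equal(read_hap_likelihood(r, 1, theta), 0.9)
  r2 <- list(u = 2L, s = 1L, b = 7)
  expect_equal(read_hap_likelihood(r2, 1, theta), 0.5)  # theta = 0.5 symmetry
  expect_equal(read_hap_likelihood(r2, 2, theta), 0.5)
  expect_error(read_hap_likelihood(list(u = integer(0), s = integer(0),
                                        b = numeric(0)), 1, theta),
               "zero usable")
})

test_that("read_hap_likelihood equals exhaustive latent-base enumeration", {
  set.seed(11)
  for (k in 1:20) {
    theta <- matrix(runif(6, 0.05, 0.95), 3, 2)
    read <- list(u = 1:3, s = sample(0:1, 3, replace = TRUE),
                 b = sample(5:30, 3))
    for (h in 1:2)
      expect_equal(read_hap_likelihood(read, h, theta),
                   oracle_read_likelihood(read, h, theta), tolerance = 1e-12)
  }
})

test_that("complete_data_loglik composes per-read terms with one 0.5 each", {
  theta <- matrix(c(1, 1e-6), 1, 2)
  expect_equal(complete_data_loglik(list(), integer(0), theta), 0)
  r <- list(u = 1L, s = 1L, b = 10)
  expect_equal(complete_data_loglik(list(r), 1L, theta), log(0.5 * 0.9))
  set.seed(2)
  theta <- matrix(runif(8, .1, .9), 4, 2)
  reads <- lapply(1:5, function(i)
    list(u = sort(sample(1:4, 2)), s = sample(0:1, 2, TRUE), b = c(10, 20)))
  a <- sample(1:2, 5, TRUE)
  expect_equal(complete_data_loglik(reads, a, theta),
               sum(vapply(1:5, function(i)
                 log(0.5) + log(read_hap_likelihood(reads[[i]], a[i], theta)),
                 numeric(1))))
})

test_that("em_fit recovers a noiseless partition up to label swap", {
  obs <- make_diploid_obs(n_sites = 10, reads_per_hap = 10, b = 40, seed = 5)
  fit <- em_fit(obs, 10, em_config(seed = 1))
  hap_true <- attr(obs, "read_hap")
  hap_est <- ifelse(fit$posterior[, 1] >= 0.5, 1L, 2L)
  agreement <- mean(hap_est == hap_true)
  expect_true(agreement %in% c(0, 1))   # exact up to global swap
  # theta within 0.01 of the 0/1 truth
  alt_on <- attr(obs, "hap_of_alt")
  est_hap1_is_true1 <- agreement == 1
  th_alt <- ifelse(alt_on == (if (est_hap1_is_true1) 1 else 2),
                   fit$theta[, 1], fit$theta[, 2])
  th_ref <- ifelse(alt_on == (if (est_hap1_is_true1) 1 else 2),
                   fit$theta[, 2], fit$theta[, 1])
  expect_true(all(th_alt > 0.99) && all(th_ref < 0.01))
})

test_that("em_fit is symmetric when reads are identical on both haplotypes", {
  obs <- data.frame(read = rep(1:20, each = 4), site = rep(1:4, 20),
                    s = rep(c(1L, 0L, 1L, 0L), 20), b = 15)
  fit <- em_fit(obs, 4, em_config(seed = 2))
  expect_equal(fit$theta[, 1], fit$theta[, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("em_fit observed-data log-likelihood is monotone and deterministic", {
  obs <- make_diploid_obs(n_sites = 6, reads_per_hap = 8, b = 10, seed = 9)
  f1 <- em_fit(obs, 6, em_config(seed = 7))
  f2 <- em_fit(obs, 6, em_config(seed = 7))
  expect_identical(f1$theta, f2$theta)
  expect_true(all(diff(f1$loglik_trace) >= -1e-9))
})

test_that("em_fit flags sites covered by no read and rejects empty input", {
  obs <- data.frame(read = c(1, 1, 2, 2), site = c(1, 3, 1, 3),
                    s = c(1, 0, 0, 1), b = 20)
  fit <- em_fit(obs, 3, em_config(seed = 1))
  expect_false(fit$estimable[2])
  expect_true(all(is.na(fit$theta[2, ])))
  expect_error(em_fit(obs[0, ], 3), "no usable")
  expect_error(em_fit(obs, 0), "n_sites")
})

test_that("phase_entropy matches direct evaluation and the clamp", {
  expect_equal(phase_entropy(0.5, 0.5), log10(16), tolerance = 1e-12)
  expect_equal(phase_entropy(0.99, 0.01), -log10(0.99 * 0.01 * 0.01 * 0.99),
               tolerance = 1e-12)
  expect_equal(phase_entropy(0, 1), 12, tolerance = 1e-3)
})

test_that("haplotype_strand_bias counts forward reads with tie to hap 1", {
  post <- rbind(matrix(c(0.9, 0.1), 10, 2, byrow = TRUE),
                matrix(c(0.2, 0.8), 5, 2, byrow = TRUE))
  strand <- c(rep("+", 5), rep("-", 5), rep("+", 5))
  sb <- haplotype_strand_bias(strand, post)
  expect_equal(sb$sb1, 5)
  expect_equal(sb$sb2, 5)
  expect_equal(sb$n1, 10)
  all_rev <- haplotype_strand_bias(rep("-", 15), post)
  expect_equal(c(all_rev$sb1, all_rev$sb2), c(0, 0))
  tie <- haplotype_strand_bias("+", matrix(c(0.5, 0.5), 1))
  expect_equal(tie$hap, 1L)
})

test_that("build_phase_sets forms transitive components and singletons", {
  obs <- data.frame(read = c(1, 1, 2, 2), site = c(1, 2, 2, 3),
                    s = 0, b = 20)
  expect_equal(build_phase_sets(obs, 3), c(1L, 1L, 1L))
  obs1 <- data.frame(read = 1:3, site = 1:3, s = 0, b = 20)
  expect_equal(build_phase_sets(obs1, 3), 1:3)
  obs2 <- data.frame(read = c(1, 1, 2, 2), site = c(1, 2, 3, 4), s = 0, b = 20)
  expect_equal(build_phase_sets(obs2, 4), c(1L, 1L, 2L, 2L))
})

test_that("EM matches brute-force assignment maximisation on small instances", {
  fails <- 0
  for (seed in 1:50) {
    n_reads <- 6
    obs <- make_diploid_obs(n_sites = 4, reads_per_hap = 3, b = 13,
                            seed = 100 + seed)
    fit <- em_fit(obs, 4, em_config(seed = seed))
    hard <- ifelse(fit$posterior[, 1] >= 0.5, 1L, 2L)
    ll_em <- oracle_profile_loglik(obs, hard)
    ll_best <- oracle_best_assignment(obs, n_reads)
    if (ll_best - ll_em > 1e-6) fails <- fails + 1
  }
  expect_equal(fails, 0)
})

test_that("swap invariance: relabelling haplotypes leaves PE and loglik alone", {
  obs <- make_diploid_obs(n_sites = 5, reads_per_hap = 6, b = 13, seed = 21)
  fit <- em_fit(obs, 5, em_config(seed = 3))
  th_sw <- fit$theta[, c(2, 1)]
  expect_equal(phase_entropy(fit$theta[, 1], fit$theta[, 2]),
               phase_entropy(th_sw[, 1], th_sw[, 2]))
  reads <- lapply(split(obs, obs$read), function(d)
    list(u = d$site, s = d$s, b = d$b))
  a <- ifelse(fit$posterior[, 1] >= 0.5, 1L, 2L)
  expect_equal(complete_data_loglik(reads, a, fit$theta),
               complete_data_loglik(reads, 3L - a, th_sw))
})

test_that("false variants get low PE, true hets high PE", {
  obs <- make_diploid_obs(n_sites = 11, reads_per_hap = 15, b = 13, seed = 31)
  obs <- inject_false_het(obs, site = 6, frac = 0.5)
  ph <- phase_reads(obs, 11, em_config(seed = 4))
  pe <- ph$sites$pe
  expect_lt(pe[6], min(pe[-6]))
  expect_lt(pe[6], 2)          # below the default bad-phasing threshold
  expect_gt(min(pe[-6]), 2)    # true hets all above it
})
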