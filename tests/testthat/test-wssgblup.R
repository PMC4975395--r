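# full-rank centered genotypes (external allele frequencies) for identity checks
full_rank_cg <- function(n, m, seed) {
  set.seed(seed)
  rd <- random_dosages(n, m)
  center_and_lambda(make_geno(rd$dos), p = rd$p)
}

test_that("back-solved SNP effects reproduce the breeding values exactly", {
  cg <- full_rank_cg(5, 8, seed = 41)
  G <- build_G(cg)
  a_g <- rnorm(5)
  u <- backsolve_snp_effects(cg, rep(1, 8), G, a_g)
  # algebraic identity: Z u = Z lambda D Z' G^-1 a = G G^-1 a = a
  expect_lt(max(abs(as.numeric(cg$Z %*% u) - a_g)), 1e-10)
  expect_equal(backsolve_snp_effects(cg, rep(1, 8), G, rep(0, 5)), rep(0, 8))
})

test_that("back-solve matches explicit matrix arithmetic on a 2x2 instance", {
  # hand-built: 2 animals, 2 SNPs, external p = (0.5, 0.25)
  dos <- rbind(c(2, 1), c(0, 1))
  rownames(dos) <- c("a1", "a2"); colnames(dos) <- c("s1", "s2")
  cg <- center_and_lambda(make_geno(dos), p = c(0.5, 0.25))
  # oracle recomputed from first principles
  Z <- dos - rep(1, 2) %o% c(1, 0.5)
  lam <- 1 / (2 * 0.5 * 0.5 + 2 * 0.25 * 0.75)
  d <- c(1.3, 0.7)
  G <- Z %*% diag(d) %*% t(Z) * lam
  a_g <- c(0.8, -0.3)
  u_oracle <- as.numeric(lam * diag(d) %*% t(Z) %*% solve(G, a_g))
  expect_equal(backsolve_snp_effects(cg, d, build_G(cg, d), a_g), u_oracle,
               tolerance = 1e-12)
})

test_that("weight updates and trace normalization follow the iteration rules", {
  expect_equal(update_weights(0, 0.3), 0)
  expect_equal(update_weights(1, 0.5), 0.5)
  expect_equal(update_weights(2, 0.1), 0.72)
  expect_equal(normalize_weights(c(3, 1)), c(1.5, 0.5))
  expect_equal(normalize_weights(rep(0.37, 6)), rep(1, 6))
  set.seed(42)
  for (i in 1:5) {
    w <- runif(sample(5:50, 1), 0, 2)
    expect_equal(sum(normalize_weights(w)), length(w), tolerance = 1e-10)
  }
  expect_error(normalize_weights(rep(0, 4)), "zero")
})

test_that("window variances decompose the genomic score per window", {
  cg <- full_rank_cg(40, 60, seed = 43)
  cg$map$chrom <- rep(1:2, each = 30)
  cg$map$bp <- rep(seq(1e5, 3e6, length.out = 30), 2)

  # zero effects give zero percentages everywhere
  w0 <- window_variances(rep(0, 60), cg, window_size = 10, sigma2_a = 1)
  expect_true(all(w0$percent_variance == 0))
  expect_equal(nrow(w0), 6)

  # a single nonzero effect: only its window is nonzero, and the percentage
  # equals the directly computed score variance
  u <- rep(0, 60); u[37] <- 0.8
  w1 <- window_variances(u, cg, window_size = 10, sigma2_a = 0.5)
  nz <- which(w1$percent_variance > 0)
  expect_equal(length(nz), 1)
  expect_equal(w1$chrom[nz], 2)
  expect_equal(w1$percent_variance[nz],
               100 * var(cg$Z[, 37] * 0.8) / 0.5)
  # bp span is (bp of first member, bp of last member)
  expect_equal(w1$start_bp[nz], cg$map$bp[31])
  expect_equal(w1$end_bp[nz], cg$map$bp[40])

  # sum over windows equals the per-window aggregate recomputed directly
  set.seed(44)
  u2 <- rnorm(60, 0, 0.1)
  w2 <- window_variances(u2, cg, window_size = 10, sigma2_a = 0.5)
  direct <- sum(vapply(split(seq_len(60), rep(1:6, each = 10)), function(ix)
    var(as.numeric(cg$Z[, ix] %*% u2[ix])), numeric(1)))
  expect_equal(sum(w2$percent_variance), 100 * direct / 0.5, tolerance = 1e-10)

  # terminal windows shorter than the window size are kept
  w3 <- window_variances(u2, cg, window_size = 25, sigma2_a = 0.5)
  expect_equal(w3$n_snps, c(25, 5, 25, 5))
})

test_that("top windows rank by percentage with positional tie-breaks", {
  rep0 <- data.frame(chrom = c(1, 1, 2, 2), window = c(1, 2, 1, 2),
                     first_snp = 1:4, last_snp = 1:4,
                     start_bp = c(100, 900, 50, 800), end_bp = c(899, 1800, 799, 1600),
                     n_snps = 10, percent_variance = c(2, 5, 5, 1))
  class(rep0) <- c("window_report", "data.frame")
  t1 <- top_windows(rep0, 1)
  expect_equal(t1$start_bp, 900)          # ties go to lower (chrom, bp)... unique max first
  t2 <- top_windows(rep0, 2)
  expect_equal(t2$percent_variance, c(5, 5))
  expect_equal(t2$chrom, c(1, 2))         # tie at 5%: chromosome 1 first
  expect_equal(attr(t2, "total_percent"), 10)

  all_equal <- rep0; all_equal$percent_variance <- 3
  t3 <- top_windows(all_equal, 3)
  expect_equal(t3$chrom, c(1, 1, 2))
  expect_equal(t3$start_bp, c(100, 900, 50))

  expect_warning(t4 <- top_windows(rep0, 10), "exceeds")
  expect_equal(nrow(t4), 4)
  expect_equal(attr(t4, "total_percent"), sum(rep0$percent_variance))
})

test_that("the iterative fit keeps the trace, reuses breeding values, and
           starts unweighted", {
  cfg <- sim_config(n_founders = 40, n_generations = 2,
                    matings_per_generation = 30, offspring_per_mating = 2,
                    n_chromosomes = 2, snps_per_chromosome = 60,
                    n_qtl = 2, qtl_variance_fractions = 0.2, h2 = 0.41,
                    n_cg = 4, genotyped_fraction = 1, seed = 45)
  sim <- simulate_dataset(cfg)
  gsub <- sim$genotypes
  gsub$dosages <- gsub$dosages[as.character(sim$genotyped_ids), ]
  fit <- wssgblup(sim$pheno, sim$pedigree, gsub, trait_type = "continuous",
                  h2 = 0.41, window_size = 20, n_iterations = 3, top_k = 6)
  m <- ncol(fit$centered$Z)
  # iteration 1 is the unweighted back-solve
  expect_equal(fit$iterations[[1]]$d, rep(1, m))
  # trace conservation at every iteration
  for (it in fit$iterations)
    expect_equal(sum(it$d), m, tolerance = 1e-8)
  # u at iteration 1 equals a one-shot unweighted back-solve
  cg <- fit$centered
  G1 <- blend_G(build_G(cg), extract_A22(build_A(sort_pedigree(sim$pedigree)),
                                         rownames(gsub$dosages)), 0.05)
  a_g <- unname(predict(fit, "genotyped"))
  expect_equal(fit$iterations[[1]]$u_hat,
               backsolve_snp_effects(cg, rep(1, m), G1, a_g),
               tolerance = 1e-10)
  # S3 surface
  expect_s3_class(fit, "wssgblup")
  expect_output(print(fit), "Weighted single-step")
  co <- coef(fit)
  expect_equal(nrow(co), m)
  expect_equal(co$iteration[1], 2)
  expect_equal(length(residuals(fit)), nrow(sim$pheno))
  expect_equal(nrow(fit$top), 6)
})

test_that("a planted major QTL gains weight between iterations 1 and 2", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_founders = 150, n_generations = 2,
                      matings_per_generation = 120, offspring_per_mating = 2,
                      n_chromosomes = 2, snps_per_chromosome = 250,
                      n_qtl = 1, qtl_variance_fractions = 0.30, h2 = 0.41,
                      n_cg = 5, genotyped_fraction = 1, seed = 500 + s)
    sim <- simulate_dataset(cfg)
    gsub <- sim$genotypes
    gsub$dosages <- gsub$dosages[as.character(sim$genotyped_ids), ]
    fit <- wssgblup(sim$pheno, sim$pedigree, gsub, trait_type = "continuous",
                    h2 = 0.41, window_size = 100, n_iterations = 2,
                    report_iteration = 2, top_k = 5)
    q <- sim$truth$qtl_snp_indices
    fit$iterations[[2]]$d[q] > fit$iterations[[1]]$d[q]
  }, logical(1))
  expect_gte(sum(hits), 9)
})
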