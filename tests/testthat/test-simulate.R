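test_that("pedigree structure follows the mating design", {
  # no matings possible
  p0 <- simulate_pedigree(sim_config(n_founders = 10, n_generations = 0, seed = 1))
  expect_equal(nrow(p0), 10)
  expect_true(all(p0$sire == 0 & p0$dam == 0))

  # 20 founders + 2 generations of 5 matings x 2 offspring = 40 animals
  cfg <- sim_config(n_founders = 20, n_generations = 2,
                    matings_per_generation = 5, offspring_per_mating = 2,
                    seed = 2)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 40)
  expect_equal(as.integer(table(ped$generation)), c(20L, 10L, 10L))
  # parents precede offspring in record order
  pos <- match(ped$animal, ped$animal)
  for (i in which(ped$sire != 0))
    expect_lt(match(ped$sire[i], ped$animal), i)
  for (i in which(ped$dam != 0))
    expect_lt(match(ped$dam[i], ped$animal), i)
})

test_that("invalid configurations are rejected with the field name", {
  expect_error(sim_config(h2 = 1.2), "h2")
  expect_error(sim_config(founder_maf_range = c(0, 0.5)), "founder_maf_range")
  expect_error(sim_config(n_qtl = 2, qtl_variance_fractions = c(0.6, 0.6)),
               "qtl_variance_fractions")
  expect_error(sim_config(liability_threshold_prevalence = 0),
               "liability_threshold_prevalence")
})

test_that("full sibs from one mating have pedigree relationship 0.5", {
  cfg <- sim_config(n_founders = 4, n_generations = 1,
                    matings_per_generation = 1, offspring_per_mating = 2,
                    seed = 3)
  ped <- simulate_pedigree(cfg)
  A <- build_A(ped)
  sibs <- ped$animal[ped$generation == 1]
  expect_equal(A[sibs[1], sibs[2]], 0.5)
})

test_that("gene dropping transmits one allele from each parent", {
  cfg <- sim_config(n_founders = 8, n_generations = 2,
                    matings_per_generation = 6, offspring_per_mating = 2,
                    n_chromosomes = 2, snps_per_chromosome = 30, seed = 4)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  dos <- gen$dosages
  pos <- match(ped$animal, ped$animal)
  for (i in which(ped$sire != 0)) {
    s <- dos[match(ped$sire[i], ped$animal), ]
    d <- dos[match(ped$dam[i], ped$animal), ]
    k <- dos[i, ]
    # a parent contributes 1 iff homozygous alt, 0 iff homozygous ref
    lo <- (s == 2) + (d == 2)
    hi <- (s > 0) + (d > 0)
    expect_true(all(k >= lo & k <= hi))
  }
  # two 0-coded parents can only produce a 0-coded offspring (checked above
  # via the bounds: lo = hi = 0)
  expect_true(all(diff(gen$map$bp[gen$map$chrom == 1]) > 0))
})

test_that("founder genotypes are in Hardy-Weinberg proportions", {
  cfg <- sim_config(n_founders = 4000, n_generations = 0,
                    n_chromosomes = 1, snps_per_chromosome = 1,
                    founder_maf_range = c(0.5, 0.5), seed = 5)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  freq <- tabulate(gen$dosages[, 1] + 1L, 3L) / 4000
  expect_equal(unname(freq), c(0.25, 0.5, 0.25), tolerance = 0.05)
})

test_that("linkage disequilibrium decays with genetic distance", {
  r2 <- function(x, y) suppressWarnings(cor(x, y))^2
  adj <- far <- numeric(0)
  for (s in 1:10) {
    cfg <- sim_config(n_founders = 60, n_generations = 3,
                      matings_per_generation = 40, offspring_per_mating = 2,
                      n_chromosomes = 1, snps_per_chromosome = 40,
                      morgans_per_chromosome = 1, seed = 100 + s)
    ped <- simulate_pedigree(cfg)
    gen <- simulate_genotypes(ped, cfg)
    last <- gen$dosages[ped$generation == max(ped$generation), ]
    keep <- apply(last, 2, var) > 0
    last <- last[, keep]
    m <- ncol(last)
    adj <- c(adj, mean(vapply(seq_len(m - 1),
                              function(j) r2(last[, j], last[, j + 1]), 0),
                       na.rm = TRUE))
    far <- c(far, mean(vapply(seq_len(m - 20),
                              function(j) r2(last[, j], last[, j + 20]), 0),
                       na.rm = TRUE))
  }
  expect_gt(mean(adj), mean(far))
})

test_that("phenotype model has unit slope on true breeding values and the
           configured heritability", {
  # slope of phenotype on TBV ~ 1 under the additive model
  cfg <- sim_config(n_founders = 2500, n_generations = 1,
                    matings_per_generation = 1250, offspring_per_mating = 2,
                    n_chromosomes = 1, snps_per_chromosome = 10,
                    n_qtl = 2, qtl_variance_fractions = 0.15,
                    h2 = 0.41, n_cg = 40, seed = 6)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(ped, gen, config = cfg)
  tbv <- ph$truth$tbv[as.character(ph$pheno$animal)]
  adj <- ph$pheno$trait - ph$truth$cg_effects[ph$truth$cg] -
    cfg$age_slope * (ph$pheno$age - 355)
  expect_equal(unname(coef(lm(adj ~ tbv))[2]), 1, tolerance = 0.05)

  # empirical heritability within 0.05 of the configured value (5 seeds)
  h2_emp <- vapply(1:5, function(s) {
    cfg <- sim_config(n_founders = 2000, n_generations = 1,
                      matings_per_generation = 1500, offspring_per_mating = 1,
                      n_chromosomes = 1, snps_per_chromosome = 8,
                      n_qtl = 2, qtl_variance_fractions = 0.15,
                      h2 = 0.41, n_cg = 30, seed = 200 + s)
    ped <- simulate_pedigree(cfg)
    gen <- simulate_genotypes(ped, cfg)
    ph <- simulate_phenotypes(ped, gen, config = cfg)
    tbv <- ph$truth$tbv[as.character(ph$pheno$animal)]
    adj <- ph$pheno$trait - ph$truth$cg_effects[ph$truth$cg] -
      cfg$age_slope * (ph$pheno$age - 355)
    var(tbv) / var(adj)
  }, numeric(1))
  expect_equal(mean(h2_emp), 0.41, tolerance = 0.05)
})

test_that("h2 = 0 leaves no genetic signal in the phenotype", {
  cfg <- sim_config(n_founders = 500, n_generations = 1,
                    matings_per_generation = 250, offspring_per_mating = 2,
                    n_chromosomes = 1, snps_per_chromosome = 5,
                    n_qtl = 0, h2 = 0, seed = 7)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(ped, gen, config = cfg)
  # with zero heritability the breeding values are identically zero, so the
  # genetic-phenotypic correlation is zero by construction
  expect_equal(unname(var(ph$truth$tbv)), 0)
})

test_that("binary liability trait reproduces the target prevalence", {
  cfg <- sim_config(n_founders = 5000, n_generations = 1,
                    matings_per_generation = 2500, offspring_per_mating = 2,
                    n_chromosomes = 1, snps_per_chromosome = 5,
                    n_qtl = 0, h2 = 0.30, trait_type = "binary_liability",
                    liability_threshold_prevalence = 0.186,
                    n_cg = 100, cg_sd = 0.3, seed = 8)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(ped, gen, config = cfg)
  expect_equal(mean(ph$pheno$trait), 0.186, tolerance = 0.02)
})

test_that("the simulator is deterministic in its seed", {
  cfg <- sim_config(seed = 99)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  expect_identical(s1$pheno, s2$pheno)
  expect_identical(s1$truth$tbv, s2$truth$tbv)
})
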