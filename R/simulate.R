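#' Simulation configuration
#'
#' Bundles all parameters of the gene-dropping simulator: a multi-generation
#' random-mating pedigree, biallelic SNPs with linkage on chromosomes, planted
#' additive QTL, a polygenic remainder drawn down the pedigree, contemporary
#' group (CG) fixed effects, and either a continuous trait or a binary trait
#' generated from a liability threshold.
#'
#' @param n_founders number of founder animals (generation 0).
#' @param n_generations number of non-founder generations to breed.
#' @param matings_per_generation matings performed in each generation.
#' @param offspring_per_mating offspring produced per mating.
#' @param n_chromosomes number of autosomes.
#' @param snps_per_chromosome SNPs simulated per chromosome.
#' @param founder_maf_range range (min, max) in (0, 0.5] from which founder
#'   minor allele frequencies are drawn uniformly.
#' @param morgans_per_chromosome genetic length of each chromosome in Morgans.
#' @param n_qtl number of QTL planted among the simulated SNPs.
#' @param qtl_variance_fractions fractions of the additive genetic variance
#'   assigned to each QTL; must sum to at most 1. Recycled to length
#'   \code{n_qtl} if a single value is given. The remainder
#'   \code{1 - sum(fractions)} is modelled as an infinitesimal polygenic term.
#' @param h2 narrow-sense heritability of the trait. For the binary trait this
#'   is the heritability on the liability scale with residual variance fixed
#'   at 1.
#' @param trait_type \code{"continuous"} or \code{"binary_liability"}.
#' @param liability_threshold_prevalence expected success fraction of the
#'   binary trait (sets the liability threshold).
#' @param n_cg number of contemporary groups.
#' @param cg_sd standard deviation of the CG effects (trait units).
#' @param genotyped_fraction fraction of last-generation animals flagged as
#'   genotyped for the analysis.
#' @param age_slope regression slope of the continuous trait on age at
#'   recording (trait units per day).
#' @param seed integer seed; all randomness in the simulator flows from it.
#'
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_founders = 40L,
                       n_generations = 2L,
                       matings_per_generation = 20L,
                       offspring_per_mating = 2L,
                       n_chromosomes = 2L,
                       snps_per_chromosome = 100L,
                       founder_maf_range = c(0.1, 0.5),
                       morgans_per_chromosome = 1,
                       n_qtl = 2L,
                       qtl_variance_fractions = 0.1,
                       h2 = 0.41,
                       trait_type = c("continuous", "binary_liability"),
                       liability_threshold_prevalence = 0.186,
                       n_cg = 5L,
                       cg_sd = 0.5,
                       genotyped_fraction = 1,
                       age_slope = 0.02,
                       seed = 1L) {
  trait_type <- match.arg(trait_type)
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              matings_per_generation = as.integer(matings_per_generation),
              offspring_per_mating = as.integer(offspring_per_mating),
              n_chromosomes = as.integer(n_chromosomes),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              founder_maf_range = as.numeric(founder_maf_range),
              morgans_per_chromosome = as.numeric(morgans_per_chromosome),
              n_qtl = as.integer(n_qtl),
              qtl_variance_fractions = rep_len(as.numeric(qtl_variance_fractions),
                                               max(as.integer(n_qtl), 0L)),
              h2 = as.numeric(h2),
              trait_type = trait_type,
              liability_threshold_prevalence = as.numeric(liability_threshold_prevalence),
              n_cg = as.integer(n_cg),
              cg_sd = as.numeric(cg_sd),
              genotyped_fraction = as.numeric(genotyped_fraction),
              age_slope = as.numeric(age_slope),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk_count <- function(x, nm, min = 1L) {
    if (length(x) != 1L || is.na(x) || x < min)
      stop(sprintf("invalid sim_config field '%s': must be a count >= %d", nm, min),
           call. = FALSE)
  }
  chk_count(cfg$n_founders, "n_founders")
  chk_count(cfg$n_generations, "n_generations", 0L)
  chk_count(cfg$matings_per_generation, "matings_per_generation")
  chk_count(cfg$offspring_per_mating, "offspring_per_mating")
  chk_count(cfg$n_chromosomes, "n_chromosomes")
  chk_count(cfg$snps_per_chromosome, "snps_per_chromosome")
  chk_count(cfg$n_qtl, "n_qtl", 0L)
  chk_count(cfg$n_cg, "n_cg")
  if (cfg$h2 < 0 || cfg$h2 > 1)
    stop("invalid sim_config field 'h2': must lie in [0, 1]", call. = FALSE)
  r <- cfg$founder_maf_range
  if (length(r) != 2L || r[1] <= 0 || r[2] > 0.5 || r[1] > r[2])
    stop("invalid sim_config field 'founder_maf_range': need 0 < min <= max <= 0.5",
         call. = FALSE)
  if (cfg$n_qtl > 0 && (any(cfg$qtl_variance_fractions < 0) ||
                        sum(cfg$qtl_variance_fractions) > 1))
    stop("invalid sim_config field 'qtl_variance_fractions': fractions must be >= 0 and sum to <= 1",
         call. = FALSE)
  p <- cfg$liability_threshold_prevalence
  if (p <= 0 || p >= 1)
    stop("invalid sim_config field 'liability_threshold_prevalence': must lie in (0, 1)",
         call. = FALSE)
  if (cfg$genotyped_fraction <= 0 || cfg$genotyped_fraction > 1)
    stop("invalid sim_config field 'genotyped_fraction': must lie in (0, 1]",
         call. = FALSE)
  if (cfg$morgans_per_chromosome <= 0)
    stop("invalid sim_config field 'morgans_per_chromosome': must be > 0",
         call. = FALSE)
  if (cfg$cg_sd < 0)
    stop("invalid sim_config field 'cg_sd': must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Simulate a multi-generation random-mating pedigree
#'
#' Founders form generation 0 with unknown parents (coded 0). Each later
#' generation is produced by random matings between a sire and a dam drawn
#' from the previous generation; every non-founder's parents precede it in
#' record order.
#'
#' @param config a \code{\link{sim_config}} object.
#' @return data.frame with columns \code{animal}, \code{sire}, \code{dam}
#'   (integer ids, 0 = unknown), \code{generation} and \code{sex}
#'   (\code{"M"}/\code{"F"}).
#' @export
simulate_pedigree <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n0 <- config$n_founders
  sex <- rep_len(c("M", "F"), n0)            # guarantee both sexes among founders
  ped <- data.frame(animal = seq_len(n0), sire = 0L, dam = 0L,
                    generation = 0L, sex = sex, stringsAsFactors = FALSE)
  if (config$n_generations == 0L) return(ped)
  nxt <- n0 + 1L
  for (g in seq_len(config$n_generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    males <- prev$animal[prev$sex == "M"]
    females <- prev$animal[prev$sex == "F"]
    if (length(males) == 0L || length(females) == 0L)
      stop("pedigree simulation failed: generation ", g - 1L,
           " lacks one sex; increase n_founders or offspring counts")
    for (m in seq_len(config$matings_per_generation)) {
      s <- males[sample.int(length(males), 1L)]
      d <- females[sample.int(length(females), 1L)]
      k <- config$offspring_per_mating
      kids <- data.frame(animal = seq.int(nxt, length.out = k),
                         sire = s, dam = d, generation = g,
                         sex = sample(c("M", "F"), k, replace = TRUE),
                         stringsAsFactors = FALSE)
      ped <- rbind(ped, kids)
      nxt <- nxt + k
    }
  }
  rownames(ped) <- NULL
  ped
}

## One gamete from a parent: recombination mosaic of its two haplotypes.
## Crossovers are a Poisson process (rate = chromosome length in Morgans),
## no interference; snp_pos_m is the genetic position (Morgans) of each SNP.
.gamete <- function(h1, h2, chrom_index, snp_pos_m, chrom_len_m) {
  out <- integer(length(h1))
  for (c in seq_along(chrom_len_m)) {
    idx <- chrom_index[[c]]
    nxo <- stats::rpois(1L, chrom_len_m[c])
    start <- sample.int(2L, 1L)
    if (nxo == 0L) {
      src <- rep.int(start, length(idx))
    } else {
      xo <- sort(stats::runif(nxo, 0, chrom_len_m[c]))
      nswitch <- findInterval(snp_pos_m[idx], xo)
      src <- 1L + (start - 1L + nswitch) %% 2L
    }
    out[idx] <- ifelse(src == 1L, h1[idx], h2[idx])
  }
  out
}

#' Simulate genotypes down a pedigree by gene dropping
#'
#' Founder haplotypes are drawn per SNP from allele frequencies sampled in
#' \code{founder_maf_range}; descendants receive one recombinant gamete from
#' each parent, with crossovers placed as a Poisson process along each
#' chromosome. Dosages count copies of the second allele (codes 0/1/2).
#'
#' @param pedigree output of \code{\link{simulate_pedigree}}.
#' @param config the same \code{\link{sim_config}}.
#' @return An object of class \code{"geno_matrix"}: list with \code{dosages}
#'   (n x m integer matrix, rownames = animal ids), \code{map} (data.frame
#'   \code{chrom}, \code{snp_id}, \code{cm}, \code{bp}) and
#'   \code{founder_freq} (allele frequency of the counted allele per SNP).
#' @export
simulate_genotypes <- function(pedigree, config) {
  validate_sim_config(config)
  if (!all(c("animal", "sire", "dam") %in% names(pedigree)))
    stop("pedigree/config mismatch: pedigree must come from simulate_pedigree()")
  set.seed(config$seed + 1L)
  n <- nrow(pedigree)
  nc <- config$n_chromosomes
  mc <- config$snps_per_chromosome
  m <- nc * mc

  # map: bp from cumulative random gaps, genetic position proportional to bp
  chrom <- rep(seq_len(nc), each = mc)
  bp <- unlist(lapply(seq_len(nc), function(c)
    cumsum(1000L + sample.int(9000L, mc, replace = TRUE))), use.names = FALSE)
  len_m <- rep(config$morgans_per_chromosome, nc)
  pos_m <- numeric(m)
  chrom_index <- split(seq_len(m), chrom)
  for (c in seq_len(nc)) {
    idx <- chrom_index[[c]]
    pos_m[idx] <- bp[idx] / max(bp[idx]) * len_m[c]
  }
  map <- data.frame(chrom = chrom,
                    snp_id = sprintf("SNP%d_%d", chrom, unlist(lapply(chrom_index, seq_along))),
                    cm = 100 * pos_m,
                    bp = bp,
                    stringsAsFactors = FALSE)

  maf <- stats::runif(m, config$founder_maf_range[1], config$founder_maf_range[2])
  flip <- stats::runif(m) < 0.5
  p <- ifelse(flip, 1 - maf, maf)   # frequency of the counted ("second") allele

  H1 <- matrix(0L, n, m)            # paternal haplotype
  H2 <- matrix(0L, n, m)            # maternal haplotype
  founders <- which(pedigree$sire == 0L & pedigree$dam == 0L)
  for (i in founders) {
    H1[i, ] <- stats::rbinom(m, 1L, p)
    H2[i, ] <- stats::rbinom(m, 1L, p)
  }
  pos_of <- match(seq_len(max(pedigree$animal)), pedigree$animal)
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    if (s == 0L && d == 0L) next
    if (s == 0L || d == 0L)
      stop("pedigree/config mismatch: gene dropping needs both parents known for non-founders")
    si <- pos_of[s]; di <- pos_of[d]
    H1[i, ] <- .gamete(H1[si, ], H2[si, ], chrom_index, pos_m, len_m)
    H2[i, ] <- .gamete(H1[di, ], H2[di, ], chrom_index, pos_m, len_m)
  }
  dos <- H1 + H2
  rownames(dos) <- as.character(pedigree$animal)
  colnames(dos) <- map$snp_id
  structure(list(dosages = dos, map = map, founder_freq = p),
            class = "geno_matrix")
}

#' Pick QTL among simulated SNPs
#'
#' Selects \code{n_qtl} SNP indices with realized minor allele frequency of at
#' least 0.1 (so planted signals survive quality control) and assigns additive
#' substitution effects scaled so each QTL contributes its configured fraction
#' of the additive genetic variance.
#'
#' @param genotypes \code{geno_matrix} from \code{\link{simulate_genotypes}}.
#' @param config the \code{\link{sim_config}}.
#' @param sigma2_a total additive genetic variance on the trait scale.
#' @return list with \code{qtl_snp_indices} and \code{qtl_effects}.
#' @export
plant_qtl <- function(genotypes, config, sigma2_a) {
  set.seed(config$seed + 2L)
  nq <- config$n_qtl
  if (nq == 0L) return(list(qtl_snp_indices = integer(0), qtl_effects = numeric(0)))
  pv <- colMeans(genotypes$dosages) / 2
  ok <- which(pmin(pv, 1 - pv) >= 0.1)
  if (length(ok) < nq)
    stop("too few polymorphic SNPs to plant ", nq, " QTL")
  idx <- sort(sample(ok, nq))
  v <- apply(genotypes$dosages[, idx, drop = FALSE], 2, stats::var)
  f <- config$qtl_variance_fractions
  beta <- sqrt(f * sigma2_a / v) * sample(c(-1, 1), nq, replace = TRUE)
  list(qtl_snp_indices = idx, qtl_effects = as.numeric(beta))
}

## Infinitesimal polygenic term dropped down the pedigree:
## parent average + Mendelian sampling deviation.
.polygenic <- function(pedigree, sigma2) {
  n <- nrow(pedigree)
  u <- numeric(n)
  if (sigma2 <= 0) return(u)
  pos_of <- match(seq_len(max(pedigree$animal)), pedigree$animal)
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    if (s == 0L && d == 0L) {
      u[i] <- stats::rnorm(1L, 0, sqrt(sigma2))
    } else if (s == 0L || d == 0L) {
      pu <- u[pos_of[max(s, d)]]
      u[i] <- 0.5 * pu + stats::rnorm(1L, 0, sqrt(0.75 * sigma2))
    } else {
      u[i] <- 0.5 * (u[pos_of[s]] + u[pos_of[d]]) +
        stats::rnorm(1L, 0, sqrt(0.5 * sigma2))
    }
  }
  u
}

## Random CG assignment with minimum group size >= 4 enforced by moving
## members of undersized groups into the largest groups.
.assign_cg <- function(n, n_cg) {
  if (n < 4L * n_cg) n_cg <- max(1L, n %/% 4L)
  cg <- sample.int(n_cg, n, replace = TRUE)
  repeat {
    sizes <- tabulate(cg, n_cg)
    small <- which(sizes > 0L & sizes < 4L)
    if (length(small) == 0L) break
    movers <- which(cg %in% small)
    big <- which(sizes >= 4L)
    if (length(big) == 0L) { cg[] <- 1L; break }
    cg[movers] <- big[sample.int(length(big), length(movers), replace = TRUE)]
  }
  cg
}

#' Simulate phenotypes with planted QTL and a polygenic remainder
#'
#' True breeding values are the sum of planted QTL contributions and an
#' infinitesimal polygenic term, scaled so the total additive variance matches
#' the configured heritability. Phenotypes add a contemporary-group effect and
#' a residual; for the binary trait the record is 1 when the liability exceeds
#' the threshold implied by the configured prevalence. The continuous trait
#' additionally carries a linear age-at-recording covariate with known slope.
#'
#' Variance scaling: for the continuous trait the phenotypic variance (net of
#' CG) is 1, so \code{sigma2_a = h2}; for the binary trait the residual
#' liability variance is fixed at 1, so \code{sigma2_a = h2 / (1 - h2)}.
#'
#' @param pedigree from \code{\link{simulate_pedigree}}.
#' @param genotypes from \code{\link{simulate_genotypes}}.
#' @param qtl from \code{\link{plant_qtl}}, or NULL to plant internally.
#' @param config the \code{\link{sim_config}}.
#' @return list with \code{pheno} (data.frame: animal, trait, the five CG
#'   fields, cg_id, age) and \code{truth} (true breeding values, QTL indices
#'   and effects, variance components, threshold, CG effects).
#' @export
simulate_phenotypes <- function(pedigree, genotypes, qtl = NULL, config) {
  validate_sim_config(config)
  n <- nrow(pedigree)
  if (nrow(genotypes$dosages) != n)
    stop("pedigree/genotype mismatch: row counts differ")
  binary <- config$trait_type == "binary_liability"
  sigma2_a <- if (binary) config$h2 / (1 - config$h2) else config$h2
  sigma2_e <- if (binary) 1 else 1 - config$h2
  if (is.null(qtl)) qtl <- plant_qtl(genotypes, config, sigma2_a)
  if (length(qtl$qtl_snp_indices) > 0) {
    if (any(qtl$qtl_snp_indices < 1L | qtl$qtl_snp_indices > ncol(genotypes$dosages)))
      stop("QTL indices out of range")
    if (any(duplicated(qtl$qtl_snp_indices))) stop("QTL indices must be unique")
  }
  set.seed(config$seed + 3L)

  f_tot <- if (config$n_qtl > 0) sum(config$qtl_variance_fractions) else 0
  if (f_tot > 1) stop("QTL variance fractions exceed 1")
  g_qtl <- if (length(qtl$qtl_snp_indices) > 0) {
    as.numeric(genotypes$dosages[, qtl$qtl_snp_indices, drop = FALSE] %*% qtl$qtl_effects)
  } else numeric(n)
  g_qtl <- g_qtl - mean(g_qtl)
  u_poly <- .polygenic(pedigree, (1 - f_tot) * sigma2_a)
  tbv <- g_qtl + u_poly

  cg <- .assign_cg(n, config$n_cg)
  cg_eff <- stats::rnorm(max(cg), 0, config$cg_sd)
  # derive the five CG fields injectively from the group index
  yob <- 2005L + (cg - 1L) %% 5L
  farm <- sprintf("F%d", 1L + ((cg - 1L) %/% 5L) %% 8L)
  mgb <- sprintf("B%d", 1L + ((cg - 1L) %/% 40L) %% 4L)
  mgw <- sprintf("W%d", cg)
  mgy <- sprintf("Y%d", 1L + (cg - 1L) %% 3L)

  e <- stats::rnorm(n, 0, sqrt(sigma2_e))
  if (binary) {
    liab <- cg_eff[cg] + tbv + e
    thr <- stats::qnorm(1 - config$liability_threshold_prevalence) *
      sqrt(config$cg_sd^2 + sigma2_a + sigma2_e)
    trait <- as.integer(liab > thr)
    age <- rep(NA_real_, n)
  } else {
    age <- round(stats::runif(n, 290, 420))
    thr <- NA_real_
    trait <- cg_eff[cg] + config$age_slope * (age - 355) + tbv + e
  }
  pheno <- data.frame(animal = pedigree$animal,
                      trait = trait,
                      year_birth = yob, farm = farm,
                      mg_birth = mgb, mg_weaning = mgw, mg_yearling = mgy,
                      age = age,
                      stringsAsFactors = FALSE)
  pheno <- form_contemporary_groups(pheno)$records
  truth <- list(tbv = stats::setNames(tbv, pedigree$animal),
                qtl_snp_indices = qtl$qtl_snp_indices,
                qtl_effects = qtl$qtl_effects,
                sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                threshold = thr,
                cg_effects = cg_eff, cg = cg)
  list(pheno = pheno, truth = truth)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running \code{\link{simulate_pedigree}},
#' \code{\link{simulate_genotypes}} and \code{\link{simulate_phenotypes}}, and
#' flagging a genotyped subset of the last generation.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{pedigree}, \code{genotypes} (all animals),
#'   \code{genotyped_ids} (ids of animals whose genotypes are observed),
#'   \code{pheno}, \code{truth} and \code{config}.
#' @export
simulate_dataset <- function(config) {
  ped <- simulate_pedigree(config)
  gen <- simulate_genotypes(ped, config)
  ph <- simulate_phenotypes(ped, gen, qtl = NULL, config = config)
  set.seed(config$seed + 4L)
  last <- ped$animal[ped$generation == max(ped$generation)]
  ng <- max(1L, round(config$genotyped_fraction * length(last)))
  genotyped <- sort(sample(last, ng))
  list(pedigree = ped, genotypes = gen, genotyped_ids = genotyped,
       pheno = ph$pheno, truth = ph$truth, config = config)
}
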