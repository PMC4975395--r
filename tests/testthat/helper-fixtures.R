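# Shared fixtures and independent oracles used across test files.

# wrap a dosage matrix + map into the genotype container
make_geno <- function(dos, chrom = NULL, bp = NULL, quality = NULL) {
  m <- ncol(dos)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  if (is.null(rownames(dos))) rownames(dos) <- sprintf("S%02d", seq_len(nrow(dos)))
  if (is.null(colnames(dos))) colnames(dos) <- sprintf("snp%d", seq_len(m))
  structure(list(dosages = dos,
                 map = data.frame(chrom = chrom, snp_id = colnames(dos),
                                  cm = bp / 1e4, bp = bp,
                                  stringsAsFactors = FALSE),
                 quality = quality),
            class = "geno_matrix")
}

# independent enumeration oracle for the exact Hardy-Weinberg test:
# direct conditional probability formula, no recurrence shared with the
# implementation
hwe_enumeration_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (min(nA, na) == 0) return(1)
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  logp <- vapply(hets, function(h) {
    lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
      lfactorial((na - h) / 2) + h * log(2) +
      lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- pr[hets == nAa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# random parents-first pedigree for matrix identities
random_pedigree <- function(n, n_founders = max(3L, n %/% 4L)) {
  sire <- dam <- integer(n)
  for (i in seq_len(n)) {
    if (i > n_founders) {
      sire[i] <- sample.int(i - 1L, 1L)
      repeat {
        dam[i] <- sample.int(i - 1L, 1L)
        if (dam[i] != sire[i]) break
      }
    }
  }
  data.frame(animal = seq_len(n), sire = sire, dam = dam)
}

# dosage matrix with external allele frequencies (keeps G full rank for
# n <= m, unlike data-centered frequencies)
random_dosages <- function(n, m, p = NULL) {
  if (is.null(p)) p <- runif(m, 0.15, 0.85)
  dos <- vapply(p, function(pp) rbinom(n, 2L, pp), integer(n))
  if (n == 1) dos <- matrix(dos, 1)
  rownames(dos) <- sprintf("G%03d", seq_len(n))
  colnames(dos) <- sprintf("snp%d", seq_len(m))
  list(dos = dos, p = p)
}

# 20-sample x 10-SNP QC fixture: sample S20 has call rate 0.8 (< 0.90) and
# leaves in round 1; SNP snp5 has call frequency 19/20 = 0.95 (kept, rule is
# strict "<") which drops to 18/19 < 0.95 once S20 is gone, so snp5 leaves
# only in round 2.
qc_two_round_fixture <- function() {
  set.seed(4242)
  repeat {
    dos <- vapply(1:10, function(j) sample(0:2, 20, replace = TRUE,
                                           prob = c(0.25, 0.5, 0.25)),
                  integer(20))
    rownames(dos) <- sprintf("S%02d", 1:20)
    colnames(dos) <- sprintf("snp%d", 1:10)
    g <- make_geno(dos)
    clean <- iterative_qc(g)
    ok <- identical(dim(clean$genotypes$dosages), dim(dos)) &&
      clean$n_rounds == 1L
    if (ok) break
  }
  dos[20, 1:2] <- NA      # S20: 8/10 called -> removed (call rate 0.8)
  dos[1, 5] <- NA         # snp5: 19/20 called with S20 present, 18/19 after
  make_geno(dos)
}
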