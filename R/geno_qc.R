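#' Quality-control thresholds for genotype data
#'
#' Defaults follow standard array QC practice for this pipeline: SNPs are
#' excluded when non-autosomal, mapped at an already-occupied position,
#' out of Hardy-Weinberg equilibrium at p < 1e-5, with minor allele frequency
#' below 2%, with a quality (GenCall-type) score below 0.15, or with call
#' frequency below 95%; samples are excluded at call rate below 90% or as
#' duplicates.
#'
#' @param hwe_p_min minimum exact-test Hardy-Weinberg p-value.
#' @param maf_min minimum minor allele frequency.
#' @param snp_quality_min minimum per-SNP quality score (used only when the
#'   genotype object carries quality scores).
#' @param snp_call_rate_min minimum per-SNP call frequency.
#' @param sample_call_rate_min minimum per-sample call rate.
#' @param exclude_non_autosomal drop SNPs whose chromosome label is not an
#'   autosome (labels outside 1..29, the cattle autosomes).
#' @param exclude_same_position drop all SNPs sharing a bp position on the
#'   same chromosome.
#' @param n_autosomes highest autosome label accepted.
#' @return list of class \code{"qc_thresholds"}.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-5, maf_min = 0.02,
                          snp_quality_min = 0.15, snp_call_rate_min = 0.95,
                          sample_call_rate_min = 0.90,
                          exclude_non_autosomal = TRUE,
                          exclude_same_position = TRUE,
                          n_autosomes = 29L) {
  th <- list(hwe_p_min = hwe_p_min, maf_min = maf_min,
             snp_quality_min = snp_quality_min,
             snp_call_rate_min = snp_call_rate_min,
             sample_call_rate_min = sample_call_rate_min,
             exclude_non_autosomal = isTRUE(exclude_non_autosomal),
             exclude_same_position = isTRUE(exclude_same_position),
             n_autosomes = as.integer(n_autosomes))
  num <- unlist(th[1:5])
  if (any(num < 0 | num > 1)) stop("qc thresholds must lie in [0, 1]")
  class(th) <- "qc_thresholds"
  th
}

#' Minor allele frequency of a dosage column
#'
#' @param dosage vector of 0/1/2 codes, NA = missing.
#' @return min(p, 1-p) where p = sum(dosage) / (2 * non-missing count).
#' @export
minor_allele_frequency <- function(dosage) {
  ok <- !is.na(dosage)
  if (!any(ok)) return(NA_real_)
  p <- sum(dosage[ok]) / (2 * sum(ok))
  min(p, 1 - p)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the allele counts, the p-value is the sum of
#' probabilities of all heterozygote counts that are no more probable than the
#' observed one, under the hypergeometric-type distribution of heterozygote
#' counts conditional on allele totals. Computed by full enumeration over all
#' heterozygote counts of the right parity, using a stable recurrence.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped individual required")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0L) return(1)                   # monomorphic: single outcome
  hets <- seq.int(rare %% 2L, rare, by = 2L)  # feasible heterozygote counts
  # log-probability up to a constant: P(het = h | allele counts)
  lp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((na - hets) / 2 + 1) + hets * log(2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  sum(pr[pr <= obs + 1e-12 * obs])
}

## per-column genotype counts ignoring missing
.geno_counts <- function(col) {
  c(AA = sum(col == 0, na.rm = TRUE),
    Aa = sum(col == 1, na.rm = TRUE),
    aa = sum(col == 2, na.rm = TRUE))
}

#' Apply the SNP exclusion rules
#'
#' Rules are checked in a fixed order (non-autosomal; same position; HWE; MAF;
#' quality; call frequency) and a SNP failing several rules is logged under
#' the first failing one. All members of a same-position group are removed.
#'
#' @param genotypes a \code{geno_matrix} (dosages + map, optional
#'   \code{quality} vector).
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @return list with \code{kept} (logical per SNP) and \code{exclusions}
#'   (data.frame: id, rule, statistic).
#' @export
apply_snp_filters <- function(genotypes, thresholds = qc_thresholds()) {
  dos <- genotypes$dosages
  map <- genotypes$map
  m <- ncol(dos)
  rule <- rep(NA_character_, m)
  stat <- rep(NA_real_, m)
  flag <- function(idx, r, s) {
    mask <- is.na(rule[idx])
    new <- idx[mask]
    rule[new] <<- r
    stat[new] <<- s[mask]
  }
  if (thresholds$exclude_non_autosomal) {
    chr <- suppressWarnings(as.integer(as.character(map$chrom)))
    bad <- which(is.na(chr) | chr < 1L | chr > thresholds$n_autosomes)
    flag(bad, "non_autosomal", rep(NA_real_, length(bad)))
  }
  if (thresholds$exclude_same_position) {
    key <- paste(map$chrom, map$bp)
    dup_keys <- unique(key[duplicated(key)])
    bad <- which(key %in% dup_keys)
    flag(bad, "same_position", as.numeric(map$bp[bad]))
  }
  todo <- which(is.na(rule))
  if (length(todo) > 0) {
    hwe_p <- vapply(todo, function(j) {
      cnt <- .geno_counts(dos[, j])
      if (sum(cnt) == 0L) return(1)           # all-missing: call-rate rule's job
      hwe_exact_test(cnt[1], cnt[2], cnt[3])
    }, numeric(1))
    bad <- todo[hwe_p < thresholds$hwe_p_min]
    flag(bad, "hwe", hwe_p[hwe_p < thresholds$hwe_p_min])
  }
  todo <- which(is.na(rule))
  if (length(todo) > 0) {
    maf <- vapply(todo, function(j) minor_allele_frequency(dos[, j]), numeric(1))
    sel <- !is.na(maf) & maf < thresholds$maf_min
    flag(todo[sel], "maf", maf[sel])
  }
  if (!is.null(genotypes$quality)) {
    todo <- which(is.na(rule))
    q <- genotypes$quality[todo]
    sel <- !is.na(q) & q < thresholds$snp_quality_min
    flag(todo[sel], "quality", q[sel])
  }
  todo <- which(is.na(rule))
  if (length(todo) > 0) {
    cr <- colMeans(!is.na(dos[, todo, drop = FALSE]))
    sel <- cr < thresholds$snp_call_rate_min
    flag(todo[sel], "snp_call_rate", cr[sel])
  }
  excl <- which(!is.na(rule))
  list(kept = is.na(rule),
       exclusions = data.frame(id = colnames(dos)[excl],
                               rule = rule[excl], statistic = stat[excl],
                               stringsAsFactors = FALSE))
}

#' Apply the sample exclusion rules
#'
#' Samples with call rate below the threshold are removed; among groups of
#' samples with identical genotype vectors (compared on jointly non-missing
#' calls being identical everywhere, i.e. the stored vectors match exactly),
#' only the lexicographically smallest sample id is kept.
#'
#' @inheritParams apply_snp_filters
#' @return list with \code{kept} (logical per sample) and \code{exclusions}.
#' @export
apply_sample_filters <- function(genotypes, thresholds = qc_thresholds()) {
  dos <- genotypes$dosages
  n <- nrow(dos)
  rule <- rep(NA_character_, n)
  stat <- rep(NA_real_, n)
  cr <- rowMeans(!is.na(dos))
  bad <- which(cr < thresholds$sample_call_rate_min)
  rule[bad] <- "sample_call_rate"
  stat[bad] <- cr[bad]
  ok <- which(is.na(rule))
  if (length(ok) > 1) {
    key <- apply(dos[ok, , drop = FALSE], 1, paste, collapse = ",")
    for (k in unique(key[duplicated(key)])) {
      grp <- ok[key == k]
      keep1 <- grp[order(rownames(dos)[grp])][1]
      drop <- setdiff(grp, keep1)
      rule[drop] <- "duplicate_sample"
      stat[drop] <- NA_real_
    }
  }
  excl <- which(!is.na(rule))
  list(kept = is.na(rule),
       exclusions = data.frame(id = rownames(dos)[excl],
                               rule = rule[excl], statistic = stat[excl],
                               stringsAsFactors = FALSE))
}

#' Iterative genotype quality control
#'
#' Repeats (SNP filters, then sample filters) until a full round removes
#' nothing. Each round acts on the matrix left by the previous one, so rules
#' whose statistics depend on the complement (e.g. a SNP's call frequency
#' after a low-call-rate sample leaves) can fire in later rounds.
#'
#' @inheritParams apply_snp_filters
#' @return list with \code{genotypes} (filtered \code{geno_matrix}),
#'   \code{report} (data.frame: round, entity, id, rule, statistic) and
#'   \code{n_rounds}.
#' @export
iterative_qc <- function(genotypes, thresholds = qc_thresholds()) {
  report <- data.frame(round = integer(0), entity = character(0),
                       id = character(0), rule = character(0),
                       statistic = numeric(0), stringsAsFactors = FALSE)
  g <- genotypes
  round <- 0L
  repeat {
    round <- round + 1L
    sf <- apply_snp_filters(g, thresholds)
    if (any(!sf$kept)) {
      report <- rbind(report, cbind(round = round, entity = "snp",
                                    sf$exclusions, stringsAsFactors = FALSE))
      g$dosages <- g$dosages[, sf$kept, drop = FALSE]
      g$map <- g$map[sf$kept, , drop = FALSE]
      if (!is.null(g$quality)) g$quality <- g$quality[sf$kept]
      if (!is.null(g$founder_freq)) g$founder_freq <- g$founder_freq[sf$kept]
    }
    if (ncol(g$dosages) == 0)
      stop("quality control removed every SNP; last rule fired: ",
           utils::tail(report$rule, 1))
    mf <- apply_sample_filters(g, thresholds)
    if (any(!mf$kept)) {
      report <- rbind(report, cbind(round = round, entity = "sample",
                                    mf$exclusions, stringsAsFactors = FALSE))
      g$dosages <- g$dosages[mf$kept, , drop = FALSE]
    }
    if (nrow(g$dosages) == 0)
      stop("quality control removed every sample; last rule fired: ",
           utils::tail(report$rule, 1))
    if (all(sf$kept) && all(mf$kept)) break
  }
  rownames(g$map) <- NULL
  list(genotypes = g, report = report, n_rounds = round)
}

#' Impute remaining missing dosages to the SNP mean
#'
#' Missing calls surviving QC are replaced by twice the observed allele
#' frequency (the column mean), which keeps the centered genotype matrix
#' centered.
#'
#' @param genotypes a \code{geno_matrix}.
#' @return the \code{geno_matrix} with no missing dosages (numeric storage).
#' @export
impute_mean <- function(genotypes) {
  dos <- genotypes$dosages
  storage.mode(dos) <- "double"
  mis <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(mis) > 0) {
    mu <- colMeans(dos, na.rm = TRUE)
    dos[mis] <- mu[mis[, 2]]
  }
  genotypes$dosages <- dos
  genotypes
}
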