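## File formats: pedigree CSV (animal,sire,dam; 0 = unknown), genotype dosage
## matrix as whitespace-delimited text with a SNP-id header, SNP map with
## PLINK .map column order (chrom, snp_id, cm, bp), phenotype CSV. Missing
## genotype codes: 5 (BLUPF90 convention) or NA.

#' Read a pedigree file
#'
#' @param path CSV with columns animal, sire, dam (0 = unknown parent).
#' @return pedigree data.frame sorted parents-first.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(ped)))
    stop("pedigree file must have columns animal, sire, dam")
  sort_pedigree(ped)
}

#' Read a genotype dosage matrix and its SNP map
#'
#' @param dosage_path whitespace-delimited dosage file; first column sample
#'   id, remaining columns one per SNP with a header of SNP ids. Codes 0/1/2;
#'   5 or NA = missing.
#' @param map_path whitespace-delimited map file without header, PLINK .map
#'   column order: chromosome, snp id, genetic position (cM), bp position.
#' @return a \code{geno_matrix}.
#' @export
read_genotypes <- function(dosage_path, map_path) {
  dos <- utils::read.table(dosage_path, header = TRUE, check.names = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  ids <- as.character(dos[[1]])
  M <- as.matrix(dos[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  M[M == 5] <- NA
  if (any(!is.na(M) & !(M %in% c(0, 1, 2))))
    stop("dosage codes must be 0/1/2 with 5 or NA for missing")
  rownames(M) <- ids
  map <- utils::read.table(map_path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "bp"))
  if (nrow(map) != ncol(M))
    stop("map rows (", nrow(map), ") do not match dosage columns (", ncol(M), ")")
  if (!identical(as.character(map$snp_id), colnames(M)))
    colnames(M) <- map$snp_id
  structure(list(dosages = M, map = map), class = "geno_matrix")
}

#' Read a phenotype file
#'
#' @param path CSV with columns animal, trait, the five CG fields
#'   (year_birth, farm, mg_birth, mg_weaning, mg_yearling) and optionally age.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("animal", "trait") %in% names(ph)))
    stop("phenotype file must have columns animal and trait")
  ph
}

#' Read and cross-validate all pipeline inputs
#'
#' @param config list with paths \code{pedigree}, \code{genotypes},
#'   \code{map}, \code{phenotypes}.
#' @return list (pedigree, genotypes, pheno).
#' @export
read_inputs <- function(config) {
  ped <- read_pedigree(config$pedigree)
  gen <- read_genotypes(config$genotypes, config$map)
  ph <- read_phenotypes(config$phenotypes)
  gmiss <- setdiff(rownames(gen$dosages), as.character(ped$animal))
  if (length(gmiss) > 0)
    stop("genotyped id(s) absent from pedigree: ",
         paste(utils::head(gmiss, 5), collapse = ", "),
         " (the single-step method requires pedigree for every genotyped animal)")
  pmiss <- setdiff(as.character(ph$animal), as.character(ped$animal))
  if (length(pmiss) > 0)
    stop("phenotyped id(s) absent from pedigree: ",
         paste(utils::head(pmiss, 5), collapse = ", "))
  list(pedigree = ped, genotypes = gen, pheno = ph)
}

## deterministic short hash of a configuration (polynomial rolling hash)
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.header_line <- function(seed, hash, iteration = NA) {
  sprintf("# seed=%s config_hash=%s iteration=%s", seed, hash,
          ifelse(is.na(iteration), "-", iteration))
}

.write_tsv <- function(df, path, header_line) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_line, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits pedigree.csv, genotypes.txt (dosages of the genotyped subset),
#' snps.map (PLINK column order), phenotypes.csv and truth.tsv (QTL indices,
#' effects and true breeding values).
#'
#' @param sim output of \code{\link{simulate_dataset}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_simulated_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pedigree = file.path(dir, "pedigree.csv"),
             genotypes = file.path(dir, "genotypes.txt"),
             map = file.path(dir, "snps.map"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             truth = file.path(dir, "truth.tsv"))
  utils::write.csv(sim$pedigree[c("animal", "sire", "dam")],
                   paths["pedigree"], row.names = FALSE, quote = FALSE)
  sel <- as.character(sim$genotyped_ids)
  dos <- sim$genotypes$dosages[sel, , drop = FALSE]
  utils::write.table(data.frame(id = rownames(dos), dos, check.names = FALSE),
                     paths["genotypes"], sep = " ", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$genotypes$map[c("chrom", "snp_id", "cm", "bp")],
                     paths["map"], sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(sim$pheno, paths["phenotypes"], row.names = FALSE, quote = FALSE)
  tb <- data.frame(animal = names(sim$truth$tbv), tbv = sim$truth$tbv)
  qt <- data.frame(animal = NA, tbv = NA,
                   qtl_index = sim$truth$qtl_snp_indices,
                   qtl_effect = sim$truth$qtl_effects)
  tb$qtl_index <- NA; tb$qtl_effect <- NA
  utils::write.table(rbind(qt, tb), paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Run the full pipeline from files to reports
#'
#' Phenotype preparation, iterative genotype QC, relationship matrices,
#' breeding-value prediction, iterative SNP reweighting and window reporting,
#' with all artifacts written as headered TSV/CSV files.
#'
#' @param config list: input paths (\code{pedigree}, \code{genotypes},
#'   \code{map}, \code{phenotypes}), \code{trait_type}, \code{h2},
#'   \code{out_dir}, \code{seed}, and optionally \code{window_size} (150),
#'   \code{n_iterations} (3), \code{report_iteration} (2), \code{top_k} (10),
#'   \code{beta} (0.05), \code{chain} (a \code{\link{chain_config}}),
#'   \code{qc} (TRUE) and \code{thresholds}.
#' @return the fitted \code{\link{wssgblup}} object, invisibly; artifacts in
#'   \code{config$out_dir}.
#' @export
run_pipeline <- function(config) {
  defaults <- list(window_size = 150L, n_iterations = 3L,
                   report_iteration = 2L, top_k = 10L, beta = 0.05,
                   qc = TRUE, seed = 1L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$chain))
    config$chain <- chain_config(seed = config$seed)
  # hash only analysis-relevant settings, not output location
  hkeys <- setdiff(sort(names(config)), "out_dir")
  hash <- .config_hash(config[hkeys])
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  inputs <- stage("read_inputs", read_inputs(config))
  trait <- if (config$trait_type %in% c("binary", "binary_liability")) "binary" else "continuous"

  prep <- stage("pheno_prep", prepare_phenotypes(inputs$pheno, trait))
  .write_tsv(prep$audit, file.path(config$out_dir, "pheno_audit.tsv"),
             .header_line(config$seed, hash))

  gen <- inputs$genotypes
  qc_rounds <- 0L
  if (isTRUE(config$qc)) {
    th <- if (is.null(config$thresholds)) qc_thresholds() else config$thresholds
    qc <- stage("geno_qc", iterative_qc(gen, th))
    gen <- qc$genotypes
    qc_rounds <- qc$n_rounds
    .write_tsv(qc$report, file.path(config$out_dir, "qc_report.tsv"),
               .header_line(config$seed, hash))
  }
  # drop phenotype records for animals not in the pedigree order is handled
  # inside the fit; restrict to records that survived preparation
  fit <- stage("wssgblup", wssgblup(
    prep$records, inputs$pedigree, gen, trait_type = trait,
    h2 = config$h2, n_iterations = config$n_iterations,
    window_size = config$window_size,
    report_iteration = config$report_iteration, top_k = config$top_k,
    beta = config$beta, chain = config$chain))

  sol <- fit$solution
  sol_df <- rbind(
    data.frame(id = names(sol$b_hat), type = "fixed",
               estimate = unname(sol$b_hat),
               posterior_sd = NA_real_, stringsAsFactors = FALSE),
    data.frame(id = names(sol$a_hat), type = "animal",
               estimate = unname(sol$a_hat),
               posterior_sd = if (is.null(sol$a_hat_sd)) NA_real_
                              else unname(sol$a_hat_sd),
               stringsAsFactors = FALSE))
  .write_tsv(sol_df, file.path(config$out_dir, "solutions.tsv"),
             .header_line(config$seed, hash))
  for (it in fit$iterations) {
    .write_tsv(coef(fit, iteration = it$t),
               file.path(config$out_dir, sprintf("snp_effects_iter%d.tsv", it$t)),
               .header_line(config$seed, hash, it$t))
    .write_tsv(as.data.frame(it$windows),
               file.path(config$out_dir, sprintf("windows_iter%d.tsv", it$t)),
               .header_line(config$seed, hash, it$t))
  }
  .write_tsv(as.data.frame(fit$top),
             file.path(config$out_dir, "top_windows.tsv"),
             .header_line(config$seed, hash, config$report_iteration))
  log_lines <- c(
    .header_line(config$seed, hash),
    paste0("r_version=", R.version.string),
    paste0("package_version=", as.character(utils::packageVersion("wssgblup"))),
    paste0("trait_type=", trait),
    paste0("records_in=", nrow(inputs$pheno)),
    paste0("records_kept=", nrow(prep$records)),
    paste0("snps_kept=", ncol(gen$dosages)),
    paste0("samples_kept=", nrow(gen$dosages)),
    paste0("qc_rounds=", qc_rounds),
    vapply(c("window_size", "n_iterations", "report_iteration", "top_k",
             "beta", "seed"),
           function(nm) paste0(nm, "=", config[[nm]]), ""))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(fit)
}
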