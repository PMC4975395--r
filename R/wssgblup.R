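#' Back-solve SNP effects from genomic breeding values
#'
#' u = lambda D Z' G^-1 a_g: the SNP effects whose weighted genomic
#' relationship matrix reproduces the genomic breeding values of the
#' genotyped animals.
#'
#' @param cg \code{centered_geno} from \code{\link{center_and_lambda}}.
#' @param weights current SNP weights (diagonal of D).
#' @param G the genomic relationship matrix built from the same Z, D and
#'   lambda (blended if the raw matrix is singular).
#' @param a_g breeding values of the genotyped animals, in Z row order.
#' @return numeric vector of m SNP effects.
#' @export
backsolve_snp_effects <- function(cg, weights, G, a_g) {
  if (length(a_g) != nrow(cg$Z)) stop("a_g must match the genotyped animals")
  if (length(weights) != ncol(cg$Z)) stop("one weight per SNP required")
  s <- tryCatch(solve(G, a_g), error = function(e)
    stop("G is singular; blend with A22 first (blend_G)", call. = FALSE))
  as.numeric(cg$lambda * weights * crossprod(cg$Z, s))
}

#' SNP variance weights from back-solved effects
#'
#' d_i = u_i^2 * 2 p_i (1 - p_i): each SNP's contribution to the additive
#' genetic variance under its current effect estimate.
#'
#' @param u_hat back-solved SNP effects.
#' @param allele_freqs allele frequencies p_i of the counted allele.
#' @return raw (unnormalized) weights.
#' @export
update_weights <- function(u_hat, allele_freqs) {
  if (length(u_hat) != length(allele_freqs)) stop("length mismatch")
  u_hat^2 * 2 * allele_freqs * (1 - allele_freqs)
}

#' Normalize SNP weights to a constant trace
#'
#' Rescales the weights so their sum equals the reference trace tr(D(0)) = m,
#' keeping the additive genetic variance implied by G constant across
#' iterations.
#'
#' @param raw_weights non-negative weights.
#' @param trace_reference target sum (defaults to the number of SNPs).
#' @return normalized weights summing to \code{trace_reference}.
#' @export
normalize_weights <- function(raw_weights, trace_reference = length(raw_weights)) {
  s <- sum(raw_weights)
  if (s <= 0) stop("all SNP weights are zero; nothing to rescale")
  raw_weights * trace_reference / s
}

#' Variance explained by windows of adjacent SNPs
#'
#' Partitions each chromosome into consecutive, non-overlapping windows of
#' \code{window_size} adjacent SNPs (the terminal window of a chromosome may
#' be shorter) and reports the percentage of the additive genetic variance
#' explained by each window. The default definition is the empirical variance,
#' across genotyped animals, of the window genomic score
#' \eqn{\sum_{i \in w} Z_i u_i}, which accounts for linkage disequilibrium
#' within the window; \code{method = "weight_share"} instead reports the
#' normalized weight share \eqn{100 \sum_{i \in w} d_i / m}.
#'
#' @param u_hat back-solved SNP effects (map order).
#' @param cg \code{centered_geno}; its map must be sorted by (chrom, bp).
#' @param window_size number of adjacent SNPs per window (default 150).
#' @param sigma2_a additive genetic variance used as the denominator.
#' @param method \code{"score_variance"} (default) or \code{"weight_share"}.
#' @param weights SNP weights (needed for \code{method = "weight_share"}).
#' @return data.frame of class \code{"window_report"}: chrom, window index
#'   within chromosome, first/last global SNP index, start/end bp, n_snps,
#'   percent_variance; attribute \code{sigma2_a} records the denominator.
#' @export
window_variances <- function(u_hat, cg, window_size = 150L, sigma2_a,
                             method = c("score_variance", "weight_share"),
                             weights = NULL) {
  method <- match.arg(method)
  map <- cg$map
  if (is.unsorted(order(map$chrom, map$bp)) ||
      any(unlist(tapply(map$bp, map$chrom, function(b) diff(b) <= 0))))
    stop("SNP map must be sorted by (chromosome, bp) with strictly increasing bp")
  if (length(u_hat) != nrow(map)) stop("u_hat must match the SNP map")
  if (sigma2_a <= 0) stop("sigma2_a must be > 0")
  rows <- list()
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    nw <- ceiling(length(idx) / window_size)
    for (w in seq_len(nw)) {
      sel <- idx[(1 + (w - 1) * window_size):min(w * window_size, length(idx))]
      v <- if (method == "score_variance") {
        score <- as.numeric(cg$Z[, sel, drop = FALSE] %*% u_hat[sel])
        stats::var(score)
      } else {
        if (is.null(weights)) stop("weights required for method = 'weight_share'")
        sum(weights[sel]) / length(u_hat) * sigma2_a
      }
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = chr, window = w,
                   first_snp = sel[1], last_snp = sel[length(sel)],
                   start_bp = map$bp[sel[1]], end_bp = map$bp[sel[length(sel)]],
                   n_snps = length(sel),
                   percent_variance = 100 * v / sigma2_a,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "sigma2_a") <- sigma2_a
  attr(out, "method") <- method
  class(out) <- c("window_report", "data.frame")
  out
}

#' Top windows by explained variance
#'
#' The k windows with the largest percentage of explained variance, ties
#' broken by (chromosome, start bp) ascending. The summed percentage of the
#' selected windows is attached as attribute \code{total_percent}.
#'
#' @param report a \code{window_report} from \code{\link{window_variances}}.
#' @param k number of windows to return (default 10).
#' @return the ranked sublist of the report.
#' @export
top_windows <- function(report, k = 10L) {
  if (nrow(report) == 0) stop("empty window report")
  if (k > nrow(report)) {
    warning("k exceeds the number of windows; returning all ", nrow(report))
    k <- nrow(report)
  }
  ord <- order(-report$percent_variance, report$chrom, report$start_bp)
  out <- report[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_percent") <- sum(out$percent_variance)
  attr(out, "sigma2_a") <- attr(report, "sigma2_a")
  class(out) <- class(report)
  out
}

#' Weighted single-step GBLUP genome-wide association
#'
#' Fits the single-trait animal model by single-step GBLUP and runs the
#' iterative SNP-reweighting GWAS: breeding values of all animals are
#' predicted once with H^-1 (mixed-model equations for a continuous trait, a
#' liability-threshold Gibbs sampler for a binary trait); SNP effects are then
#' back-solved from the genomic breeding values of the genotyped animals,
#' converted to SNP-variance weights, normalized to a constant trace, and the
#' genomic relationship matrix is rebuilt with the new weights for the next
#' back-solve. The breeding values are computed once and reused across
#' iterations. Results are reported as the percentage of additive genetic
#' variance explained by windows of adjacent SNPs.
#'
#' @param pheno prepared phenotype data.frame (\code{animal}, \code{trait},
#'   \code{cg_id}, optional \code{age}); run \code{\link{prepare_phenotypes}}
#'   first.
#' @param pedigree pedigree data.frame (re-sorted parents-first internally).
#' @param genotypes QC'd \code{geno_matrix} of the genotyped animals only
#'   (rownames = animal ids); missing dosages are mean-imputed.
#' @param trait_type \code{"continuous"} or \code{"binary"}.
#' @param h2 heritability used to derive the variance components
#'   (continuous: phenotypic variance scaled to the data variance; binary:
#'   liability scale with residual variance 1). Ignored when \code{varcomp}
#'   is supplied.
#' @param varcomp optional list \code{(sigma2_a, sigma2_e)} overriding
#'   \code{h2}. For the binary trait \code{sigma2_a} is only the starting
#'   value of the sampler.
#' @param n_iterations number of reweighting iterations (default 3).
#' @param window_size SNPs per window (default 150).
#' @param report_iteration iteration whose window report is treated as the
#'   main result (default 2).
#' @param top_k number of top windows reported (default 10).
#' @param beta blending fraction of A22 into G (default 0.05).
#' @param chain a \code{\link{chain_config}} for the binary trait.
#' @param window_method window variance definition, see
#'   \code{\link{window_variances}}.
#' @return object of class \code{"wssgblup"}; see
#'   \code{\link{print.wssgblup}}, \code{\link{summary.wssgblup}},
#'   \code{\link{coef.wssgblup}}, \code{\link{predict.wssgblup}},
#'   \code{\link{plot.wssgblup}}.
#' @export
wssgblup <- function(pheno, pedigree, genotypes,
                     trait_type = c("continuous", "binary"),
                     h2 = NULL, varcomp = NULL,
                     n_iterations = 3L, window_size = 150L,
                     report_iteration = 2L, top_k = 10L,
                     beta = 0.05, chain = chain_config(),
                     window_method = c("score_variance", "weight_share")) {
  trait_type <- match.arg(trait_type)
  window_method <- match.arg(window_method)
  if (report_iteration > n_iterations)
    stop("report_iteration exceeds n_iterations")
  pedigree <- sort_pedigree(pedigree)
  gid <- rownames(genotypes$dosages)
  gidx <- match(gid, as.character(pedigree$animal))
  if (anyNA(gidx))
    stop("genotyped animal(s) absent from pedigree: ",
         paste(utils::head(gid[is.na(gidx)], 5), collapse = ", "))

  # variance components
  if (is.null(varcomp)) {
    if (is.null(h2)) stop("supply h2 or varcomp")
    if (h2 <= 0 || h2 >= 1) stop("h2 must lie in (0, 1)")
    varcomp <- if (trait_type == "binary") {
      list(sigma2_a = h2 / (1 - h2), sigma2_e = 1)
    } else {
      vp <- stats::var(pheno$trait)
      list(sigma2_a = h2 * vp, sigma2_e = (1 - h2) * vp)
    }
  }

  # relationship machinery
  A <- build_A(pedigree)
  A_inv <- build_A_inverse(pedigree)
  A22 <- extract_A22(A, gid)
  A22_inv <- invert_G(A22)
  cg <- center_and_lambda(impute_mean(genotypes))
  m <- ncol(cg$Z)

  model <- build_model(pheno, pedigree$animal, trait_type)
  d <- rep(1, m)                              # iteration 1: D = I
  iterations <- vector("list", n_iterations)
  solution <- NULL
  a_g <- NULL
  for (t in seq_len(n_iterations)) {
    G <- build_G(cg, d)
    Gb <- blend_G(G, A22, beta)
    if (t == 1L) {
      G_inv <- invert_G(Gb)
      H_inv <- build_H_inverse(A_inv, G_inv, A22_inv, gidx)
      solution <- if (trait_type == "continuous") {
        solve_mme_linear(model, H_inv, varcomp$sigma2_a, varcomp$sigma2_e)
      } else {
        gibbs_threshold(model, H_inv, chain,
                        start_sigma2_a = varcomp$sigma2_a)
      }
      a_g <- unname(solution$a_hat[gidx])     # fixed across iterations
    }
    u_hat <- backsolve_snp_effects(cg, d, Gb, a_g)
    sigma2_a_rep <- solution$sigma2_a         # posterior mean for binary
    windows <- window_variances(u_hat, cg, window_size, sigma2_a_rep,
                                method = window_method, weights = d)
    windows$iteration <- t
    iterations[[t]] <- list(t = t, u_hat = u_hat, d = d, windows = windows)
    d <- normalize_weights(update_weights(u_hat, cg$p), m)
  }

  structure(list(iterations = iterations,
                 solution = solution,
                 top = top_windows(iterations[[report_iteration]]$windows, top_k),
                 centered = cg,
                 genotyped_ids = gid,
                 genotyped_index = gidx,
                 model = model,
                 pheno = pheno,
                 varcomp = list(sigma2_a = solution$sigma2_a,
                                sigma2_e = solution$sigma2_e),
                 settings = list(trait_type = trait_type,
                                 n_iterations = n_iterations,
                                 window_size = window_size,
                                 report_iteration = report_iteration,
                                 top_k = top_k, beta = beta,
                                 window_method = window_method,
                                 chain = if (trait_type == "binary") chain else NULL)),
            class = "wssgblup")
}

#' @describeIn wssgblup number of genotyped animals and SNPs, settings and
#'   top-window preview.
#' @param x,object a fitted \code{wssgblup} object.
#' @param ... unused.
#' @export
print.wssgblup <- function(x, ...) {
  s <- x$settings
  cat("Weighted single-step GBLUP GWAS (", s$trait_type, " trait)\n", sep = "")
  cat("  animals in pedigree: ", length(x$solution$a_hat),
      "; genotyped: ", length(x$genotyped_ids),
      "; SNPs: ", ncol(x$centered$Z), "\n", sep = "")
  cat("  iterations: ", s$n_iterations, " (reported: ", s$report_iteration,
      "); window size: ", s$window_size, " SNPs\n", sep = "")
  cat("  sigma2_a = ", format(x$varcomp$sigma2_a, digits = 4),
      ", sigma2_e = ", format(x$varcomp$sigma2_e, digits = 4), "\n", sep = "")
  cat("  top ", nrow(x$top), " windows explain ",
      format(attr(x$top, "total_percent"), digits = 4),
      "% of the additive genetic variance\n", sep = "")
  invisible(x)
}

#' @describeIn wssgblup prints the top-window table and per-iteration summary.
#' @export
summary.wssgblup <- function(object, ...) {
  print(object)
  cat("\nTop windows (iteration ", object$settings$report_iteration, "):\n", sep = "")
  print(as.data.frame(object$top), row.names = FALSE)
  cat("\nPer-iteration totals:\n")
  for (it in object$iterations) {
    cat(sprintf("  t=%d  sum(d)=%.4f  max window %%var=%.4f\n",
                it$t, sum(it$d), max(it$windows$percent_variance)))
  }
  invisible(object)
}

#' @describeIn wssgblup back-solved SNP effects at the reported iteration
#'   (set \code{iteration} to choose another).
#' @param iteration which iteration's effects/weights to return.
#' @export
coef.wssgblup <- function(object, iteration = object$settings$report_iteration, ...) {
  it <- object$iterations[[iteration]]
  data.frame(snp_id = object$centered$map$snp_id,
             chrom = object$centered$map$chrom,
             bp = object$centered$map$bp,
             u_hat = it$u_hat, d = it$d,
             iteration = it$t, stringsAsFactors = FALSE)
}

#' @describeIn wssgblup estimated breeding values; \code{which = "genotyped"}
#'   restricts to the genotyped animals.
#' @param which \code{"all"} or \code{"genotyped"}.
#' @export
predict.wssgblup <- function(object, which = c("all", "genotyped"), ...) {
  which <- match.arg(which)
  if (which == "all") object$solution$a_hat
  else object$solution$a_hat[object$genotyped_index]
}

#' @describeIn wssgblup record-level residuals y - Xb - a (continuous trait).
#' @export
residuals.wssgblup <- function(object, ...) {
  if (object$settings$trait_type != "continuous")
    stop("residuals on the observed scale are defined for the continuous trait only")
  mdl <- object$model
  as.numeric(mdl$y - mdl$X %*% object$solution$b_hat -
               mdl$W %*% object$solution$a_hat)
}

#' @describeIn wssgblup Manhattan-style plot of window variance percentages
#'   at the reported iteration.
#' @export
plot.wssgblup <- function(x, iteration = x$settings$report_iteration, ...) {
  w <- x$iterations[[iteration]]$windows
  chrs <- unique(w$chrom)
  off <- c(0, cumsum(vapply(chrs, function(c) max(w$end_bp[w$chrom == c]), 0)))
  pos <- (w$start_bp + w$end_bp) / 2 + off[match(w$chrom, chrs)]
  cols <- c("grey30", "steelblue")[1 + match(w$chrom, chrs) %% 2]
  graphics::plot(pos, w$percent_variance, pch = 19, col = cols,
                 xlab = "genome position", xaxt = "n",
                 ylab = "% additive genetic variance per window",
                 main = paste0("Window variances, iteration ", iteration), ...)
  graphics::axis(1, at = off[-length(off)] + diff(off) / 2, labels = chrs)
  invisible(x)
}
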