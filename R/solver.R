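#' Gibbs chain configuration
#'
#' Defaults: a single chain of 300,000 cycles with a conservative burn-in of
#' 30,000 cycles and a thinning interval of 30, retaining 9,000 samples.
#'
#' @param n_cycles total Gibbs cycles.
#' @param burn_in cycles discarded before retention starts.
#' @param thin retain every \code{thin}-th post-burn-in cycle.
#' @param seed integer seed for the chain.
#' @return list of class \code{"chain_config"}.
#' @export
chain_config <- function(n_cycles = 300000L, burn_in = 30000L, thin = 30L,
                         seed = 1L) {
  cc <- list(n_cycles = as.integer(n_cycles), burn_in = as.integer(burn_in),
             thin = as.integer(thin), seed = as.integer(seed))
  retained_samples(cc$n_cycles, cc$burn_in, cc$thin)  # validates
  class(cc) <- "chain_config"
  cc
}

#' Number of retained Gibbs samples
#'
#' floor((n_cycles - burn_in) / thin); the default chain
#' (300,000 / 30,000 / 30) retains exactly 9,000 samples.
#'
#' @inheritParams chain_config
#' @return integer count of retained samples.
#' @export
retained_samples <- function(n_cycles, burn_in, thin) {
  if (thin < 1) stop("thin must be >= 1")
  if (burn_in < 0 || burn_in >= n_cycles)
    stop("burn_in must satisfy 0 <= burn_in < n_cycles")
  k <- (n_cycles - burn_in) %/% thin
  if (k < 1)
    stop("chain configuration retains no samples; lengthen the chain or reduce thin")
  as.integer(k)
}

#' Build the single-trait animal model design
#'
#' Fixed effects: intercept, contemporary-group dummies (first level absorbed
#' into the intercept for identifiability) and, for the continuous trait, the
#' centered age-at-recording covariate. The random-effect incidence maps each
#' record to its animal's position in the pedigree ordering.
#'
#' @param pheno prepared phenotype data.frame (\code{animal}, \code{trait},
#'   \code{cg_id}, optional \code{age}).
#' @param animal_ids full vector of pedigree animal ids (model order).
#' @param trait_type \code{"continuous"} or \code{"binary"}.
#' @return list with \code{y}, dense \code{X} (with column names), sparse
#'   incidence \code{W} (records x animals) and \code{trait_type}.
#' @export
build_model <- function(pheno, animal_ids, trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  pos <- match(pheno$animal, animal_ids)
  if (anyNA(pos))
    stop("phenotyped animal(s) missing from pedigree: ",
         paste(utils::head(pheno$animal[is.na(pos)], 5), collapse = ", "))
  y <- as.numeric(pheno$trait)
  cg <- factor(pheno$cg_id)
  X <- matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)"))
  if (nlevels(cg) > 1) {
    Xcg <- stats::model.matrix(~ cg)[, -1, drop = FALSE]
    colnames(Xcg) <- paste0("cg:", levels(cg)[-1])
    X <- cbind(X, Xcg)
  }
  if (trait_type == "continuous" && !is.null(pheno$age) && !all(is.na(pheno$age))) {
    X <- cbind(X, age = as.numeric(pheno$age) - mean(as.numeric(pheno$age)))
  }
  W <- Matrix::sparseMatrix(i = seq_along(y), j = pos, x = 1,
                            dims = c(length(y), length(animal_ids)),
                            dimnames = list(NULL, as.character(animal_ids)))
  list(y = y, X = X, W = W, trait_type = trait_type)
}

#' Solve the single-step mixed-model equations for a continuous trait
#'
#' Solves
#' \deqn{[X'X, X'W; W'X, W'W + H^{-1} k] [b; a] = [X'y; W'y]}
#' with \eqn{k = \sigma^2_e / \sigma^2_a}, by sparse symmetric factorization.
#'
#' @param model design list from \code{\link{build_model}}.
#' @param H_inv sparse inverse relationship matrix (animals in model order).
#' @param sigma2_a additive genetic variance.
#' @param sigma2_e residual variance.
#' @return list of class \code{"bv_solution"}: \code{b_hat} (named),
#'   \code{a_hat} (named by animal), the variance components, and the relative
#'   residual of the solved system.
#' @export
solve_mme_linear <- function(model, H_inv, sigma2_a, sigma2_e) {
  if (sigma2_a <= 0) stop("sigma2_a must be > 0")
  X <- Matrix::Matrix(model$X, sparse = TRUE)
  W <- model$W
  k <- sigma2_e / sigma2_a
  XtX <- Matrix::crossprod(X)
  qrX <- qr(model$X)
  if (qrX$rank < ncol(model$X)) {
    dropped <- colnames(model$X)[qrX$pivot[(qrX$rank + 1):ncol(model$X)]]
    stop("fixed-effect design is rank deficient; confounded column(s): ",
         paste(dropped, collapse = ", "))
  }
  C <- rbind(cbind(XtX, Matrix::crossprod(X, W)),
             cbind(Matrix::crossprod(W, X), Matrix::crossprod(W) + k * H_inv))
  r <- c(as.numeric(Matrix::crossprod(X, model$y)),
         as.numeric(Matrix::crossprod(W, model$y)))
  sol <- as.numeric(Matrix::solve(Matrix::forceSymmetric(C), r))
  p <- ncol(X)
  resid <- as.numeric(C %*% sol) - r
  structure(list(b_hat = stats::setNames(sol[seq_len(p)], colnames(model$X)),
                 a_hat = stats::setNames(sol[-seq_len(p)], colnames(W)),
                 sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                 trait_type = "continuous",
                 mme_relative_residual = sqrt(sum(resid^2)) / max(sqrt(sum(r^2)), 1e-300)),
            class = "bv_solution")
}

## Draw from truncated standard-normal-location model: l ~ N(eta, 1) truncated
## to (0, Inf) when y = 1 and (-Inf, 0] when y = 0. Inverse-cdf method.
.draw_liability <- function(eta, y) {
  p0 <- stats::pnorm(0, mean = eta)           # P(l <= 0)
  u <- stats::runif(length(eta))
  q <- ifelse(y == 1, p0 + u * (1 - p0), u * p0)
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  stats::qnorm(q, mean = eta)
}

#' Liability-threshold Gibbs sampler for a binary trait
#'
#' Data-augmentation sampler for the threshold animal model: the binary record
#' is 1 when an unobserved normal liability exceeds 0 (the threshold is fixed
#' at 0 and the intercept is free, an equivalent parameterization). Residual
#' liability variance is fixed at 1 since it is not identifiable. Each cycle
#' draws (1) liabilities from truncated normals given the observed category,
#' (2) all location effects (b, a) jointly from their multivariate-normal full
#' conditional via a sparse Cholesky factorization, and (3) the additive
#' variance from its scaled inverse chi-square full conditional using the
#' quadratic form a' H^-1 a. Priors are flat for fixed effects and a flat
#' scaled inverse chi-square (nu = -2, S = 0) for the additive variance.
#'
#' @param model design list from \code{\link{build_model}} (binary trait).
#' @param H_inv sparse inverse relationship matrix, animals in model order.
#' @param chain a \code{\link{chain_config}}.
#' @param start_sigma2_a starting value for the additive variance.
#' @param fix_sigma2_a if non-NULL, the additive variance is held at this
#'   value instead of being sampled (variance treated as a known input).
#' @param keep_chain if TRUE the retained \code{sigma2_a} draws are returned.
#' @return list of class \code{"bv_solution"} with posterior means
#'   \code{b_hat}, \code{a_hat}, posterior mean/SD of \code{sigma2_a}
#'   (\code{sigma2_a}, \code{sigma2_a_sd}), posterior SDs of \code{a_hat},
#'   number of retained samples, and optionally the variance chain.
#' @export
gibbs_threshold <- function(model, H_inv, chain = chain_config(),
                            start_sigma2_a = 0.5, fix_sigma2_a = NULL,
                            keep_chain = TRUE) {
  if (!all(model$y %in% c(0, 1)))
    stop("gibbs_threshold requires a 0/1 response")
  n_keep <- retained_samples(chain$n_cycles, chain$burn_in, chain$thin)
  # monomorphic-CG drift check: any fixed-effect class (including the
  # reference level) observed in one response category only
  dums <- model$X[, -1, drop = FALSE] != 0
  grp <- if (ncol(dums) > 0) apply(dums, 1, function(r) paste(which(r), collapse = "+"))
         else rep("", nrow(model$X))
  cls <- tapply(model$y, grp, mean)
  if (length(cls) > 1 && any(cls %in% c(0, 1)))
    warning("fixed-effect class with all-0 or all-1 records; ",
            "its solution will drift (prepare_phenotypes should have removed it)")
  set.seed(chain$seed)

  X <- Matrix::Matrix(model$X, sparse = TRUE)
  W <- model$W
  M <- cbind(X, W)
  p <- ncol(X); n_a <- ncol(W)
  C0 <- Matrix::forceSymmetric(Matrix::crossprod(M))
  K <- Matrix::forceSymmetric(
    Matrix::bdiag(Matrix::Diagonal(p, 0), H_inv))
  # fixed sparsity pattern: symbolic factorization reused every cycle
  sigma2_a <- if (is.null(fix_sigma2_a)) start_sigma2_a else fix_sigma2_a
  Cs <- methods::as(C0 + (1 / sigma2_a) * K, "CsparseMatrix")
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Cs), LDL = FALSE, super = TRUE)

  theta <- numeric(p + n_a)
  l <- .draw_liability(rep(0, length(model$y)), model$y)
  sum_theta <- numeric(p + n_a)
  sumsq_theta <- numeric(p + n_a)
  sum_s2 <- 0; sumsq_s2 <- 0
  s2_chain <- if (keep_chain) numeric(n_keep) else NULL
  kept <- 0L

  for (cyc in seq_len(chain$n_cycles)) {
    Cs <- Matrix::forceSymmetric(C0 + (1 / sigma2_a) * K)
    ch <- update(ch, Cs)
    r <- as.numeric(Matrix::crossprod(M, l))
    mu <- as.numeric(Matrix::solve(ch, r, system = "A"))
    z <- stats::rnorm(p + n_a)
    dev <- as.numeric(Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"),
                                    system = "Pt"))
    theta <- mu + dev
    eta <- as.numeric(M %*% theta)
    l <- .draw_liability(eta, model$y)
    if (is.null(fix_sigma2_a)) {
      a <- theta[(p + 1):(p + n_a)]
      q <- as.numeric(a %*% (H_inv %*% a))
      df <- n_a - 2                     # flat scaled inv-chi-square prior
      sigma2_a <- q / stats::rchisq(1, df = df)
    }
    if (cyc > chain$burn_in && (cyc - chain$burn_in) %% chain$thin == 0L) {
      kept <- kept + 1L
      sum_theta <- sum_theta + theta
      sumsq_theta <- sumsq_theta + theta^2
      sum_s2 <- sum_s2 + sigma2_a
      sumsq_s2 <- sumsq_s2 + sigma2_a^2
      if (keep_chain) s2_chain[kept] <- sigma2_a
    }
  }
  post_mean <- sum_theta / kept
  post_sd <- sqrt(pmax(sumsq_theta / kept - post_mean^2, 0))
  structure(list(b_hat = stats::setNames(post_mean[seq_len(p)], colnames(model$X)),
                 a_hat = stats::setNames(post_mean[-seq_len(p)], colnames(W)),
                 a_hat_sd = stats::setNames(post_sd[-seq_len(p)], colnames(W)),
                 sigma2_a = sum_s2 / kept,
                 sigma2_a_sd = sqrt(max(sumsq_s2 / kept - (sum_s2 / kept)^2, 0)),
                 sigma2_e = 1,
                 trait_type = "binary",
                 n_retained = kept,
                 sigma2_a_chain = s2_chain),
            class = "bv_solution")
}

#' @export
print.bv_solution <- function(x, ...) {
  cat("Breeding-value solution (", x$trait_type, " trait)\n", sep = "")
  cat("  fixed effects: ", length(x$b_hat), "\n", sep = "")
  cat("  animals:       ", length(x$a_hat), "\n", sep = "")
  cat("  sigma2_a = ", format(x$sigma2_a, digits = 4),
      ", sigma2_e = ", format(x$sigma2_e, digits = 4), "\n", sep = "")
  if (!is.null(x$n_retained))
    cat("  posterior means from ", x$n_retained, " retained Gibbs samples\n", sep = "")
  invisible(x)
}
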