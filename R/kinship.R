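## Pedigree utilities ---------------------------------------------------------

## Validate and index a pedigree data.frame (animal, sire, dam; 0 = unknown).
## Returns parents as positions in record order (0 = unknown).
.ped_index <- function(pedigree) {
  an <- pedigree$animal
  if (anyDuplicated(an)) stop("duplicate animal ids in pedigree")
  pos <- function(p) {
    out <- integer(length(p))
    known <- p != 0
    out[known] <- match(p[known], an)
    if (any(known & is.na(out)))
      stop("unknown id referenced as parent: ",
           paste(unique(p[known][is.na(out[known])]), collapse = ", "))
    out
  }
  s <- pos(pedigree$sire)
  d <- pos(pedigree$dam)
  if (any(s >= seq_along(an) & s > 0) || any(d >= seq_along(an) & d > 0))
    stop("pedigree not sorted parents-first; use sort_pedigree()")
  list(animal = an, sire = s, dam = d, n = length(an))
}

#' Topologically sort a pedigree parents-first
#'
#' @param pedigree data.frame with \code{animal}, \code{sire}, \code{dam}
#'   (0 = unknown parent).
#' @return the pedigree re-ordered so every parent precedes its offspring.
#' @export
sort_pedigree <- function(pedigree) {
  n <- nrow(pedigree)
  placed <- logical(n)
  ord <- integer(0)
  an <- pedigree$animal
  repeat {
    ready <- !placed &
      (pedigree$sire == 0 | pedigree$sire %in% an[placed]) &
      (pedigree$dam == 0 | pedigree$dam %in% an[placed])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed))
    stop("pedigree contains a cycle or a parent with no own record: ",
         paste(utils::head(an[!placed], 5), collapse = ", "))
  out <- pedigree[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds A by the tabular method with inbreeding: the diagonal is 1 + F_i
#' where F_i is half the relationship between the parents, and off-diagonals
#' follow the parent-average recursion. O(n^2) memory.
#'
#' @param pedigree parents-first pedigree data.frame.
#' @return dense symmetric matrix with animal ids as dimnames and attribute
#'   \code{role = "A"}.
#' @export
build_A <- function(pedigree) {
  px <- .ped_index(pedigree)
  n <- px$n
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- px$sire[i]; d <- px$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[s, j]
      if (d > 0L) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(px$animal, px$animal)
  attr(A, "role") <- "A"
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' F_i = a(sire, dam) / 2 computed by the recursive kinship formula with
#' memoisation; animals with an unknown parent have F = 0.
#'
#' @param pedigree parents-first pedigree data.frame.
#' @return numeric vector of inbreeding coefficients, named by animal id.
#' @export
inbreeding <- function(pedigree) {
  px <- .ped_index(pedigree)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  kin <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (i == j) {
      0.5 * (1 + kin(px$sire[i], px$dam[i]))
    } else {
      0.5 * (kin(i, px$sire[j]) + kin(i, px$dam[j]))
    }
    memo[[key]] <- v
    v
  }
  f <- vapply(seq_len(px$n), function(i) {
    s <- px$sire[i]; d <- px$dam[i]
    if (s == 0L || d == 0L) 0 else kin(s, d)
  }, numeric(1))
  stats::setNames(f, px$animal)
}

#' Sparse inverse of the pedigree relationship matrix
#'
#' Assembled directly by Henderson's rules with inbreeding: each animal
#' contributes 1/m_i to its own diagonal and the standard -1/2 and 1/4 shares
#' to parent entries, where the Mendelian sampling variance m_i accounts for
#' parental inbreeding.
#'
#' @param pedigree parents-first pedigree data.frame.
#' @return sparse symmetric \code{\link[Matrix]{dsCMatrix}} with animal ids as
#'   dimnames.
#' @export
build_A_inverse <- function(pedigree) {
  px <- .ped_index(pedigree)
  f <- unname(inbreeding(pedigree))
  n <- px$n
  ti <- tj <- tx <- vector("list", n)
  for (i in seq_len(n)) {
    s <- px$sire[i]; d <- px$dam[i]
    mi <- if (s > 0L && d > 0L) 0.5 - 0.25 * (f[s] + f[d])
          else if (s > 0L) 0.75 - 0.25 * f[s]
          else if (d > 0L) 0.75 - 0.25 * f[d]
          else 1
    a <- 1 / mi
    par <- c(s, d); par <- par[par > 0L]
    tI <- i; tJ <- i; tX <- a
    for (p in par) {
      tI <- c(tI, i, p); tJ <- c(tJ, p, i); tX <- c(tX, -a / 2, -a / 2)
    }
    for (p in par) for (q in par) {
      tI <- c(tI, p); tJ <- c(tJ, q); tX <- c(tX, a / 4)
    }
    ti[[i]] <- tI; tj[[i]] <- tJ; tx[[i]] <- tX
  }
  M <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(n, n),
                            dimnames = list(as.character(px$animal),
                                            as.character(px$animal)))
  Matrix::forceSymmetric(M)
}

#' Pedigree relationships among the genotyped animals
#'
#' Principal submatrix of A on the genotyped ids, in the genotype-matrix
#' sample order.
#'
#' @param A_source dense A from \code{\link{build_A}} (ids as dimnames).
#' @param genotyped_ids character or integer ids of genotyped animals.
#' @return dense matrix A22 with attribute \code{role = "A22"}.
#' @export
extract_A22 <- function(A_source, genotyped_ids) {
  ids <- as.character(genotyped_ids)
  miss <- setdiff(ids, rownames(A_source))
  if (length(miss) > 0)
    stop("genotyped id(s) not in pedigree: ", paste(utils::head(miss, 5), collapse = ", "))
  A22 <- A_source[ids, ids, drop = FALSE]
  attr(A22, "role") <- "A22"
  A22
}

## Genomic matrices -----------------------------------------------------------

#' Center genotypes and compute the VanRaden normalizing constant
#'
#' Z = M - P where P holds twice the observed frequency of the counted allele
#' per SNP, and lambda = 1 / sum(2 p_i (1 - p_i)) is the ratio of the per-SNP
#' to the total additive variance used to scale G.
#'
#' @param genotypes a QC'd \code{geno_matrix} with no missing dosages (run
#'   \code{\link{impute_mean}} first).
#' @param p optional externally known allele frequencies; by default they are
#'   estimated from the genotyped animals themselves. Note that with
#'   data-estimated frequencies the columns of Z sum to zero, so G is always
#'   rank deficient and needs blending before inversion.
#' @return object of class \code{"centered_geno"}: list with \code{Z}
#'   (n x m), \code{p} (allele frequencies), \code{lambda}, and the SNP
#'   \code{map}.
#' @export
center_and_lambda <- function(genotypes, p = NULL) {
  dos <- genotypes$dosages
  if (anyNA(dos)) stop("missing dosages present; run impute_mean() first")
  if (is.null(p)) p <- colMeans(dos) / 2
  if (length(p) != ncol(dos)) stop("one allele frequency per SNP required")
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNP present (p = 0 or 1); run quality control first")
  Z <- sweep(dos, 2, 2 * p, `-`)
  structure(list(Z = Z, p = unname(p),
                 lambda = 1 / sum(2 * p * (1 - p)),
                 map = genotypes$map),
            class = "centered_geno")
}

#' Weighted genomic relationship matrix
#'
#' G = Z D Z' lambda, the VanRaden genomic relationship matrix with diagonal
#' SNP-variance weights D.
#'
#' @param cg a \code{centered_geno} from \code{\link{center_and_lambda}}.
#' @param weights vector of m SNP weights (diagonal of D); defaults to 1.
#' @return dense symmetric matrix with attribute \code{role = "G"}.
#' @export
build_G <- function(cg, weights = NULL) {
  m <- ncol(cg$Z)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) stop("dimension mismatch: need one weight per SNP")
  if (any(weights < 0)) stop("SNP weights must be non-negative")
  ZD <- sweep(cg$Z, 2, weights, `*`)
  G <- tcrossprod(ZD, cg$Z) * cg$lambda
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(cg$Z), rownames(cg$Z))
  attr(G, "role") <- "G"
  G
}

#' Blend G with the pedigree relationships of the genotyped animals
#'
#' Returns (1 - beta) G + beta A22. Raw G is singular whenever the number of
#' genotyped animals exceeds its effective rank, so a small pedigree admixture
#' keeps it invertible; beta = 0 returns G unchanged.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationships of the same animals, same order.
#' @param beta blending fraction in [0, 1).
#' @return blended matrix with attribute \code{role = "G_blended"}.
#' @export
blend_G <- function(G, A22, beta = 0.05) {
  if (beta < 0 || beta >= 1) stop("beta must lie in [0, 1)")
  if (!all(dim(G) == dim(A22))) stop("index mismatch: G and A22 differ in size")
  if (!is.null(rownames(G)) && !is.null(rownames(A22)) &&
      !identical(rownames(G), rownames(A22)))
    stop("index mismatch: G and A22 are ordered differently")
  if (beta == 0) return(G)
  Gb <- (1 - beta) * G + beta * A22
  attr(Gb, "role") <- "G_blended"
  Gb
}

#' Inverse of the single-step relationship matrix H
#'
#' H^-1 = A^-1 plus the correction (G^-1 - A22^-1) added into the genotyped
#' block; the pedigree part stays sparse and only the genotyped block is
#' dense.
#'
#' @param A_inv sparse pedigree inverse from \code{\link{build_A_inverse}}.
#' @param G_inv inverse of the (blended) genomic matrix, genotyped order.
#' @param A22_inv inverse of A22, same order as \code{G_inv}.
#' @param genotyped_index positions of the genotyped animals within the
#'   A_inv ordering, aligned with the rows of \code{G_inv}.
#' @return sparse symmetric H^-1 (\code{Matrix} class).
#' @export
build_H_inverse <- function(A_inv, G_inv, A22_inv, genotyped_index) {
  ng <- length(genotyped_index)
  if (ng == 0) return(A_inv)
  if (!all(dim(G_inv) == c(ng, ng)) || !all(dim(A22_inv) == c(ng, ng)))
    stop("genotyped block dimensions do not match genotyped_index")
  H <- methods::as(A_inv, "generalMatrix")
  H[genotyped_index, genotyped_index] <-
    H[genotyped_index, genotyped_index] + (G_inv - A22_inv)
  Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
}

#' Invert a (blended) genomic relationship matrix
#'
#' Cholesky-based inverse with a clear error when G is numerically singular.
#'
#' @param G symmetric positive definite matrix.
#' @return the inverse, symmetric.
#' @export
invert_G <- function(G) {
  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(ch))
    stop("G is singular or indefinite; blend with A22 first (blend_G)")
  Gi <- chol2inv(ch)
  dimnames(Gi) <- dimnames(G)
  (Gi + t(Gi)) / 2
}
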