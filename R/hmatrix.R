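#' Blend a genomic relationship matrix toward pedigree expectations
#'
#' Convex combination `theta * G + (1 - theta) * A22`. Blending shrinks
#' realized genomic relationships toward pedigree expectations; because
#' the minimum eigenvalue of the blend is at least the corresponding
#' convex combination of the two minima (Weyl), theta < 1 also repairs
#' mildly non-positive-definite G.
#'
#' @param G genomic relationship matrix over the genotyped individuals.
#' @param A22 pedigree relationship block over the same individuals, same
#'   order.
#' @param theta blending weight in \[0, 1\]; 1 leaves G unchanged, 0
#'   returns A22.
#' @return blended matrix (plain numeric matrix, id dimnames preserved).
#' @export
blend_grm <- function(G, A22, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 1)
    stop("theta must be a single value in [0, 1]")
  check_conformable(G, A22)
  out <- theta * unclass(G) + (1 - theta) * unclass(A22)
  dimnames(out) <- dimnames(G)
  out
}

#' Tune a genomic relationship matrix to the pedigree base population
#'
#' Affine adjustment `beta * G + omega * J` (J = all-ones) matching
#' moments of G to the pedigree block A22, compensating for allele
#' frequencies estimated from genotyped individuals rather than the
#' (unobserved) base population.
#'
#' * `method = 1` (Christensen-style moment matching): beta matches the
#'   diagonal/off-diagonal mean contrast,
#'   `beta = (mean(diag A22) - mean(A22)) / (mean(diag G) - mean(G))`,
#'   `omega = mean(A22) - beta * mean(G)`; afterwards both the overall
#'   mean and the diagonal mean of the tuned matrix equal those of A22.
#' * `method = 2` (Vitezica-style): `beta = 1`,
#'   `omega = mean(A22) - mean(G)`; only the overall mean is matched.
#'
#' All means are over all n^2 entries.
#'
#' @param G (blended) genomic relationship matrix.
#' @param A22 pedigree block, same individuals and order.
#' @param method 1 or 2.
#' @return the tuned matrix with attributes `omega` and `beta`.
#' @export
tune_grm <- function(G, A22, method) {
  check_conformable(G, A22)
  if (!method %in% c(1, 2)) stop("tuning method must be 1 or 2")
  G <- unclass(G); A22 <- unclass(A22)
  mA <- mean(A22); mG <- mean(G)
  if (method == 1) {
    denom <- mean(diag(G)) - mG
    if (abs(denom) < 1e-12)
      stop("tune method 1 degenerate (mean diagonal equals overall mean); ",
           "use method 2")
    beta <- (mean(diag(A22)) - mA) / denom
    omega <- mA - beta * mG
  } else {
    beta <- 1
    omega <- mA - mG
  }
  out <- beta * G + omega
  dimnames(out) <- dimnames(G)
  structure(out, omega = omega, beta = beta)
}

#' Apply blending and tuning in a chosen order
#'
#' Convenience wrapper producing the adjusted genomic matrix that enters
#' the H matrix. The default order tunes the blended matrix; the reverse
#' order is available because the two do not commute in general.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree block over the genotyped individuals.
#' @param theta blending weight (default 1 = no blending).
#' @param tune tuning method: 0 none (default), 1 or 2.
#' @param order `"blend_then_tune"` (default) or `"tune_then_blend"`.
#' @return adjusted matrix with attribute `provenance` (list of the
#'   hyper-parameters applied).
#' @export
adjust_grm <- function(G, A22, theta = 1, tune = 0,
                       order = c("blend_then_tune", "tune_then_blend")) {
  order <- match.arg(order)
  out <- unclass(G)
  if (order == "blend_then_tune") {
    out <- blend_grm(out, A22, theta)
    if (tune != 0) out <- tune_grm(out, A22, tune)
  } else {
    if (tune != 0) out <- tune_grm(out, A22, tune)
    out <- blend_grm(out, A22, theta)
  }
  attr(out, "provenance") <- list(alpha = attr(G, "alpha"), theta = theta,
                                  tune = tune, order = order)
  out
}

#' Assemble the single-step H relationship matrix
#'
#' Combines pedigree and (adjusted) genomic relationships over all
#' pedigree individuals:
#'
#'   `H11 = A11 + A12 A22^-1 (G - A22) A22^-1 A21`
#'   `H12 = A12 A22^-1 G`,  `H21 = H12'`,  `H22 = G`
#'
#' so the genotyped block equals G exactly and H collapses to A when
#' G = A22. Individuals are ordered non-genotyped first, genotyped second.
#'
#' @param blocks partition from [partition_nrm].
#' @param G_adj adjusted genomic matrix over `blocks$genotyped_ids`
#'   (same order).
#' @param warn_indefinite emit a warning when the smallest eigenvalue of
#'   `G_adj` is below -1e-8 (the REML solver tolerates an indefinite H,
#'   but it is worth knowing about). Default TRUE.
#' @return object of class `hmatrix`: symmetric matrix over all ids with
#'   attribute `provenance` carried over from `G_adj`, plus
#'   `genotyped_ids`.
#' @export
assemble_h <- function(blocks, G_adj, warn_indefinite = TRUE) {
  gid <- blocks$genotyped_ids
  G_adj <- unclass(G_adj)
  if (!is.null(rownames(G_adj)) && !identical(rownames(G_adj), gid))
    stop("G_adj ids misaligned with the genotyped partition")
  if (nrow(G_adj) != nrow(blocks$A22))
    stop("G_adj and A22 dimensions differ")
  if (warn_indefinite && nrow(G_adj) > 0L) {
    ev <- eigen(G_adj, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      warning("adjusted G is not positive definite (min eigenvalue ",
              signif(min(ev), 3), "); direct AI-REML tolerates this")
  }
  n1 <- length(blocks$nongenotyped_ids); n2 <- length(gid)
  ids <- c(blocks$nongenotyped_ids, gid)
  H <- matrix(0, n1 + n2, n1 + n2, dimnames = list(ids, ids))
  if (n2 == 0L) {
    H[] <- blocks$A11
    return(structure(H, class = c("hmatrix", "matrix", "array"),
                     genotyped_ids = gid,
                     provenance = attr(G_adj, "provenance")))
  }
  if (n1 > 0L) {
    cf <- chol(blocks$A22)
    # M = A12 %*% A22^-1  (n1 x n2)
    M <- t(backsolve(cf, backsolve(cf, t(blocks$A12), transpose = TRUE)))
    D <- G_adj - blocks$A22
    H11 <- blocks$A11 + M %*% D %*% t(M)
    H12 <- M %*% G_adj
    H[1:n1, 1:n1] <- (H11 + t(H11)) / 2
    H[1:n1, (n1 + 1):(n1 + n2)] <- H12
    H[(n1 + 1):(n1 + n2), 1:n1] <- t(H12)
  }
  H[(n1 + 1):(n1 + n2), (n1 + 1):(n1 + n2)] <- G_adj
  structure(H, class = c("hmatrix", "matrix", "array"),
            genotyped_ids = gid, provenance = attr(G_adj, "provenance"))
}

#' Build the H matrix from pedigree, genotypes and hyper-parameters
#'
#' One-call pipeline: NRM partition around the genotyped individuals,
#' GRM at the requested scale factor, blending/tuning, H assembly.
#'
#' @param A numerator relationship matrix (from [build_nrm]).
#' @param gm a [genotype_matrix] over a subset of the pedigree ids.
#' @param alpha GRM scale factor (default -0.5).
#' @param theta blending weight (default 1).
#' @param tune tuning method 0/1/2 (default 0).
#' @param order adjustment order, see [adjust_grm].
#' @param normalization GRM normalization, see [compute_grm].
#' @return an `hmatrix` over all pedigree ids.
#' @export
build_hmatrix <- function(A, gm, alpha = -0.5, theta = 1, tune = 0,
                          order = "blend_then_tune",
                          normalization = "empirical") {
  blocks <- partition_nrm(A, gm$ids)
  G <- compute_grm(gm, alpha = alpha, normalization = normalization)
  G_adj <- adjust_grm(G, blocks$A22, theta = theta, tune = tune,
                      order = order)
  assemble_h(blocks, G_adj, warn_indefinite = FALSE)
}

check_conformable <- function(G, A22) {
  if (!identical(dim(unclass(G)), dim(unclass(A22))))
    stop("matrices are not conformable")
  if (!is.null(rownames(G)) && !is.null(rownames(A22)) &&
      !identical(rownames(G), rownames(A22)))
    stop("matrix id orders differ")
  invisible(TRUE)
}
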