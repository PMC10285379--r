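#' Genomic relationship matrix with allele-frequency scale factor
#'
#' Computes the GRM parameterized by the scale factor alpha, which sets
#' how per-allele effect size is assumed to relate to allele frequency
#' (effects proportional to `[2p(1-p)]^alpha`):
#'
#'   `G_ij = (1/d) * sum_k (x_ik - 2 p_k) (x_jk - 2 p_k) [2 p_k (1 - p_k)]^(2 alpha)`
#'
#' `alpha = -0.5` reproduces the GCTA/PLINK estimator (each SNP
#' standardized to unit variance); `alpha = 0` is VanRaden method 1
#' (frequency-independent effects). The normalization `d` is either
#' *empirical* — the mean over individuals of the weighted squared
#' centered genotypes, so that `trace(G)/n = 1` exactly — or
#' *theoretical* — `sum_k [2 p_k (1 - p_k)]^(1 + 2 alpha)`, the
#' Hardy-Weinberg expectation of the diagonal.
#'
#' Monomorphic SNPs (undefined weight for negative alpha) are dropped with
#' a message; missing genotypes are mean-imputed to `2 p_k` before
#' centering.
#'
#' @param gm a [genotype_matrix].
#' @param alpha scale factor, a real number (grid searches typically use
#'   \[-1, 1\]).
#' @param normalization `"empirical"` (default; trace/n = 1) or
#'   `"theoretical"` (HWE expectation, matches GCTA at alpha = -0.5).
#' @param freqs optional per-SNP allele frequencies (e.g. base-population
#'   estimates); default computes them in-sample via
#'   [allele_frequencies].
#' @return object of class `grm`: symmetric numeric matrix over the
#'   genotyped ids, with attributes `alpha`, `d`, `freq_source`,
#'   `n_snps_used`.
#' @export
compute_grm <- function(gm, alpha = -0.5,
                        normalization = c("empirical", "theoretical"),
                        freqs = NULL) {
  normalization <- match.arg(normalization)
  n <- nrow(gm$counts)
  if (n < 2L) stop("need at least 2 genotyped individuals")
  freq_source <- if (is.null(freqs)) "in-sample" else "supplied"
  p <- if (is.null(freqs)) allele_frequencies(gm) else freqs
  if (length(p) != ncol(gm$counts))
    stop("frequency vector length does not match SNP count")
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    message("dropping ", sum(mono), " monomorphic SNP(s) from GRM")
    if (all(mono)) stop("all SNPs monomorphic; GRM undefined")
  }
  X <- gm$counts[, !mono, drop = FALSE]
  p <- p[!mono]
  # mean-impute missing to 2p, then center
  if (anyNA(X)) {
    miss <- which(is.na(X))
    ci <- (miss - 1L) %/% nrow(X) + 1L
    X[miss] <- 2 * p[ci]
  }
  W <- sweep(X, 2L, 2 * p, "-")
  het <- 2 * p * (1 - p)
  Ww <- sweep(W, 2L, het^alpha, "*")
  G <- tcrossprod(Ww)
  d <- switch(normalization,
              empirical = mean(diag(G)),
              theoretical = sum(het^(1 + 2 * alpha)))
  if (!is.finite(d) || d <= 0) stop("degenerate GRM normalization (d <= 0)")
  G <- G / d
  dimnames(G) <- list(gm$ids, gm$ids)
  structure(G, class = c("grm", "matrix", "array"), alpha = alpha, d = d,
            freq_source = freq_source, n_snps_used = length(p))
}

#' Write a relationship matrix in GCTA binary GRM format
#'
#' Writes `prefix.grm.bin` (lower triangle, row-wise, little-endian
#' 4-byte floats), `prefix.grm.id` (two-column text: family id repeated as
#' individual id) and `prefix.grm.N.bin` (per-pair SNP count, 4-byte
#' floats).
#'
#' @param K relationship matrix with id dimnames.
#' @param prefix output path prefix.
#' @param n_snps number of SNPs underlying K (recycled over pairs).
#' @export
write_grm_gcta <- function(K, prefix, n_snps = 1L) {
  n <- nrow(K)
  # GCTA stores row i, columns 1..i; column-major upper.tri of t(K) yields it
  lower <- t(K)[upper.tri(K, diag = TRUE)]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4L, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(n_snps), length(lower)), con, size = 4L,
           endian = "little")
  close(con)
  utils::write.table(data.frame(rownames(K), rownames(K)),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GCTA binary GRM
#' @param prefix path prefix of `.grm.bin` / `.grm.id`.
#' @return symmetric numeric matrix with id dimnames.
#' @export
read_grm_gcta <- function(prefix) {
  idf <- utils::read.table(paste0(prefix, ".grm.id"),
                           colClasses = "character")
  n <- nrow(idf)
  m <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = m, size = 4L,
                  endian = "little")
  K <- matrix(0, n, n, dimnames = list(idf[[2L]], idf[[2L]]))
  K[upper.tri(K, diag = TRUE)] <- vals   # fills t(K)'s lower rows
  K <- t(K)
  K[upper.tri(K)] <- t(K)[upper.tri(K)]
  K
}
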