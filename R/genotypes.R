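#' Construct a genotype matrix
#'
#' Container for additive SNP genotypes coded 0/1/2 (count of the counted
#' allele), with `NA` for missing calls.
#'
#' @param counts integer/numeric matrix, individuals x SNPs, values in
#'   {0, 1, 2, NA}.
#' @param ids individual identifiers (default rownames).
#' @param snp_ids SNP identifiers (default colnames or SNP1..SNPL).
#' @return object of class `genotype_matrix`: list with `counts`, `ids`,
#'   `snp_ids`.
#' @export
genotype_matrix <- function(counts, ids = rownames(counts),
                            snp_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  ok <- counts %in% c(0, 1, 2) | is.na(counts)
  if (!all(ok)) stop("genotype counts must be 0, 1, 2 or NA")
  if (is.null(ids)) ids <- as.character(seq_len(nrow(counts)))
  if (is.null(snp_ids)) snp_ids <- paste0("SNP", seq_len(ncol(counts)))
  dimnames(counts) <- list(ids, snp_ids)
  structure(list(counts = counts, ids = as.character(ids),
                 snp_ids = as.character(snp_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$counts), "individuals x",
      ncol(x$counts), "SNPs;",
      sum(is.na(x$counts)), "missing calls\n")
  invisible(x)
}

#' Per-SNP allele frequencies
#'
#' Frequency of the counted allele, `p_k = sum(counts) / (2 * n)` over
#' non-missing genotypes per SNP. Monomorphic SNPs (p = 0 or 1) are
#' flagged in the `"monomorphic"` attribute.
#'
#' @param gm a [genotype_matrix].
#' @return numeric vector of frequencies, names = SNP ids, attribute
#'   `monomorphic` = logical vector.
#' @export
allele_frequencies <- function(gm) {
  nonmiss <- colSums(!is.na(gm$counts))
  if (any(nonmiss == 0L))
    stop("SNP(s) with all genotypes missing: ",
         paste(gm$snp_ids[nonmiss == 0L], collapse = ", "))
  p <- colSums(gm$counts, na.rm = TRUE) / (2 * nonmiss)
  names(p) <- gm$snp_ids
  attr(p, "monomorphic") <- p <= 0 | p >= 1
  p
}

#' Write genotypes in PLINK .raw (additive) format
#'
#' Header `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP
#' (suffix `_A` marking the counted allele), additive 0/1/2 coding, `NA`
#' for missing.
#'
#' @param gm a [genotype_matrix].
#' @param path output file.
#' @export
write_plink_raw <- function(gm, path) {
  n <- length(gm$ids)
  d <- data.frame(FID = gm$ids, IID = gm$ids, PAT = 0L, MAT = 0L,
                  SEX = 0L, PHENOTYPE = -9L, check.names = FALSE)
  g <- as.data.frame(gm$counts)
  names(g) <- paste0(gm$snp_ids, "_A")
  utils::write.table(cbind(d, g), path, sep = " ", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read PLINK .raw additive genotypes
#'
#' @param path a `.raw` file as produced by `plink --recode A` (or
#'   [write_plink_raw]).
#' @return a [genotype_matrix]; IID column becomes the individual ids and
#'   the allele suffix is stripped from SNP names.
#' @export
read_plink_raw <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  d <- utils::read.table(path, header = TRUE, check.names = FALSE,
                         na.strings = c("NA", "-9"))
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(fixed %in% names(d)[1:6]))
    stop("not a PLINK .raw file (missing FID/IID header): ", path)
  g <- as.matrix(d[, -(1:6), drop = FALSE])
  storage.mode(g) <- "double"
  snp <- sub("_[ACGT0-9]+$", "", colnames(g))
  genotype_matrix(g, ids = as.character(d$IID), snp_ids = snp)
}

#' Write genotypes in PLINK binary format (.bed/.bim/.fam)
#'
#' SNP-major .bed layout: magic bytes 0x6c 0x1b 0x01, then per SNP
#' ceiling(n/4) bytes, two bits per individual (00 = two counted alleles
#' i.e. count 2, 10 = het, 11 = count 0, 01 = missing). The .bim map uses
#' dummy chromosome/position unless a `map` data.frame (chr, pos) is given.
#'
#' @param gm a [genotype_matrix].
#' @param prefix output path prefix (writes prefix.bed/.bim/.fam).
#' @param map optional data.frame with columns `chr` and `pos` per SNP.
#' @export
write_plink_bed <- function(gm, prefix, map = NULL) {
  n <- length(gm$ids); L <- length(gm$snp_ids)
  fam <- data.frame(gm$ids, gm$ids, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (is.null(map)) map <- data.frame(chr = 1L, pos = seq_len(L))
  bim <- data.frame(map$chr, gm$snp_ids, 0L, map$pos, "A", "C")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  # 2-bit codes per genotype count: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(3L, n, L)                       # count 0
  code[gm$counts == 1] <- 2L
  code[gm$counts == 2] <- 0L
  code[is.na(gm$counts)] <- 1L
  nbytes <- ceiling(n / 4)
  pad <- nbytes * 4L - n
  if (pad > 0L) code <- rbind(code, matrix(0L, pad, L))
  shifts <- c(1L, 4L, 16L, 64L)
  dim(code) <- c(4L, nbytes * L)
  bytes <- as.raw(colSums(code * shifts))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  invisible(prefix)
}

#' Read PLINK binary genotypes (.bed/.bim/.fam)
#'
#' @param prefix path prefix of the `.bed`, `.bim` and `.fam` files.
#' @return a [genotype_matrix] counting the A1 allele of the .bim file.
#' @export
read_plink_bed <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  for (f in paste0(prefix, c(".bed", ".bim", ".fam")))
    if (!file.exists(f)) stop("PLINK file not found: ", f)
  fam <- utils::read.table(paste0(prefix, ".fam"), colClasses = "character")
  bim <- utils::read.table(paste0(prefix, ".bim"), colClasses = "character")
  n <- nrow(fam); L <- nrow(bim)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file: ", bed)
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed supported: ", bed)
  raw <- raw[-(1:3)]
  nbytes <- ceiling(n / 4)
  stopifnot(length(raw) == nbytes * L)
  ints <- as.integer(raw)
  two_bits <- rbind(ints %% 4L, ints %/% 4L %% 4L,
                    ints %/% 16L %% 4L, ints %/% 64L)
  dim(two_bits) <- c(4L * nbytes, L)
  two_bits <- two_bits[seq_len(n), , drop = FALSE]
  counts <- matrix(NA_real_, n, L)
  counts[two_bits == 0L] <- 2
  counts[two_bits == 2L] <- 1
  counts[two_bits == 3L] <- 0
  genotype_matrix(counts, ids = fam[[2L]], snp_ids = bim[[2L]])
}
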