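#' Construct and validate a pedigree
#'
#' A pedigree is an ordered set of individual records with sire and dam
#' links. Individuals referenced as parents but never listed themselves are
#' inserted as founders, and records are topologically sorted so that
#' parents always precede offspring (a requirement of the tabular
#' relationship-matrix recursion).
#'
#' @param id character vector of individual identifiers.
#' @param sire,dam character vectors of parent identifiers; use
#'   `unknown_code` for a missing parent.
#' @param generation optional integer generation labels (kept as metadata).
#' @param unknown_code token marking an unknown parent (default `"0"`).
#' @return An object of class `pedigree`: a data.frame with columns
#'   `id`, `sire`, `dam` (NA = unknown) and optionally `generation`,
#'   topologically sorted.
#' @examples
#' ped <- pedigree(id = c("3", "1", "2"), sire = c("1", "0", "0"),
#'                 dam = c("2", "0", "0"))
#' ped$id  # parents first
#' @export
pedigree <- function(id, sire, dam, generation = NULL, unknown_code = "0") {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  stopifnot(length(sire) == length(id), length(dam) == length(id))
  if (anyDuplicated(id))
    stop("duplicate individual ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  sire[sire == unknown_code | is.na(sire)] <- NA_character_
  dam[dam == unknown_code | is.na(dam)] <- NA_character_
  self <- which(!is.na(sire) & sire == id | !is.na(dam) & dam == id)
  if (length(self))
    stop("individual recorded as its own parent: ",
         paste(id[self], collapse = ", "))

  # auto-insert unlisted parents as founders
  parents <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(parents)) {
    id <- c(parents, id)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
    if (!is.null(generation))
      generation <- c(rep(NA_integer_, length(parents)), generation)
  }

  ord <- topo_order(id, sire, dam)
  ped <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(generation)) ped$generation <- generation[ord]
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn topological sort; errors on cycles naming the individuals involved.
topo_order <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) < n) {
    cyc <- setdiff(seq_len(n), out)
    stop("pedigree contains a cycle involving: ",
         paste(id[cyc], collapse = ", "))
  }
  out
}

#' Read a pedigree file
#'
#' Expects delimited text (comma, tab or whitespace) with at least three
#' columns: individual id, sire, dam, and optionally a generation label.
#' A header line is detected automatically.
#'
#' @param path file path.
#' @param unknown_code token marking an unknown parent (default `"0"`).
#' @param sep field separator; `NULL` (default) auto-detects comma vs
#'   whitespace from the first line.
#' @return A [pedigree] object (topologically sorted).
#' @export
read_pedigree <- function(path, unknown_code = "0", sep = NULL) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  first <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  header <- grepl("id", first, ignore.case = TRUE)
  d <- utils::read.table(path, sep = sep, header = header,
                         colClasses = "character", strip.white = TRUE)
  if (ncol(d) < 3L) stop("pedigree file needs >= 3 columns (id, sire, dam)")
  gen <- if (ncol(d) >= 4L) suppressWarnings(as.integer(d[[4L]])) else NULL
  pedigree(d[[1L]], d[[2L]], d[[3L]], generation = gen,
           unknown_code = unknown_code)
}

#' Numerator relationship matrix from a pedigree
#'
#' Builds the additive (numerator) relationship matrix A with the tabular
#' method: processing individuals in topological order,
#' `a_ii = 1 + a(sire, dam)/2` and `a_ij = (a(j, sire) + a(j, dam))/2` for
#' previously processed `j`, unknown parents contributing zero. Inbreeding
#' is therefore handled exactly; founders have diagonal exactly 1.
#'
#' @param ped a [pedigree] object (or data.frame coercible to one).
#' @return An object of class `nrm`: symmetric numeric matrix with
#'   dimnames = individual ids in pedigree order.
#' @examples
#' ped <- pedigree(c("1", "2", "3"), c("0", "0", "1"), c("0", "0", "2"))
#' build_nrm(ped)
#' @export
build_nrm <- function(ped) {
  if (!inherits(ped, "pedigree"))
    ped <- pedigree(ped[[1L]], ped[[2L]], ped[[3L]])
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  if (any(si >= idx & si > 0L) || any(di >= idx & di > 0L))
    stop("pedigree is not topologically sorted")
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[j, s] else 0
      ad_ <- if (d > 0L) A[j, d] else 0
      aij <- 0.5 * (as_ + ad_)
      A[j, i] <- aij
      A[i, j] <- aij
    }
  }
  class(A) <- c("nrm", "matrix", "array")
  A
}

#' Partition a relationship matrix around a genotyped subset
#'
#' Splits A into the four blocks used in single-step evaluation: A11
#' (non-genotyped), A22 (genotyped), and the cross blocks A12/A21. The
#' genotyped block is ordered exactly as `genotyped_ids`, so it aligns
#' with a genomic relationship matrix computed over the same individuals.
#'
#' @param A relationship matrix with id dimnames (e.g. from [build_nrm]).
#' @param genotyped_ids character vector of genotyped individual ids.
#' @return list with `A11`, `A12`, `A21`, `A22`, `nongenotyped_ids`,
#'   `genotyped_ids`.
#' @export
partition_nrm <- function(A, genotyped_ids) {
  ids <- rownames(A)
  genotyped_ids <- as.character(genotyped_ids)
  bad <- setdiff(genotyped_ids, ids)
  if (length(bad))
    stop("genotyped ids absent from relationship matrix: ",
         paste(bad, collapse = ", "))
  ng <- setdiff(ids, genotyped_ids)
  A <- unclass(A)
  list(A11 = A[ng, ng, drop = FALSE],
       A12 = A[ng, genotyped_ids, drop = FALSE],
       A21 = A[genotyped_ids, ng, drop = FALSE],
       A22 = A[genotyped_ids, genotyped_ids, drop = FALSE],
       nongenotyped_ids = ng, genotyped_ids = genotyped_ids)
}

#' Write a relationship matrix as TSV
#'
#' Plain text export: full symmetric matrix with an `id` column and one
#' column per individual.
#'
#' @param K relationship matrix with id dimnames.
#' @param path output file.
#' @export
write_relmat_tsv <- function(K, path) {
  d <- data.frame(id = rownames(K), unclass(K), check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV relationship matrix written by [write_relmat_tsv]
#' @param path input file.
#' @return numeric matrix with id dimnames.
#' @export
read_relmat_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, colClasses = "character")
  K <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(K) <- "double"
  rownames(K) <- d[[1L]]
  K
}
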