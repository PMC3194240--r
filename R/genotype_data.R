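#' Construct a case-control genotype dataset
#'
#' A \code{genotype_dataset} holds an N x n matrix of additive genotype
#' codes (minor-allele counts, 0/1/2), a binary disease label per
#' individual (1 = case, 0 = control) and the SNP identifiers.  All
#' downstream scoring, screening and search functions operate on this
#' container.  Missing values are rejected: the contingency counts that
#' drive every score assume complete data.
#'
#' @param genotypes integer matrix, individuals in rows and SNPs in
#'   columns; every entry must be 0, 1 or 2.
#' @param labels integer vector of length \code{nrow(genotypes)} with
#'   disease status, 0 = control and 1 = case.
#' @param snp_ids character vector of unique SNP identifiers, one per
#'   column of \code{genotypes}.  Defaults to existing column names or
#'   \code{snp1, snp2, ...}.
#' @return An object of class \code{genotype_dataset} with components
#'   \code{genotypes}, \code{labels}, \code{snp_ids}, \code{N}
#'   (individuals) and \code{n} (SNPs).
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L, 1L, 1L), nrow = 3)
#' genotype_dataset(g, labels = c(0L, 1L, 1L))
#' @export
genotype_dataset <- function(genotypes, labels, snp_ids = NULL) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  labels <- as.integer(labels)
  if (is.null(snp_ids)) {
    snp_ids <- colnames(genotypes)
    if (is.null(snp_ids))
      snp_ids <- sprintf("snp%d", seq_len(ncol(genotypes)))
  }
  snp_ids <- as.character(snp_ids)
  obj <- structure(
    list(genotypes = unname(genotypes), labels = labels,
         snp_ids = snp_ids, N = nrow(genotypes), n = ncol(genotypes)),
    class = "genotype_dataset")
  validate_genotype_dataset(obj)
  obj
}

validate_genotype_dataset <- function(x) {
  if (x$N < 1L)
    stop("a genotype dataset must contain at least one individual",
         call. = FALSE)
  if (length(x$snp_ids) != x$n)
    stop("number of SNP ids (", length(x$snp_ids),
         ") does not match number of genotype columns (", x$n, ")",
         call. = FALSE)
  if (anyDuplicated(x$snp_ids))
    stop("duplicate SNP ids: ",
         paste(unique(x$snp_ids[duplicated(x$snp_ids)]), collapse = ", "),
         call. = FALSE)
  if (length(x$labels) != x$N)
    stop("length of labels (", length(x$labels),
         ") does not match number of individuals (", x$N, ")",
         call. = FALSE)
  bad <- which(is.na(x$labels) | !(x$labels %in% c(0L, 1L)))
  if (length(bad))
    stop("invalid disease label at row ", bad[1L],
         ": labels must be 0 (control) or 1 (case)", call. = FALSE)
  badg <- which(is.na(x$genotypes) | x$genotypes < 0L | x$genotypes > 2L)
  if (length(badg)) {
    rc <- arrayInd(badg[1L], dim(x$genotypes))
    stop("invalid genotype code at row ", rc[1L], ", SNP '",
         x$snp_ids[rc[2L]], "': codes must be 0, 1 or 2", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", x$N, "individuals x", x$n, "SNPs;",
      sum(x$labels == 1L), "cases /", sum(x$labels == 0L), "controls\n")
  invisible(x)
}

# Scoring and search need both classes present; plain construction does not.
require_both_classes <- function(data) {
  if (!any(data$labels == 1L) || !any(data$labels == 0L))
    stop("dataset must contain at least one case and one control",
         call. = FALSE)
  invisible(data)
}

# Resolve SNP ids or numeric indices to validated column indices.
resolve_snp_index <- function(data, snps) {
  if (length(snps) == 0L) return(integer(0))
  if (is.character(snps)) {
    idx <- match(snps, data$snp_ids)
    if (anyNA(idx))
      stop("unknown SNP id(s): ", paste(snps[is.na(idx)], collapse = ", "),
           call. = FALSE)
  } else {
    idx <- as.integer(snps)
    if (any(is.na(idx) | idx < 1L | idx > data$n))
      stop("SNP index out of range 1..", data$n, call. = FALSE)
  }
  if (anyDuplicated(idx))
    stop("duplicate SNP in parent/candidate set: ",
         paste(data$snp_ids[idx[duplicated(idx)]], collapse = ", "),
         call. = FALSE)
  idx
}
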