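#' Read a genotype dataset from delimited text
#'
#' The expected layout is one header row naming the SNP columns plus a
#' label column, then one row per individual.  Genotypes are additive
#' codes 0/1/2 and the label column holds 0 (control) or 1 (case).
#'
#' @param path path to a CSV or TSV file.
#' @param sep field separator; \code{","} (default) or \code{"\t"}.
#' @param label_col name of the disease-status column (default
#'   \code{"label"}).
#' @return A [genotype_dataset].
#' @seealso [write_delimited()], [read_ped_map()]
#' @export
read_delimited <- function(path, sep = ",", label_col = "label") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "integer",
                          comment.char = "")
  if (!label_col %in% names(df))
    stop("label column '", label_col, "' not found in ", path, call. = FALSE)
  snp_ids <- setdiff(names(df), label_col)
  geno <- as.matrix(df[snp_ids])
  if (length(snp_ids) == 0L)
    geno <- matrix(integer(0), nrow = nrow(df), ncol = 0L)
  genotype_dataset(geno, labels = df[[label_col]], snp_ids = snp_ids)
}

#' Write a genotype dataset to delimited text
#'
#' Produces a file that [read_delimited()] reads back into an identical
#' dataset.
#'
#' @param data a [genotype_dataset].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @param label_col header name for the label column.
#' @return Invisibly, \code{path}.
#' @export
write_delimited <- function(data, path, sep = ",", label_col = "label") {
  stopifnot(inherits(data, "genotype_dataset"))
  if (label_col %in% data$snp_ids)
    stop("label column name collides with a SNP id: ", label_col,
         call. = FALSE)
  df <- as.data.frame(data$genotypes)
  names(df) <- data$snp_ids
  df[[label_col]] <- data$labels
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype dataset from PLINK PED/MAP text files
#'
#' Classic whitespace-delimited PED: six leading columns (family id,
#' individual id, paternal id, maternal id, sex, phenotype) followed by
#' two allele columns per SNP.  The MAP file supplies SNP identifiers in
#' matching order (column 2).  Phenotypes must be 1 (control) or 2
#' (case) and are recoded to 0/1; alleles are recoded additively as the
#' per-file minor-allele count.  Frequency ties take the
#' lexicographically smaller allele symbol as "minor" so the coding is
#' deterministic; monomorphic SNPs code as all zero (the minor allele
#' is the unobserved one).  Missing genotypes or phenotypes are
#' rejected.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @return A [genotype_dataset].
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("file not found: ", ped_path, call. = FALSE)
  if (!file.exists(map_path)) stop("file not found: ", map_path, call. = FALSE)
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) < 2L)
    stop("MAP file must have at least 2 columns (chromosome, SNP id)",
         call. = FALSE)
  snp_ids <- map[[2L]]
  n <- length(snp_ids)
  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  if (ncol(ped) != 6L + 2L * n)
    stop("PED file has ", ncol(ped), " columns but MAP lists ", n,
         " SNPs (expected ", 6L + 2L * n, " columns)", call. = FALSE)
  pheno <- ped[[6L]]
  if (!all(pheno %in% c("1", "2")))
    stop("unsupported phenotype value(s): ",
         paste(unique(pheno[!pheno %in% c("1", "2")]), collapse = ", "),
         "; phenotypes must be 1 (control) or 2 (case)", call. = FALSE)
  labels <- as.integer(pheno == "2")
  N <- nrow(ped)
  geno <- matrix(0L, nrow = N, ncol = n)
  for (s in seq_len(n)) {
    a1 <- ped[[5L + 2L * s]]
    a2 <- ped[[6L + 2L * s]]
    alleles <- c(a1, a2)
    if (any(alleles %in% c("0", "-", "N", ".")))
      stop("missing genotype at SNP '", snp_ids[s],
           "': missing data are not supported", call. = FALSE)
    sym <- sort(unique(alleles))
    if (length(sym) > 2L)
      stop("SNP '", snp_ids[s], "' has ", length(sym),
           " alleles; only biallelic SNPs are supported", call. = FALSE)
    if (length(sym) == 1L) next  # monomorphic: minor allele unobserved
    counts <- table(factor(alleles, levels = sym))
    # Minor allele = globally less frequent; ties resolve to the
    # lexicographically smaller symbol.
    minor <- sym[order(as.integer(counts), sym)][1L]
    geno[, s] <- (a1 == minor) + (a2 == minor)
  }
  genotype_dataset(geno, labels = labels, snp_ids = snp_ids)
}
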