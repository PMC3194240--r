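#' G-squared (likelihood-ratio) test of independence for a count table
#'
#' \deqn{G^2 = 2 \sum_{cells} O \ln(O / E)}
#' with expected counts \eqn{E} from the row/column margins under
#' independence and the convention \eqn{0 \ln 0 = 0}.  Degrees of
#' freedom use the full table shape, \eqn{(rows-1)(cols-1)}, even when
#' a row or column is empty: category counts are fixed by the model
#' (3 genotype states, 2 label states), not by the realisation, so a
#' SNP-label test always has df = 2.
#'
#' @param observed matrix of nonnegative counts with at least one
#'   positive entry.
#' @return A list with \code{g2}, \code{df} and \code{p_value} (upper
#'   chi-square tail).
#' @examples
#' g2_statistic(matrix(c(10, 30, 20, 40), nrow = 2))
#' @export
g2_statistic <- function(observed) {
  observed <- as.matrix(observed)
  if (any(observed < 0) || anyNA(observed))
    stop("observed counts must be nonnegative", call. = FALSE)
  total <- sum(observed)
  if (total == 0) stop("all-zero contingency table", call. = FALSE)
  E <- outer(rowSums(observed), colSums(observed)) / total
  nz <- observed > 0
  g2 <- 2 * sum(observed[nz] * log(observed[nz] / E[nz]))
  df <- (nrow(observed) - 1L) * (ncol(observed) - 1L)
  list(g2 = g2, df = df,
       p_value = stats::pchisq(g2, df, lower.tail = FALSE))
}

# 3 x 2 genotype-by-label count table for one SNP column.
snp_label_table <- function(data, snp_idx) {
  cnt <- tabulate(data$genotypes[, snp_idx] * 2L + data$labels + 1L,
                  nbins = 6L)
  matrix(cnt, nrow = 3L, ncol = 2L, byrow = TRUE,
         dimnames = list(genotype = 0:2, label = c("control", "case")))
}

# Marginal G^2 of every SNP against the label (vectorised over SNPs).
marginal_g2_values <- function(data) {
  G <- data$genotypes
  case <- data$labels == 1L
  n_case <- sum(case)
  n_ctl <- data$N - n_case
  O <- matrix(0, nrow = data$n, ncol = 6L)  # (g0,g1,g2) x (ctl,case)
  for (v in 0:2) {
    eq <- G == v
    O[, v + 1L] <- colSums(eq & !case)
    O[, v + 4L] <- colSums(eq & case)
  }
  row_tot <- O[, 1:3] + O[, 4:6]           # per-genotype margins
  E <- cbind(row_tot * (n_ctl / data$N), row_tot * (n_case / data$N))
  term <- ifelse(O > 0, O * log(O / E), 0)
  2 * rowSums(term)
}

#' Marginal screen of SNPs by G-squared association with the disease
#'
#' Computes the 3 x 2 genotype-by-label G-squared statistic for every
#' SNP and returns candidates ranked by descending G-squared (ties
#' broken by SNP id).  Exactly one of \code{top_k} and \code{alpha}
#' must be given: \code{top_k} keeps the strongest K SNPs (the usual
#' pre-search screen on large panels, e.g. top 200); \code{alpha}
#' keeps every SNP with p-value below the threshold.  P-values come
#' from the chi-square df = 2 upper tail with no continuity correction;
#' \code{bonferroni = TRUE} multiplies the threshold comparison by the
#' number of SNPs tested.
#'
#' @param data a [genotype_dataset].
#' @param top_k number of top-ranked SNPs to keep.
#' @param alpha per-test significance threshold on the p-value.
#' @param bonferroni apply a Bonferroni correction in \code{alpha}
#'   mode (off by default; the screening stage traditionally applies a
#'   plain top-K cut).
#' @return A data frame with columns \code{snp_id}, \code{g2},
#'   \code{df}, \code{p_value}, sorted by rank.
#' @examples
#' set.seed(1)
#' g <- matrix(sample(0:2, 500, TRUE), ncol = 5)
#' d <- genotype_dataset(g, rep(c(0L, 1L), 50))
#' marginal_screen(d, top_k = 2)
#' @export
marginal_screen <- function(data, top_k = NULL, alpha = NULL,
                            bonferroni = FALSE) {
  stopifnot(inherits(data, "genotype_dataset"))
  require_both_classes(data)
  if (is.null(top_k) == is.null(alpha))
    stop("give exactly one of top_k or alpha", call. = FALSE)
  g2 <- marginal_g2_values(data)
  res <- data.frame(snp_id = data$snp_ids, g2 = g2, df = 2L,
                    p_value = stats::pchisq(g2, 2L, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$g2, res$snp_id), , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(top_k)) {
    if (top_k > data$n) {
      warning("top_k (", top_k, ") exceeds the number of SNPs (", data$n,
              "); returning all", call. = FALSE)
      top_k <- data$n
    }
    res[seq_len(top_k), , drop = FALSE]
  } else {
    thr <- if (bonferroni) alpha / data$n else alpha
    res[res$p_value < thr, , drop = FALSE]
  }
}
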