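#' Search configuration for parent-set selection
#'
#' Controls the branch-and-bound search over subsets of candidate SNPs
#' for the parent set of the disease-status node.
#'
#' The search descends a depth-first tree over canonically ordered
#' subsets: the children of a node \eqn{S} are \eqn{S \cup \{x\}} for
#' candidates \eqn{x} ranked after the last element of \eqn{S}, so each
#' subset is generated exactly once.  Every generated child is scored
#' and compared against the incumbent best.  Recursion into a child is
#' cut when its score falls below its parent node's score, subject to
#' the pruning mode:
#' \describe{
#'   \item{\code{lookahead}}{(default) the cut only applies at depth
#'     \eqn{\ge} \code{lookahead_depth}.  Shallow levels are explored
#'     unconditionally so that pure interactions with no marginal
#'     effect -- for which every first added parent lowers the score --
#'     are still reachable.  The default depth 3 matches the highest
#'     interaction order in the bundled disease models.}
#'   \item{\code{strict}}{the literal score-decrease rule: cut at any
#'     depth.  Fails on XOR-like interactions; kept to study that
#'     behaviour.}
#'   \item{\code{none}}{never cut; visits every subset up to
#'     \code{max_parents} (exhaustive enumeration).}
#' }
#'
#' @param candidates SNP ids (character) or column indices eligible as
#'   parents, or \code{NULL} (default) for all SNPs in the dataset.
#' @param max_parents cap on the parent-set size (default 5; with
#'   \eqn{q = 3^5} configurations, larger sets are implausible at
#'   realistic sample sizes).
#' @param ordering \code{"g2"} (default) explores candidates in
#'   descending order of marginal G-squared with the label, ties broken
#'   by SNP id, which makes the result invariant to the input column
#'   order; \code{"given"} keeps the supplied order.
#' @param pruning \code{"lookahead"}, \code{"strict"} or \code{"none"}.
#' @param lookahead_depth depth from which the score-decrease cut is
#'   enforced under \code{pruning = "lookahead"} (default 3).
#' @param score_spec a [score_spec()] (default rescaled BIC, c = 0.17).
#' @return An object of class \code{search_config}.
#' @export
search_config <- function(candidates = NULL, max_parents = 5L,
                          ordering = c("g2", "given"),
                          pruning = c("lookahead", "strict", "none"),
                          lookahead_depth = 3L,
                          score_spec = epibnb::score_spec()) {
  ordering <- match.arg(ordering)
  pruning <- match.arg(pruning)
  max_parents <- as.integer(max_parents)
  lookahead_depth <- as.integer(lookahead_depth)
  if (max_parents < 1L) stop("max_parents must be >= 1", call. = FALSE)
  if (lookahead_depth < 1L) stop("lookahead_depth must be >= 1",
                                 call. = FALSE)
  structure(list(candidates = candidates, max_parents = max_parents,
                 ordering = ordering, pruning = pruning,
                 lookahead_depth = lookahead_depth,
                 score_spec = score_spec),
            class = "search_config")
}

# Candidate column indices in search order.
order_candidates <- function(data, config) {
  idx <- if (is.null(config$candidates)) seq_len(data$n)
         else resolve_snp_index(data, config$candidates)
  if (config$ordering == "g2" && length(idx) > 1L) {
    g2 <- marginal_g2_values(data)[idx]
    idx <- idx[order(-g2, data$snp_ids[idx])]
  }
  idx
}

# TRUE if candidate set a beats b under the tie-break (higher score,
# then smaller size, then lexicographically smaller sorted id string).
better_result <- function(score_a, ids_a, score_b, ids_b) {
  if (score_a > score_b) return(TRUE)
  if (score_a < score_b) return(FALSE)
  if (length(ids_a) != length(ids_b)) return(length(ids_a) < length(ids_b))
  key_a <- paste(sort(ids_a), collapse = "\r")
  key_b <- paste(sort(ids_b), collapse = "\r")
  key_a < key_b
}

#' Branch-and-bound search for the best parent set of the disease node
#'
#' Depth-first search over subsets of the candidate SNPs, maximising
#' the local score of the disease-status node (see [search_config()]
#' for the enumeration and pruning rules).  Deterministic given the
#' data and configuration.
#'
#' @param data a [genotype_dataset] containing at least one case and
#'   one control.
#' @param config a [search_config()].
#' @return An object of class \code{search_result} with components
#'   \code{best_set} (SNP ids, canonically sorted), \code{best_score},
#'   \code{nodes_evaluated} (subsets scored, including the empty root),
#'   \code{pruned_branches} (children whose subtree was cut) and
#'   \code{score_spec}.
#' @examples
#' set.seed(1)
#' g <- matrix(sample(0:2, 300, TRUE), ncol = 3)
#' lab <- as.integer(g[, 1] >= 1)      # SNP 1 drives the label
#' d <- genotype_dataset(g, lab, c("a", "b", "c"))
#' bnb_search(d, search_config())$best_set
#' @export
bnb_search <- function(data, config = search_config()) {
  stopifnot(inherits(data, "genotype_dataset"),
            inherits(config, "search_config"))
  require_both_classes(data)
  cand <- order_candidates(data, config)
  score_fun <- make_score_fun(data, config$score_spec)

  root_score <- score_fun(integer(0))
  env <- new.env(parent = emptyenv())
  env$best_idx <- integer(0)
  env$best_score <- root_score
  env$nodes <- 1L
  env$pruned <- 0L
  K <- length(cand)
  pruning <- config$pruning
  d_min <- config$lookahead_depth
  max_p <- config$max_parents
  ids <- data$snp_ids

  recurse <- function(S, s_parent, start) {
    depth <- length(S) + 1L
    for (m in start:K) {
      child <- c(S, cand[m])
      s <- score_fun(child)
      env$nodes <- env$nodes + 1L
      if (better_result(s, ids[child], env$best_score, ids[env$best_idx]))
        { env$best_idx <- child; env$best_score <- s }
      if (depth < max_p && m < K) {
        cut <- switch(pruning,
                      none = FALSE,
                      strict = s < s_parent,
                      lookahead = s < s_parent && depth >= d_min)
        if (cut) env$pruned <- env$pruned + 1L
        else recurse(child, s, m + 1L)
      }
    }
  }
  if (K > 0L) recurse(integer(0), root_score, 1L)

  structure(list(best_set = sort(ids[env$best_idx]),
                 best_score = env$best_score,
                 nodes_evaluated = env$nodes,
                 pruned_branches = env$pruned,
                 score_spec = config$score_spec),
            class = "search_result")
}

#' Exhaustive parent-set search (oracle)
#'
#' Scores every subset of the candidates up to \code{max_parents} and
#' returns the global maximiser, with the same tie-breaking as
#' [bnb_search()] (higher score, then smaller set, then lexicographic
#' id order).  Intended as a ground-truth oracle on small candidate
#' panels; refuses when the number of subsets exceeds \code{ceiling}.
#'
#' @inheritParams bnb_search
#' @param ceiling maximum number of subsets to enumerate (default
#'   200000).
#' @return A \code{search_result}; \code{pruned_branches} is 0.
#' @export
exhaustive_search <- function(data, config = search_config(),
                              ceiling = 2e5) {
  stopifnot(inherits(data, "genotype_dataset"),
            inherits(config, "search_config"))
  require_both_classes(data)
  cand <- order_candidates(data, config)
  K <- length(cand)
  kmax <- min(config$max_parents, K)
  n_subsets <- sum(vapply(0:kmax, function(k) choose(K, k), numeric(1)))
  if (n_subsets > ceiling)
    stop("exhaustive enumeration of ", n_subsets,
         " subsets exceeds the ceiling of ", ceiling, call. = FALSE)
  score_fun <- make_score_fun(data, config$score_spec)
  ids <- data$snp_ids

  best_idx <- integer(0)
  best_score <- score_fun(integer(0))
  nodes <- 1L
  for (k in seq_len(kmax)) {
    sets <- utils::combn(cand, k)
    for (col in seq_len(ncol(sets))) {
      S <- sets[, col]
      s <- score_fun(S)
      nodes <- nodes + 1L
      if (better_result(s, ids[S], best_score, ids[best_idx]))
        { best_idx <- S; best_score <- s }
    }
  }
  structure(list(best_set = sort(ids[best_idx]), best_score = best_score,
                 nodes_evaluated = nodes, pruned_branches = 0L,
                 score_spec = config$score_spec),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  set <- if (length(x$best_set)) paste(x$best_set, collapse = ", ")
         else "(empty)"
  cat("search_result: best parent set {", set, "}\n",
      "  score = ", format(x$best_score), " (", x$score_spec$family, ")\n",
      "  nodes evaluated = ", x$nodes_evaluated,
      ", branches pruned = ", x$pruned_branches, "\n", sep = "")
  invisible(x)
}
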