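#' Tau tissue-specificity index
#'
#' Tau = sum_i (1 - x_i / max(x)) / (n - 1): 0 for uniform expression,
#' 1 for expression confined to a single tissue.  Scale invariant.
#'
#' @param x non-negative expression vector across tissues (max > 0).
#' @return Tau in [0, 1].
#' @export
tau_score <- function(x) {
  stopifnot(length(x) >= 2L, all(x >= 0), max(x) > 0)
  sum(1 - x / max(x)) / (length(x) - 1L)
}

#' Shannon entropy of an expression distribution
#'
#' H = -sum p_i log2 p_i with p_i = x_i / sum(x) and 0 log 0 = 0, in
#' bits: log2(n) for uniform expression, 0 for a single expressed tissue.
#'
#' @param x non-negative expression vector (sum > 0).
#' @return entropy in bits.
#' @export
entropy_score <- function(x) {
  stopifnot(all(x >= 0), sum(x) > 0)
  p <- x / sum(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Tau and entropy for every row of a tissue expression matrix
#'
#' @param mat non-negative matrix, genes x tissues, with rownames.
#' @return \code{data.frame} with \code{gene_id}, \code{tau},
#'   \code{entropy}; genes with all-zero expression get \code{NA}.
#' @export
specificity_scores <- function(mat) {
  mat <- as.matrix(mat)
  data.frame(gene_id = rownames(mat) %||%
               as.character(seq_len(nrow(mat))),
             tau = apply(mat, 1L, function(x)
               if (max(x) > 0) tau_score(x) else NA_real_),
             entropy = apply(mat, 1L, function(x)
               if (sum(x) > 0) entropy_score(x) else NA_real_),
             stringsAsFactors = FALSE)
}

#' Permutation test of gene-set overlap with a catalogue
#'
#' Compares the observed overlap of a query gene set with a catalogue
#' (e.g. cell-cycle periodic genes) against overlaps of random same-size
#' sets drawn from the universe without replacement.
#' p = (1 + #\{permutation overlap >= observed\}) / (n_perm + 1).
#'
#' @param query character vector of gene ids (non-empty subset of
#'   \code{universe}).
#' @param catalogue character vector of catalogue gene ids.
#' @param universe character vector of all eligible gene ids.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional integer seed recorded in the result.
#' @return list with \code{observed}, \code{expected} (mean permuted
#'   overlap), \code{p_value}, \code{n_perm}, \code{seed}.
#' @export
permutation_enrichment <- function(query, catalogue, universe,
                                   n_perm = 10000L, seed = NULL) {
  if (length(query) == 0L) .stopf("empty query set")
  if (!all(query %in% universe))
    .stopf("query must be a subset of the universe")
  if (!is.null(seed)) set.seed(seed)
  in_cat <- universe %in% catalogue
  observed <- sum(query %in% catalogue)
  k <- length(query)
  perm <- vapply(seq_len(n_perm), function(i)
    sum(in_cat[sample.int(length(universe), k)]), integer(1))
  list(observed = observed, expected = mean(perm),
       p_value = (1 + sum(perm >= observed)) / (n_perm + 1),
       n_perm = n_perm, seed = seed)
}

#' Chi-square test of the intersection of two gene sets
#'
#' Builds the 2x2 membership table of two sets over a common universe and
#' reports the expected intersection size |A||B|/|U| and the Pearson
#' chi-square statistic (no continuity correction by default).
#'
#' @param set_a,set_b character vectors, subsets of \code{universe}.
#' @param universe character vector of all genes considered.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with \code{observed}, \code{expected}, \code{statistic},
#'   \code{p_value} and the 2x2 \code{table}.
#' @export
overlap_chisq <- function(set_a, set_b, universe, correct = FALSE) {
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    .stopf("both sets must be subsets of the universe")
  universe <- unique(universe)
  a <- universe %in% set_a
  b <- universe %in% set_b
  tab <- table(factor(a, c(TRUE, FALSE)), factor(b, c(TRUE, FALSE)))
  expected_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - expected_tab)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected_tab)
  list(observed = tab[1L, 1L],
       expected = length(set_a) * length(set_b) / length(universe),
       statistic = stat,
       p_value = pchisq(stat, df = 1L, lower.tail = FALSE),
       table = tab)
}
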