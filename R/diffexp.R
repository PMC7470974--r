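#' Median-of-ratios size factors
#'
#' Library-size factors computed as the median across features of each
#' sample's counts divided by the feature-wise geometric mean (features
#' with a zero in any sample are excluded from the reference).
#'
#' @param counts numeric matrix, features x samples.
#' @return numeric vector of per-sample factors (all 1 when columns are
#'   identical).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  logs <- log(counts)
  ref <- rowMeans(logs)
  use <- is.finite(ref)
  if (!any(use))
    .stopf("no feature has nonzero counts in every sample")
  apply(counts[use, , drop = FALSE], 2L, function(k)
    exp(median(log(k) - ref[use])))
}

# gene-wise method-of-moments NB dispersion on normalized counts,
# pooled across the two conditions
.mom_dispersion <- function(qa, qb) {
  mu <- (rowMeans(qa) + rowMeans(qb)) / 2
  v <- (apply(qa, 1L, var) + apply(qb, 1L, var)) / 2
  pmax((v - mu) / pmax(mu, 1e-8)^2, 1e-8)
}

# mean-dispersion trend alpha(mu) = a0 + a1/mu fitted on bin means of the
# gene-wise estimates (binned by log10 mean expression)
.dispersion_trend <- function(mu, alpha_gene, n_bins = 20L) {
  ok <- is.finite(mu) & mu > 0 & is.finite(alpha_gene)
  if (sum(ok) < 10L)
    return(c(a0 = max(mean(alpha_gene[ok]), 1e-4), a1 = 0))
  br <- cut(log10(mu[ok]), breaks = max(3L, min(n_bins, sum(ok) %/% 5L)))
  bin_a <- tapply(alpha_gene[ok], br, mean)
  bin_mu <- tapply(mu[ok], br, median)
  keep <- !is.na(bin_a) & !is.na(bin_mu)
  if (sum(keep) < 3L)
    return(c(a0 = max(mean(alpha_gene[ok]), 1e-4), a1 = 0))
  fit <- lm(bin_a[keep] ~ I(1 / bin_mu[keep]))
  c(a0 = max(unname(coef(fit)[1L]), 1e-8),
    a1 = max(unname(coef(fit)[2L]), 0))
}

#' Negative-binomial Wald test for two-condition differential expression
#'
#' Tests each consensus cluster for a difference in mean normalized counts
#' between two replicated conditions.  Dispersions are estimated per CC by
#' method of moments and shrunk on the log scale towards a fitted
#' mean-dispersion trend (a0 + a1/mean), with the shrinkage weight set by
#' \code{prior_df} against the residual degrees of freedom, in the spirit
#' of empirical-Bayes dispersion moderation.  The Wald statistic compares
#' the log2 ratio of condition means against its delta-method standard
#' error; p-values are two-sided normal and BH-adjusted.
#'
#' @param counts raw count matrix, CCs x samples, with rownames.
#' @param condition factor (or vector) of length \code{ncol(counts)} with
#'   exactly two levels; at least two replicates per condition.
#' @param sf optional size factors; computed by [size_factors()] when
#'   missing.
#' @param prior_df prior degrees of freedom of the trend (default 80).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return \code{data.frame} with \code{cc_id}, \code{base_mean}, the two
#'   condition means, \code{log2_fold_change} (second level over first),
#'   \code{dispersion}, \code{p_value}, \code{padj} and \code{call}
#'   (\code{up_<level>} or \code{unchanged}).  All-zero CCs get p = 1 and
#'   log2FC = 0.
#' @export
nb_diffexp <- function(counts, condition, sf = NULL, prior_df = 80,
                       alpha = 0.05) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L)
    .stopf("exactly two condition levels required")
  if (any(table(condition) < 2L))
    .stopf("at least two replicates per condition required")
  if (is.null(sf)) sf <- size_factors(counts)
  q <- sweep(counts, 2L, sf, "/")
  la <- levels(condition)[1L]; lb <- levels(condition)[2L]
  qa <- q[, condition == la, drop = FALSE]
  qb <- q[, condition == lb, drop = FALSE]
  na <- ncol(qa); nb <- ncol(qb)
  ma <- rowMeans(qa); mb <- rowMeans(qb)
  mu0 <- (ma + mb) / 2
  a_gene <- .mom_dispersion(qa, qb)
  tr <- .dispersion_trend(mu0, a_gene)
  a_trend <- tr["a0"] + tr["a1"] / pmax(mu0, 1e-8)
  d_resid <- (na - 1L) + (nb - 1L)
  w <- prior_df / (prior_df + d_resid)
  a_use <- exp(w * log(pmax(a_trend, 1e-8)) +
                 (1 - w) * log(pmax(a_gene, 1e-8)))
  lfc <- log2((mb + 1e-8) / (ma + 1e-8))
  se <- sqrt((1 / pmax(ma, 0.5) + a_use) / na +
               (1 / pmax(mb, 0.5) + a_use) / nb) / log(2)
  p <- 2 * pnorm(-abs(lfc / se))
  zero <- ma == 0 & mb == 0
  p[zero] <- 1
  lfc[zero] <- 0
  padj <- bh_adjust(p)
  call <- rep("unchanged", nrow(counts))
  call[padj < alpha & lfc > 0] <- paste0("up_", lb)
  call[padj < alpha & lfc < 0] <- paste0("up_", la)
  out <- data.frame(cc_id = rownames(counts) %||%
                      as.character(seq_len(nrow(counts))),
                    base_mean = mu0, stringsAsFactors = FALSE)
  out[[paste0("mean_", la)]] <- ma
  out[[paste0("mean_", lb)]] <- mb
  out$log2_fold_change <- lfc
  out$dispersion <- a_use
  out$p_value <- p
  out$padj <- padj
  out$call <- call
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single-cluster negative-binomial test
#'
#' Low-level per-CC variant: Wald test on the log2 ratio of normalized
#' replicate means for one cluster.  Without the across-cluster trend the
#' dispersion defaults to the method-of-moments estimate (or a supplied
#' value).
#'
#' @param counts_a,counts_b raw replicate count vectors.
#' @param sf size factors for \code{c(counts_a, counts_b)}; defaults to 1.
#' @param dispersion optional known dispersion.
#' @return list with \code{p_value}, \code{log2_fold_change} and
#'   \code{dispersion}.
#' @export
nb_test <- function(counts_a, counts_b, sf = NULL, dispersion = NULL) {
  if (length(counts_a) < 2L || length(counts_b) < 2L)
    .stopf("at least two replicates per condition required")
  if (is.null(sf)) sf <- rep(1, length(counts_a) + length(counts_b))
  qa <- counts_a / sf[seq_along(counts_a)]
  qb <- counts_b / sf[length(counts_a) + seq_along(counts_b)]
  ma <- mean(qa); mb <- mean(qb)
  if (ma == 0 && mb == 0)
    return(list(p_value = 1, log2_fold_change = 0, dispersion = NA_real_))
  mu0 <- (ma + mb) / 2
  if (is.null(dispersion)) {
    v <- (var(qa) + var(qb)) / 2
    dispersion <- max((v - mu0) / mu0^2, 1e-8)
  }
  lfc <- log2((mb + 1e-8) / (ma + 1e-8))
  se <- sqrt((1 / max(ma, 0.5) + dispersion) / length(qa) +
               (1 / max(mb, 0.5) + dispersion) / length(qb)) / log(2)
  list(p_value = 2 * pnorm(-abs(lfc / se)), log2_fold_change = lfc,
       dispersion = dispersion)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")
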