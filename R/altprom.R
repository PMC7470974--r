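#' Select expressed canonical/alternative promoter pairs
#'
#' A twinned promoter pair is a candidate for alternative-promoter
#' analysis only when, within each condition, at least one of its two
#' regions is expressed above \code{min_tpm} (strict).
#'
#' @param pairs \code{data.frame} with columns \code{gene_id},
#'   \code{cano_a}, \code{alt_a}, \code{cano_b}, \code{alt_b}: TPM of the
#'   canonical and alternative regions in conditions A and B.
#' @param min_tpm expression threshold (default 5, strict).
#' @return the retained rows.
#' @export
select_expressed_pairs <- function(pairs, min_tpm = 5) {
  keep <- pmax(pairs$cano_a, pairs$alt_a) > min_tpm &
    pmax(pairs$cano_b, pairs$alt_b) > min_tpm
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify differential alternative-promoter utilization
#'
#' For each expressed pair, the relative use of the alternative promoter
#' is rel = alt / cano per condition.  Pairs whose relative use changes at
#' least \code{fold}-fold between conditions are candidates and are
#' assigned to one of four groups from the signed relative changes of each
#' promoter versus condition A
#' (Delta = (B - A) / A):
#' \itemize{
#' \item \code{canonical_down}: Delta cano <= -0.5 and |Delta alt| < 0.25
#' \item \code{alternative_down}: |Delta cano| < 0.25 and Delta alt <= -0.5
#' \item \code{canonical_up}: Delta cano >= +0.5 and |Delta alt| < 0.25
#' \item \code{alternative_up}: |Delta cano| < 0.25 and Delta alt >= +0.5
#' }
#' Candidates outside all four patterns are \code{discarded};
#' non-candidates are \code{not_candidate}.
#'
#' @param pairs expressed pairs from [select_expressed_pairs()].
#' @param fold candidate gate on the relative-use change (default 2).
#' @param delta_small the "under 25 percent" stability bound (strict).
#' @param delta_large the "over 50 percent" change bound (inclusive).
#' @param pseudo pseudo-TPM added to numerator and denominator of ratios
#'   whose denominator is zero (default 0.5); such rows are flagged.
#' @return the input with \code{rel_a}, \code{rel_b}, \code{rel_fold},
#'   \code{delta_cano}, \code{delta_alt}, \code{pseudo_used} and
#'   \code{group} appended.
#' @export
classify_alt_usage <- function(pairs, fold = 2, delta_small = 0.25,
                               delta_large = 0.5, pseudo = 0.5) {
  ratio <- function(num, den) {
    z <- den == 0
    out <- numeric(length(num))
    out[!z] <- num[!z] / den[!z]
    out[z] <- (num[z] + pseudo) / (den[z] + pseudo)
    out
  }
  rel_change <- function(b, a) {
    z <- a == 0
    out <- numeric(length(a))
    out[!z] <- (b[!z] - a[!z]) / a[!z]
    out[z] <- (b[z] - a[z]) / (a[z] + pseudo)
    out
  }
  pairs$pseudo_used <- pairs$cano_a == 0 | pairs$cano_b == 0 |
    pairs$alt_a == 0
  pairs$rel_a <- ratio(pairs$alt_a, pairs$cano_a)
  pairs$rel_b <- ratio(pairs$alt_b, pairs$cano_b)
  pairs$rel_fold <- pmax(pairs$rel_a / pairs$rel_b,
                         pairs$rel_b / pairs$rel_a)
  pairs$delta_cano <- rel_change(pairs$cano_b, pairs$cano_a)
  pairs$delta_alt <- rel_change(pairs$alt_b, pairs$alt_a)
  dc <- pairs$delta_cano; da <- pairs$delta_alt
  small <- function(x) abs(x) < delta_small
  grp <- rep("discarded", nrow(pairs))
  grp[dc <= -delta_large & small(da)] <- "canonical_down"
  grp[small(dc) & da <= -delta_large] <- "alternative_down"
  grp[dc >= delta_large & small(da)] <- "canonical_up"
  grp[small(dc) & da >= delta_large] <- "alternative_up"
  grp[!(pairs$rel_fold >= fold)] <- "not_candidate"
  pairs$group <- grp
  pairs
}
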