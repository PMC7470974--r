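#' Classify monotone expression trends across three ordered stages
#'
#' A consensus cluster is eligible when its expression exceeds
#' \code{min_tpm} in at least one stage.  Eligible clusters are
#' \code{gained} when expression rises more than \code{fold}-fold at each
#' sequential step (stage1 to stage2 and stage2 to stage3), \code{lost}
#' when it falls more than \code{fold}-fold at each step, and \code{none}
#' otherwise.
#'
#' @param x \code{data.frame} with columns \code{cc_id}, \code{tpm_1},
#'   \code{tpm_2}, \code{tpm_3} (or a 3-column matrix).
#' @param min_tpm eligibility threshold (default 5, strict).
#' @param fold per-step fold threshold (default 1.5, strict).
#' @param pseudo pseudo-TPM added to all three values of a cluster when
#'   any is zero (default 0.5).
#' @return \code{data.frame} with \code{cc_id}, the three tpm values,
#'   \code{eligible} and \code{trend}.
#' @export
classify_temporal <- function(x, min_tpm = 5, fold = 1.5, pseudo = 0.5) {
  if (is.matrix(x)) {
    x <- data.frame(cc_id = rownames(x) %||%
                      as.character(seq_len(nrow(x))),
                    tpm_1 = x[, 1L], tpm_2 = x[, 2L], tpm_3 = x[, 3L],
                    stringsAsFactors = FALSE)
  }
  stopifnot(all(c("tpm_1", "tpm_2", "tpm_3") %in% names(x)))
  t1 <- x$tpm_1; t2 <- x$tpm_2; t3 <- x$tpm_3
  eligible <- pmax(t1, t2, t3) > min_tpm
  z <- t1 == 0 | t2 == 0 | t3 == 0
  t1[z] <- t1[z] + pseudo; t2[z] <- t2[z] + pseudo; t3[z] <- t3[z] + pseudo
  gained <- t2 / t1 > fold & t3 / t2 > fold
  lost <- t1 / t2 > fold & t2 / t3 > fold
  trend <- rep("none", nrow(x))
  trend[gained] <- "gained"
  trend[lost] <- "lost"
  trend[!eligible] <- "none"
  x$eligible <- eligible
  x$trend <- trend
  x
}
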