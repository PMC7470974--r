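#' Classify promoter shape from interquantile width and dominant fraction
#'
#' Promoters are classed \code{sharp} when the 10-90 interquantile width
#' is below \code{sharp_width} bp; otherwise \code{peaked_broad} when a
#' single dominant CTSS carries more than \code{dom_frac} of the cluster
#' expression, and \code{broad} otherwise.
#'
#' @param iq_width integer interquantile widths (inclusive bases).
#' @param dominant_fraction dominant CTSS expression over cluster total,
#'   in (0, 1].
#' @param sharp_width width threshold in bp (default 10; width exactly 10
#'   is not sharp).
#' @param dom_frac dominant-fraction threshold (default 0.6; exactly 0.6
#'   is not peaked).
#' @param strict_sharp when TRUE, sharp additionally requires the
#'   dominant fraction to exceed \code{dom_frac}; narrow clusters without
#'   a dominant CTSS then fall to \code{broad}.  Default FALSE
#'   (width-only sharp).
#' @return character vector in \code{c("sharp", "peaked_broad", "broad")};
#'   \code{NA} inputs give \code{NA}.
#' @export
classify_shape <- function(iq_width, dominant_fraction, sharp_width = 10,
                           dom_frac = 0.6, strict_sharp = FALSE) {
  n <- max(length(iq_width), length(dominant_fraction))
  iq_width <- rep_len(iq_width, n)
  dominant_fraction <- rep_len(dominant_fraction, n)
  sharp <- iq_width < sharp_width
  if (strict_sharp) sharp <- sharp & dominant_fraction > dom_frac
  out <- ifelse(sharp, "sharp",
                ifelse(dominant_fraction > dom_frac, "peaked_broad",
                       "broad"))
  out[is.na(iq_width) | is.na(dominant_fraction)] <- NA_character_
  out
}

#' Shape calls for consensus clusters in one sample
#'
#' Combines [cc_shape_stats()] output with [classify_shape()].
#'
#' @param stats per-sample CC statistics from [cc_shape_stats()].
#' @inheritParams classify_shape
#' @return the input with a \code{shape_class} column appended.
#' @export
call_shapes <- function(stats, sharp_width = 10, dom_frac = 0.6,
                        strict_sharp = FALSE) {
  stats$shape_class <- classify_shape(stats$iq_width,
                                      stats$dominant_fraction,
                                      sharp_width = sharp_width,
                                      dom_frac = dom_frac,
                                      strict_sharp = strict_sharp)
  stats
}

#' Shape transitions between two conditions
#'
#' Restricts to CCs expressed at \code{min_tpm} or more in both samples,
#' tabulates the 3 x 3 matrix of (shape in A, shape in B) counts and lists
#' the CCs changing class.
#'
#' @param calls_a,calls_b shape-call tables from [call_shapes()] for the
#'   two conditions (must share \code{cc_id}s).
#' @param min_tpm expression floor applied in both samples (inclusive,
#'   default 10).
#' @return list with \code{matrix} (3 x 3 counts, rows = condition A),
#'   \code{long} (source shape, target shape, count), \code{transitions}
#'   (per-CC labels for off-diagonal CCs) and \code{n} (CCs compared).
#' @export
shape_transitions <- function(calls_a, calls_b, min_tpm = 10) {
  m <- merge(calls_a[, c("cc_id", "tpm", "shape_class")],
             calls_b[, c("cc_id", "tpm", "shape_class")],
             by = "cc_id", suffixes = c("_a", "_b"))
  m <- m[!is.na(m$shape_class_a) & !is.na(m$shape_class_b) &
           m$tpm_a >= min_tpm & m$tpm_b >= min_tpm, , drop = FALSE]
  lev <- c("sharp", "peaked_broad", "broad")
  tab <- table(factor(m$shape_class_a, lev), factor(m$shape_class_b, lev))
  names(dimnames(tab)) <- c("condition_a", "condition_b")
  long <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(long) <- c("source", "target", "count")
  trans <- m[m$shape_class_a != m$shape_class_b, , drop = FALSE]
  rownames(trans) <- NULL
  list(matrix = unclass(tab), long = long, transitions = trans,
       n = nrow(m))
}
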