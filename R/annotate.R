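#' Annotate consensus clusters against gene models
#'
#' Assigns each CC to the nearest annotated TSS on the same chromosome and
#' strand (distance measured from the CC dominant position, signed so that
#' negative means upstream of the gene TSS on the transcribed strand), and
#' classifies its genomic feature with precedence
#' Promoter (<=1kb) > 5' UTR > Exon > Intron > 3' UTR >
#' Promoter (1-3kb) > Downstream (<3kb) > Distal intergenic.
#' CCs in the promoter (<=1kb) class or mapping to a 5' UTR form the
#' promoter set used by downstream promoter-level analyses.
#'
#' @param ccs consensus-cluster table from [build_consensus_clusters()].
#' @param genes \code{data.frame} with columns \code{gene_id},
#'   \code{chrom}, \code{strand}, \code{tss} (1-based) and
#'   \code{gene_end} (genomic coordinate of the 3' end on the gene
#'   strand).
#' @param features optional \code{data.frame} of half-open
#'   \code{[start, end)} genomic feature intervals with columns
#'   \code{gene_id}, \code{feature} (one of \code{five_utr},
#'   \code{exon}, \code{intron}, \code{three_utr}), \code{start},
#'   \code{end}.
#' @param promoter_window upstream extent in bp of the proximal promoter
#'   class (default 1000).
#' @param far_window upstream extent of the distal promoter class
#'   (default 3000).
#' @param downstream_window extent of the downstream class past the gene
#'   end (default 3000).
#' @return the CC table with columns \code{gene_id}, \code{tss_dist}
#'   (signed, strand-aware), \code{feature} and logical
#'   \code{promoter_set} appended.
#' @export
annotate_cc <- function(ccs, genes, features = NULL,
                        promoter_window = 1000L, far_window = 3000L,
                        downstream_window = 3000L) {
  ccs$gene_id <- NA_character_
  ccs$tss_dist <- NA_integer_
  ccs$feature <- "Distal intergenic"
  ccs$promoter_set <- FALSE
  if (is.null(genes) || nrow(genes) == 0L) {
    warning("empty gene annotation: all CCs classified distal intergenic")
    return(ccs)
  }
  gene_grp <- paste(genes$chrom, genes$strand, sep = "\r")
  cc_grp <- paste(ccs$chrom, ccs$strand, sep = "\r")
  for (g in unique(cc_grp)) {
    gi <- which(gene_grp == g)
    ci <- which(cc_grp == g)
    if (!length(gi)) next
    tss <- genes$tss[gi]
    o <- order(tss)
    gi <- gi[o]; tss <- tss[o]
    dom <- ccs$dominant_pos[ci]
    left <- pmax(findInterval(dom, tss), 1L)
    right <- pmin(left + 1L, length(tss))
    use_right <- abs(dom - tss[right]) < abs(dom - tss[left])
    nearest <- ifelse(use_right, right, left)
    gidx <- gi[nearest]
    strand <- ccs$strand[ci[1L]]
    d <- if (strand == "+") dom - genes$tss[gidx] else genes$tss[gidx] - dom
    ccs$gene_id[ci] <- genes$gene_id[gidx]
    ccs$tss_dist[ci] <- d
  }
  ccs$feature <- .classify_feature(ccs, genes, features,
                                   promoter_window, far_window,
                                   downstream_window)
  ccs$promoter_set <- ccs$feature %in% c("Promoter (<=1kb)", "5' UTR")
  ccs
}

.classify_feature <- function(ccs, genes, features, promoter_window,
                              far_window, downstream_window) {
  gmatch <- match(ccs$gene_id, genes$gene_id)
  d <- ccs$tss_dist
  n <- nrow(ccs)
  in_feat <- function(kind) {
    out <- logical(n)
    if (is.null(features)) return(out)
    f <- features[features$feature == kind, , drop = FALSE]
    if (nrow(f) == 0L) return(out)
    for (i in seq_len(n)) {
      if (is.na(ccs$gene_id[i])) next
      fi <- f$gene_id == ccs$gene_id[i]
      if (!any(fi)) next
      p <- ccs$dominant_pos[i]
      out[i] <- any(p >= f$start[fi] & p < f$end[fi])
    }
    out
  }
  downstream <- logical(n)
  ok <- !is.na(gmatch)
  if (any(ok)) {
    ge <- genes$gene_end[gmatch[ok]]
    strand <- ccs$strand[ok]
    dp <- ccs$dominant_pos[ok]
    past <- ifelse(strand == "+", dp - ge, ge - dp)
    downstream[ok] <- past > 0 & past <= downstream_window
  }
  feature <- rep("Distal intergenic", n)
  feature[downstream] <- "Downstream (<3kb)"
  sel <- !is.na(d) & d <= -(promoter_window + 1L) & d >= -far_window
  feature[sel] <- "Promoter (1-3kb)"
  feature[in_feat("three_utr")] <- "3' UTR"
  feature[in_feat("intron")] <- "Intron"
  feature[in_feat("exon")] <- "Exon"
  feature[in_feat("five_utr")] <- "5' UTR"
  sel <- !is.na(d) & d >= -promoter_window & d <= 0
  feature[sel] <- "Promoter (<=1kb)"
  feature
}

#' Reduce to one representative CC per gene
#'
#' When several CCs map to the promoter region of one gene, the CC with
#' the highest total expression (tpm summed across samples) represents
#' the gene in gene-level analyses.
#'
#' @param ccs annotated CC table from [annotate_cc()].
#' @param promoter_only restrict to the promoter set (proximal promoter or
#'   5' UTR) before reducing (default TRUE).
#' @return the reduced CC table, one row per gene.
#' @export
reduce_to_gene_representative <- function(ccs, promoter_only = TRUE) {
  if (promoter_only) ccs <- ccs[ccs$promoter_set, , drop = FALSE]
  ccs <- ccs[!is.na(ccs$gene_id), , drop = FALSE]
  if (nrow(ccs) == 0L) return(ccs)
  o <- order(ccs$gene_id, -ccs$total_tpm, ccs$cc_id)
  ccs <- ccs[o, , drop = FALSE]
  out <- ccs[!duplicated(ccs$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
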