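#' Keep CTSSs supported in at least one sample
#'
#' A CTSS key (chrom, pos, strand) is retained in every sample if its
#' normalized expression reaches \code{min_tpm} in at least one sample;
#' otherwise it is dropped from all samples.
#'
#' @param tables named list of CTSS \code{data.frame}s with a \code{tpm}
#'   column.
#' @param min_tpm support threshold in tpm (default 0.5).
#' @return the list with unsupported CTSSs removed from every table.
#' @export
filter_supported_ctss <- function(tables, min_tpm = 0.5) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  for (t in tables) {
    if (!"tpm" %in% names(t)) .stopf("all tables must carry a 'tpm' column")
  }
  if (min_tpm <= 0) return(tables)
  keys <- unlist(lapply(tables, function(t) .ctss_key(t)[t$tpm >= min_tpm]),
                 use.names = FALSE)
  keep <- unique(keys)
  lapply(tables, function(t) {
    out <- t[.ctss_key(t) %in% keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Trim a tag cluster to its 10th-90th expression percentiles
#'
#' Given member CTSS positions (ascending) and their expression, finds the
#' smallest position whose cumulative expression reaches \code{lower} of
#' the cluster total (\code{q_low}) and the smallest reaching \code{upper}
#' (\code{q_high}).  Members outside \code{[q_low, q_high]} are trimmed;
#' the interquantile width counts inclusive bases.
#'
#' @param pos integer positions sorted ascending.
#' @param tpm matching expression values.
#' @param lower,upper cumulative fractions (defaults 0.1 / 0.9).
#' @return list with \code{q_low}, \code{q_high}, \code{iq_width}
#'   (\code{q_high - q_low + 1}) and logical \code{keep} marking retained
#'   members.
#' @export
trim_cluster <- function(pos, tpm, lower = 0.1, upper = 0.9) {
  stopifnot(length(pos) == length(tpm), !is.unsorted(pos))
  tot <- sum(tpm)
  if (tot <= 0) .stopf("cluster has no expression")
  cum <- cumsum(tpm)
  q_low <- pos[which(cum >= lower * tot)[1L]]
  q_high <- pos[which(cum >= upper * tot)[1L]]
  keep <- pos >= q_low & pos <= q_high
  list(q_low = q_low, q_high = q_high,
       iq_width = as.integer(q_high - q_low + 1L), keep = keep)
}

# dominant position: maximal tpm, ties broken towards the 5' end of the
# transcribed strand (smallest position on +, largest on -)
.dominant_pos <- function(pos, tpm, strand) {
  i <- which(tpm == max(tpm))
  if (strand == "-") max(pos[i]) else min(pos[i])
}

#' Call tag clusters in one sample
#'
#' Chains same-strand CTSSs into tag clusters (TCs) while the distance
#' between neighbouring CTSSs stays within \code{max_gap}, trims each
#' cluster to its 10th-90th expression percentiles, and discards trimmed
#' clusters whose total expression does not exceed \code{min_cluster_tpm}.
#'
#' @param tab CTSS \code{data.frame} with \code{tpm}.
#' @param max_gap maximum allowed distance in bp between neighbouring
#'   member CTSSs (default 20; the boundary case merges).
#' @param min_cluster_tpm expression floor; clusters are kept only when
#'   trimmed total tpm is strictly greater (default 5).
#' @param sample_id optional label stored in the output.
#' @return \code{data.frame} with one row per retained TC: \code{chrom},
#'   \code{strand}, \code{start}, \code{end} (the trimmed span),
#'   \code{dominant_pos}, \code{dominant_tpm}, \code{total_tpm},
#'   \code{iq_width}, \code{n_ctss}.
#' @export
call_tag_clusters <- function(tab, max_gap = 20L, min_cluster_tpm = 5,
                              sample_id = NA_character_) {
  if (!"tpm" %in% names(tab)) .stopf("CTSS table must carry 'tpm'")
  if (nrow(tab) == 0L) return(.empty_tc(sample_id))
  o <- order(tab$chrom, tab$strand, tab$pos)
  tab <- tab[o, , drop = FALSE]
  grp <- paste(tab$chrom, tab$strand, sep = "\r")
  new_grp <- c(TRUE, grp[-1L] != grp[-nrow(tab)])
  gap_break <- c(TRUE, diff(tab$pos) > max_gap)
  cid <- cumsum(new_grp | gap_break)
  idx <- split(seq_len(nrow(tab)), cid)
  rows <- lapply(idx, function(i) {
    pos <- tab$pos[i]; tpm <- tab$tpm[i]
    tr <- trim_cluster(pos, tpm)
    pos <- pos[tr$keep]; tpm <- tpm[tr$keep]
    tot <- sum(tpm)
    if (tot <= min_cluster_tpm) return(NULL)
    strand <- tab$strand[i[1L]]
    dom <- .dominant_pos(pos, tpm, strand)
    data.frame(sample_id = sample_id, chrom = tab$chrom[i[1L]],
               strand = strand, start = tr$q_low, end = tr$q_high,
               dominant_pos = dom, dominant_tpm = max(tpm),
               total_tpm = tot, iq_width = tr$iq_width,
               n_ctss = length(pos), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.empty_tc(sample_id))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.empty_tc <- function(sample_id = NA_character_) {
  data.frame(sample_id = character(), chrom = character(),
             strand = character(), start = integer(), end = integer(),
             dominant_pos = integer(), dominant_tpm = numeric(),
             total_tpm = numeric(), iq_width = integer(),
             n_ctss = integer(), stringsAsFactors = FALSE)
}

# assign positions to sorted non-overlapping intervals; 0 = unassigned
.assign_to_intervals <- function(pos, starts, ends) {
  idx <- findInterval(pos, starts)
  ok <- idx > 0L
  ok[ok] <- pos[ok] <= ends[idx[ok]]
  idx[!ok] <- 0L
  idx
}

#' Aggregate tag clusters across samples into consensus clusters
#'
#' Same-strand tag clusters from any sample are merged transitively
#' whenever the gap between their spans (next start minus current end) is
#' at most \code{max_cc_gap}.  Each consensus cluster (CC) then receives
#' per-sample expression (tpm, and raw counts when present) summed over
#' the sample's CTSSs inside the CC span, plus pooled (all samples
#' combined) dominant TSS, interquantile width and dominant fraction.
#'
#' @param tc_list named list of per-sample tag-cluster tables from
#'   [call_tag_clusters()].
#' @param ctss_tables named list (same names) of the supported CTSS
#'   tables with \code{tpm}.
#' @param max_cc_gap maximum merging gap in bp (default 100; the boundary
#'   case merges).
#' @return \code{data.frame} with one row per CC: \code{cc_id},
#'   coordinates, pooled \code{dominant_pos}, \code{iq_width},
#'   \code{dominant_fraction}, \code{total_tpm}, and per-sample
#'   \code{tpm_<sample>} (and \code{count_<sample>}) columns.
#' @export
build_consensus_clusters <- function(tc_list, ctss_tables,
                                     max_cc_gap = 100L) {
  stopifnot(is.list(tc_list), is.list(ctss_tables),
            !is.null(names(ctss_tables)))
  tcs <- do.call(rbind, lapply(tc_list, function(t)
    t[, c("chrom", "strand", "start", "end")]))
  if (is.null(tcs) || nrow(tcs) == 0L)
    .stopf("no tag clusters to aggregate")
  grp <- paste(tcs$chrom, tcs$strand, sep = "\r")
  ccs <- do.call(rbind, lapply(split(seq_len(nrow(tcs)), grp), function(i) {
    s <- tcs$start[i]; e <- tcs$end[i]
    o <- order(s, e)
    s <- s[o]; e <- e[o]
    run_end <- e[1L]
    gid <- integer(length(s)); gid[1L] <- 1L
    if (length(s) > 1L) {
      for (j in 2L:length(s)) {
        if (s[j] - run_end > max_cc_gap) {
          gid[j] <- gid[j - 1L] + 1L
          run_end <- e[j]
        } else {
          gid[j] <- gid[j - 1L]
          run_end <- max(run_end, e[j])
        }
      }
    }
    data.frame(chrom = tcs$chrom[i[1L]], strand = tcs$strand[i[1L]],
               start = tapply(s, gid, min), end = tapply(e, gid, max),
               stringsAsFactors = FALSE)
  }))
  ccs <- ccs[order(ccs$chrom, ccs$start, ccs$strand), , drop = FALSE]
  rownames(ccs) <- NULL
  ccs$cc_id <- sprintf("cc_%06d", seq_len(nrow(ccs)))
  ccs <- ccs[, c("cc_id", "chrom", "strand", "start", "end")]

  # pooled per-position expression across samples
  pooled <- do.call(rbind, lapply(ctss_tables, function(t)
    t[, c("chrom", "pos", "strand", "tpm")]))
  key <- paste(pooled$chrom, pooled$pos, pooled$strand, sep = "\r")
  agg <- rowsum(pooled$tpm, key)
  first <- !duplicated(key)
  pooled <- pooled[first, , drop = FALSE]
  pooled$tpm <- agg[match(key[first], rownames(agg)), 1L]

  ccs$dominant_pos <- NA_integer_
  ccs$iq_width <- NA_integer_
  ccs$dominant_fraction <- NA_real_
  ccs$total_tpm <- 0

  cc_of <- .map_ctss_to_cc(pooled, ccs)
  inside <- which(cc_of > 0L)
  for (grp_i in split(inside, cc_of[inside])) {
    j <- as.integer(cc_of[grp_i[1L]])
    o <- order(pooled$pos[grp_i])
    pos <- pooled$pos[grp_i][o]; tpm <- pooled$tpm[grp_i][o]
    tr <- trim_cluster(pos, tpm)
    ccs$dominant_pos[j] <- .dominant_pos(pos, tpm, ccs$strand[j])
    ccs$iq_width[j] <- tr$iq_width
    tot <- sum(tpm)
    ccs$dominant_fraction[j] <- max(tpm) / tot
    ccs$total_tpm[j] <- tot
  }

  for (s in names(ctss_tables)) {
    t <- ctss_tables[[s]]
    cc_of_s <- .map_ctss_to_cc(t, ccs)
    tpm_col <- numeric(nrow(ccs))
    hit <- cc_of_s > 0L
    if (any(hit)) {
      a <- rowsum(t$tpm[hit], cc_of_s[hit])
      tpm_col[as.integer(rownames(a))] <- a[, 1L]
    }
    ccs[[paste0("tpm_", s)]] <- tpm_col
    if ("count" %in% names(t)) {
      cnt_col <- numeric(nrow(ccs))
      if (any(hit)) {
        a <- rowsum(t$count[hit], cc_of_s[hit])
        cnt_col[as.integer(rownames(a))] <- a[, 1L]
      }
      ccs[[paste0("count_", s)]] <- cnt_col
    }
  }
  ccs
}

# map CTSS rows to cc row indices (0 = outside every CC)
.map_ctss_to_cc <- function(tab, ccs) {
  out <- integer(nrow(tab))
  tab_grp <- paste(tab$chrom, tab$strand, sep = "\r")
  cc_grp <- paste(ccs$chrom, ccs$strand, sep = "\r")
  for (g in unique(tab_grp)) {
    ti <- which(tab_grp == g)
    ci <- which(cc_grp == g)
    if (!length(ci)) next
    o <- order(ccs$start[ci])
    ci <- ci[o]
    idx <- .assign_to_intervals(tab$pos[ti], ccs$start[ci], ccs$end[ci])
    out[ti[idx > 0L]] <- ci[idx[idx > 0L]]
  }
  out
}

#' Per-sample shape statistics of consensus clusters
#'
#' Computes, for one sample, the expression, interquantile width, dominant
#' TSS and dominant fraction of each CC using that sample's CTSSs inside
#' the CC span.
#'
#' @param ccs consensus-cluster table from [build_consensus_clusters()].
#' @param ctss_tab the sample's CTSS table with \code{tpm}.
#' @param sample_id label stored in the output.
#' @return \code{data.frame} with \code{cc_id}, \code{sample_id},
#'   \code{tpm}, \code{iq_width}, \code{dominant_pos},
#'   \code{dominant_fraction}; CCs without expression in this sample get
#'   \code{tpm = 0} and \code{NA} statistics.
#' @export
cc_shape_stats <- function(ccs, ctss_tab, sample_id = NA_character_) {
  out <- data.frame(cc_id = ccs$cc_id, sample_id = sample_id,
                    tpm = 0, iq_width = NA_integer_,
                    dominant_pos = NA_integer_,
                    dominant_fraction = NA_real_,
                    stringsAsFactors = FALSE)
  cc_of <- .map_ctss_to_cc(ctss_tab, ccs)
  inside <- which(cc_of > 0L)
  for (grp_i in split(inside, cc_of[inside])) {
    j <- as.integer(cc_of[grp_i[1L]])
    o <- order(ctss_tab$pos[grp_i])
    pos <- ctss_tab$pos[grp_i][o]; tpm <- ctss_tab$tpm[grp_i][o]
    tr <- trim_cluster(pos, tpm)
    out$tpm[j] <- sum(tpm)
    out$iq_width[j] <- tr$iq_width
    out$dominant_pos[j] <- .dominant_pos(pos, tpm, ccs$strand[j])
    out$dominant_fraction[j] <- max(tpm) / sum(tpm)
  }
  out
}
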