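#' Per-offset PWM match percentages in a promoter window
#'
#' Scores the sense strand of a promoter window at every offset where the
#' full motif fits, using log2-odds against the PWM background, and
#' rescales scores to a match percentage between the PWM's attainable
#' minimum (0) and maximum (100).
#'
#' @param pwm a \code{pwm_model}.
#' @param window a \code{promoter_window} from
#'   [extract_promoter_window()], or a plain character sequence (then
#'   \code{offset_start} gives its frame).
#' @param offset_start frame offset of the first base when \code{window}
#'   is a bare string; ignored otherwise.
#' @return \code{data.frame} with \code{offset} (motif start relative to
#'   the dominant TSS) and \code{match_percent}.
#' @details Bases outside A/C/G/T contribute a background (zero log-odds)
#'   score.  A degenerate PWM whose maximum equals its minimum attainable
#'   score is an error.
#' @export
pwm_match_percent <- function(pwm, window, offset_start = 0L) {
  if (inherits(window, "promoter_window")) {
    seq <- window$seq
    offset_start <- window$offset_start
  } else seq <- window
  S <- log2(pwm$freq / pwm$background)
  L <- ncol(S)
  smin <- sum(apply(S, 2L, min))
  smax <- sum(apply(S, 2L, max))
  if (smax <= smin) .stopf("degenerate PWM '%s': max score equals min",
                           pwm$name)
  n <- nchar(seq)
  if (n < L)
    return(data.frame(offset = integer(), match_percent = numeric()))
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]],
               c("A", "C", "G", "T"))
  n_off <- n - L + 1L
  score <- numeric(n_off)
  for (j in seq_len(L)) {
    col <- S[, j]
    b <- idx[j:(j + n_off - 1L)]
    contrib <- col[b]
    contrib[is.na(b)] <- 0
    score <- score + contrib
  }
  data.frame(offset = offset_start + seq_len(n_off) - 1L,
             match_percent = 100 * (score - smin) / (smax - smin))
}

#' Scan promoter windows for motif hits
#'
#' Scans each window with each PWM (sense strand only) and reports the
#' best match percentage, its offset, and whether any offset reaches the
#' hit threshold.  Optionally restricts motif start offsets to a region
#' relative to the dominant TSS.
#'
#' @param windows named list of \code{promoter_window}s (names are CC
#'   ids).
#' @param pwms named list of \code{pwm_model}s.
#' @param threshold match percentage defining a hit (default 90).
#' @param region optional length-2 integer range of allowed motif start
#'   offsets, inclusive (e.g. \code{c(-40, -20)}).
#' @return \code{data.frame} with \code{cc_id}, \code{motif},
#'   \code{best_match}, \code{best_offset}, \code{is_hit}; the attribute
#'   \code{"hits"} holds every threshold-passing offset
#'   (\code{cc_id}, \code{motif}, \code{offset}, \code{match_percent}).
#' @export
scan_promoters <- function(windows, pwms, threshold = 90, region = NULL) {
  stopifnot(!is.null(names(windows)), !is.null(names(pwms)))
  rows <- vector("list", length(windows) * length(pwms))
  hit_rows <- list()
  k <- 0L
  for (w in names(windows)) {
    for (m in names(pwms)) {
      k <- k + 1L
      sc <- pwm_match_percent(pwms[[m]], windows[[w]])
      if (!is.null(region))
        sc <- sc[sc$offset >= region[1L] & sc$offset <= region[2L], ,
                 drop = FALSE]
      if (nrow(sc) == 0L) {
        rows[[k]] <- data.frame(cc_id = w, motif = m,
                                best_match = NA_real_,
                                best_offset = NA_integer_,
                                is_hit = FALSE, stringsAsFactors = FALSE)
        next
      }
      best <- which.max(sc$match_percent)
      pass <- sc$match_percent >= threshold
      rows[[k]] <- data.frame(cc_id = w, motif = m,
                              best_match = sc$match_percent[best],
                              best_offset = sc$offset[best],
                              is_hit = any(pass), stringsAsFactors = FALSE)
      if (any(pass)) {
        hit_rows[[length(hit_rows) + 1L]] <-
          data.frame(cc_id = w, motif = m, offset = sc$offset[pass],
                     match_percent = sc$match_percent[pass],
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "hits") <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(cc_id = character(), motif = character(),
               offset = integer(), match_percent = numeric())
  out
}

# 2x2 Fisher with sample odds ratio; Haldane 0.5 correction when any cell
# is zero (for the odds ratio only; the exact p uses the raw table)
.fisher2x2 <- function(a, b, c, d) {
  p <- fisher.test(matrix(c(a, b, c, d), 2L, byrow = TRUE))$p.value
  if (min(a, b, c, d) == 0L) {
    or <- (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5))
  } else or <- (a * d) / (b * c)
  list(or = or, p = p)
}

#' Motif enrichment of gene groups against a background group
#'
#' For each motif and each group of CCs, counts promoters with at least
#' one hit, compares against the background group with a two-sided
#' Fisher's exact test, and reports the log2 odds ratio (Haldane 0.5
#' correction when any cell of the 2x2 table is zero).
#'
#' @param scan result of [scan_promoters()] (uses \code{is_hit}).
#' @param groups named character vector mapping \code{cc_id} to group.
#' @param background_group name of the background (e.g. the
#'   non-significant CC set).
#' @param p_threshold significance cut applied to the raw Fisher p
#'   (default 0.01).
#' @return \code{data.frame} with \code{motif}, \code{group}, the 2x2
#'   cells \code{a} (group hits), \code{b} (group misses), \code{c}
#'   (background hits), \code{d} (background misses),
#'   \code{log2_odds_ratio}, \code{p_value}, \code{p_bh} (optional BH
#'   column over all tests) and \code{significant}.
#' @export
motif_enrichment <- function(scan, groups, background_group,
                             p_threshold = 0.01) {
  scan <- scan[scan$cc_id %in% names(groups), , drop = FALSE]
  scan$group <- unname(groups[scan$cc_id])
  if (!background_group %in% scan$group)
    .stopf("background group '%s' has no scanned CCs", background_group)
  rows <- list()
  for (m in unique(scan$motif)) {
    sm <- scan[scan$motif == m, , drop = FALSE]
    bg <- sm$group == background_group
    cc <- sum(sm$is_hit[bg]); dd <- sum(!sm$is_hit[bg])
    for (g in setdiff(unique(sm$group), background_group)) {
      gi <- sm$group == g
      if (!any(gi)) {
        warning(sprintf("empty group '%s' skipped for motif '%s'", g, m))
        next
      }
      a <- sum(sm$is_hit[gi]); b <- sum(!sm$is_hit[gi])
      ft <- .fisher2x2(a, b, cc, dd)
      rows[[length(rows) + 1L]] <-
        data.frame(motif = m, group = g, a = a, b = b, c = cc, d = dd,
                   log2_odds_ratio = log2(ft$or), p_value = ft$p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_bh <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < p_threshold
  out
}

#' Best TATA match per promoter in the canonical placement region
#'
#' Reports, per promoter, the maximum PWM match percentage with the motif
#' start restricted to \code{region} (default -40..-20 bp of the dominant
#' TSS), and bins the distribution (default bins: below 75, 75-90, above
#' 90).
#'
#' @param windows named list of \code{promoter_window}s.
#' @param tata_pwm the TATA-box \code{pwm_model}.
#' @param region inclusive motif-start offset range.
#' @param breaks two cut points defining the three bins.
#' @return list with \code{per_promoter} (\code{cc_id},
#'   \code{best_match}, \code{bin}) and \code{bins} (counts per bin).
#' @export
tata_match_distribution <- function(windows, tata_pwm,
                                    region = c(-40L, -20L),
                                    breaks = c(75, 90)) {
  sc <- scan_promoters(windows, list(TATA = tata_pwm), threshold = Inf,
                       region = region)
  lev <- c(sprintf("<%g", breaks[1L]),
           sprintf("%g-%g", breaks[1L], breaks[2L]),
           sprintf(">%g", breaks[2L]))
  bin <- ifelse(sc$best_match < breaks[1L], lev[1L],
                ifelse(sc$best_match <= breaks[2L], lev[2L], lev[3L]))
  per <- data.frame(cc_id = sc$cc_id, best_match = sc$best_match,
                    bin = factor(bin, lev), stringsAsFactors = FALSE)
  list(per_promoter = per, bins = table(per$bin))
}

#' WW-dinucleotide frequency profile across promoter windows
#'
#' At each offset of the strand-oriented promoter frame, the fraction of
#' promoters whose bases at (offset, offset + 1) are both A or T.
#'
#' @param windows named list of \code{promoter_window}s.
#' @return \code{data.frame} with \code{offset}, \code{frequency} and
#'   \code{n} (windows covering the offset pair).
#' @export
ww_dinucleotide_profile <- function(windows) {
  lo <- min(vapply(windows, `[[`, integer(1), "offset_start"))
  hi <- max(vapply(windows, function(w)
    w$offset_start + nchar(w$seq) - 1L, integer(1)))
  offs <- lo:(hi - 1L)
  ww_n <- n_cov <- integer(length(offs))
  for (w in windows) {
    chars <- strsplit(w$seq, "", fixed = TRUE)[[1]]
    is_w <- chars %in% c("A", "T")
    if (length(is_w) < 2L) next
    pair_w <- is_w[-length(is_w)] & is_w[-1L]
    at <- (w$offset_start + seq_along(pair_w) - 1L) - lo + 1L
    ww_n[at] <- ww_n[at] + pair_w
    n_cov[at] <- n_cov[at] + 1L
  }
  data.frame(offset = offs, frequency = ifelse(n_cov > 0, ww_n / n_cov, NA),
             n = n_cov)
}

#' Poly-W pentamer enrichment in the TATA placement region
#'
#' Enumerates all 32 pentamers over \{A, T\}, counts promoters containing
#' each with the pentamer start inside \code{region}, compares each group
#' against the background group by Fisher's exact test, and flags
#' occurrences overlapping a canonical TATA-box PWM hit (match at or above
#' \code{threshold}) to separate TATA-embedded W-boxes from TATA-free
#' ones.
#'
#' @param windows named list of \code{promoter_window}s.
#' @param groups named character vector mapping window name to group.
#' @param background_group the comparison group.
#' @param region inclusive pentamer-start offset range (default -40..-20).
#' @param tata_pwm optional TATA \code{pwm_model} used for overlap flags.
#' @param threshold TATA hit threshold (default 90).
#' @return \code{data.frame} per pentamer x group: cells \code{a,b,c,d},
#'   \code{log2_odds_ratio}, \code{p_value}, and
#'   \code{n_tata_overlap} / \code{n_occurrences} over the group's
#'   occurrences.
#' @export
polyw_pentamer_enrichment <- function(windows, groups, background_group,
                                      region = c(-40L, -20L),
                                      tata_pwm = NULL, threshold = 90) {
  pent <- apply(expand.grid(rep(list(c("A", "T")), 5L))[, 5:1], 1L,
                paste, collapse = "")
  occ <- matrix(FALSE, length(windows), length(pent),
                dimnames = list(names(windows), pent))
  tata_olap <- matrix(FALSE, length(windows), length(pent),
                      dimnames = dimnames(occ))
  for (w in names(windows)) {
    win <- windows[[w]]
    tata_spans <- NULL
    if (!is.null(tata_pwm)) {
      sc <- pwm_match_percent(tata_pwm, win)
      hit <- sc$offset[sc$match_percent >= threshold]
      if (length(hit))
        tata_spans <- cbind(hit, hit + ncol(tata_pwm$freq) - 1L)
    }
    starts <- region[1L]:region[2L]
    for (s in starts) {
      i <- s - win$offset_start + 1L
      if (i < 1L || i + 4L > nchar(win$seq)) next
      kmer <- substr(win$seq, i, i + 4L)
      if (!kmer %in% pent) next
      occ[w, kmer] <- TRUE
      if (!is.null(tata_spans)) {
        if (any(s <= tata_spans[, 2L] & (s + 4L) >= tata_spans[, 1L]))
          tata_olap[w, kmer] <- TRUE
      }
    }
  }
  grp <- unname(groups[rownames(occ)])
  bg <- grp == background_group
  if (!any(bg)) .stopf("background group '%s' has no windows",
                       background_group)
  rows <- list()
  for (g in setdiff(unique(grp[!is.na(grp)]), background_group)) {
    gi <- grp == g & !is.na(grp)
    for (k in pent) {
      a <- sum(occ[gi, k]); b <- sum(gi) - a
      cc <- sum(occ[bg, k]); dd <- sum(bg) - cc
      ft <- .fisher2x2(a, b, cc, dd)
      rows[[length(rows) + 1L]] <-
        data.frame(pentamer = k, group = g, a = a, b = b, c = cc, d = dd,
                   log2_odds_ratio = log2(ft$or), p_value = ft$p,
                   n_occurrences = a,
                   n_tata_overlap = sum(tata_olap[gi, k]),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
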