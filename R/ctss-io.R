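#' Read a CTSS count table
#'
#' Reads a per-sample table of CAGE-defined transcription start sites
#' (CTSSs): one row per unique 5' end position with its raw tag count.
#' The expected dialect is tab-separated with columns
#' \code{chrom}, \code{pos} (1-based), \code{strand} (\code{+}/\code{-})
#' and \code{count}.
#'
#' @param path path to a TSV file.
#' @param header logical; does the file carry a header line?  Column order
#'   is positional either way.
#' @return a \code{data.frame} with columns \code{chrom} (character),
#'   \code{pos} (integer), \code{strand} (character) and \code{count}
#'   (numeric), sorted by (chrom, pos, strand).
#' @details Duplicate (chrom, pos, strand) keys, positions below 1,
#'   negative counts and malformed lines are errors; malformed lines are
#'   reported with their line number.  An empty file yields an empty table.
#' @seealso [write_ctss()], [normalize_to_tpm()]
#' @export
read_ctss <- function(path, header = FALSE) {
  if (!file.exists(path)) .stopf("CTSS file not found: %s", path)
  nf <- tryCatch(count.fields(path, sep = "\t", quote = ""),
                 error = function(e) .stopf("cannot read %s: %s", path,
                                            conditionMessage(e)))
  if (length(nf) == 0L || (header && length(nf) == 1L)) {
    return(.empty_ctss())
  }
  body_lines <- if (header) seq_along(nf)[-1L] else seq_along(nf)
  bad <- body_lines[nf[body_lines] != 4L]
  if (length(bad)) {
    .stopf("malformed CTSS line %d in %s: expected 4 tab-separated fields, found %d",
           bad[1L], path, nf[bad[1L]])
  }
  tab <- read.delim(path, header = header, sep = "\t", quote = "",
                    col.names = c("chrom", "pos", "strand", "count"),
                    colClasses = c("character", "character", "character",
                                   "character"),
                    stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.integer(tab$pos))
  count <- suppressWarnings(as.numeric(tab$count))
  if (anyNA(pos)) {
    i <- which(is.na(pos))[1L]
    .stopf("malformed CTSS line %d in %s: non-integer position '%s'",
           i + header, path, tab$pos[i])
  }
  if (anyNA(count)) {
    i <- which(is.na(count))[1L]
    .stopf("malformed CTSS line %d in %s: non-numeric count '%s'",
           i + header, path, tab$count[i])
  }
  out <- data.frame(chrom = tab$chrom, pos = pos, strand = tab$strand,
                    count = count, stringsAsFactors = FALSE)
  validate_ctss(out, where = path)
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_ctss <- function() {
  data.frame(chrom = character(), pos = integer(), strand = character(),
             count = numeric(), stringsAsFactors = FALSE)
}

#' Validate a CTSS table
#'
#' Checks the CTSS invariants: 1-based positions, non-negative counts,
#' strand in \code{+}/\code{-}, unique (chrom, pos, strand) keys.
#'
#' @param tab a CTSS \code{data.frame}.
#' @param where label used in error messages.
#' @return the table, invisibly, if valid; otherwise an error.
#' @export
validate_ctss <- function(tab, where = "CTSS table") {
  need <- c("chrom", "pos", "strand", "count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) .stopf("%s: missing column(s) %s", where,
                           paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) return(invisible(tab))
  if (any(tab$pos < 1L)) .stopf("%s: positions must be >= 1", where)
  if (any(tab$count < 0)) .stopf("%s: negative tag count", where)
  if (!all(tab$strand %in% c("+", "-")))
    .stopf("%s: strand must be '+' or '-'", where)
  key <- .ctss_key(tab)
  if (anyDuplicated(key)) {
    d <- tab[duplicated(key), , drop = FALSE][1L, ]
    .stopf("%s: duplicate CTSS key (%s, %d, %s)", where,
           d$chrom, d$pos, d$strand)
  }
  invisible(tab)
}

#' Write a CTSS table
#'
#' Writes a CTSS table as headered TSV, including the \code{tpm} column
#' when present.
#'
#' @param tab a CTSS \code{data.frame}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ctss <- function(tab, path) {
  validate_ctss(tab)
  keep <- intersect(c("chrom", "pos", "strand", "count", "tpm"), names(tab))
  .write_tsv(tab[, keep, drop = FALSE], path)
}

#' Merge replicate CTSS tables by summing raw counts
#'
#' Biological replicates that pass QC are merged before cluster-level
#' analyses; merging sums raw tag counts per (chrom, pos, strand) so a
#' single joint normalization stays well defined.
#'
#' @param tables list of CTSS \code{data.frame}s.
#' @return one CTSS \code{data.frame} with summed counts.
#' @export
merge_ctss_samples <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  all <- do.call(rbind, lapply(tables, function(t) {
    validate_ctss(t)
    t[, c("chrom", "pos", "strand", "count")]
  }))
  if (nrow(all) == 0L) return(.empty_ctss())
  key <- .ctss_key(all)
  cnt <- rowsum(all$count, key)
  first <- !duplicated(key)
  out <- all[first, , drop = FALSE]
  out$count <- cnt[match(key[first], rownames(cnt)), 1L]
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
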