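#' Read a genome FASTA
#'
#' Thin wrapper over \pkg{Biostrings} returning sequences as a named
#' character vector (names truncated at the first whitespace, matching
#' \code{.fai} conventions).
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write a genome FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Extract a strand-oriented promoter window around a dominant TSS
#'
#' Returns the sequence covering \code{up} bases 5' and \code{down} bases
#' 3' of a dominant TSS on the transcribed strand.  On the minus strand
#' the genomic interval is mirrored and reverse-complemented, so that in
#' the returned coordinate frame offset 0 is always the dominant TSS and
#' negative offsets are upstream (5').
#'
#' @param genome named character vector from [read_genome()].
#' @param chrom chromosome name.
#' @param pos 1-based position of the dominant TSS.
#' @param strand \code{"+"} or \code{"-"}.
#' @param up,down bases upstream / downstream of the TSS (defaults 120/50).
#' @return a \code{promoter_window}: a list with \code{seq} (character),
#'   \code{offset_start} (offset of the first returned base relative to
#'   the TSS), \code{clipped} (logical, TRUE when the window hit a
#'   chromosome end), and the request coordinates.
#' @export
extract_promoter_window <- function(genome, chrom, pos, strand,
                                    up = 120L, down = 50L) {
  if (!chrom %in% names(genome))
    .stopf("chromosome '%s' absent from genome", chrom)
  len <- nchar(genome[[chrom]])
  if (pos < 1L || pos > len)
    .stopf("position %d outside chromosome '%s' (length %d)", pos, chrom, len)
  if (strand == "+") {
    gstart <- max(1L, pos - up)
    gend <- min(len, pos + down)
    seq <- substr(genome[[chrom]], gstart, gend)
    offset_start <- gstart - pos
  } else if (strand == "-") {
    gstart <- max(1L, pos - down)
    gend <- min(len, pos + up)
    seq <- .revcomp(substr(genome[[chrom]], gstart, gend))
    offset_start <- pos - gend
  } else .stopf("strand must be '+' or '-'")
  clipped <- (pos - up < 1L) || (pos + down > len)
  structure(list(seq = seq, offset_start = as.integer(offset_start),
                 clipped = clipped, chrom = chrom, pos = as.integer(pos),
                 strand = strand, up = as.integer(up),
                 down = as.integer(down)),
            class = "promoter_window")
}

#' @export
print.promoter_window <- function(x, ...) {
  cat(sprintf("<promoter_window> %s:%d(%s) offsets %d..%d%s\n%s\n",
              x$chrom, x$pos, x$strand, x$offset_start,
              x$offset_start + nchar(x$seq) - 1L,
              if (x$clipped) " [clipped]" else "", x$seq))
  invisible(x)
}

#' Extract promoter windows for a table of dominant TSSs
#'
#' Vectorized companion of [extract_promoter_window()].
#'
#' @param genome named character vector.
#' @param tab data.frame with columns \code{chrom}, \code{pos},
#'   \code{strand}; rownames (or a \code{cc_id} column) name the windows.
#' @inheritParams extract_promoter_window
#' @return named list of \code{promoter_window} objects.
#' @export
extract_promoter_windows <- function(genome, tab, up = 120L, down = 50L) {
  ids <- if ("cc_id" %in% names(tab)) tab$cc_id else rownames(tab)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    extract_promoter_window(genome, tab$chrom[i], tab$pos[i], tab$strand[i],
                            up = up, down = down)
  })
  names(out) <- ids
  out
}
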