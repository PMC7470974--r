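# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm median pchisq pnorm pt quantile rnbinom runif
#'   rmultinom dnorm p.adjust fisher.test uniroot var setNames aggregate
#' @importFrom utils read.delim write.table head count.fields
NULL

.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, ...)
}

# reverse complement of a plain character DNA string (IUPAC subset ACGTN)
.revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.ctss_key <- function(tab) paste(tab$chrom, tab$pos, tab$strand, sep = "\r")

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
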