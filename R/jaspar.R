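#' Read position frequency matrices in JASPAR text format
#'
#' Parses one or more position frequency matrices (PFMs) from a JASPAR-style
#' text file: a \code{">ID NAME"} header followed by four rows of
#' non-negative counts for A, C, G, T (optionally bracketed, e.g.
#' \code{A [ 4 19 0 ]}).
#'
#' @param path path to the PFM text file.
#' @param pseudocount total pseudocount added per column, spread according
#'   to \code{background}.  Avoids minus-infinite log-odds for zero counts.
#' @param background base composition used both to spread the pseudocount
#'   and as the log-odds background; defaults to uniform.
#' @return a named list of \code{pwm_model} objects.  Each holds the raw
#'   \code{counts} matrix, the regularized column-stochastic \code{freq}
#'   matrix, \code{name}, \code{id}, \code{pseudocount} and
#'   \code{background}.
#' @details Rows of unequal length, files without exactly four base rows
#'   per record, and columns whose raw counts are all zero are errors.
#' @export
read_jaspar <- function(path, pseudocount = 0.8,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (!file.exists(path)) .stopf("PFM file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) .stopf("%s: no '>' record headers found", path)
  bounds <- c(heads, length(lines) + 1L)
  out <- list()
  for (i in seq_along(heads)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    id <- toks[1L]
    name <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ") else id
    if (length(block) != 4L)
      .stopf("%s: record '%s' must have exactly 4 base rows, found %d",
             path, id, length(block))
    rows <- lapply(block, .parse_pfm_row)
    bases <- vapply(rows, `[[`, character(1), "base")
    if (!setequal(bases, c("A", "C", "G", "T")))
      .stopf("%s: record '%s' must carry rows A, C, G, T", path, id)
    lens <- vapply(rows, function(r) length(r$counts), integer(1))
    if (length(unique(lens)) != 1L)
      .stopf("%s: record '%s' has rows of unequal length", path, id)
    counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
    rownames(counts) <- bases
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
    out[[name]] <- pwm_model(counts, name = name, id = id,
                             pseudocount = pseudocount,
                             background = background)
  }
  out
}

.parse_pfm_row <- function(line) {
  base <- NA_character_
  m <- regmatches(line, regexec("^([ACGTacgt])\\b", line))[[1]]
  if (length(m)) {
    base <- toupper(m[2L])
    line <- sub("^[ACGTacgt]\\s*", "", line)
  }
  line <- gsub("\\[|\\]", " ", line)
  vals <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
  if (anyNA(vals)) .stopf("cannot parse PFM row: '%s'", line)
  if (any(vals < 0)) .stopf("negative PFM count in row: '%s'", line)
  list(base = base, counts = vals)
}

#' Construct a position weight matrix model
#'
#' Builds a \code{pwm_model} from a 4 x L count (or frequency) matrix with
#' rows A, C, G, T.  Columns are regularized with a background-spread
#' pseudocount and normalized to sum to one.
#'
#' @param counts numeric 4 x L matrix, rownames A/C/G/T.
#' @param name,id motif labels.
#' @inheritParams read_jaspar
#' @return an object of class \code{pwm_model}.
#' @export
pwm_model <- function(counts, name = "motif", id = name, pseudocount = 0.8,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) .stopf("PWM '%s': need 4 rows (A,C,G,T)", name)
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (ncol(counts) < 2L) .stopf("PWM '%s': length must be >= 2", name)
  cs <- colSums(counts)
  if (any(cs <= 0)) .stopf("PWM '%s': column %d has all-zero counts",
                           name, which(cs <= 0)[1L])
  background <- background / sum(background)
  freq <- sweep(counts, 2L,
                cs + pseudocount, "/") + (pseudocount * background) %o%
    (1 / (cs + pseudocount))
  structure(list(name = name, id = id, counts = counts, freq = freq,
                 pseudocount = pseudocount, background = background),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("<pwm_model> %s (%s), length %d, consensus %s\n",
              x$name, x$id, ncol(x$freq), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param pwm a \code{pwm_model}.
#' @return character string of per-column majority bases.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$freq)[apply(pwm$freq, 2L, which.max)], collapse = "")
}

#' Write PFMs in JASPAR text format
#'
#' Writes raw count matrices back out in the same dialect accepted by
#' [read_jaspar()], so a read-write-read cycle is an identity on counts.
#'
#' @param pwms a \code{pwm_model} or list of them.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  if (inherits(pwms, "pwm_model")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}
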