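#' Fit a power law to the reverse-cumulative count distribution
#'
#' CAGE tag counts per CTSS follow an approximate power law: the
#' reverse-cumulative frequency r(x) = #\{CTSS with count >= x\} is close
#' to linear in log-log space.  This fits an ordinary least-squares line
#' to log10 r(x) versus log10 x over the distinct raw counts inside
#' \code{fit_range}, one point per distinct count.
#'
#' @param counts numeric vector of raw per-CTSS tag counts (a multiset;
#'   repeats allowed).
#' @param fit_range numeric length-2, counts included in the fit
#'   (inclusive).  Default \code{c(5, 1000)} covers the stable mid-range
#'   of typical CAGE libraries.
#' @return a \code{power_law_model} with \code{fitted_slope} (expected
#'   negative), \code{fitted_intercept} (log10 scale), \code{fit_range}
#'   and \code{n_points}.
#' @details At least 10 distinct count values must fall inside
#'   \code{fit_range}; otherwise an error suggests widening the range.
#' @seealso [normalize_to_tpm()]
#' @export
fit_power_law <- function(counts, fit_range = c(5, 1000)) {
  stopifnot(length(fit_range) == 2L, fit_range[1] >= 1,
            fit_range[1] < fit_range[2])
  counts <- counts[counts > 0]
  tab <- table(counts)
  x <- as.numeric(names(tab))
  revcum <- rev(cumsum(rev(as.numeric(tab))))
  keep <- x >= fit_range[1] & x <= fit_range[2]
  if (sum(keep) < 10L)
    .stopf(paste0("only %d distinct count values inside fit_range [%g, %g]; ",
                  "need >= 10 - widen fit_range"),
           sum(keep), fit_range[1], fit_range[2])
  fit <- lm(log10(revcum[keep]) ~ log10(x[keep]))
  structure(list(fitted_slope = unname(coef(fit)[2L]),
                 fitted_intercept = unname(coef(fit)[1L]),
                 fit_range = fit_range, n_points = sum(keep)),
            class = "power_law_model")
}

#' @export
print.power_law_model <- function(x, ...) {
  cat(sprintf(paste0("<power_law_model> slope %.4f, intercept %.4f ",
                     "(%d points in [%g, %g])\n"),
              x$fitted_slope, x$fitted_intercept, x$n_points,
              x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

# Scale beta of the reference law r_ref(y) = beta * y^(-alpha), chosen so
# that the law's implied total tag count equals total_ref.  For an
# integer-valued law, sum_k r(k) over k = 1..kmax equals the total tag
# count, where kmax = floor(beta^(1/alpha)) is the largest count with at
# least one site.  Solved numerically; monotone in beta.
.reference_beta <- function(alpha_ref, total_ref) {
  # partial sum of k^(-alpha) for k = 1..kmax; exact up to 1e6 terms,
  # integral tail beyond
  partial_zeta <- function(kmax, alpha) {
    k_exact <- min(kmax, 1e6)
    s <- sum(seq_len(k_exact)^(-alpha))
    if (kmax > k_exact)
      s <- s + (kmax^(1 - alpha) - k_exact^(1 - alpha)) / (1 - alpha)
    s
  }
  total_of <- function(lbeta) {
    beta <- 10^lbeta
    kmax <- max(1, floor(beta^(1 / alpha_ref)))
    beta * partial_zeta(kmax, alpha_ref) - total_ref
  }
  10^uniroot(total_of, c(0, 12), tol = 1e-10)$root
}

#' Normalize raw CTSS counts to power-law tags per million
#'
#' Maps each raw count through the sample's fitted power law onto a common
#' reference law with exponent \code{alpha_ref} and an implied library
#' size of \code{total_ref} tags (one million by default), yielding
#' normalized tags per million (tpm).  Writing the sample fit as
#' r(x) = 10^b * x^s and the reference as r_ref(y) = beta * y^(-alpha),
#' the mapping is tpm(x) = (10^b * x^s / beta)^(-1/alpha): the value whose
#' reference reverse-cumulative equals the sample's at x.  It is strictly
#' increasing, so count ranks are preserved exactly and tied counts stay
#' tied.
#'
#' @param tab CTSS \code{data.frame} with a \code{count} column.
#' @param model a \code{power_law_model} fitted on this table's counts.
#' @param alpha_ref reference exponent (> 0), default 1.05 as commonly
#'   used for CAGE libraries.
#' @param total_ref reference library size in tags, default 1e6.
#' @return the table with a \code{tpm} column appended.
#' @export
normalize_to_tpm <- function(tab, model, alpha_ref = 1.05, total_ref = 1e6) {
  if (!inherits(model, "power_law_model"))
    .stopf("'model' must be a fitted power_law_model (see fit_power_law)")
  stopifnot(alpha_ref > 0, total_ref > 0)
  if (!is.finite(model$fitted_slope) || model$fitted_slope >= 0)
    .stopf("fitted slope must be negative; got %g", model$fitted_slope)
  beta <- .reference_beta(alpha_ref, total_ref)
  s <- model$fitted_slope
  b <- model$fitted_intercept
  x <- tab$count
  tpm <- numeric(length(x))
  pos <- x > 0
  tpm[pos] <- (10^b * x[pos]^s / beta)^(-1 / alpha_ref)
  tab$tpm <- tpm
  tab
}

#' Fit and normalize in one step
#'
#' Convenience wrapper: fits the sample power law and maps counts to tpm.
#' The fitted model is attached as attribute \code{"power_law_model"}.
#'
#' @inheritParams fit_power_law
#' @inheritParams normalize_to_tpm
#' @return the CTSS table with a \code{tpm} column.
#' @export
normalize_ctss <- function(tab, fit_range = c(5, 1000), alpha_ref = 1.05,
                           total_ref = 1e6) {
  model <- fit_power_law(tab$count, fit_range = fit_range)
  out <- normalize_to_tpm(tab, model, alpha_ref = alpha_ref,
                          total_ref = total_ref)
  attr(out, "power_law_model") <- model
  out
}
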