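# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive algorithms and share no code with R/.

# single-linkage chaining of positions: repeatedly merge any two groups
# containing positions within max_gap of each other
oracle_chain_positions <- function(pos, max_gap) {
  groups <- as.list(sort(pos))
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        gap <- min(abs(outer(groups[[i]], groups[[j]], "-")))
        if (gap <= max_gap) {
          groups[[i]] <- sort(c(groups[[i]], groups[[j]]))
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  groups[order(vapply(groups, min, numeric(1)))]
}

# transitive merge of intervals with gap (start - end) <= max_gap
oracle_merge_intervals <- function(starts, ends, max_gap) {
  n <- length(starts)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (grp[i] == grp[j]) next
      gap <- max(starts[i], starts[j]) - min(ends[i], ends[j])
      if (gap <= max_gap) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- lapply(unique(grp), function(g)
    c(start = min(starts[grp == g]), end = max(ends[grp == g])))
  out[order(vapply(out, `[[`, numeric(1), "start"))]
}

# cumulative-sum interquantile trim
oracle_trim <- function(pos, tpm, lower = 0.1, upper = 0.9) {
  o <- order(pos)
  pos <- pos[o]; tpm <- tpm[o]
  cum <- cumsum(tpm)
  tot <- sum(tpm)
  ql <- pos[min(which(cum >= lower * tot))]
  qh <- pos[min(which(cum >= upper * tot))]
  list(q_low = ql, q_high = qh, iq_width = qh - ql + 1)
}

# naive per-offset PWM rescoring of a sequence (log2 odds vs background)
oracle_pwm_scan <- function(freq, background, seq) {
  L <- ncol(freq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  smin <- sum(apply(log2(freq / background), 2, min))
  smax <- sum(apply(log2(freq / background), 2, max))
  n_off <- length(chars) - L + 1
  vapply(seq_len(n_off), function(o) {
    sc <- 0
    for (j in seq_len(L)) {
      b <- chars[o + j - 1]
      sc <- sc + if (b %in% rownames(freq))
        log2(freq[b, j] / background[b]) else 0
    }
    100 * (sc - smin) / (smax - smin)
  }, numeric(1))
}

# two-sided Fisher exact p by enumeration over the hypergeometric support
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# hand reverse complement
oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

# random DNA string
rand_dna <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

# random valid PWM model
rand_pwm <- function(len = NULL) {
  if (is.null(len)) len <- sample(3:8, 1)
  counts <- matrix(sample(0:50, 4 * len, replace = TRUE), 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  zero <- colSums(counts) == 0
  counts[1, zero] <- 1
  pwm_model(counts, name = "rand")
}

# log10-log10 OLS slope of the reverse-cumulative distribution of values,
# restricted to values within range
revcum_slope <- function(values, range) {
  values <- values[values > 0]
  v <- sort(unique(values))
  rc <- vapply(v, function(x) sum(values >= x), numeric(1))
  keep <- v >= range[1] & v <= range[2]
  x <- log10(v[keep]); y <- log10(rc[keep])
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}
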