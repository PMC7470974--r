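mk_window <- function(seq, offset_start = -10L) {
  structure(list(seq = seq, offset_start = as.integer(offset_start),
                 clipped = FALSE, chrom = "c", pos = 1L, strand = "+",
                 up = 10L, down = 10L), class = "promoter_window")
}

test_that("a forced PWM reaches 100 percent exactly at its consensus", {
  pwm <- pwm_model(rbind(A = c(0, 40), C = c(0, 0), G = c(0, 0),
                         T = c(40, 0)), name = "TA")
  sc <- pwm_match_percent(pwm, mk_window("GGTAGG", -2L))
  expect_equal(sc$offset, -2:2)
  expect_equal(sc$match_percent[which(sc$offset == 0)], 100)
  expect_lt(max(sc$match_percent[sc$offset != 0]), 100)
})

test_that("scanning equals naive per-offset rescoring on random windows", {
  set.seed(101)
  for (i in 1:100) {
    pwm <- rand_pwm()
    w <- mk_window(rand_dna(sample(20:60, 1)), sample(-40:-10, 1))
    got <- pwm_match_percent(pwm, w)
    want <- oracle_pwm_scan(pwm$freq, pwm$background, w$seq)
    expect_equal(got$match_percent, want, tolerance = 1e-10)
  }
})

test_that("an all-C window scores a TATA matrix at the all-C value", {
  tata <- synthetic_pwms()$TATA_SYN
  w <- mk_window(strrep("C", 30), -15L)
  got <- pwm_match_percent(tata, w)
  want <- oracle_pwm_scan(tata$freq, tata$background, w$seq)
  expect_equal(got$match_percent, want, tolerance = 1e-10)
  expect_true(all(got$match_percent < 10))
  # degenerate PWM errors
  flat <- pwm_model(matrix(1, 4, 3,
                           dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_error(pwm_match_percent(flat, w), "degenerate")
})

test_that("Fisher enrichment reproduces the worked 2x2 example", {
  scan <- data.frame(
    cc_id = paste0("c", 1:300),
    motif = "M",
    is_hit = c(rep(TRUE, 10), rep(FALSE, 90),    # group: 10 / 90
               rep(TRUE, 5), rep(FALSE, 195)),   # background: 5 / 195
    stringsAsFactors = FALSE)
  groups <- setNames(rep(c("grp", "bg"), c(100, 200)), scan$cc_id)
  res <- motif_enrichment(scan, groups, background_group = "bg")
  expect_equal(res$a, 10); expect_equal(res$d, 195)
  expect_equal(2^res$log2_odds_ratio, 10 * 195 / (90 * 5),
               tolerance = 1e-12)  # 4.333...
  expect_equal(res$p_value, oracle_fisher_p(10, 90, 5, 195),
               tolerance = 1e-9)
})

test_that("identical hit rates give a null odds ratio", {
  scan <- data.frame(cc_id = paste0("c", 1:200), motif = "M",
                     is_hit = rep(c(TRUE, FALSE), 100),
                     stringsAsFactors = FALSE)
  groups <- setNames(rep(c("grp", "bg"), each = 100), scan$cc_id)
  res <- motif_enrichment(scan, groups, "bg")
  expect_equal(res$log2_odds_ratio, 0, tolerance = 1e-12)
  expect_gt(res$p_value, 0.99)
})

test_that("planted TATA prevalence is detected as significant positive
          enrichment", {
  set.seed(55)
  tata <- synthetic_pwms()$TATA_SYN
  cons <- pwm_consensus(tata)
  mk <- function(plant) {
    s <- rand_dna(171, c(A = .3, C = .2, G = .2, T = .3))
    if (plant) substr(s, 91, 90 + nchar(cons)) <- cons  # offset -30
    mk_window(s, -120L)
  }
  windows <- c(lapply(runif(200) < 0.6, mk), lapply(runif(200) < 0.1, mk))
  names(windows) <- paste0("c", seq_along(windows))
  groups <- setNames(rep(c("grp", "bg"), each = 200), names(windows))
  scan <- scan_promoters(windows, list(TATA = tata))
  res <- motif_enrichment(scan, groups, "bg")
  expect_gt(res$log2_odds_ratio, 0)
  expect_lt(res$p_value, 0.01)
  expect_true(res$significant)
})

test_that("region-restricted scans never report hits outside the region", {
  set.seed(77)
  tata <- synthetic_pwms()$TATA_SYN
  windows <- lapply(1:30, function(i) mk_window(rand_dna(171,
    c(A = .4, C = .1, G = .1, T = .4)), -120L))
  names(windows) <- paste0("w", 1:30)
  sc <- scan_promoters(windows, list(TATA = tata), threshold = 60,
                       region = c(-40L, -20L))
  hits <- attr(sc, "hits")
  if (nrow(hits)) {
    expect_true(all(hits$offset >= -40 & hits$offset <= -20))
  }
  expect_true(all(sc$best_offset >= -40 & sc$best_offset <= -20,
                  na.rm = TRUE))
})

test_that("the TATA match distribution bins canonical and absent motifs", {
  tata <- synthetic_pwms()$TATA_SYN
  cons <- pwm_consensus(tata)
  good <- mk_window(rand_dna(171, c(A=.3,C=.2,G=.2,T=.3)), -120L)
  substr(good$seq, 91, 90 + nchar(cons)) <- cons   # start at -30
  bad <- mk_window(strrep("G", 171), -120L)        # no A/T in region
  d <- tata_match_distribution(list(a = good, b = bad), tata)
  expect_equal(as.character(d$per_promoter$bin), c(">90", "<75"))
  expect_equal(unname(d$bins[">90"]), 1, ignore_attr = TRUE)
})

test_that("WW-dinucleotide profiles hit the analytic extremes", {
  all_at <- mk_window(strrep("AT", 20), -20L)
  all_gc <- mk_window(strrep("GC", 20), -20L)
  p1 <- ww_dinucleotide_profile(list(a = all_at))
  expect_true(all(p1$frequency == 1))
  p0 <- ww_dinucleotide_profile(list(a = all_gc))
  expect_true(all(p0$frequency == 0))
  set.seed(12)
  wins <- lapply(1:400, function(i) mk_window(rand_dna(60), -30L))
  names(wins) <- paste0("w", 1:400)
  pr <- ww_dinucleotide_profile(wins)
  # uniform base composition: expected WW frequency (1/2)^2
  expect_lt(max(abs(pr$frequency - 0.25)), 0.08)
})

test_that("poly-W pentamer counting covers the 32-mer universe and flags
          TATA overlap", {
  tata <- synthetic_pwms()$TATA_SYN
  w <- mk_window(strrep("G", 171), -120L)
  substr(w$seq, 91, 98) <- "TATAAATA"  # plants TATAA pentamers at -30
  bg <- mk_window(strrep("G", 171), -120L)
  groups <- c(a = "grp", b = "bg")
  res <- polyw_pentamer_enrichment(list(a = w, b = bg), groups, "bg",
                                   tata_pwm = tata)
  expect_equal(length(unique(res$pentamer)), 32L)
  row <- res[res$pentamer == "TATAA", ]
  expect_equal(row$a, 1)
  expect_equal(row$n_tata_overlap, 1)
})

test_that("planted pentamer prevalence reaches Fisher significance", {
  set.seed(99)
  mk <- function(plant) {
    s <- rand_dna(171, c(A = .25, C = .25, G = .25, T = .25))
    if (plant) substr(s, 91, 95) <- "TTAAA"
    mk_window(s, -120L)
  }
  wins <- c(lapply(runif(150) < 0.4, mk), lapply(runif(150) < 0.05, mk))
  names(wins) <- paste0("w", seq_along(wins))
  groups <- setNames(rep(c("grp", "bg"), each = 150), names(wins))
  res <- polyw_pentamer_enrichment(wins, groups, "bg")
  row <- res[res$pentamer == "TTAAA", ]
  expect_gt(row$log2_odds_ratio, 0)
  expect_lt(row$p_value, 0.01)
})
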