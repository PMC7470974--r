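test_that("the support filter keeps a CTSS everywhere if any sample
          reaches the threshold", {
  a <- toy_ctss(c(100, 200), tpm = c(0.6, 0.4))
  b <- toy_ctss(c(100, 200), tpm = c(0.1, 0.4))
  out <- filter_supported_ctss(list(A = a, B = b), min_tpm = 0.5)
  expect_equal(out$A$pos, 100L)   # 0.6 somewhere: kept in both
  expect_equal(out$B$pos, 100L)   # kept despite 0.1
  # 0.4/0.4 dropped everywhere; min_tpm = 0 is the identity
  out0 <- filter_supported_ctss(list(A = a, B = b), min_tpm = 0)
  expect_equal(out0$A, a)
})

test_that("tag clusters chain CTSSs by the neighbour-gap rule", {
  tab <- toy_ctss(c(100, 115, 140), tpm = c(10, 10, 10))
  tc <- call_tag_clusters(tab, max_gap = 20)
  expect_equal(nrow(tc), 2L)      # gaps 15 (merge) and 25 (split)
  expect_equal(tc$start, c(100L, 140L))
  expect_equal(tc$end, c(115L, 140L))
})

test_that("strands never merge and the expression floor is strict", {
  tab <- rbind(toy_ctss(100, tpm = 20, strand = "+"),
               toy_ctss(100, tpm = 20, strand = "-"))
  tc <- call_tag_clusters(tab)
  expect_equal(nrow(tc), 2L)
  # exactly 5 tpm total is discarded ("higher than 5")
  expect_equal(nrow(call_tag_clusters(toy_ctss(50, tpm = 5))), 0L)
  expect_equal(nrow(call_tag_clusters(toy_ctss(50, tpm = 5.01))), 1L)
})

test_that("interquantile trimming follows the cumulative-expression rule", {
  tr <- trim_cluster(c(100L, 105L, 110L), c(10, 80, 10))
  expect_equal(tr$q_low, 100L)
  expect_equal(tr$q_high, 105L)
  expect_equal(tr$iq_width, 6L)
  # single-CTSS cluster
  tr1 <- trim_cluster(42L, 7)
  expect_equal(c(tr1$q_low, tr1$q_high, tr1$iq_width), c(42L, 42L, 1L))
  # uniform expression over 10 consecutive positions
  tru <- trim_cluster(20:29, rep(3, 10))
  expect_equal(tru$q_low, 20L)
  expect_equal(tru$q_high, 28L)
  expect_equal(tru$iq_width, 9L)
})

test_that("trimming is a monotone shrinkage of the cluster span", {
  # repeated trimming can only move the boundaries inward: the span never
  # widens, and a dominant-enough boundary CTSS keeps it fixed
  set.seed(31)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    pos <- sort(sample(1:200, n))
    tpm <- runif(n, 0.1, 50)
    tr <- trim_cluster(pos, tpm)
    expect_lte(tr$iq_width, max(pos) - min(pos) + 1L)
    tr2 <- trim_cluster(pos[tr$keep], tpm[tr$keep])
    expect_gte(tr2$q_low, tr$q_low)
    expect_lte(tr2$q_high, tr$q_high)
  }
  # with >= 10% of trimmed mass on each boundary member, re-trimming is
  # an exact fixpoint
  tr <- trim_cluster(c(10L, 15L, 20L), c(30, 40, 30))
  tr2 <- trim_cluster(c(10L, 15L, 20L)[tr$keep], c(30, 40, 30)[tr$keep])
  expect_equal(tr2[c("q_low", "q_high")], tr[c("q_low", "q_high")])
})

test_that("clustering matches the brute-force single-linkage oracle", {
  set.seed(17)
  for (i in 1:300) {
    n <- sample(2:25, 1)
    pos <- sort(sample(1:300, n))
    gap <- sample(3:30, 1)
    tab <- toy_ctss(pos, tpm = runif(n, 1, 20))
    tc <- call_tag_clusters(tab, max_gap = gap, min_cluster_tpm = 0)
    groups <- oracle_chain_positions(pos, gap)
    # untrimmed group spans must contain the trimmed cluster spans 1:1
    expect_equal(nrow(tc), length(groups))
    for (k in seq_along(groups)) {
      expect_gte(tc$start[k], min(groups[[k]]))
      expect_lte(tc$end[k], max(groups[[k]]))
    }
  }
})

test_that("consensus merging matches the interval-merge oracle", {
  mk_tc <- function(start, end, sample_id = "A") {
    data.frame(sample_id = sample_id, chrom = "chr1", strand = "+",
               start = start, end = end, dominant_pos = start,
               dominant_tpm = 1, total_tpm = 10, iq_width = end - start + 1,
               n_ctss = 2, stringsAsFactors = FALSE)
  }
  ctss <- list(A = toy_ctss(c(100, 120), tpm = c(5, 5)),
               B = toy_ctss(c(180, 200), tpm = c(5, 5)))
  # gap 60 -> one CC spanning both
  cc <- build_consensus_clusters(list(A = mk_tc(100, 120),
                                      B = mk_tc(180, 200, "B")), ctss)
  expect_equal(nrow(cc), 1L)
  expect_equal(c(cc$start, cc$end), c(100L, 200L))
  # gap 101 -> two CCs
  cc2 <- build_consensus_clusters(list(A = mk_tc(100, 120),
                                       B = mk_tc(221, 300, "B")), ctss)
  expect_equal(nrow(cc2), 2L)
  # transitive chain spanning more than the pairwise gap
  cc3 <- build_consensus_clusters(
    list(A = rbind(mk_tc(100, 110), mk_tc(200, 210), mk_tc(300, 310))),
    ctss["A"])
  expect_equal(nrow(cc3), 1L)
  expect_equal(c(cc3$start, cc3$end), c(100L, 310L))

  set.seed(23)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    s <- sort(sample(1:2000, n))
    e <- s + sample(5:50, n, replace = TRUE)
    gap <- sample(20:150, 1)
    got <- build_consensus_clusters(
      list(A = mk_tc(s, e)),
      list(A = toy_ctss(s, tpm = rep(1, n))), max_cc_gap = gap)
    want <- oracle_merge_intervals(s, e, gap)
    expect_equal(nrow(got), length(want))
    expect_equal(got$start, vapply(want, `[[`, numeric(1), "start"))
    expect_equal(got$end, vapply(want, `[[`, numeric(1), "end"))
  }
})

test_that("per-sample CC expression conserves member CTSS tpm", {
  s <- small_study()
  ccs <- s$res$ccs
  filt <- s$res$filtered
  for (cd in names(filt)) {
    col <- ccs[[paste0("tpm_", cd)]]
    tab <- filt[[cd]]
    inside <- promcage:::.map_ctss_to_cc(tab, ccs) > 0
    expect_equal(sum(col), sum(tab$tpm[inside]), tolerance = 1e-8)
  }
})

test_that("CC annotation classifies promoter distances and 5' UTR", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = c("+", "+"), tss = c(10000L, 50000L),
                      gene_end = c(10999L, 50999L),
                      stringsAsFactors = FALSE)
  features <- data.frame(gene_id = "g2", feature = "five_utr",
                         start = 50000L, end = 50200L,
                         stringsAsFactors = FALSE)
  ccs <- data.frame(cc_id = c("c1", "c2", "c3"), chrom = "chr1",
                    strand = "+",
                    start = c(9400L, 8400L, 50090L),
                    end = c(9600L, 8600L, 50130L),
                    dominant_pos = c(9500L, 8500L, 50100L),
                    total_tpm = c(10, 10, 10), stringsAsFactors = FALSE)
  ann <- annotate_cc(ccs, genes, features)
  expect_equal(ann$feature,
               c("Promoter (<=1kb)", "Promoter (1-3kb)", "5' UTR"))
  expect_equal(ann$promoter_set, c(TRUE, FALSE, TRUE))
  expect_equal(ann$tss_dist, c(-500L, -1500L, 100L))
  expect_equal(ann$gene_id, c("g1", "g1", "g2"))
  expect_warning(annotate_cc(ccs, genes[0, ]), "empty")
})

test_that("one representative CC is kept per gene by total expression", {
  ccs <- data.frame(cc_id = c("a", "b", "c"), gene_id = c("g1", "g1", "g2"),
                    promoter_set = TRUE, total_tpm = c(5, 50, 7),
                    stringsAsFactors = FALSE)
  out <- reduce_to_gene_representative(ccs)
  expect_equal(out$cc_id, c("b", "c"))
})
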