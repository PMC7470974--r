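test_that("the generator is a pure function of the seed", {
  cfg <- small_config(seed = 5)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$truth, g2$truth)
  c1 <- simulate_ctss(cfg, g1)
  c2 <- simulate_ctss(cfg, g2)
  expect_identical(c1$ctss, c2$ctss)
  # a different seed changes the sequence
  g3 <- simulate_genome(small_config(seed = 6))
  expect_false(identical(g1$genome, g3$genome))
})

test_that("written FASTA is byte-identical across runs from one seed", {
  cfg <- small_config(seed = 5)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome(simulate_genome(cfg)$genome, f1)
  write_genome(simulate_genome(cfg)$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("certain motif planting puts a strong TATA hit in every
          promoter region", {
  cfg <- small_config(seed = 8)
  cfg$n_genes <- 60L
  cfg$temporal_counts <- c(gained = 10, lost = 10, none = 30,
                           not_expressed = 10)
  cfg$motif_probs["TATA_SYN", ] <- 1
  g <- simulate_genome(cfg)
  tata <- synthetic_pwms()$TATA_SYN
  wins <- extract_promoter_windows(
    g$genome, data.frame(cc_id = g$truth$gene_id, chrom = g$truth$chrom,
                         pos = g$truth$tss, strand = g$truth$strand))
  sc <- scan_promoters(wins, list(TATA = tata), region = c(-40L, -20L))
  expect_true(all(sc$is_hit))
})

test_that("a GC fraction of zero gives an all-A/T background", {
  cfg <- small_config(seed = 9)
  cfg$n_genes <- 20L
  cfg$genes_per_chrom <- 20L
  cfg$gc <- 0
  cfg$n_de_up_a <- 2L
  cfg$n_de_up_b <- 2L
  cfg$n_shape_transitions <- 2L
  cfg$temporal_counts <- c(gained = 5, lost = 5, none = 5,
                           not_expressed = 5)
  cfg$motif_probs[, ] <- 0  # no planted motifs
  g <- simulate_genome(cfg)
  expect_true(all(strsplit(g$genome[[1]], "")[[1]] %in% c("A", "T")))
})

test_that("emitted CTSS tables are valid and land within gene windows", {
  cfg <- small_config(seed = 10)
  sim <- simulate_genome(cfg)
  cts <- simulate_ctss(cfg, sim)
  expect_length(cts$ctss, 2L * cfg$n_replicates)
  for (tab in cts$ctss) {
    expect_silent(validate_ctss(tab))
    expect_false(is.unsorted(order(tab$chrom, tab$pos, tab$strand)))
  }
  # tags stay within offset_range of the annotated TSS
  t1 <- cts$ctss[[1]]
  for (ch in unique(t1$chrom)) {
    pos <- t1$pos[t1$chrom == ch]
    tss <- sim$truth$tss[sim$truth$chrom == ch]
    d <- vapply(pos, function(p) min(abs(p - tss)), numeric(1))
    expect_lte(max(d), cfg$offset_range)
  }
})

test_that("replicate log-expression is tightly correlated within
          condition", {
  s <- small_study()
  cc <- s$res$ccs
  counts <- s$res$cc_counts
  a <- log1p(counts[, "A_rep1"]); b <- log1p(counts[, "A_rep2"])
  expect_gt(cor(a, b), 0.9)
})

test_that("sharp-class genes yield narrow interquantile widths", {
  # distribution of the 10-90 spread under the sharp dispersion: a deeply
  # sequenced sharp promoter is almost surely under 10 bp wide
  set.seed(77)
  cfg <- small_config()
  sp <- promcage:::.shape_offset_probs(cfg)
  widths <- vapply(1:200, function(i) {
    k <- rmultinom(1, 1e4, sp$probs$sharp)[, 1]
    nz <- k > 0
    trim_cluster(sp$offsets[nz], k[nz])$iq_width
  }, integer(1))
  expect_gte(mean(widths < 10), 0.99)
  # and the end-to-end pipeline sees it the same way
  s <- small_study()
  truth <- s$sim$truth
  sc <- s$res$shape_calls$A
  m <- match(s$res$ccs$gene_id, truth$gene_id)
  sharp <- which(truth$shape_a[m] == "sharp" & !is.na(sc$iq_width))
  expect_gt(mean(sc$iq_width[sharp] < 10), 0.95)
})
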