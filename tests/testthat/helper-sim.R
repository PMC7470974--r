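# Shared fixtures built in code.  The full-scale synthetic study and its
# pipeline run are expensive, so they are built once per test session and
# cached for every test that needs them.

.fixture_cache <- new.env(parent = emptyenv())

# default-scale synthetic study (5000 genes, 2 x 3 replicates, 3 stages)
# plus a complete pipeline run on it
full_study <- function() {
  if (is.null(.fixture_cache$full)) {
    sim <- simulate_cage_study(sim_config(seed = 1))
    outdir <- file.path(tempdir(), "promcage_full_run")
    res <- run_pipeline(pipeline_config_from_sim(sim), outdir = outdir)
    .fixture_cache$full <- list(sim = sim, res = res, outdir = outdir)
  }
  .fixture_cache$full
}

# small study for cheap end-to-end checks
small_config <- function(seed = 7) {
  sim_config(seed = seed, n_genes = 200, genes_per_chrom = 100,
             n_de_up_a = 15, n_de_up_b = 15, n_shape_transitions = 8,
             temporal_counts = c(gained = 30, lost = 15, none = 140,
                                 not_expressed = 15),
             alt_counts = c(canonical_down = 5, alternative_down = 5,
                            canonical_up = 5, alternative_up = 5,
                            discarded = 3, not_candidate = 40,
                            not_expressed = 10))
}

small_study <- function() {
  if (is.null(.fixture_cache$small)) {
    sim <- simulate_cage_study(small_config())
    outdir <- file.path(tempdir(), "promcage_small_run")
    res <- run_pipeline(pipeline_config_from_sim(sim), outdir = outdir)
    .fixture_cache$small <- list(sim = sim, res = res, outdir = outdir)
  }
  .fixture_cache$small
}

# a toy CTSS table
toy_ctss <- function(pos, tpm, chrom = "chr1", strand = "+",
                     count = round(tpm)) {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             count = count, tpm = tpm, stringsAsFactors = FALSE)
}
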