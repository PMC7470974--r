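#' Default pipeline parameters
#'
#' Every threshold of the analysis in one place; all are overridable via
#' the \code{params} element of the pipeline configuration.
#'
#' @return named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(min_tpm_support = 0.5,   # CTSS support filter (tpm, >= in any sample)
       max_gap = 20L,           # CTSS chaining distance (bp)
       min_cluster_tpm = 5,     # TC expression floor (strictly greater)
       max_cc_gap = 100L,       # TC aggregation distance (bp)
       fit_range = c(5, 1000),  # power-law fit range (raw counts)
       alpha_ref = 1.05,        # reference power-law exponent
       total_ref = 1e6,         # reference library size (tags)
       promoter_window = 1000L, # proximal promoter extent (bp upstream)
       sharp_width = 10,        # sharp promoter IQW bound (bp, strict)
       dom_frac = 0.6,          # peaked dominant fraction bound (strict)
       strict_sharp = FALSE,
       transition_min_tpm = 10, # shape-transition expression floor
       scan_up = 120L, scan_down = 50L,  # promoter window extent
       motif_threshold = 90,    # PWM hit threshold (match percent)
       enrichment_p = 0.01,     # raw Fisher significance cut
       de_alpha = 0.05,         # BH-adjusted DE significance cut
       prior_df = 80,           # dispersion-shrinkage prior df
       alt_min_tpm = 5, alt_fold = 2,
       temporal_min_tpm = 5, temporal_fold = 1.5)
}

#' Build a pipeline configuration from a synthetic study
#'
#' @param sim a \code{cage_sim} bundle from [simulate_cage_study()].
#' @param params parameter overrides merged over [pipeline_defaults()].
#' @return a pipeline configuration list for [run_pipeline()].
#' @export
pipeline_config_from_sim <- function(sim, params = list()) {
  stopifnot(inherits(sim, "cage_sim"))
  list(ctss = sim$ctss, condition_map = sim$condition_map,
       genome = sim$genome, genes = sim$genes, features = sim$features,
       pwms = sim$pwms, alt_pairs = sim$alt_pairs,
       temporal = sim$temporal, params = params,
       seed = sim$config$seed)
}

#' Read a pipeline configuration from a YAML file
#'
#' The file carries paths (per-sample CTSS TSVs, genome FASTA, annotation
#' TSVs, PFM file, optional promoter-pair and temporal TSVs), the
#' condition map, parameter overrides and the seed.  Referenced files
#' must exist.
#'
#' @param path YAML file.
#' @return configuration list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("genome", "genes", "features", "pwms", "alt_pairs",
                "temporal")) {
    if (!is.null(cfg[[key]]) && is.character(cfg[[key]]) &&
        !file.exists(cfg[[key]]))
      .stopf("configuration file '%s': %s file not found: %s",
             path, key, cfg[[key]])
  }
  for (p in unlist(cfg$ctss))
    if (!file.exists(p)) .stopf("CTSS file not found: %s", p)
  cfg$condition_map <- unlist(cfg$condition_map)
  cfg
}

.load_cfg_inputs <- function(config) {
  getdf <- function(x, reader) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L) reader(x) else x
  }
  config$ctss <- lapply(config$ctss, function(x)
    if (is.character(x)) read_ctss(x) else x)
  config$genome <- getdf(config$genome, read_genome)
  config$genes <- getdf(config$genes, .read_tsv)
  config$features <- getdf(config$features, .read_tsv)
  config$pwms <- if (is.character(config$pwms)) read_jaspar(config$pwms)
    else config$pwms
  config$alt_pairs <- getdf(config$alt_pairs, .read_tsv)
  config$temporal <- getdf(config$temporal, .read_tsv)
  config
}

.log_params <- function(log, stage, params) {
  rbind(log, data.frame(stage = stage, parameter = names(params),
                        value = vapply(params, function(v)
                          paste(format(v), collapse = ","), character(1)),
                        stringsAsFactors = FALSE))
}

#' Raw-count matrix of consensus clusters across samples
#'
#' Sums each sample's raw CTSS counts inside every CC span.
#'
#' @param ccs consensus-cluster table.
#' @param ctss_tables named list of CTSS tables with \code{count}.
#' @return numeric matrix, CCs x samples, rownames \code{cc_id}.
#' @export
cc_count_matrix <- function(ccs, ctss_tables) {
  out <- matrix(0, nrow(ccs), length(ctss_tables),
                dimnames = list(ccs$cc_id, names(ctss_tables)))
  for (s in names(ctss_tables)) {
    t <- ctss_tables[[s]]
    cc_of <- .map_ctss_to_cc(t, ccs)
    hit <- cc_of > 0L
    if (any(hit)) {
      a <- rowsum(t$count[hit], cc_of[hit])
      out[as.integer(rownames(a)), s] <- a[, 1L]
    }
  }
  out
}

#' Run the promoterome analysis pipeline
#'
#' Executes the stages in dependency order -- normalize, cluster, shape,
#' motifs, diffexp, altprom, temporal -- writing one TSV per stage plus a
#' parameter log to \code{outdir}.  Stages whose inputs are not
#' configured are skipped with a warning; a stage re-run on its own
#' reloads upstream intermediates from \code{outdir} and stops with an
#' actionable message when they are missing.  Given the same
#' configuration and seed the outputs are byte-identical across runs.
#'
#' @param config configuration list (see [pipeline_config_from_sim()] and
#'   [read_pipeline_config()]): \code{ctss} (named list of tables or
#'   paths), \code{condition_map}, optional \code{genome}, \code{genes},
#'   \code{features}, \code{pwms}, \code{alt_pairs}, \code{temporal},
#'   \code{params}, \code{seed}.
#' @param outdir output directory (created).
#' @param stages character vector of stages to run (default all).
#' @return invisible list with the in-memory results of the executed
#'   stages.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("normalize", "cluster", "shape",
                                    "motifs", "diffexp", "altprom",
                                    "temporal")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  config <- .load_cfg_inputs(config)
  par <- utils::modifyList(pipeline_defaults(), config$params %||% list())
  log <- data.frame(stage = character(), parameter = character(),
                    value = character(), stringsAsFactors = FALSE)
  res <- list()
  out_path <- function(f) file.path(outdir, f)
  need <- function(obj, file, stage_hint) {
    if (!is.null(obj)) return(obj)
    if (file.exists(out_path(file))) return(.read_tsv(out_path(file)))
    .stopf("missing upstream intermediate '%s': re-run stage '%s' first",
           file, stage_hint)
  }

  merged <- normalized <- filtered <- NULL
  if ("normalize" %in% stages || "cluster" %in% stages) {
    if (is.null(config$ctss) || is.null(config$condition_map))
      .stopf("configuration must provide 'ctss' tables and 'condition_map'")
    cmap <- config$condition_map
    conds <- unique(cmap[names(config$ctss)])
    merged <- lapply(setNames(conds, conds), function(cd)
      merge_ctss_samples(config$ctss[names(cmap)[cmap == cd]]))
    normalized <- lapply(merged, normalize_ctss, fit_range = par$fit_range,
                         alpha_ref = par$alpha_ref,
                         total_ref = par$total_ref)
    for (cd in names(normalized))
      write_ctss(normalized[[cd]], out_path(sprintf("ctss_%s.tsv", cd)))
    log <- .log_params(log, "normalize",
                       par[c("fit_range", "alpha_ref", "total_ref")])
    res$normalized <- normalized
  }

  ccs <- NULL
  if ("cluster" %in% stages) {
    filtered <- filter_supported_ctss(normalized,
                                      min_tpm = par$min_tpm_support)
    tcs <- lapply(names(filtered), function(cd)
      call_tag_clusters(filtered[[cd]], max_gap = par$max_gap,
                        min_cluster_tpm = par$min_cluster_tpm,
                        sample_id = cd))
    names(tcs) <- names(filtered)
    ccs <- build_consensus_clusters(tcs, filtered,
                                    max_cc_gap = par$max_cc_gap)
    if (!is.null(config$genes)) {
      ccs <- annotate_cc(ccs, config$genes, config$features,
                         promoter_window = par$promoter_window)
    }
    .write_tsv(ccs, out_path("consensus_clusters.tsv"))
    for (cd in names(tcs))
      .write_tsv(tcs[[cd]], out_path(sprintf("tag_clusters_%s.tsv", cd)))
    counts <- cc_count_matrix(ccs, config$ctss)
    .write_tsv(data.frame(cc_id = rownames(counts), counts,
                          check.names = FALSE, stringsAsFactors = FALSE),
               out_path("cc_counts.tsv"))
    log <- .log_params(log, "cluster",
                       par[c("min_tpm_support", "max_gap",
                             "min_cluster_tpm", "max_cc_gap",
                             "promoter_window")])
    res$tag_clusters <- tcs
    res$ccs <- ccs
    res$cc_counts <- counts
    res$filtered <- filtered
  }

  shape_calls <- NULL
  if ("shape" %in% stages) {
    ccs <- need(ccs, "consensus_clusters.tsv", "cluster")
    if (is.null(filtered)) .stopf(
      "shape stage needs the filtered CTSS tables: run 'cluster' in the same call")
    shape_calls <- lapply(names(filtered), function(cd)
      call_shapes(cc_shape_stats(ccs, filtered[[cd]], sample_id = cd),
                  sharp_width = par$sharp_width, dom_frac = par$dom_frac,
                  strict_sharp = par$strict_sharp))
    names(shape_calls) <- names(filtered)
    all_calls <- do.call(rbind, shape_calls)
    .write_tsv(all_calls, out_path("shape_calls.tsv"))
    if (length(shape_calls) == 2L) {
      tr <- shape_transitions(shape_calls[[1L]], shape_calls[[2L]],
                              min_tpm = par$transition_min_tpm)
      .write_tsv(tr$long, out_path("shape_transitions.tsv"))
      res$transitions <- tr
    }
    log <- .log_params(log, "shape",
                       par[c("sharp_width", "dom_frac", "strict_sharp",
                             "transition_min_tpm")])
    res$shape_calls <- shape_calls
  }

  de <- NULL
  if ("diffexp" %in% stages) {
    ccs <- need(ccs, "consensus_clusters.tsv", "cluster")
    counts <- res$cc_counts
    if (is.null(counts)) {
      ctab <- need(NULL, "cc_counts.tsv", "cluster")
      counts <- as.matrix(ctab[, -1L, drop = FALSE])
      rownames(counts) <- ctab$cc_id
    }
    test_ccs <- if ("promoter_set" %in% names(ccs))
      reduce_to_gene_representative(ccs) else ccs
    counts <- counts[test_ccs$cc_id, , drop = FALSE]
    cond <- factor(config$condition_map[colnames(counts)])
    de <- nb_diffexp(counts, cond, prior_df = par$prior_df,
                     alpha = par$de_alpha)
    if ("gene_id" %in% names(test_ccs))
      de$gene_id <- test_ccs$gene_id[match(de$cc_id, test_ccs$cc_id)]
    .write_tsv(de, out_path("diffexp.tsv"))
    log <- .log_params(log, "diffexp", par[c("de_alpha", "prior_df")])
    res$diffexp <- de
  }

  if ("motifs" %in% stages) {
    if (is.null(config$genome) || is.null(config$pwms)) {
      warning("motifs stage skipped: genome or PWMs not configured")
    } else {
      ccs <- need(ccs, "consensus_clusters.tsv", "cluster")
      de <- need(de, "diffexp.tsv", "diffexp")
      scan_ccs <- ccs[ccs$cc_id %in% de$cc_id &
                        !is.na(ccs$dominant_pos), , drop = FALSE]
      windows <- extract_promoter_windows(
        config$genome,
        data.frame(cc_id = scan_ccs$cc_id, chrom = scan_ccs$chrom,
                   pos = scan_ccs$dominant_pos,
                   strand = scan_ccs$strand, stringsAsFactors = FALSE),
        up = par$scan_up, down = par$scan_down)
      scan <- scan_promoters(windows, config$pwms,
                             threshold = par$motif_threshold)
      groups <- setNames(de$call, de$cc_id)
      enr <- motif_enrichment(scan, groups,
                              background_group = "unchanged",
                              p_threshold = par$enrichment_p)
      .write_tsv(scan, out_path("motif_hits.tsv"))
      .write_tsv(enr, out_path("motif_enrichment.tsv"))
      log <- .log_params(log, "motifs",
                         par[c("scan_up", "scan_down", "motif_threshold",
                               "enrichment_p")])
      res$motif_scan <- scan
      res$motif_enrichment <- enr
      res$windows <- windows
    }
  }

  if ("altprom" %in% stages) {
    if (is.null(config$alt_pairs)) {
      warning("altprom stage skipped: no promoter-pair table configured")
    } else {
      sel <- select_expressed_pairs(config$alt_pairs,
                                    min_tpm = par$alt_min_tpm)
      calls <- classify_alt_usage(sel, fold = par$alt_fold)
      .write_tsv(calls, out_path("alt_promoters.tsv"))
      log <- .log_params(log, "altprom", par[c("alt_min_tpm", "alt_fold")])
      res$alt_promoters <- calls
    }
  }

  if ("temporal" %in% stages) {
    if (is.null(config$temporal)) {
      warning("temporal stage skipped: no stage-expression table configured")
    } else {
      tcls <- classify_temporal(config$temporal,
                                min_tpm = par$temporal_min_tpm,
                                fold = par$temporal_fold)
      .write_tsv(tcls, out_path("temporal.tsv"))
      log <- .log_params(log, "temporal",
                         par[c("temporal_min_tpm", "temporal_fold")])
      res$temporal <- tcls
    }
  }

  .write_tsv(log, out_path("pipeline_log.tsv"))
  res$log <- log
  invisible(res)
}
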