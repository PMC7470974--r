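#' Configuration for the synthetic CAGE study generator
#'
#' Bundles every knob of the synthetic promoterome: genome layout and
#' composition, promoter shape classes and their TSS dispersion, planted
#' core-promoter motifs per differential-expression group, the power-law
#' expression distribution, negative-binomial replicate noise, planted
#' fold changes, alternative-promoter and temporal class recipes, and the
#' mandatory seed.
#'
#' The defaults emulate the statistical structure of a sorted-cell CAGE
#' experiment: two conditions (A, slowly cycling-like; B, rapidly
#' cycling-like) with three biological replicates each, plus three
#' ordered developmental stages; sharp promoters with near-single-base
#' TSS dispersion versus broad promoters spreading over tens of bases;
#' TATA-box planting enriched in genes up-regulated in condition A and
#' CCAAT-box planting enriched in genes up-regulated in condition B.
#'
#' @param seed integer seed; every emitted dataset is a pure function of
#'   the configuration including this seed.
#' @param n_genes number of simulated promoters (default 5000).
#' @param genes_per_chrom promoters per synthetic chromosome.
#' @param gene_spacing bp between promoter slots.
#' @param gc genome GC fraction (default 0.40).
#' @param shape_props proportions of sharp / peaked_broad / broad
#'   promoters (sum to 1).
#' @param sharp_sd,broad_sd TSS dispersion (bp, discretized Gaussian) of
#'   sharp and broad promoters (defaults 1 and 15).
#' @param peaked_mass fraction of a peaked-broad promoter's tags on the
#'   dominant TSS; the remainder is split between two satellite TSS
#'   groups flanking it (minor start sites, as commonly seen at peaked
#'   promoters), keeping every member position well above the CTSS
#'   support filter at any library depth.
#' @param peaked_satellite inclusive offset range (absolute bp) of the
#'   flanking satellite groups.
#' @param offset_range tags fall within this many bp of the gene TSS.
#' @param min_tags,max_tags truncation of the per-gene expression power
#'   law (tags per replicate library).
#' @param power_alpha exponent of the expression power law; matches the
#'   normalization reference exponent so normalization round-trips
#'   cleanly.
#' @param nb_dispersion negative-binomial dispersion of replicate totals.
#' @param n_replicates replicates per condition.
#' @param n_de_up_a,n_de_up_b genes up-regulated in condition A / B.
#' @param de_log2fc planted |log2 fold change| of DE genes.
#' @param n_shape_transitions sharp-in-A promoters that broaden in
#'   condition B.
#' @param motif_probs matrix of planting probabilities, motifs x groups
#'   (\code{up_a}, \code{up_b}, \code{unchanged}).
#' @param motif_offsets named list of inclusive start-offset ranges for
#'   planted motifs (strand-oriented, 0 = dominant TSS).
#' @param alt_counts named counts of alternative-promoter pair classes.
#' @param temporal_counts named counts of temporal trend classes.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 5000L,
                       genes_per_chrom = 500L,
                       gene_spacing = 3000L,
                       gc = 0.40,
                       shape_props = c(sharp = 0.35, peaked_broad = 0.25,
                                       broad = 0.40),
                       sharp_sd = 1, broad_sd = 15,
                       peaked_mass = 0.66, peaked_satellite = c(6L, 8L),
                       offset_range = 60L,
                       min_tags = 200, max_tags = 1e5,
                       power_alpha = 1.05,
                       nb_dispersion = 0.05,
                       n_replicates = 3L,
                       n_de_up_a = 150L, n_de_up_b = 150L,
                       de_log2fc = 2,
                       n_shape_transitions = 150L,
                       motif_probs = rbind(
                         TATA_SYN  = c(up_a = 0.60, up_b = 0.10, unchanged = 0.10),
                         CCAAT_SYN = c(up_a = 0.10, up_b = 0.60, unchanged = 0.10),
                         SP1_SYN   = c(up_a = 0.35, up_b = 0.15, unchanged = 0.15),
                         INR_SYN   = c(up_a = 0.30, up_b = 0.30, unchanged = 0.30),
                         YY1_SYN   = c(up_a = 0.15, up_b = 0.15, unchanged = 0.15)),
                       motif_offsets = list(
                         TATA_SYN = c(-32L, -28L),
                         CCAAT_SYN = c(-100L, -68L),
                         SP1_SYN = c(-60L, -45L),
                         INR_SYN = c(-3L, -1L),
                         YY1_SYN = c(8L, 30L)),
                       alt_counts = c(canonical_down = 20L,
                                      alternative_down = 15L,
                                      canonical_up = 20L,
                                      alternative_up = 15L,
                                      discarded = 9L,
                                      not_candidate = 1433L,
                                      not_expressed = 100L),
                       temporal_counts = c(gained = 434L, lost = 93L,
                                           none = 4273L,
                                           not_expressed = 200L)) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (abs(sum(shape_props) - 1) > 1e-8)
    .stopf("shape_props must sum to 1")
  stopifnot(sharp_sd > 0, broad_sd > 0, peaked_mass > 0, peaked_mass < 1,
            length(peaked_satellite) == 2L,
            peaked_satellite[1L] >= 1L,
            peaked_satellite[1L] <= peaked_satellite[2L],
            min_tags >= 1, min_tags < max_tags, power_alpha > 0,
            nb_dispersion > 0, n_replicates >= 2L)
  if (sum(temporal_counts) != n_genes)
    .stopf("temporal_counts must sum to n_genes")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d genes, 2 conditions x %d replicates,",
                     " 3 stages, seed %d\n"),
              x$n_genes, x$n_replicates, as.integer(x$seed)))
  invisible(x)
}

#' Synthetic core-promoter position frequency matrices
#'
#' Loads the package's synthetic PFMs (TATA-, CCAAT-, Sp1-, INR- and
#' YY1-like; consensus-dominated columns, constructed for simulation and
#' testing, not derived from any motif database).
#'
#' @inheritParams read_jaspar
#' @return named list of \code{pwm_model}s.
#' @export
synthetic_pwms <- function(pseudocount = 0.8) {
  path <- system.file("extdata", "synthetic_pfms.txt", package = "promcage",
                      mustWork = TRUE)
  read_jaspar(path, pseudocount = pseudocount)
}

#' Simulate a genome, gene annotation and planted truth
#'
#' Emits a random-background genome with one promoter per gene, plants
#' core-promoter motif consensus sequences at drawn strand-oriented
#' offsets with group-dependent probabilities, and records the full
#' ground truth (differential-expression group, per-condition shape
#' class, temporal class, planted motifs).
#'
#' @param config a [sim_config()].
#' @return list with \code{genome} (named character), \code{genes},
#'   \code{features} (annotation tables as consumed by [annotate_cc()])
#'   and \code{truth} (per-gene planted labels).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gpc <- config$genes_per_chrom
  n_chrom <- ceiling(n / gpc)
  chrom_len <- gpc * config$gene_spacing + 2000L
  base_probs <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
                  G = config$gc / 2, T = (1 - config$gc) / 2)

  gene_id <- sprintf("g%05d", seq_len(n))
  chrom <- sprintf("chrS%02d", (seq_len(n) - 1L) %/% gpc + 1L)
  slot <- (seq_len(n) - 1L) %% gpc
  tss <- slot * config$gene_spacing + 1500L +
    sample(-200L:200L, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)

  de_group <- rep("unchanged", n)
  de_idx <- sample.int(n, config$n_de_up_a + config$n_de_up_b)
  de_group[de_idx[seq_len(config$n_de_up_a)]] <- "up_a"
  de_group[de_idx[config$n_de_up_a + seq_len(config$n_de_up_b)]] <- "up_b"
  log2fc <- ifelse(de_group == "up_b", config$de_log2fc,
                   ifelse(de_group == "up_a", -config$de_log2fc, 0))

  shape_a <- sample(names(config$shape_props), n, replace = TRUE,
                    prob = config$shape_props)
  shape_b <- shape_a
  sharp_idx <- which(shape_a == "sharp")
  n_tr <- min(config$n_shape_transitions, length(sharp_idx))
  shape_b[sample(sharp_idx, n_tr)] <- "broad"

  temporal <- sample(rep(names(config$temporal_counts),
                         config$temporal_counts))

  pwms <- synthetic_pwms()
  plant <- matrix(FALSE, n, nrow(config$motif_probs),
                  dimnames = list(gene_id, rownames(config$motif_probs)))
  plant_off <- matrix(NA_integer_, n, nrow(config$motif_probs),
                      dimnames = dimnames(plant))
  for (m in rownames(config$motif_probs)) {
    pr <- config$motif_probs[m, ][match(de_group,
                                        colnames(config$motif_probs))]
    plant[, m] <- runif(n) < pr
    rng <- config$motif_offsets[[m]]
    plant_off[, m] <- sample(rng[1L]:rng[2L], n, replace = TRUE)
  }

  genome <- vector("list", n_chrom)
  names(genome) <- sprintf("chrS%02d", seq_len(n_chrom))
  for (ci in seq_len(n_chrom)) {
    vec <- sample(names(base_probs), chrom_len, replace = TRUE,
                  prob = base_probs)
    gi <- which(chrom == names(genome)[ci])
    for (g in gi) {
      for (m in colnames(plant)) {
        if (!plant[g, m]) next
        cons <- pwm_consensus(pwms[[m]])
        L <- nchar(cons)
        o <- plant_off[g, m]
        if (strand[g] == "+") {
          s <- tss[g] + o
          vec[s:(s + L - 1L)] <- strsplit(cons, "", fixed = TRUE)[[1]]
        } else {
          e <- tss[g] - o
          vec[(e - L + 1L):e] <-
            strsplit(.revcomp(cons), "", fixed = TRUE)[[1]]
        }
      }
    }
    genome[[ci]] <- paste(vec, collapse = "")
  }
  genome <- unlist(genome)

  gene_end <- ifelse(strand == "+", tss + 999L, tss - 999L)
  genes <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      tss = tss, gene_end = gene_end,
                      stringsAsFactors = FALSE)
  feat_kind <- c("five_utr", "exon", "intron", "three_utr")
  feat_lo <- c(0L, 200L, 400L, 800L)
  feat_hi <- c(200L, 400L, 800L, 1000L)
  features <- do.call(rbind, lapply(seq_along(feat_kind), function(k) {
    s <- ifelse(strand == "+", tss + feat_lo[k], tss - feat_hi[k] + 1L)
    e <- ifelse(strand == "+", tss + feat_hi[k], tss - feat_lo[k] + 1L)
    data.frame(gene_id = gene_id, feature = feat_kind[k], start = s,
               end = e, stringsAsFactors = FALSE)
  }))

  truth <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      tss = tss, de_group = de_group, log2fc = log2fc,
                      shape_a = shape_a, shape_b = shape_b,
                      temporal = temporal, stringsAsFactors = FALSE)
  for (m in colnames(plant)) {
    truth[[paste0("has_", m)]] <- plant[, m]
    truth[[paste0("offset_", m)]] <- plant_off[, m]
  }
  list(genome = genome, genes = genes, features = features, truth = truth)
}

# truncated Pareto draw (power-law tail with exponent alpha)
.rpareto_trunc <- function(n, alpha, xmin, xmax) {
  u <- runif(n)
  # inverse CDF of Pareto truncated at xmax
  a <- xmin^(-alpha); b <- xmax^(-alpha)
  (a - u * (a - b))^(-1 / alpha)
}

.shape_offset_probs <- function(config) {
  o <- -config$offset_range:config$offset_range
  sharp <- dnorm(o, 0, config$sharp_sd)
  broad <- dnorm(o, 0, config$broad_sd)
  sat <- abs(o) >= config$peaked_satellite[1L] &
    abs(o) <= config$peaked_satellite[2L]
  peaked <- config$peaked_mass * (o == 0L) +
    (1 - config$peaked_mass) * sat / sum(sat)
  list(offsets = o,
       probs = list(sharp = sharp / sum(sharp),
                    peaked_broad = peaked / sum(peaked),
                    broad = broad / sum(broad)))
}

#' Simulate per-replicate CTSS count tables
#'
#' Draws each gene's base expression from a truncated power law, each
#' replicate's total from a negative binomial around the condition mean
#' (base expression times the planted fold change, split symmetrically),
#' and places tags at offsets from the gene TSS according to the gene's
#' shape class in that condition.
#'
#' @param config a [sim_config()].
#' @param sim output of [simulate_genome()].
#' @return list with \code{ctss} (named list of CTSS tables,
#'   \code{A_rep1} ... \code{B_rep<n>}), \code{condition_map} and the
#'   truth table extended with \code{base_tags}.
#' @export
simulate_ctss <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  truth <- sim$truth
  n <- nrow(truth)
  base_tags <- .rpareto_trunc(n, config$power_alpha, config$min_tags,
                              config$max_tags)
  mu_a <- base_tags * 2^(-truth$log2fc / 2)
  mu_b <- base_tags * 2^(truth$log2fc / 2)
  sp <- .shape_offset_probs(config)
  samples <- c(paste0("A_rep", seq_len(config$n_replicates)),
               paste0("B_rep", seq_len(config$n_replicates)))
  condition_map <- setNames(rep(c("A", "B"), each = config$n_replicates),
                            samples)
  ctss <- setNames(vector("list", length(samples)), samples)
  n_off <- length(sp$offsets)
  for (s in samples) {
    cond <- condition_map[[s]]
    mu <- if (cond == "A") mu_a else mu_b
    shape <- if (cond == "A") truth$shape_a else truth$shape_b
    tot <- rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
    cnt <- matrix(0L, n_off, n)
    for (g in seq_len(n)) {
      if (tot[g] == 0L) next
      cnt[, g] <- rmultinom(1L, tot[g], sp$probs[[shape[g]]])[, 1L]
    }
    nz <- which(cnt > 0L, arr.ind = TRUE)
    gidx <- nz[, 2L]
    off <- sp$offsets[nz[, 1L]]
    pos <- ifelse(truth$strand[gidx] == "+", truth$tss[gidx] + off,
                  truth$tss[gidx] - off)
    tab <- data.frame(chrom = truth$chrom[gidx], pos = pos,
                      strand = truth$strand[gidx],
                      count = as.numeric(cnt[nz]),
                      stringsAsFactors = FALSE)
    tab <- tab[order(tab$chrom, tab$pos, tab$strand), , drop = FALSE]
    rownames(tab) <- NULL
    ctss[[s]] <- tab
  }
  truth$base_tags <- base_tags
  list(ctss = ctss, condition_map = condition_map, truth = truth)
}

#' Simulate twinned canonical/alternative promoter pairs
#'
#' Generates per-pair TPM quadruples (canonical and alternative region in
#' each condition) directly at the expression level, one recipe per
#' planted class, with margins wide enough that the deterministic
#' classification rules recover every class exactly.
#'
#' @param config a [sim_config()].
#' @return \code{data.frame} of pairs with the planted \code{true_group}.
#' @export
simulate_alt_pairs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  counts <- config$alt_counts
  mk <- function(class, k) {
    if (k == 0L) return(NULL)
    cano_a <- 10^runif(k, log10(30), log10(300))
    alt_a <- cano_a * runif(k, 0.4, 0.8)
    dc <- da <- numeric(k)
    if (class == "canonical_down") {
      dc <- runif(k, -0.9, -0.6); da <- runif(k, -0.1, 0.1)
    } else if (class == "alternative_down") {
      dc <- runif(k, -0.1, 0.1); da <- runif(k, -0.9, -0.6)
    } else if (class == "canonical_up") {
      dc <- runif(k, 1.5, 3); da <- runif(k, -0.1, 0.1)
    } else if (class == "alternative_up") {
      dc <- runif(k, -0.1, 0.1); da <- runif(k, 1.5, 3)
    } else if (class == "discarded") {
      # candidate gate passes but both promoters move moderately:
      # outside every group pattern
      dc <- runif(k, -0.7, -0.6); da <- runif(k, 0.3, 0.4)
    } else if (class == "not_candidate") {
      dc <- runif(k, -0.12, 0.12); da <- runif(k, -0.12, 0.12)
    } else if (class == "not_expressed") {
      cano_a <- runif(k, 0.2, 4.5); alt_a <- runif(k, 0.2, 4.5)
      dc <- runif(k, -0.1, 0.1); da <- runif(k, -0.1, 0.1)
    }
    data.frame(true_group = class, cano_a = cano_a, alt_a = alt_a,
               cano_b = cano_a * (1 + dc), alt_b = alt_a * (1 + da),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(names(counts), function(cl)
    mk(cl, counts[[cl]])))
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  out <- data.frame(gene_id = sprintf("ap%04d", seq_len(nrow(out))),
                    out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate temporal stage expression
#'
#' Emits per-gene TPM across three ordered stages, modelled directly at
#' the expression level (emulating deeply sequenced merged stage
#' libraries in which counting noise is negligible): planted
#' \code{gained} genes rise 2-3 fold at each step, \code{lost} genes
#' fall symmetrically, \code{none} genes drift within the 1.5-fold
#' threshold, and \code{not_expressed} genes stay below the eligibility
#' floor.
#'
#' @param config a [sim_config()].
#' @param truth per-gene truth from [simulate_genome()] (uses the
#'   \code{temporal} column).
#' @return \code{data.frame} with \code{cc_id}, \code{tpm_1..3} and the
#'   planted \code{true_trend}.
#' @export
simulate_temporal <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  n <- nrow(truth)
  cls <- truth$temporal
  t1 <- t2 <- t3 <- numeric(n)
  i <- cls == "gained"
  if (any(i)) {
    b <- 10^runif(sum(i), 1, 2.2)
    f2 <- runif(sum(i), 2, 3); f3 <- runif(sum(i), 2, 3)
    t1[i] <- b; t2[i] <- b * f2; t3[i] <- b * f2 * f3
  }
  i <- cls == "lost"
  if (any(i)) {
    b <- 10^runif(sum(i), 1, 2.2)
    f2 <- runif(sum(i), 2, 3); f3 <- runif(sum(i), 2, 3)
    t3[i] <- b; t2[i] <- b * f3; t1[i] <- b * f2 * f3
  }
  i <- cls == "none"
  if (any(i)) {
    b <- 10^runif(sum(i), 1, 2.2)
    t1[i] <- b
    t2[i] <- b * runif(sum(i), 0.85, 1.18)
    t3[i] <- t2[i] * runif(sum(i), 0.85, 1.18)
  }
  i <- cls == "not_expressed"
  if (any(i)) {
    t1[i] <- runif(sum(i), 0.2, 4.5)
    t2[i] <- runif(sum(i), 0.2, 4.5)
    t3[i] <- runif(sum(i), 0.2, 4.5)
  }
  data.frame(cc_id = truth$gene_id, tpm_1 = t1, tpm_2 = t2, tpm_3 = t3,
             true_trend = ifelse(cls %in% c("gained", "lost"), cls, "none"),
             true_class = cls, stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic CAGE study
#'
#' Runs every generator stage under one seed and returns the full bundle:
#' genome, annotation, per-replicate CTSS tables, alternative-promoter
#' pairs, temporal stage expression, the synthetic PWM set and the
#' planted truth for every downstream module.
#'
#' @param config a [sim_config()].
#' @return list of class \code{cage_sim} with elements \code{genome},
#'   \code{genes}, \code{features}, \code{ctss}, \code{condition_map},
#'   \code{alt_pairs}, \code{temporal}, \code{pwms}, \code{truth},
#'   \code{config}.
#' @export
simulate_cage_study <- function(config = sim_config()) {
  g <- simulate_genome(config)
  cts <- simulate_ctss(config, g)
  alt <- simulate_alt_pairs(config)
  temporal <- simulate_temporal(config, cts$truth)
  structure(list(genome = g$genome, genes = g$genes,
                 features = g$features, ctss = cts$ctss,
                 condition_map = cts$condition_map,
                 alt_pairs = alt, temporal = temporal,
                 pwms = synthetic_pwms(), truth = cts$truth,
                 config = config),
            class = "cage_sim")
}

#' @export
print.cage_sim <- function(x, ...) {
  cat(sprintf(paste0("<cage_sim> %d genes on %d chromosomes; %d CTSS ",
                     "tables; %d promoter pairs; seed %d\n"),
              nrow(x$genes), length(x$genome), length(x$ctss),
              nrow(x$alt_pairs), as.integer(x$config$seed)))
  invisible(x)
}
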