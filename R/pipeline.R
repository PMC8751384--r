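#' Pipeline run configuration
#'
#' One structured object carrying all stage thresholds, input paths (or a
#' simulation config for synthetic runs), the root seed and stage toggles.
#' Round-trips losslessly through YAML via \code{\link{write_run_config}} /
#' \code{\link{read_run_config}}.
#'
#' @param outdir output directory for result tables and the manifest
#' @param seed root seed; all stage randomness derives from it
#' @param simulate a \code{\link{sim_config}} to generate inputs, or NULL to
#'   read them from paths
#' @param fasta,gff,counts,metadata,abundance input paths (used when
#'   \code{simulate} is NULL; \code{abundance} is optional either way)
#' @param min_mapq,min_identity read filters (entry-point dependent)
#' @param min_breadth,min_depth genome breadth gate
#' @param snp_min_cov,snp_min_minor_count,snp_min_minor_freq SNP caller
#' @param fst_min_cov per-site F_ST coverage gate
#' @param gene_cov_sd gene coverage exclusion width (SDs)
#' @param max_dist,min_pair_cov,max_pairs linkage collection
#' @param locus_window,locus_z high-F_ST locus definition
#' @param rho_cutoff,fdr_target,n_perm ecology layer
#' @param run_linkage,run_selection,run_fst,run_ecology stage toggles
#' @return a \code{run_config} list
#' @export
run_config <- function(outdir = tempfile("strainpop_run_"), seed = 1,
                       simulate = sim_config(seed = seed),
                       fasta = NULL, gff = NULL, counts = NULL,
                       metadata = NULL, abundance = NULL,
                       min_mapq = 30, min_identity = 96,
                       min_breadth = 0.5, min_depth = 5,
                       snp_min_cov = 5, snp_min_minor_count = 4,
                       snp_min_minor_freq = 0.05,
                       fst_min_cov = 20, gene_cov_sd = 2,
                       max_dist = 500, min_pair_cov = 10, max_pairs = 5000,
                       locus_window = 3, locus_z = 2,
                       rho_cutoff = 0.56, fdr_target = 0.05, n_perm = 1000,
                       run_linkage = TRUE, run_selection = TRUE,
                       run_fst = TRUE, run_ecology = !is.null(abundance)) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#' @param config a \code{\link{run_config}}
#' @param path output YAML path
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$simulate <- if (is.null(x$simulate)) NULL else unclass(x$simulate)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML path written by \code{\link{write_run_config}}
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$simulate)) x$simulate <- do.call(sim_config, x$simulate)
  do.call(run_config, x[setdiff(names(x), "simulate")]) -> cfg
  cfg$simulate <- x$simulate
  cfg
}

#' Run the full strain-level pipeline
#'
#' Orchestrates: input generation (or loading), breadth gating, population
#' pooling, SNP calling, diversity and clonal-expansion flags, read-level
#' linkage (simulated runs), per-gene selection statistics and
#' positive-selection scan, pairwise F_ST with high-F_ST loci and sweep
#' candidates, and the compositional co-occurrence layer when an abundance
#' table is supplied. All result tables are written to \code{config$outdir}
#' in the fixed schemas along with a YAML run manifest (thresholds, input
#' checksums, per-stage exclusion counts). Deterministic given the seed.
#'
#' @param config a \code{\link{run_config}}
#' @return invisibly, a list of the in-memory result tables
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(thresholds = config[
    c("min_mapq", "min_identity", "min_breadth", "min_depth", "snp_min_cov",
      "snp_min_minor_count", "snp_min_minor_freq", "fst_min_cov",
      "gene_cov_sd", "max_dist", "min_pair_cov", "locus_window", "locus_z",
      "rho_cutoff", "fdr_target", "n_perm")],
    seed = config$seed)

  if (!is.null(config$simulate)) {
    manifest$entry_point <- "simulated"
    sim <- config$simulate
    ann <- simulate_reference(sim)
    truth <- simulate_haplotypes(ann, sim)
    truth <- assign_population_frequencies(truth)
    counts <- emit_site_counts(truth)
    metadata <- sim_sample_metadata(truth)
    reads <- if (config$run_linkage) emit_reads(truth) else NULL
    write_truth(truth, file.path(config$outdir, "truth.tsv"))
  } else {
    manifest$entry_point <- "sitecounts"
    manifest$input_checksums <- as.list(tools::md5sum(
      stats::na.omit(c(config$fasta, config$gff, config$counts,
                       config$metadata, config$abundance))))
    ann <- read_reference(config$fasta, config$gff)
    counts <- read_site_counts(config$counts)
    metadata <- read_sample_metadata(config$metadata)
    truth <- NULL
    reads <- NULL
  }

  glen <- stats::setNames(sum(nchar(ann$contigs)), ann$species_id)
  gate <- gate_sample_genome(counts, glen, config$min_breadth,
                             config$min_depth)
  pooled <- pool_populations(counts, metadata, gate)
  manifest$samples_retained <- sum(gate$passed)

  snps <- call_snps(pooled, ann, config$snp_min_cov,
                    config$snp_min_minor_count, config$snp_min_minor_freq)
  gstats <- genome_diversity(pooled, snps, config$snp_min_cov)
  gstats <- flag_clonal_expansion(gstats)
  write_table(cbind(snps[, c("species", "contig", "pos", "ref", "major",
                             "minor", "coverage", "major_freq", "gene_id",
                             "effect_class")]),
              file.path(config$outdir, "snps.tsv"), "snps")

  link <- NULL
  if (config$run_linkage && !is.null(reads)) {
    pairs <- collect_pair_observations(reads, truth, snps,
                                       max_dist = config$max_dist,
                                       min_pair_cov = config$min_pair_cov,
                                       max_pairs = config$max_pairs,
                                       seed = config$seed)
    link <- d_prime_aggregate(pairs)
    manifest$linkage_pairs <- nrow(pairs)
  }

  sel <- NULL
  if (config$run_selection) {
    sel <- gene_selection_stats(snps, ann)
    if (nrow(sel) >= 20) {
      sel <- positive_selection_scan(sel)
    } else {
      sp_log("selection", "fewer than 20 genes: outlier scan skipped")
      sel$outlier_p <- NA_real_
      sel$outlier <- FALSE
    }
  }

  # per-gene coverage (for the 2-SD gate and gene_stats)
  dt <- data.table::copy(data.table::as.data.table(pooled))
  dt[, coverage := nA + nC + nG + nT]
  gmap <- ann$genes
  dt[, gene_id := NA_character_]
  for (gi in seq_len(nrow(gmap))) {
    dt[contig == gmap$contig_id[gi] & pos >= gmap$start[gi] &
         pos <= gmap$end[gi], gene_id := gmap$gene_id[gi]]
  }
  gene_cov <- as.data.frame(dt[!is.na(gene_id),
                               .(mean_coverage = mean(coverage)),
                               by = .(species, population = sample, gene_id)])
  retained <- gate_gene_coverage(gene_cov, config$gene_cov_sd)

  gene_pi <- as.data.frame(dt[!is.na(gene_id) & coverage >= config$snp_min_cov,
                              .(pi = sum(pi_site(cbind(nA, nC, nG, nT)),
                                         na.rm = TRUE) / .N, n_sites = .N),
                              by = .(species, population = sample, gene_id)])

  fst_g <- NULL; loci <- NULL
  if (config$run_fst && length(setdiff(unique(pooled$sample), "ALL")) >= 2) {
    fst_g <- fst_genes(pooled, ann, min_cov = config$fst_min_cov,
                       retained = retained)
    write_table(fst_g, file.path(config$outdir, "fst_genes.tsv"), "fst_pairs")
    loci <- scan_all_pairs(fst_g, ann, dt, link, snps, truth, reads, config)
    if (!is.null(loci)) {
      write_table(loci, file.path(config$outdir, "loci.tsv"), "loci")
    }
  }

  genome_stats <- build_genome_stats(gstats, link, sel, snps, ann, retained)
  write_table(genome_stats, file.path(config$outdir, "genome_stats.tsv"),
              "genome_stats")
  gene_stats_tbl <- build_gene_stats(gene_cov, gene_pi, sel, ann)
  write_table(gene_stats_tbl, file.path(config$outdir, "gene_stats.tsv"),
              "gene_stats")

  eco <- NULL
  if (config$run_ecology && !is.null(config$abundance)) {
    ab <- read_abundance(config$abundance)
    cl <- clr(czm_zero_replace(ab))
    eco <- network_edges(cl, cutoff = config$rho_cutoff,
                         fdr_target = config$fdr_target,
                         n_perm = config$n_perm, seed = config$seed)
    write_table(eco$edges, file.path(config$outdir, "network_edges.tsv"),
                "network_edges")
  }

  yaml::write_yaml(manifest, file.path(config$outdir, "manifest.yaml"))
  invisible(list(annotation = ann, truth = truth, gate = gate,
                 pooled = pooled, snps = snps, genome_stats = genome_stats,
                 gene_stats = gene_stats_tbl, selection = sel,
                 linkage = link, fst_genes = fst_g, loci = loci,
                 ecology = eco, manifest = manifest))
}

# per-pair locus scan + sweep flags; returns NULL when the background is too
# small for the scan
scan_all_pairs <- function(fst_g, ann, dt, link, snps, truth, reads, config) {
  if (is.null(fst_g)) return(NULL)
  site_pi_all <- as.data.frame(dt[!is.na(gene_id) & sample == "ALL" &
                                    coverage >= config$snp_min_cov,
                                  .(gene_id, pi = pi_site(cbind(nA, nC, nG, nT)))])
  site_d <- NULL
  if (!is.null(truth) && !is.null(reads)) {
    prs <- collect_pair_observations(reads, truth, snps,
                                     max_dist = config$max_dist,
                                     min_pair_cov = config$min_pair_cov,
                                     max_pairs = config$max_pairs,
                                     by_population = FALSE,
                                     seed = config$seed)
    if (nrow(prs) > 0) {
      gidx <- codon_context(ann, names(ann$contigs)[1])$gene_idx
      gm <- ifelse(gidx[prs$site_a] > 0,
                   ann$genes$gene_id[pmax(gidx[prs$site_a], 1L)],
                   NA_character_)
      site_d <- data.frame(gene_id = gm, d_prime = prs$d_prime)[!is.na(gm), ]
    }
  }
  if (is.null(site_d) || nrow(site_d) < 4) return(NULL)
  out <- list()
  for (key in unique(paste(fst_g$pop_a, fst_g$pop_b))) {
    sub <- fst_g[paste(fst_g$pop_a, fst_g$pop_b) == key, ]
    gt <- data.frame(gene_id = sub$gene_id,
                     contig = ann$genes$contig_id[match(sub$gene_id,
                                                        ann$genes$gene_id)],
                     start = ann$genes$start[match(sub$gene_id,
                                                   ann$genes$gene_id)],
                     fst = sub$fst)
    if (sum(!is.na(gt$fst)) < 30) next
    loci <- high_fst_loci(gt, site_pi_all, site_d,
                          window = config$locus_window,
                          z_thresh = config$locus_z)
    loci <- sweep_candidates(loci, mean(site_pi_all$pi, na.rm = TRUE),
                             mean(site_d$d_prime, na.rm = TRUE))
    if (nrow(loci) > 0) {
      loci$species <- sub$species[1]
      loci$pop_a <- sub$pop_a[1]
      loci$pop_b <- sub$pop_b[1]
      out[[length(out) + 1]] <- loci
    }
  }
  if (length(out) == 0) return(empty_loci_schema())
  do.call(rbind, out)[, .schemas$loci]
}

empty_loci_schema <- function() {
  x <- empty_loci()
  x$species <- character(0); x$pop_a <- character(0); x$pop_b <- character(0)
  x$sweep_flag <- logical(0)
  x[, .schemas$loci]
}

build_genome_stats <- function(gstats, link, sel, snps, ann, retained) {
  out <- gstats
  out$mean_dprime <- NA_real_
  out$n_pairs <- NA_integer_
  if (!is.null(link) && nrow(link) > 0) {
    m <- match(out$population, link$population)
    out$mean_dprime <- link$mean_dprime[m]
    out$n_pairs <- link$n_pairs[m]
  }
  if (!is.null(sel)) {
    gp <- genome_pnps(sel)
    out$pnps <- gp$pnps
    out$n_nonsyn <- gp$n_nonsyn
    out$n_syn <- gp$n_syn
  } else {
    out$pnps <- NA_real_; out$n_nonsyn <- NA_integer_; out$n_syn <- NA_integer_
  }
  out[, .schemas$genome_stats]
}

build_gene_stats <- function(gene_cov, gene_pi, sel, ann) {
  dt <- merge(gene_cov, gene_pi,
              by = c("species", "population", "gene_id"), all.x = TRUE)
  g <- ann$genes
  m <- match(dt$gene_id, g$gene_id)
  dt$contig <- g$contig_id[m]; dt$start <- g$start[m]; dt$end <- g$end[m]
  dt$gene_class <- g$gene_class[m]
  if (!is.null(sel)) {
    ms <- match(dt$gene_id, sel$gene_id)
    dt$n_nonsyn <- sel$n_nonsyn[ms]; dt$n_syn <- sel$n_syn[ms]
    dt$pn <- sel$pn[ms]; dt$ps <- sel$ps[ms]; dt$pnps <- sel$pnps[ms]
  } else {
    dt$n_nonsyn <- NA_integer_; dt$n_syn <- NA_integer_
    dt$pn <- NA_real_; dt$ps <- NA_real_; dt$pnps <- NA_real_
  }
  dt[, .schemas$gene_stats]
}

#' Long-format pi / D' / pN/pS triplet report
#'
#' One row per (species, population, metric) for the diversity,
#' recombination and selection triplet, ready to join with external
#' habitat-comparison tables. Missing metrics are kept as NA rows, not
#' dropped.
#'
#' @param genome_stats a \code{genome_stats} table from
#'   \code{\link{run_pipeline}}
#' @return data.frame species, population, metric, value
#' @export
triplet_report <- function(genome_stats) {
  long <- lapply(c(pi = "pi", dprime = "mean_dprime", pnps = "pnps"),
                 function(col) genome_stats[[col]])
  out <- data.frame(
    species = rep(genome_stats$species, 3),
    population = rep(genome_stats$population, 3),
    metric = rep(c("pi", "dprime", "pnps"), each = nrow(genome_stats)),
    value = unlist(long, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  out
}
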