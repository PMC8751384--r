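#' Simulation configuration
#'
#' Bundles every knob of the synthetic haplotype-community generator. The
#' defaults describe the calibration community used throughout the package's
#' tests: a 60 kb coding genome with 50 genes, a pool of 20 haplotypes at
#' target nucleotide diversity 0.01, four populations (waterworks) with two
#' samples each, 50x mean depth.
#'
#' @param seed root random seed; every stage derives its own stream from it
#' @param genome_length reference length in bp
#' @param n_genes number of non-overlapping CDS genes
#' @param n_haplotypes size of the haplotype pool
#' @param target_pi expected per-site pairwise diversity among haplotypes
#'   (uniform weights); must be in [0, 0.1]
#' @param ns_fraction probability that a coding mutation is placed to be
#'   nonsynonymous (vs synonymous) where the codon permits
#' @param recomb_rate per-haplotype expected number of segment-reassortment
#'   events
#' @param n_populations number of populations (waterworks)
#' @param dirichlet_alpha Dirichlet concentration for per-population haplotype
#'   frequencies; smaller values give stronger between-population
#'   differentiation (higher F_ST); \code{Inf} means identical frequencies
#' @param coverage_mean mean per-site read depth per sample
#' @param error_rate per-base miscall probability
#' @param samples_per_population samples emitted per population
#' @param fragment_length span (bp) of one sequenced fragment, standing for a
#'   short-insert read pair; used by the read-level emitter for linkage
#' @param overdispersion depth overdispersion; 0 gives Poisson depth,
#'   values > 0 switch to negative binomial with size 1/overdispersion
#' @return a validated \code{sim_config} list
#' @export
sim_config <- function(seed = 1, genome_length = 60000, n_genes = 50,
                       n_haplotypes = 20, target_pi = 0.01, ns_fraction = 0.2,
                       recomb_rate = 0, n_populations = 4,
                       dirichlet_alpha = 1, coverage_mean = 50,
                       error_rate = 0.001, samples_per_population = 2,
                       fragment_length = 300, overdispersion = 0) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes), n_haplotypes = as.integer(n_haplotypes),
              target_pi = target_pi, ns_fraction = ns_fraction,
              recomb_rate = recomb_rate, n_populations = as.integer(n_populations),
              dirichlet_alpha = dirichlet_alpha, coverage_mean = coverage_mean,
              error_rate = error_rate,
              samples_per_population = as.integer(samples_per_population),
              fragment_length = as.integer(fragment_length),
              overdispersion = overdispersion)
  assert_that(cfg$target_pi >= 0 && cfg$target_pi <= 0.1,
              "target_pi must be in [0, 0.1]")
  assert_that(cfg$ns_fraction >= 0 && cfg$ns_fraction <= 1,
              "ns_fraction must be in [0, 1]")
  assert_that(all(c(cfg$genome_length, cfg$n_genes, cfg$n_haplotypes,
                    cfg$n_populations, cfg$samples_per_population) > 0),
              "all counts must be positive")
  assert_that(cfg$error_rate >= 0 && cfg$error_rate < 1,
              "error_rate must be in [0, 1)")
  structure(cfg, class = "sim_config")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
MIN_GENE_CODONS <- 35L

#' Simulate a random coding reference genome
#'
#' Generates one contig with \code{n_genes} non-overlapping CDS (start codon,
#' stop-free interior, terminal stop; length a multiple of 3) covering at
#' least 60\% of the genome, on random strands, separated by random intergenic
#' spacers. The first six genes are labelled with the nitrification gene
#' classes (amoA, amoB, haoA, haoB, nxrA, nxrB) so gene-class comparisons can
#' be exercised; the rest are "other". Deterministic given the config seed.
#'
#' @param config a \code{\link{sim_config}}
#' @return a \code{genome_annotation}
#' @export
simulate_reference <- function(config) {
  L <- config$genome_length
  n <- config$n_genes
  if (n * (3 * MIN_GENE_CODONS + 3) > L) {
    stop("genome too short for ", n, " genes", call. = FALSE)
  }
  set.seed(stage_seed(config$seed, 0L))
  avg <- max(MIN_GENE_CODONS + 2, floor(0.7 * L / 3 / n))
  codons_per_gene <- pmax(MIN_GENE_CODONS,
                          round(stats::runif(n, 0.7 * avg, 1.3 * avg)))
  # shrink if the draw does not fit with minimal spacers
  while (sum(3 * codons_per_gene) > 0.95 * L) {
    codons_per_gene <- pmax(MIN_GENE_CODONS, floor(codons_per_gene * 0.9))
    if (all(codons_per_gene == MIN_GENE_CODONS)) break
  }
  if (sum(3 * codons_per_gene) > L) {
    stop("genome too short for ", n, " genes", call. = FALSE)
  }
  tb <- codon_tables()
  sense <- setdiff(names(tb$aa), STOP_CODONS)
  slack <- L - sum(3 * codons_per_gene)
  gaps <- as.vector(stats::rmultinom(1, slack, rep(1, n + 1)))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  classes <- c(c("amoA", "amoB", "haoA", "haoB", "nxrA", "nxrB"),
               rep("other", max(0, n - 6)))[seq_len(n)]
  pieces <- character(2 * n + 1)
  pieces[1] <- paste(sample(BASES, gaps[1], replace = TRUE), collapse = "")
  genes <- vector("list", n)
  cursor <- gaps[1]
  for (i in seq_len(n)) {
    nc <- codons_per_gene[i]
    coding <- paste0("ATG",
                     paste(sample(sense, nc - 2, replace = TRUE), collapse = ""),
                     sample(STOP_CODONS, 1))
    genomic <- if (strands[i] == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(coding)))
    } else coding
    genes[[i]] <- data.frame(
      gene_id = sprintf("gene_%03d", i), contig_id = "contig_1",
      start = cursor + 1, end = cursor + 3 * nc, strand = strands[i],
      product = sprintf("hypothetical protein %d", i), gene_class = classes[i],
      stringsAsFactors = FALSE
    )
    pieces[2 * i] <- genomic
    cursor <- cursor + 3 * nc
    pieces[2 * i + 1] <- paste(sample(BASES, gaps[i + 1], replace = TRUE),
                               collapse = "")
    cursor <- cursor + gaps[i + 1]
  }
  contig <- paste(pieces, collapse = "")
  genome_annotation(sprintf("sim_species_%d", config$seed),
                    c(contig_1 = contig), do.call(rbind, genes))
}

# Per-position codon context for one contig of an annotation: gene index
# (0 = intergenic), codon string on the coding strand, offset within codon,
# strand. Used by the simulator and the vectorized SNP classifier.
codon_context <- function(ann, contig_id) {
  L <- nchar(ann$contigs[[contig_id]])
  gene_idx <- integer(L)
  codon_at <- character(L)
  off_at <- integer(L)
  strand_at <- character(L)
  g <- ann$genes[ann$genes$contig_id == contig_id, ]
  for (i in seq_len(nrow(g))) {
    cds <- gene_cds_seq(ann, g$gene_id[i])
    len <- g$end[i] - g$start[i] + 1
    cpos <- seq_len(len)
    gpos <- if (g$strand[i] == "+") g$start[i] - 1 + cpos else g$end[i] + 1 - cpos
    ci <- (cpos - 1) %/% 3
    off <- cpos - 3 * ci
    codons <- substring(cds, 3 * ci + 1, 3 * ci + 3)
    gene_idx[gpos] <- match(g$gene_id[i], ann$genes$gene_id)
    codon_at[gpos] <- codons
    off_at[gpos] <- off
    strand_at[gpos] <- g$strand[i]
  }
  list(gene_idx = gene_idx, codon_at = codon_at, off_at = off_at,
       strand_at = strand_at)
}

#' Simulate a haplotype pool with known mutation classes
#'
#' Haplotypes descend from the reference through a random increasing genealogy
#' (each new haplotype copies a random earlier one), and mutations are placed
#' on genealogy branches so each mutation is carried by a clade. The number of
#' mutations is tuned analytically so the expected pairwise diversity under
#' uniform haplotype weights equals \code{target_pi} (infinite-sites model:
#' sites are sampled without collision). Within CDS, a mutation is realized as
#' nonsynonymous with probability \code{ns_fraction} by choosing an admissible
#' substitution for its codon, else synonymous; sites whose codon admits no
#' substitution of the drawn class are resampled (count logged). Finally,
#' \code{recomb_rate} controls random segment swaps between haplotype pairs.
#'
#' @param annotation a single-contig \code{genome_annotation} from
#'   \code{\link{simulate_reference}}
#' @param config a \code{\link{sim_config}}
#' @return a \code{sim_truth} object holding the mutation table, the
#'   mutation-by-haplotype carrier matrix and the realized uniform-weight
#'   diversity
#' @export
simulate_haplotypes <- function(annotation, config) {
  assert_that(length(annotation$contigs) == 1,
              "simulator expects a single-contig annotation")
  contig_id <- names(annotation$contigs)[1]
  L <- nchar(annotation$contigs[[1]])
  H <- config$n_haplotypes
  set.seed(stage_seed(config$seed, 1L))

  # genealogy: parent of haplotype i is uniform among 1..(i-1); haplotype 1 is
  # the reference. A mutation on the branch above i is carried by i and all
  # its descendants.
  parent <- c(NA_integer_, vapply(seq_len(max(H - 1, 0)), function(i) {
    sample.int(i, 1)
  }, integer(1)))
  carriers_of_node <- function(node) {
    carried <- logical(H)
    carried[node] <- TRUE
    if (node < H) for (j in (node + 1):H) if (carried[parent[j]]) carried[j] <- TRUE
    carried
  }
  clade <- if (H >= 2) lapply(2:H, carriers_of_node) else list()
  clade_size <- vapply(clade, sum, integer(1))

  het <- function(k) 2 * k * (H - k) / (H * (H - 1))
  M <- if (H >= 2 && length(clade_size) > 0) {
    round(config$target_pi * L / mean(het(clade_size)))
  } else 0L

  ctx <- codon_context(annotation, contig_id)
  ref_chars <- strsplit(annotation$contigs[[1]], "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  tb <- codon_tables()

  taken <- logical(L)
  pos <- integer(M); alt <- character(M); class <- character(M)
  node <- integer(M)
  resampled <- 0L
  m <- 0L
  while (m < M) {
    s <- sample.int(L, 1)
    if (taken[s]) { resampled <- resampled + 1L; next }
    if (ctx$gene_idx[s] > 0) {
      want <- if (stats::runif(1) < config$ns_fraction) "N" else "S"
      key <- paste0(ctx$codon_at[s], ctx$off_at[s])
      alts <- if (want == "S") tb$syn_alts[[key]] else tb$nonsyn_alts[[key]]
      if (length(alts) == 0) { resampled <- resampled + 1L; next }
      a <- if (length(alts) == 1) alts else sample(alts, 1)
      if (ctx$strand_at[s] == "-") a <- unname(comp[a])
      cls <- want
    } else {
      a <- sample(setdiff(BASES, ref_chars[s]), 1)
      cls <- "noncoding"
    }
    m <- m + 1L
    taken[s] <- TRUE
    pos[m] <- s; alt[m] <- a; class[m] <- cls
    node[m] <- sample.int(H - 1, 1) + 1L
  }
  if (resampled > 0) sp_log("simulate", resampled, " mutation placements resampled")

  carriers <- matrix(FALSE, nrow = M, ncol = H)
  for (i in seq_len(M)) carriers[i, ] <- clade[[node[i] - 1L]]

  # segment reassortment: recomb_rate events expected per haplotype, each
  # event swapping a random 0.5-5 kb segment between two haplotypes
  n_events <- stats::rpois(1, config$recomb_rate * H / 2)
  for (e in seq_len(n_events)) {
    pair <- sample.int(H, 2)
    start <- sample.int(L, 1)
    len <- round(stats::runif(1, 500, 5000))
    in_seg <- pos >= start & pos <= min(L, start + len - 1)
    tmp <- carriers[in_seg, pair[1]]
    carriers[in_seg, pair[1]] <- carriers[in_seg, pair[2]]
    carriers[in_seg, pair[2]] <- tmp
  }

  ord <- order(pos[seq_len(M)])
  mutations <- data.frame(
    species = rep(annotation$species_id, M), contig = rep(contig_id, M),
    pos = pos[ord], ref = ref_chars[pos[ord]], alt = alt[ord],
    class = class[ord], derived_count = rowSums(carriers)[ord],
    stringsAsFactors = FALSE
  )
  carriers <- carriers[ord, , drop = FALSE]

  truth <- structure(list(
    annotation = annotation, config = config, mutations = mutations,
    carriers = carriers, n_recomb_events = n_events,
    pi_uniform = sum(het(rowSums(carriers))) / L,
    freqs = NULL, realized_pi = NULL, true_fst = NULL
  ), class = "sim_truth")
  truth
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(paste0("sim_truth: %d haplotypes, %d mutations over %s bp, ",
                     "uniform-weight pi = %.4g\n"),
              x$config$n_haplotypes, nrow(x$mutations),
              format(nchar(x$annotation$contigs[[1]]), big.mark = ","),
              x$pi_uniform))
  if (!is.null(x$freqs)) {
    cat(sprintf("  %d populations assigned (dirichlet alpha = %s)\n",
                ncol(x$freqs), format(x$config$dirichlet_alpha)))
  }
  invisible(x)
}

#' Haplotype alleles at every mutated site
#'
#' @param truth a \code{sim_truth}
#' @return character matrix (mutated sites x haplotypes)
#' @export
haplotype_alleles <- function(truth) {
  M <- nrow(truth$mutations)
  out <- matrix(rep(truth$mutations$ref, truth$config$n_haplotypes),
                nrow = M)
  out[truth$carriers] <- rep(truth$mutations$alt,
                             truth$config$n_haplotypes)[truth$carriers]
  rownames(out) <- truth$mutations$pos
  out
}

#' Full haplotype sequences
#'
#' @param truth a \code{sim_truth}
#' @return character vector of \code{n_haplotypes} genome sequences
#' @export
haplotype_seqs <- function(truth) {
  ref <- strsplit(truth$annotation$contigs[[1]], "")[[1]]
  vapply(seq_len(truth$config$n_haplotypes), function(h) {
    x <- ref
    hit <- truth$carriers[, h]
    x[truth$mutations$pos[hit]] <- truth$mutations$alt[hit]
    paste(x, collapse = "")
  }, character(1))
}

#' Assign per-population haplotype frequencies
#'
#' Each population receives a haplotype frequency vector drawn from a
#' symmetric Dirichlet with concentration \code{dirichlet_alpha}; smaller
#' alpha concentrates mass on few haplotypes and therefore raises expected
#' between-population F_ST. \code{alpha = Inf} yields identical (uniform)
#' vectors and true F_ST 0 everywhere. The truth object gains the frequency
#' matrix, realized per-population diversity and the per-site true Hudson
#' F_ST for every population pair computed from the true allele frequencies.
#'
#' @param truth a \code{sim_truth}
#' @param config a \code{\link{sim_config}}
#' @return the augmented \code{sim_truth}
#' @export
assign_population_frequencies <- function(truth, config = truth$config) {
  H <- config$n_haplotypes
  P <- config$n_populations
  set.seed(stage_seed(config$seed, 2L))
  freqs <- if (is.infinite(config$dirichlet_alpha)) {
    matrix(1 / H, nrow = H, ncol = P)
  } else {
    g <- matrix(stats::rgamma(H * P, shape = config$dirichlet_alpha, rate = 1),
                nrow = H)
    sweep(g, 2, colSums(g), "/")
  }
  colnames(freqs) <- sprintf("pop_%d", seq_len(P))
  truth$freqs <- freqs
  truth$realized_pi <- truth_pi(truth)
  truth$true_fst <- truth_fst(truth)
  truth
}

#' Recompute realized per-population diversity from stored truth
#'
#' Diversity of population k is \code{sum_m 2 p_mk (1 - p_mk) / L} where
#' \code{p_mk} is the true derived-allele frequency of mutation m, i.e. the
#' expected heterozygosity under sampling reads with replacement; the "ALL"
#' entry uses the mean frequency across populations, matching equal-depth
#' pooling.
#'
#' @param truth a \code{sim_truth} with frequencies assigned
#' @return named numeric vector over populations plus "ALL"
#' @export
truth_pi <- function(truth) {
  assert_that(!is.null(truth$freqs), "assign_population_frequencies first")
  L <- nchar(truth$annotation$contigs[[1]])
  p <- crossprod(t(truth$carriers * 1), truth$freqs)  # M x P derived freq
  p <- cbind(p, ALL = rowMeans(p))
  colSums(2 * p * (1 - p)) / L
}

#' Recompute per-site true F_ST for every population pair
#'
#' Hudson's estimator in its population-frequency (infinite sample size)
#' form: \code{1 - Hw/Hb} with \code{Hw = p1(1-p1) + p2(1-p2)} and
#' \code{Hb = p1(1-p2) + p2(1-p1)}; sites with \code{Hb = 0} are NA.
#'
#' @param truth a \code{sim_truth} with frequencies assigned
#' @return data.frame pop_a, pop_b, pos, fst
#' @export
truth_fst <- function(truth) {
  assert_that(!is.null(truth$freqs), "assign_population_frequencies first")
  p <- crossprod(t(truth$carriers * 1), truth$freqs)
  pops <- colnames(truth$freqs)
  out <- list()
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (j <= i) next
    p1 <- p[, i]; p2 <- p[, j]
    hw <- p1 * (1 - p1) + p2 * (1 - p2)
    hb <- p1 * (1 - p2) + p2 * (1 - p1)
    fst <- ifelse(hb == 0, NA_real_, 1 - hw / hb)
    out[[length(out) + 1]] <- data.frame(
      pop_a = pops[i], pop_b = pops[j], pos = truth$mutations$pos, fst = fst,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Emit per-sample site counts from the simulated community
#'
#' For every sample and site, depth is Poisson(\code{coverage_mean}) (negative
#' binomial if \code{overdispersion > 0}); each read draws a haplotype by the
#' sample population's frequencies and is miscalled to one of the other three
#' bases uniformly with probability \code{error_rate}. Deterministic given the
#' config seed. Samples are named \code{<population>_s<j>}.
#'
#' @param truth a \code{sim_truth} with frequencies assigned
#' @param config a \code{\link{sim_config}}
#' @param samples_per_population samples emitted per population
#' @return sitecounts data.table (species contig pos ref sample nA nC nG nT)
#' @export
emit_site_counts <- function(truth, config = truth$config,
                             samples_per_population = config$samples_per_population) {
  assert_that(!is.null(truth$freqs), "assign_population_frequencies first")
  set.seed(stage_seed(config$seed, 3L))
  L <- nchar(truth$annotation$contigs[[1]])
  ref_chars <- strsplit(truth$annotation$contigs[[1]], "")[[1]]
  ref_idx <- match(ref_chars, BASES)
  p_alt_site <- crossprod(t(truth$carriers * 1), truth$freqs)  # M x P
  alt_idx_mut <- match(truth$mutations$alt, BASES)
  e <- config$error_rate
  # bases other than b, for the error redistribution
  triples <- t(vapply(1:4, function(b) setdiff(1:4, b), integer(3)))
  out <- vector("list", ncol(truth$freqs) * samples_per_population)
  k <- 0
  for (popi in seq_len(ncol(truth$freqs))) {
    pop <- colnames(truth$freqs)[popi]
    p_alt <- numeric(L)
    p_alt[truth$mutations$pos] <- p_alt_site[, popi]
    alt_idx <- ref_idx
    alt_idx[truth$mutations$pos] <- alt_idx_mut
    for (si in seq_len(samples_per_population)) {
      d <- if (config$overdispersion > 0) {
        stats::rnbinom(L, mu = config$coverage_mean, size = 1 / config$overdispersion)
      } else {
        stats::rpois(L, config$coverage_mean)
      }
      a <- stats::rbinom(L, d, p_alt)
      r <- d - a
      er <- stats::rbinom(L, r, e)
      ea <- stats::rbinom(L, a, e)
      counts <- matrix(0L, nrow = L, ncol = 4)
      idx <- cbind(seq_len(L), ref_idx)
      counts[idx] <- counts[idx] + (r - er)
      idx <- cbind(seq_len(L), alt_idx)
      counts[idx] <- counts[idx] + (a - ea)
      for (src in list(list(n = er, from = ref_idx), list(n = ea, from = alt_idx))) {
        x1 <- stats::rbinom(L, src$n, 1 / 3)
        x2 <- stats::rbinom(L, src$n - x1, 1 / 2)
        x3 <- src$n - x1 - x2
        oth <- triples[src$from, , drop = FALSE]
        for (jj in 1:3) {
          xj <- list(x1, x2, x3)[[jj]]
          idx <- cbind(seq_len(L), oth[, jj])
          counts[idx] <- counts[idx] + xj
        }
      }
      k <- k + 1
      out[[k]] <- data.table::data.table(
        species = truth$annotation$species_id, contig = "contig_1",
        pos = seq_len(L), ref = ref_chars,
        sample = sprintf("%s_s%d", pop, si),
        nA = counts[, 1], nC = counts[, 2], nG = counts[, 3], nT = counts[, 4]
      )
    }
  }
  data.table::rbindlist(out)
}

#' Sample sheet for a simulated community
#'
#' @param truth a \code{sim_truth} with frequencies assigned
#' @param samples_per_population samples per population, matching
#'   \code{\link{emit_site_counts}}
#' @return data.frame with sample and population columns
#' @export
sim_sample_metadata <- function(truth,
                                samples_per_population = truth$config$samples_per_population) {
  pops <- colnames(truth$freqs)
  data.frame(
    sample = as.vector(t(outer(pops, seq_len(samples_per_population),
                               function(p, s) sprintf("%s_s%d", p, s)))),
    population = rep(pops, each = samples_per_population),
    stringsAsFactors = FALSE
  )
}

#' Emit read fragments for linkage analysis
#'
#' Each fragment is one contiguous span of \code{fragment_length} bp standing
#' for a short-insert read pair; it carries the haplotype it was drawn from,
#' so physically linked alleles can be observed jointly. Fragment count per
#' sample is set to reach \code{coverage_mean} on average.
#'
#' @inheritParams emit_site_counts
#' @return data.table with sample, population, hap, start, end
#' @export
emit_reads <- function(truth, config = truth$config,
                       samples_per_population = config$samples_per_population) {
  assert_that(!is.null(truth$freqs), "assign_population_frequencies first")
  set.seed(stage_seed(config$seed, 4L))
  L <- nchar(truth$annotation$contigs[[1]])
  flen <- config$fragment_length
  n_reads <- ceiling(config$coverage_mean * L / flen)
  out <- list()
  for (popi in seq_len(ncol(truth$freqs))) {
    pop <- colnames(truth$freqs)[popi]
    for (si in seq_len(samples_per_population)) {
      hap <- sample.int(config$n_haplotypes, n_reads, replace = TRUE,
                        prob = truth$freqs[, popi])
      start <- sample.int(L - flen + 1, n_reads, replace = TRUE)
      out[[length(out) + 1]] <- data.table::data.table(
        sample = sprintf("%s_s%d", pop, si), population = pop,
        hap = hap, start = start, end = start + flen - 1L
      )
    }
  }
  data.table::rbindlist(out)
}

#' Write simulation truth to the fixed truth schema
#'
#' @param truth a \code{sim_truth}
#' @param path output TSV
#' @export
write_truth <- function(truth, path) {
  write_table(truth$mutations, path, "truth")
}
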