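# Shared fixtures, generated in code and cached per test run.

.fixture_env <- new.env()

# small community used by several files: 12 kb, 10 genes, 12 haplotypes,
# 2 populations x 2 samples, no sequencing error
small_sim <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- sim_config(seed = 42, genome_length = 12000, n_genes = 10,
                      n_haplotypes = 12, target_pi = 0.01, ns_fraction = 0.3,
                      recomb_rate = 0, n_populations = 2, dirichlet_alpha = 1,
                      coverage_mean = 40, error_rate = 0,
                      samples_per_population = 2)
    ann <- simulate_reference(cfg)
    truth <- assign_population_frequencies(simulate_haplotypes(ann, cfg))
    counts <- emit_site_counts(truth)
    md <- sim_sample_metadata(truth)
    pooled <- pool_populations(counts, md)
    snps <- suppressMessages(call_snps(pooled, ann))
    .fixture_env$small <- list(cfg = cfg, ann = ann, truth = truth,
                               counts = counts, md = md, pooled = pooled,
                               snps = snps)
  }
  .fixture_env$small
}

# hand-built two-gene annotation (one gene per strand) for codon logic tests
toy_annotation <- function() {
  # plus gene 1..9: ATG TTT TAA ; minus gene 16..24 whose coding strand reads
  # ATG CCC TAA (genomic segment = reverse complement TTA GGG CAT)
  contig <- paste0("ATGTTTTAA", "ACGTAC", "TTAGGGCAT", "GC")
  genes <- data.frame(
    gene_id = c("gplus", "gminus"), contig_id = "c1",
    start = c(1L, 16L), end = c(9L, 24L), strand = c("+", "-"),
    product = NA_character_, gene_class = "other",
    stringsAsFactors = FALSE
  )
  genome_annotation("toy", c(c1 = contig), genes)
}

# write a FASTA + GFF3 pair for reader tests
write_ref_files <- function(ann, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fa <- file.path(dir, "ref.fa")
  gff <- file.path(dir, "ref.gff")
  writeLines(unlist(lapply(names(ann$contigs), function(ctg) {
    c(paste0(">", ctg), ann$contigs[[ctg]])
  })), fa)
  g <- ann$genes
  writeLines(c("##gff-version 3",
               sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;gene_class=%s",
                       g$contig_id, g$start, g$end, g$strand, g$gene_id,
                       g$gene_class)), gff)
  list(fasta = fa, gff = gff)
}

# independent oracle: mean pairwise per-site difference between haplotype
# sequences, by direct character comparison over all distinct pairs
pairwise_pi_oracle <- function(seqs) {
  H <- length(seqs)
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  tot <- 0
  for (i in seq_len(H - 1)) for (j in (i + 1):H) {
    tot <- tot + sum(chars[[i]] != chars[[j]])
  }
  tot / choose(H, 2) / nchar(seqs[1])
}

# independent oracle for per-site pi: enumerate all read pairs
pi_site_oracle <- function(counts) {
  reads <- rep(BASES <- c("A", "C", "G", "T"), counts)
  n <- length(reads)
  if (n < 2) return(NA_real_)
  diff <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (reads[i] != reads[j]) diff <- diff + 1
  }
  diff / choose(n, 2)
}
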