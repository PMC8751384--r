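test_that("site F_ST matches hand evaluations of the Hudson estimator", {
  # fixed difference
  expect_equal(site_fst(1, 1e6, 0, 1e6)$fst, 1)
  # equal frequencies: the small-sample correction pushes the raw value just
  # below 0, clamped to 0
  expect_equal(site_fst(0.4, 1e6, 0.4, 1e6)$fst, 0, tolerance = 1e-4)
  # p1=0.9, p2=0.1 at large depth: 1 - 0.18/0.82
  expect_equal(site_fst(0.9, 1e6, 0.1, 1e6)$fst, 1 - 0.18 / 0.82,
               tolerance = 1e-4)
  # coverage gate: below 20x in either population the site is skipped
  expect_true(is.na(suppressMessages(site_fst(0.9, 19, 0.1, 100))$fst))
  expect_false(is.na(site_fst(0.9, 20, 0.1, 20)$fst))
})

test_that("site F_ST is symmetric and invariant to allele relabeling", {
  set.seed(31)
  for (i in 1:50) {
    p1 <- runif(1); p2 <- runif(1)
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    a <- site_fst(p1, n1, p2, n2)$fst
    b <- site_fst(p2, n2, p1, n1)$fst          # population order
    c_ <- site_fst(1 - p1, n1, 1 - p2, n2)$fst # allele labels
    if (is.na(a)) { expect_true(is.na(b) && is.na(c_)); next }
    expect_equal(a, b, tolerance = 1e-12)
    expect_equal(a, c_, tolerance = 1e-12)
  }
})

test_that("gene F_ST is a clamped ratio of averages reducing to site F_ST", {
  one <- site_fst(0.9, 100, 0.1, 100)
  expect_equal(gene_fst(one), one$fst, tolerance = 1e-12)
  flat <- site_fst(c(0.3, 0.6), c(100, 80), c(0.3, 0.6), c(100, 80))
  expect_equal(suppressMessages(gene_fst(flat)), 0)  # clamped at 0
  expect_true(is.na(gene_fst(flat[0, ])))
})

test_that("gene F_ST recovers truth for populations fixed on different strains", {
  cfg <- sim_config(seed = 17, genome_length = 9000, n_genes = 8,
                    n_haplotypes = 4, target_pi = 0.01, n_populations = 2,
                    error_rate = 0, coverage_mean = 60,
                    samples_per_population = 1)
  ann <- simulate_reference(cfg)
  truth <- suppressMessages(simulate_haplotypes(ann, cfg))
  H <- cfg$n_haplotypes
  # pop_1 fixed for haplotypes {1,2}; pop_2 fixed for {3,4}
  f <- matrix(0, nrow = H, ncol = 2, dimnames = list(NULL, c("pop_1", "pop_2")))
  f[1:2, 1] <- 0.5; f[3:4, 2] <- 0.5
  truth$freqs <- f
  truth$realized_pi <- truth_pi(truth)
  truth$true_fst <- truth_fst(truth)
  pooled <- suppressMessages(pool_populations(emit_site_counts(truth),
                                              sim_sample_metadata(truth, 1)))
  got <- suppressMessages(fst_genes(pooled, ann, min_cov = 20))
  # truth gene values: ratio of averages over the same estimator's components
  tf <- truth$true_fst
  for (k in seq_len(nrow(got))) {
    g <- ann$genes[ann$genes$gene_id == got$gene_id[k], ]
    sel <- tf$pos >= g$start & tf$pos <= g$end & !is.na(tf$fst)
    if (sum(sel) == 0 || is.na(got$fst[k])) next
    p <- crossprod(t(truth$carriers * 1), truth$freqs)
    p1 <- p[sel, 1]; p2 <- p[sel, 2]
    hw <- p1 * (1 - p1) + p2 * (1 - p2)
    hb <- p1 * (1 - p2) + p2 * (1 - p1)
    truth_gene <- 1 - sum(hw) / sum(hb)
    expect_lt(abs(got$fst[k] - truth_gene), 0.12)
  }
  expect_gt(mean(got$fst, na.rm = TRUE), 0.4)  # strong differentiation
})

test_that("estimated genome F_ST rises as dirichlet alpha falls", {
  mean_est_fst <- function(alpha, seed) {
    cfg <- sim_config(seed = seed, genome_length = 6000, n_genes = 5,
                      dirichlet_alpha = alpha, n_populations = 2,
                      error_rate = 0, coverage_mean = 50,
                      samples_per_population = 1)
    ann <- simulate_reference(cfg)
    truth <- suppressMessages(
      assign_population_frequencies(simulate_haplotypes(ann, cfg)))
    pooled <- suppressMessages(pool_populations(emit_site_counts(truth),
                                                sim_sample_metadata(truth, 1)))
    g <- suppressMessages(fst_genes(pooled, ann, min_cov = 20))
    mean(g$fst, na.rm = TRUE)
  }
  seeds <- 1:3
  lo <- mean(vapply(seeds, function(s) mean_est_fst(0.1, s), numeric(1)))
  mid <- mean(vapply(seeds, function(s) mean_est_fst(1, s), numeric(1)))
  hi <- mean(vapply(seeds, function(s) mean_est_fst(10, s), numeric(1)))
  expect_gt(lo, mid)
  expect_gt(mid, hi)
})

fake_gene_table <- function(fst_vec) {
  data.frame(gene_id = sprintf("g%02d", seq_along(fst_vec)), contig = "c1",
             start = seq_along(fst_vec) * 1000L, fst = fst_vec,
             stringsAsFactors = FALSE)
}

test_that("locus detection needs a run of jointly extreme genes", {
  # all genes equal: zero loci
  flat <- fake_gene_table(rep(0.05, 40))
  sp <- data.frame(gene_id = rep(flat$gene_id, each = 5),
                   pi = runif(200, 0, 0.01))
  sd_ <- data.frame(gene_id = rep(flat$gene_id, each = 5),
                    d_prime = runif(200, 0.5, 1))
  expect_equal(nrow(high_fst_loci(flat, sp, sd_)), 0)

  # constructed run of 3 genes at 0.9 over a 0.05 +/- 0.02 background
  set.seed(12)
  fst <- pmax(rnorm(40, 0.05, 0.02), 0)
  fst[20:22] <- 0.9
  gt <- fake_gene_table(fst)
  loci <- high_fst_loci(gt, sp, sd_)
  expect_equal(nrow(loci), 1)
  expect_identical(loci$first_gene, "g20")
  expect_identical(loci$last_gene, "g22")

  # gene order within the table must not matter
  shuffle <- gt[sample.int(nrow(gt)), ]
  expect_equal(high_fst_loci(shuffle, sp, sd_)[, c("first_gene", "last_gene")],
               loci[, c("first_gene", "last_gene")])
  expect_error(high_fst_loci(gt[1:10, ], sp, sd_), "fewer than 30")
})

test_that("sweep flags require the full high-FST/low-pi/high-D' signature", {
  loci <- data.frame(contig = "c1", first_gene = "g1", last_gene = "g3",
                     n_genes = 3L, mean_fst = 0.9,
                     mean_pi = c(0.02, 0.001), mean_dprime = c(0.99, 0.99),
                     linkage_p = 0.001, diversity_p = 0.001)
  got <- sweep_candidates(loci, genome_mean_pi = 0.01,
                          genome_mean_dprime = 0.8)
  expect_identical(got$sweep_flag, c(FALSE, TRUE))  # high pi never sweeps
  empty <- sweep_candidates(loci[0, ], 0.01, 0.8)
  expect_equal(nrow(empty), 0)
})

test_that("local clonal replacements are detected as a sweep, others are not", {
  flagged <- logical(5)
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, genome_length = 36000, n_genes = 36,
                      n_haplotypes = 12, target_pi = 0.012, recomb_rate = 150,
                      n_populations = 2, dirichlet_alpha = Inf,
                      error_rate = 0, coverage_mean = 50,
                      samples_per_population = 1)
    ann <- simulate_reference(cfg)
    truth <- suppressMessages(
      assign_population_frequencies(simulate_haplotypes(ann, cfg)))
    counts <- emit_site_counts(truth)
    reads <- emit_reads(truth)
    # sweep region: genes 16-18; each population is locally taken over by
    # one strain, the two strains being close relatives (the classic local
    # sweep signature: the locus keeps only the between-strain differences)
    region <- c(ann$genes$start[16], ann$genes$end[19])
    alle <- haplotype_alleles(truth)
    mpos <- truth$mutations$pos
    in_region <- mpos >= region[1] & mpos <= region[2]
    per_gene_ok <- function(h) {
      diffs <- mpos[in_region & alle[, 1] != alle[, h]]
      all(vapply(16:19, function(g) {
        sum(diffs >= ann$genes$start[g] & diffs <= ann$genes$end[g]) >= 2
      }, logical(1)))
    }
    n_diff <- vapply(2:12, function(h) sum(in_region & alle[, 1] != alle[, h]),
                     numeric(1))
    ok <- which(vapply(2:12, per_gene_ok, logical(1)))
    hb <- (2:12)[ok][which.min(abs(n_diff[ok] - 25))]
    haps <- lapply(c(1, hb),
                   function(h) strsplit(haplotype_seqs(truth)[h], "")[[1]])
    for (pp in 1:2) {
      in_reg <- counts$pos >= region[1] & counts$pos <= region[2] &
        counts$sample == sprintf("pop_%d_s1", pp)
      cov_reg <- with(counts[in_reg], nA + nC + nG + nT)
      for (b in c("A", "C", "G", "T")) {
        counts[[paste0("n", b)]][which(in_reg)] <-
          ifelse(haps[[pp]][counts$pos[in_reg]] == b, cov_reg, 0L)
      }
      reads$hap[reads$population == sprintf("pop_%d", pp) &
                  reads$start <= region[2] & reads$end >= region[1]] <-
        c(1L, hb)[pp]
    }
    pooled <- suppressMessages(pool_populations(counts,
                                                sim_sample_metadata(truth, 1)))
    snps <- suppressMessages(call_snps(pooled, ann))
    fst_g <- suppressMessages(fst_genes(pooled, ann, min_cov = 20))
    # site-level inputs through the package machinery
    all_rows <- pooled[pooled$sample == "ALL"]
    cnt <- as.matrix(all_rows[, c("nA", "nC", "nG", "nT")])
    ctx <- strainpop:::codon_context(ann, "contig_1")
    gi <- ctx$gene_idx[all_rows$pos]
    site_pi <- data.frame(gene_id = ann$genes$gene_id[pmax(gi, 1L)],
                          pi = pi_site(cnt))[gi > 0, ]
    prs <- suppressMessages(collect_pair_observations(
      reads, truth, snps, max_pairs = 30000, by_population = FALSE,
      seed = seed))
    gp <- ctx$gene_idx[prs$site_a]
    site_d <- data.frame(gene_id = ann$genes$gene_id[pmax(gp, 1L)],
                         d_prime = prs$d_prime)[gp > 0, ]
    gt <- data.frame(gene_id = fst_g$gene_id,
                     contig = "contig_1",
                     start = ann$genes$start[match(fst_g$gene_id,
                                                   ann$genes$gene_id)],
                     fst = fst_g$fst)
    loci <- high_fst_loci(gt, site_pi, site_d)
    loci <- sweep_candidates(loci, mean(site_pi$pi, na.rm = TRUE),
                             mean(site_d$d_prime, na.rm = TRUE))
    # the constructed region is always detected as a high-FST locus with the
    # diversity arm of the sweep signature
    in_region_locus <- loci$first_gene %in% ann$genes$gene_id[15:19]
    expect_true(any(in_region_locus))
    expect_true(all(loci$diversity_p[in_region_locus] < 0.05))
    expect_true(all(loci$mean_pi[in_region_locus] <
                      mean(site_pi$pi, na.rm = TRUE)))
    # a sweep flag is never raised anywhere else
    expect_false(any(loci$sweep_flag & !in_region_locus))
    flagged[seed] <- any(loci$sweep_flag & in_region_locus)
  }
  # the linkage arm (locus D' above a genuinely recombined background) is the
  # limiting signal, as in real data where most high-FST loci fail the full
  # sweep battery; require it in at least 4 of 5 replicates
  expect_gte(sum(flagged), 4)
})

test_that("allele-profile dissimilarity and the Mantel test behave", {
  m <- matrix(c(0.9, 0.8, 0.9, 0.8, 0.9, 0.3), nrow = 2,
              dimnames = list(c("c1:5", "c1:9"), c("w1", "w2", "w3")))
  d <- allele_profile_dissimilarity(m)
  expect_equal(d["w1", "w2"], 0)       # identical binarized profiles
  expect_equal(d["w1", "w3"], 0.5)     # shares one of two present alleles
  expect_true(isSymmetric(d))

  set.seed(5)
  x <- as.matrix(dist(matrix(runif(20), ncol = 2)))
  res <- mantel_test(x, x, n_perm = 199, seed = 2)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 200)
  # agreement with the community-standard implementation on the statistic
  y <- as.matrix(dist(matrix(runif(20), ncol = 2)))
  ours <- mantel_test(x, y, n_perm = 99, seed = 3)
  ref <- vegan::mantel(x, y, permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_error(mantel_test(x, y[1:8, 1:8]), "square")
})
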